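# Shared fixtures: small libraries and fast simulation configs.

small_library <- function() enumerate_library(c(14L, 22L), c(0L, 6L))

# a three-compound freshwater profile for noiseless screening checks
three_compound_profiles <- function() {
  fresh <- c("14:0 dhCA" = 0.5, "18:3 dhCA" = 0.3, "22:6 dhCA" = 0.2)
  marine <- c("14:0 CA" = 0.4, "22:6 dhCA" = 0.6)
  list(freshwater = fresh, marine = marine)
}

noiseless_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, mz_sd = 0, area_sigma = 0, background_rate = 0,
             allometry = list(slope = 0.296, intercept = 0.25, sigma = 0),
             ...)
}

fast_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_sites = c(freshwater = 3L, marine = 2L),
             n_individuals = 4L, ...)
}

# hits data.frame builder for transition-selection tests
make_hits <- function(intensity, mz = seq_along(intensity) + 660,
                      annotation = paste0("cmpd", seq_along(intensity)),
                      sample = "s1") {
  data.frame(sample = sample, mz = mz, channel = 432.3,
             intensity = intensity, annotation = annotation,
             scaffold = "dhCA", acyl = "14:0", mass_error = 0,
             stringsAsFactors = FALSE)
}
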
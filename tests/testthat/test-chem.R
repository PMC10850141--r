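# Chemistry core: formula arithmetic, homolog enumeration, annotation.

test_that("monoisotopic masses reproduce the diagnostic fragment m/z", {
  expect_equal(round(monoisotopic_mass("C2H6NO3S", "cation"), 1), 124.0)
  expect_equal(monoisotopic_mass("C22H42NO5S", "cation"), 432.278,
               tolerance = 0.001)
  expect_equal(round(monoisotopic_mass("C22H40NO5S", "cation")), 430)
  expect_equal(round(monoisotopic_mass("SO3", "cation")), 80)
  expect_identical(monoisotopic_mass(character_formula <- ""), 0)
  expect_identical(monoisotopic_mass(integer(0)), 0)
})

test_that("cation mode subtracts exactly one electron mass", {
  d <- monoisotopic_mass("C22H42NO5S") - monoisotopic_mass("C22H42NO5S", "cation")
  expect_lt(abs(d - 0.000548579909), 1e-10)
})

test_that("unknown element symbols fail loudly by name", {
  expect_error(monoisotopic_mass(c(C = 1L, Xx = 2L)), "Xx")
  expect_error(monoisotopic_mass("C2Qq3"), "Qq")
})

test_that("formula map and string-parser paths agree (two-path oracle)", {
  cases <- list(
    list(str = "C22H42NO5S", map = c(C = 22L, H = 42L, N = 1L, O = 5L, S = 1L)),
    list(str = "C2H6NO3S",  map = c(C = 2L, H = 6L, N = 1L, O = 3L, S = 1L)),
    list(str = "H2O",       map = c(H = 2L, O = 1L)),
    list(str = "SO3",       map = c(S = 1L, O = 3L))
  )
  for (cs in cases) {
    expect_identical(parse_formula(cs$str)[names(cs$map)], cs$map)
    expect_equal(monoisotopic_mass(cs$str), monoisotopic_mass(cs$map))
  }
})

test_that("free fatty acid formulas follow CnH(2n-2d)O2", {
  expect_identical(fatty_acid_formula("14:0"), c(C = 14L, H = 28L, O = 2L))
  expect_identical(fatty_acid_formula("2:0"), c(C = 2L, H = 4L, O = 2L))
  expect_identical(fatty_acid_formula("22:6"), c(C = 22L, H = 32L, O = 2L))
})

test_that("invalid acyls are rejected", {
  expect_error(fatty_acyl(1, 0), "at least 2 carbons")
  expect_error(fatty_acyl(2, 1), "double bond")
  expect_error(fatty_acyl(14, 7), "double bond")
  expect_error(parse_acyl("14"), "C:D")
  # label round-trips
  a <- parse_acyl("18:4")
  expect_identical(a$label, "18:4")
  expect_identical(parse_acyl(a$label)$carbons, 18L)
})

test_that("precursor m/z reproduces reported values and derived sums", {
  expect_equal(round(precursor_mz("dhCA", "14:0"), 1), 660.5)
  expect_equal(round(precursor_mz("CA", "14:0"), 1), 658.5)
  expect_equal(round(precursor_mz("dhCA", "15:1"), 1), 672.5)
  expect_equal(precursor_mz("dhCA", "22:6"), 760.52, tolerance = 0.01)
})

test_that("scaffold pair and homolog spacing invariants hold exactly", {
  two_h <- 2 * 1.00782503207
  for (acyl in c("14:0", "16:1", "18:4", "20:5", "22:6")) {
    expect_equal(precursor_mz("dhCA", acyl) - precursor_mz("CA", acyl),
                 two_h, tolerance = 1e-10)
  }
  # one double bond removes H2; one CH2 adds 14.01565
  expect_equal(precursor_mz("dhCA", "18:3") - precursor_mz("dhCA", "18:4"),
               2.01565, tolerance = 1e-4)
  expect_equal(precursor_mz("CA", "19:2") - precursor_mz("CA", "18:2"),
               14.01565, tolerance = 1e-4)
  # dhCA fragment is the CA fragment plus two hydrogens
  sc <- copepodamide_scaffolds()
  expect_equal(sc$dhCA$diagnostic_product_mz - sc$CA$diagnostic_product_mz,
               two_h, tolerance = 1e-10)
})

test_that("library enumeration matches the combinatorial count oracle", {
  lib <- enumerate_library(c(14L, 14L), c(0L, 0L))
  expect_equal(nrow(lib), 2L)
  expect_equal(sort(round(lib$precursor_mz, 2)), c(658.47, 660.49))

  # oracle: per chain length n, valid d spans unsat_range capped at (n-2)/2
  count_oracle <- function(chains, unsat) {
    2L * sum(vapply(seq(chains[1], chains[2]), function(n) {
      dmax <- min(unsat[2], (n - 2L) %/% 2L)
      max(0L, dmax - unsat[1] + 1L)
    }, integer(1)))
  }
  for (rng in list(list(c(14L, 22L), c(0L, 6L)), list(c(12L, 24L), c(0L, 6L)),
                   list(c(2L, 6L), c(0L, 3L)))) {
    lib <- enumerate_library(rng[[1]], rng[[2]])
    expect_equal(nrow(lib), count_oracle(rng[[1]], rng[[2]]))
  }

  expect_equal(nrow(enumerate_library(c(2L, 2L), c(0L, 0L), "dhCA")), 1L)
  # ranges excluding every valid acyl give an empty library
  expect_equal(nrow(enumerate_library(c(2L, 2L), c(1L, 6L))), 0L)
  # sorted by scaffold, carbons, double bonds
  lib <- enumerate_library(c(14L, 16L), c(0L, 2L))
  expect_false(is.unsorted(order(lib$scaffold, lib$carbons, lib$double_bonds)))
})

test_that("assign_acyl resolves reported precursor/product pairs", {
  hit <- assign_acyl(660.5, 432.3, 0.3)
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$name, "14:0 dhCA")

  miss <- assign_acyl(500.0, 432.3, 0.3)
  expect_equal(nrow(miss), 0L)
  expect_identical(attr(miss, "status"), "no acyl")

  best <- assign_acyl(760.5, 432.3, 0.3)
  expect_identical(best$name[1], "22:6 dhCA")

  nos <- assign_acyl(660.5, 300.0, 0.3)
  expect_equal(nrow(nos), 0L)
  expect_identical(attr(nos, "status"), "no scaffold")

  expect_error(assign_acyl(400.0, 432.3, 0.3), "neutral loss")
})

test_that("annotation round-trips over the whole default library", {
  lib <- enumerate_library()
  for (i in seq_len(nrow(lib))) {
    cand <- assign_acyl(lib$precursor_mz[i], lib$product_mz[i], 0.3,
                        library = lib)
    expect_identical(cand$name[1], lib$name[i])
    # no collisions within 0.3 Da in the default library: candidates beyond
    # the self-match would be reported here
    expect_equal(nrow(cand), 1L)
    expect_lt(abs(cand$mass_error[1]), 1e-9)
  }
})

test_that("transition lists carry scaffold and confirmatory products", {
  one <- enumerate_library(c(14L, 14L), c(0L, 0L), "dhCA")
  expect_equal(nrow(build_transitions(one)), 1L)
  tr3 <- build_transitions(one, include_confirmatory = TRUE)
  expect_equal(nrow(tr3), 3L)
  expect_setequal(tr3$kind, c("scaffold", "taurine", "sulfonate"))
  expect_equal(tr3$product_mz[tr3$kind == "taurine"], 124.006, tolerance = 0.001)
  expect_equal(tr3$product_mz[tr3$kind == "sulfonate"], 79.956, tolerance = 0.001)
  expect_true(all(tr3$product_mz < tr3$precursor_mz))

  many <- enumerate_library()[1:35, ]
  trm <- build_transitions(many)
  expect_equal(nrow(trm), 35L)
  expect_true(all(abs(trm$product_mz - 430.26) < 0.05 |
                    abs(trm$product_mz - 432.28) < 0.05))
})

test_that("transition CSV export is vendor-neutral and re-readable", {
  tr <- build_transitions(enumerate_library(c(14L, 15L), c(0L, 1L)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_transitions(tr, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("compound_name", "scaffold", "acyl", "precursor_mz",
                     "product_mz", "kind"))
  expect_equal(back$precursor_mz, round(tr$precursor_mz, 4))
})
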
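# Statistics: Bray-Curtis, PERMANOVA, PERMDISP, nMDS, ANCOVA, ellipses.
# vegan and base isoreg serve as independent oracles where available.

test_that("Bray-Curtis matches hand computations and its invariants", {
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 2, 3), c(1, 2, 3)))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 0), c(0, 1)))), 1)
  expect_equal(as.numeric(bray_curtis(rbind(c(6, 2), c(2, 2)))), 4 / 12)
  set.seed(3)
  x <- matrix(rpois(50, 10), 10, 5)
  d <- as.matrix(bray_curtis(x))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # normalisation rescales rows to relative abundance first
  expect_equal(as.numeric(bray_curtis(rbind(c(2, 2), c(5, 5)), normalise = TRUE)), 0)
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 2))), "negative")
  expect_warning(dz <- bray_curtis(rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))),
                 "all-zero")
  expect_true(is.na(as.matrix(dz)["a", "b"]))
})

test_that("Bray-Curtis agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(8)
  x <- matrix(runif(60, 0, 50), 12, 5)
  expect_equal(as.matrix(bray_curtis(x)),
               as.matrix(vegan::vegdist(x, "bray")), ignore_attr = TRUE)
})

test_that("PERMANOVA matches the exhaustive enumeration oracle on n = 4", {
  # two groups of two, zero within-group and unit between-group distance:
  # 6 distinct labelings, the 2 perfectly separated ones are extreme
  dm <- matrix(1, 4, 4); dm[1, 2] <- dm[2, 1] <- 0; dm[3, 4] <- dm[4, 3] <- 0
  diag(dm) <- 0
  res <- permanova(as.dist(dm), c("a", "a", "b", "b"), exact = TRUE)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$n_perm, 6L)
})

test_that("Monte-Carlo p agrees with full enumeration within binomial error", {
  set.seed(15)
  x <- matrix(runif(32), 8, 4)
  d <- bray_curtis(x)
  g <- rep(c("a", "b"), each = 4)
  exact <- permanova(d, g, exact = TRUE)
  expect_equal(exact$n_perm, 70L)  # choose(8, 4)
  mc <- permanova(d, g, n_perm = 4999, seed = 2)
  tol <- 3 * sqrt(exact$p_value * (1 - exact$p_value) / 4999) + 1 / 4999
  expect_lt(abs(mc$p_value - exact$p_value), max(tol, 0.03))
})

test_that("PERMANOVA F and R2 agree with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(4)
  x <- matrix(rpois(60, 20), 10, 6)
  g <- rep(c("a", "b"), each = 5)
  mine <- permanova(bray_curtis(x), g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(vegan::vegdist(x, "bray") ~ g, permutations = 99)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$df[1], ref$Df[1])
})

test_that("duplicating every sample leaves PERMANOVA R2 unchanged", {
  set.seed(5)
  x <- matrix(runif(40), 8, 5)
  g <- rep(c("a", "b"), each = 4)
  r1 <- permanova(bray_curtis(x), g, n_perm = 9, seed = 1)$r_squared
  r2 <- permanova(bray_curtis(x[rep(1:8, 2), ]), rep(g, 2),
                  n_perm = 9, seed = 1)$r_squared
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("degenerate all-equal distances give an explicit status", {
  dm <- matrix(0, 4, 4)
  res <- permanova(as.dist(dm), c("a", "a", "b", "b"), n_perm = 9)
  expect_true(is.na(res$statistic))
  expect_match(res$status, "degenerate")
  pd <- permdisp(as.dist(dm), c("a", "a", "b", "b"), n_perm = 9)
  expect_match(pd$status, "degenerate")
  expect_true(all(pd$group_dispersion == 0))
})

test_that("PERMDISP centroid distances match betadisper on Euclidean data", {
  skip_if_not_installed("vegan")
  set.seed(2)
  x <- matrix(rnorm(40), 10, 4)
  d <- dist(x)
  g <- rep(c("a", "b"), each = 5)
  mine <- permdisp(d, g, n_perm = 99, seed = 1)
  ref <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(mine$centroid_distances, unname(ref$distances), tolerance = 1e-8)
  expect_equal(mine$statistic, anova(ref)$F[1], tolerance = 1e-8)
  expect_equal(mine$n_negative_eigenvalues, 0L)
})

test_that("PERMDISP detects a 10x dispersion difference", {
  set.seed(6)
  hits <- 0L
  for (r in 1:10) {
    tight <- matrix(rnorm(40, sd = 0.1), 20, 2)
    loose <- matrix(rnorm(40, sd = 1), 20, 2)
    d <- dist(rbind(tight, loose))
    p <- permdisp(d, rep(c("t", "l"), each = 20), n_perm = 199,
                  seed = r)$p_value
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("PAVA matches the isotonic least-squares oracle", {
  expect_equal(pava(c(3, 1, 2)), c(2, 2, 2))
  expect_equal(pava(1:5), 1:5 + 0)
  expect_equal(pava(5:1), rep(3, 5))
  set.seed(10)
  for (i in 1:20) {
    y <- rnorm(sample(2:40, 1))
    expect_equal(pava(y), isoreg(y)$yf, tolerance = 1e-12)
  }
  # integer weights equal replication (weighted oracle by expansion)
  y <- c(4, 1, 3, 2); w <- c(2, 1, 3, 1)
  expanded <- isoreg(rep(y, w))$yf
  expect_equal(rep(pava(y, w), w), expanded, tolerance = 1e-12)
})

test_that("nMDS embeds exactly embeddable configurations at ~zero stress", {
  # three equidistant points
  dm <- matrix(1, 3, 3); diag(dm) <- 0
  res <- nmds(as.dist(dm), k = 2, n_restarts = 2, seed = 1)
  expect_lt(res$stress, 1e-6)
  # distances from a true 2-d configuration are recovered
  set.seed(20)
  x <- matrix(rnorm(24), 12, 2)
  res <- nmds(dist(x), k = 2, n_restarts = 4, seed = 2)
  expect_lt(res$stress, 1e-4)
  expect_true(res$converged)
})

test_that("nMDS stress is comparable to vegan's on a hard problem", {
  skip_if_not_installed("vegan")
  set.seed(30)
  x <- matrix(rpois(120, 15), 12, 10)
  d <- bray_curtis(x)
  mine <- nmds(d, k = 2, n_restarts = 8, seed = 3)
  ref <- vegan::metaMDS(as.dist(as.matrix(d)), k = 2, trace = 0)
  expect_lt(mine$stress, ref$stress + 0.01)
})

test_that("stress-1 is invariant to rotation, translation and scaling", {
  set.seed(31)
  x <- matrix(rnorm(20), 10, 2)
  d <- bray_curtis(matrix(runif(50), 10, 5))
  dvec <- as.matrix(d)[lower.tri(as.matrix(d))]
  stress_of <- function(conf) {
    cd <- as.vector(dist(conf))
    dhat <- copepodamides:::.monotone_fit(dvec, cd)
    copepodamides:::.stress1(cd, dhat)
  }
  s0 <- stress_of(x)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  expect_equal(stress_of(x %*% rot), s0, tolerance = 1e-12)
  expect_equal(stress_of(sweep(x, 2, c(5, -3), "+")), s0, tolerance = 1e-12)
  expect_equal(stress_of(3.7 * x), s0, tolerance = 1e-12)
})

test_that("ANCOVA recovers pure-covariate and pure-group structure", {
  set.seed(40)
  g <- rep(c("a", "b"), each = 15)
  x <- rnorm(30)
  # response equals the covariate: covariate explains everything
  res <- ancova(x, g, x)
  expect_equal(res$terms$partial_eta_sq[res$terms$term == "covariate"], 1)
  expect_lt(res$terms$partial_eta_sq[res$terms$term == "group"], 1e-10)
  # perfectly separated groups with zero residual
  y <- ifelse(g == "a", 1, 5)
  res2 <- suppressWarnings(ancova(y, g, rep(1, 30)))  # constant covariate
  expect_equal(res2$terms$partial_eta_sq[res2$terms$term == "group"], 1)
})

test_that("single-group ANCOVA reduces to simple linear regression", {
  set.seed(41)
  x <- rnorm(20); y <- 1 + 2 * x + rnorm(20, sd = 0.1)
  res <- ancova(y, rep("only", 20), x)
  ref <- lm(y ~ x)
  expect_equal(unname(coef(res$fit)), unname(coef(ref)), tolerance = 1e-12)
  expect_true(is.na(res$interaction_p))
})

test_that("ANCOVA diagnostics: interaction and normality are reported", {
  set.seed(42)
  g <- rep(c("a", "b"), each = 20)
  x <- rnorm(40)
  # different slopes per group: interaction must be detected
  y <- ifelse(g == "a", 2 * x, -2 * x) + rnorm(40, sd = 0.2)
  res <- ancova(y, g, x)
  expect_lt(res$interaction_p, 1e-6)
  expect_true(res$shapiro["p"] > 0 && res$shapiro["p"] <= 1)
})

test_that("centroid ellipses are equivariant and degenerate correctly", {
  set.seed(50)
  pts <- matrix(rnorm(60), 30, 2)
  g <- rep(c("a", "b"), 15)
  e1 <- centroid_ellipses(pts, g)
  e2 <- centroid_ellipses(sweep(pts, 2, c(10, -2), "+"), g)
  expect_equal(e2$a$centroid, e1$a$centroid + c(10, -2))
  expect_equal(e2$a$ellipse, sweep(e1$a$ellipse, 2, c(10, -2), "+"))
  # identical points: zero-area ellipse
  same <- matrix(1, 6, 2)
  ed <- centroid_ellipses(same, rep("a", 6))
  expect_equal(max(abs(sweep(ed$a$ellipse, 2, ed$a$centroid))), 0)
  # n < 3: centroid only
  e3 <- centroid_ellipses(pts[1:2, ], c("a", "a"))
  expect_null(e3$a$ellipse)
  # near-isotropic cloud gives near-circular ellipse
  big <- matrix(rnorm(4000), 2000, 2)
  eb <- centroid_ellipses(big, rep("a", 2000))$a
  rad <- sqrt(rowSums(sweep(eb$ellipse, 2, eb$centroid)^2))
  expect_lt(max(rad) / min(rad), 1.2)
})
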
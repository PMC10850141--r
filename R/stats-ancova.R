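# ANCOVA with partial eta squared, slope-homogeneity and normality
# diagnostics, and centroid confidence ellipses for ordination plots.

#' Analysis of covariance with partial eta squared
#'
#' Fits the additive model response ~ group + covariate by least squares and
#' reports Type-II F tests (each term adjusted for the other), partial eta
#' squared per term (SS_term / (SS_term + SS_residual)), the
#' slope-homogeneity diagnostic (p-value of the group x covariate
#' interaction from the augmented model) and a Shapiro-Wilk normality test
#' on the residuals.
#'
#' @param response Numeric response vector.
#' @param group Factor (or coercible) with >= 1 level; with a single level
#'   the analysis reduces to simple linear regression on the covariate.
#' @param covariate Numeric covariate; if constant it is dropped with a
#'   warning and a one-way ANOVA is performed.
#' @return Object of class \code{"ca_ancova"}: data.frame \code{terms}
#'   (term, df, ss, F, p, partial_eta_sq), \code{interaction_p},
#'   \code{shapiro} (statistic, p), \code{fit}.
#' @export
ancova <- function(response, group, covariate) {
  group <- droplevels(as.factor(group))
  stopifnot(length(response) == length(group),
            length(response) == length(covariate), is.numeric(covariate))
  if (min(table(group)) < 3L) stop("need >= 3 observations per group")
  has_cov <- stats::var(covariate) > 0
  if (!has_cov) warning("constant covariate dropped")
  has_grp <- nlevels(group) >= 2L
  if (!has_grp && !has_cov) stop("nothing to fit: one group and constant covariate")

  dat <- data.frame(y = response, g = group, x = covariate)
  rss <- function(f) sum(stats::resid(stats::lm(f, data = dat))^2)
  full_formula <- if (has_grp && has_cov) y ~ g + x else if (has_grp) y ~ g else y ~ x
  fit <- stats::lm(full_formula, data = dat)
  ss_res <- sum(stats::resid(fit)^2)
  df_res <- stats::df.residual(fit)
  # sums of squares at rounding-noise level are treated as exact zeros so
  # degenerate fits (zero residual, fully explained terms) stay clean
  ss_eps <- 1e-12 * sum((response - mean(response))^2)
  if (ss_res <= ss_eps) ss_res <- 0

  rows <- list()
  add_term <- function(term, ss, df) {
    ms <- ss / df
    f <- if (ss_res > 0) ms / (ss_res / df_res) else if (ss > 0) Inf else 0
    p <- if (is.finite(f)) stats::pf(f, df, df_res, lower.tail = FALSE) else 0
    data.frame(term = term, df = df, ss = ss, F = f, p = p,
               partial_eta_sq = if (ss + ss_res > 0) ss / (ss + ss_res) else 0,
               stringsAsFactors = FALSE)
  }
  if (has_grp) {
    ss_g <- (if (has_cov) rss(y ~ x) else rss(y ~ 1)) - ss_res
    if (ss_g <= ss_eps) ss_g <- 0
    rows$g <- add_term("group", max(ss_g, 0), nlevels(group) - 1L)
  }
  if (has_cov) {
    ss_x <- (if (has_grp) rss(y ~ g) else rss(y ~ 1)) - ss_res
    if (ss_x <= ss_eps) ss_x <- 0
    rows$x <- add_term("covariate", max(ss_x, 0), 1L)
  }
  terms <- do.call(rbind, rows)
  rownames(terms) <- NULL

  interaction_p <- NA_real_
  if (has_grp && has_cov) {
    cmp <- stats::anova(fit, stats::lm(y ~ g * x, data = dat))
    interaction_p <- cmp$`Pr(>F)`[2]
  }
  shap <- tryCatch({
    r <- stats::resid(fit)
    if (length(r) >= 3 && length(r) <= 5000 && stats::sd(r) > 0) {
      s <- stats::shapiro.test(r)
      c(statistic = unname(s$statistic), p = s$p.value)
    } else c(statistic = NA_real_, p = NA_real_)
  }, error = function(e) c(statistic = NA_real_, p = NA_real_))

  structure(list(terms = terms, interaction_p = interaction_p,
                 shapiro = shap, fit = fit, df_residual = df_res),
            class = "ca_ancova")
}

#' @export
print.ca_ancova <- function(x, ...) {
  cat("ANCOVA (Type II)\n")
  for (i in seq_len(nrow(x$terms))) {
    with(x$terms[i, ], cat(sprintf(
      "  %-10s df = %d, %d  F = %.4g  p = %.4g  partial eta^2 = %.3f\n",
      term, df, x$df_residual, F, p, partial_eta_sq)))
  }
  if (!is.na(x$interaction_p)) {
    cat(sprintf("  slope homogeneity (interaction) p = %.4g\n", x$interaction_p))
  }
  if (!is.na(x$shapiro["p"])) {
    cat(sprintf("  Shapiro-Wilk on residuals: W = %.4f, p = %.4g\n",
                x$shapiro["statistic"], x$shapiro["p"]))
  }
  invisible(x)
}

#' Group centroids with confidence ellipses
#'
#' For each group, the centroid (mean) of the 2-D coordinates and the
#' confidence ellipse of that centroid from its standard-error covariance
#' (covariance of the points divided by n), scaled by the Hotelling
#' T-squared quantile c^2 = 2 (n - 1) / (n (n - 2)) * F(level; 2, n - 2).
#' Groups with fewer than 3 points get a centroid but no ellipse.
#'
#' @param coords n x 2 numeric matrix of coordinates.
#' @param groups Factor of group labels.
#' @param level Confidence level (default 0.95).
#' @param n_segments Polygon resolution of the returned ellipse outline.
#' @return Named list (one element per group): \code{centroid}, \code{n},
#'   \code{cov} (centroid covariance), \code{ellipse} (outline matrix or
#'   NULL).
#' @export
centroid_ellipses <- function(coords, groups, level = 0.95, n_segments = 100) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) == length(groups),
            level > 0, level < 1)
  groups <- droplevels(as.factor(groups))
  out <- list()
  theta <- seq(0, 2 * pi, length.out = n_segments + 1)
  circle <- cbind(cos(theta), sin(theta))
  for (g in levels(groups)) {
    pts <- coords[groups == g, , drop = FALSE]
    n <- nrow(pts)
    cen <- colMeans(pts)
    if (n < 3L) {
      out[[g]] <- list(centroid = cen, n = n, cov = NULL, ellipse = NULL)
      next
    }
    s <- stats::cov(pts)
    # Hotelling region for the mean: (xbar - mu)' S^-1 (xbar - mu) <= c^2
    c2 <- 2 * (n - 1) / (n * (n - 2)) * stats::qf(level, 2, n - 2)
    e <- eigen(s, symmetric = TRUE)
    axes <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2)
    outline <- sweep(circle %*% t(axes) * sqrt(c2), 2, cen, "+")
    out[[g]] <- list(centroid = cen, n = n, cov = s / n, ellipse = outline)
  }
  out
}
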
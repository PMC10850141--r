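# Distance-based permutation tests: one-way PERMANOVA on the partition of
# summed squared interpoint distances, and PERMDISP on distances to group
# centroids in a principal-coordinates embedding.

# sums of squares from squared distances for a grouping
# SS_total = sum_{i<j} d_ij^2 / n ; SS_within = sum over groups of
# within-group pair d^2 / group size (Anderson's decomposition, equivalent
# to the trace of the Gower-centred inner-product matrix).
.perm_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_t <- sum(d2[lower.tri(d2)]) / n
  ss_w <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  c(ss_t = ss_t, ss_w = ss_w)
}

.pseudo_f <- function(d2, groups) {
  a <- nlevels(groups); n <- nrow(d2)
  ss <- .perm_ss(d2, groups)
  ss_a <- ss["ss_t"] - ss["ss_w"]
  f <- (ss_a / (a - 1)) / (ss["ss_w"] / (n - a))
  c(f = unname(f), r2 = unname(ss_a / ss["ss_t"]))
}

# all distinct assignments of group sizes to n positions (multiset
# permutations of the label vector); feasible only for small n
.enumerate_labelings <- function(groups) {
  lev <- levels(groups)
  counts <- table(groups)
  n <- length(groups)
  res <- list()
  rec <- function(assigned, remaining) {
    if (!length(remaining)) {
      res[[length(res) + 1L]] <<- factor(assigned, levels = lev)
      return(invisible())
    }
    for (g in lev) {
      if (sum(assigned == g, na.rm = TRUE) < counts[[g]]) {
        assigned[n - length(remaining) + 1L] <- g
        rec(assigned, remaining[-1])
        assigned[n - length(remaining) + 1L] <- NA
      }
    }
  }
  rec(rep(NA_character_, n), seq_len(n))
  res
}

#' Permutational multivariate analysis of variance (one-way PERMANOVA)
#'
#' Pseudo-F from the partition of summed squared interpoint distances into
#' among- and within-group components; significance by free permutation of
#' the group labels. The Monte-Carlo p-value includes the observed statistic
#' in numerator and denominator: p = (count >= observed + 1) / (n_perm + 1).
#'
#' @param d Distance matrix (\code{dist} or square matrix).
#' @param groups Factor (or coercible) of group labels, >= 2 levels.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param exact Enumerate all distinct label assignments instead of sampling
#'   (feasible for small n); p is then the exact proportion of assignments
#'   with F >= observed.
#' @return Object of class \code{"ca_permutest"}: \code{statistic}
#'   (pseudo-F), \code{df} (among, within), \code{r_squared},
#'   \code{p_value}, \code{n_perm}, \code{seed}, \code{method}.
#' @examples
#' d <- bray_curtis(matrix(runif(40), 8))
#' permanova(d, rep(c("a", "b"), each = 4), n_perm = 199, seed = 1)
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = NULL, exact = FALSE) {
  d <- as.matrix(d)
  groups <- droplevels(as.factor(groups))
  n <- nrow(d)
  stopifnot(length(groups) == n, nlevels(groups) >= 2L, n_perm >= 1)
  if (any(is.na(d))) stop("distance matrix contains NA")
  d2 <- d^2
  obs <- .pseudo_f(d2, groups)
  a <- nlevels(groups)
  if (is.nan(obs["f"])) {
    # 0/0: every distance zero (or all points coincident)
    res <- list(statistic = NA_real_, df = c(a - 1L, n - a),
                r_squared = obs["r2"], p_value = NA_real_, n_perm = 0L,
                seed = seed, method = "PERMANOVA",
                status = "degenerate: F undefined (all distances equal zero)")
    return(structure(res, class = "ca_permutest"))
  }
  # an infinite F (zero within-group SS, perfect separation) is kept: the
  # permutation comparison F_perm >= F_obs still ranks it correctly
  if (exact) {
    labs <- .enumerate_labelings(groups)
    fs <- vapply(labs, function(g) .pseudo_f(d2, g)["f"], numeric(1))
    p <- mean(fs >= obs["f"] - 1e-12)
    n_used <- length(labs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (b in seq_len(n_perm)) {
      g <- groups[sample.int(n)]
      if (.pseudo_f(d2, g)["f"] >= obs["f"] - 1e-12) count <- count + 1L
    }
    p <- (count + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(statistic = unname(obs["f"]), df = c(a - 1L, n - a),
                 r_squared = unname(obs["r2"]), p_value = p,
                 n_perm = n_used, seed = seed, method = "PERMANOVA",
                 status = "ok"),
            class = "ca_permutest")
}

# principal-coordinates embedding from a distance matrix; negative
# eigenvalues are truncated at zero (count recorded)
.pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-10
  n_neg <- sum(e$values < -max(abs(e$values)) * 1e-10)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  rownames(coords) <- rownames(d)
  list(coords = coords, eigenvalues = e$values, n_negative = n_neg)
}

#' Permutation test of multivariate dispersion (PERMDISP)
#'
#' Samples are embedded by principal-coordinates decomposition of the
#' distance matrix (negative eigenvalues truncated at zero, count reported),
#' each sample's distance to its group centroid (the group mean in the
#' embedding) is computed, and the one-way ANOVA F on those distances is
#' assessed by permuting them across groups.
#'
#' @inheritParams permanova
#' @return Object of class \code{"ca_permutest"} with the dispersion F,
#'   plus \code{group_dispersion} (mean centroid distance per group) and
#'   \code{centroid_distances}.
#' @export
permdisp <- function(d, groups, n_perm = 9999, seed = NULL) {
  dm <- as.matrix(d)
  groups <- droplevels(as.factor(groups))
  n <- nrow(dm)
  stopifnot(length(groups) == n, nlevels(groups) >= 2L)
  emb <- .pcoa(dm)
  z <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cen <- colMeans(emb$coords[idx, , drop = FALSE])
    z[idx] <- sqrt(rowSums(sweep(emb$coords[idx, , drop = FALSE], 2, cen)^2))
    # a singleton group has dispersion 0 by construction
  }
  a <- nlevels(groups)
  f_of <- function(zz, g) {
    gm <- tapply(zz, g, mean); ng <- tabulate(g)
    ss_a <- sum(ng * (gm - mean(zz))^2)
    ss_w <- sum((zz - gm[g])^2)
    (ss_a / (a - 1)) / (ss_w / (n - a))
  }
  obs <- f_of(z, groups)
  if (!is.finite(obs)) {
    res <- list(statistic = NA_real_, df = c(a - 1L, n - a), p_value = NA_real_,
                n_perm = 0L, seed = seed, method = "PERMDISP",
                status = "degenerate: zero dispersion in every group",
                group_dispersion = tapply(z, groups, mean),
                centroid_distances = z, n_negative_eigenvalues = emb$n_negative)
    return(structure(res, class = "ca_permutest"))
  }
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    if (f_of(z[sample.int(n)], groups) >= obs - 1e-12) count <- count + 1L
  }
  structure(list(statistic = obs, df = c(a - 1L, n - a),
                 p_value = (count + 1) / (n_perm + 1), n_perm = n_perm,
                 seed = seed, method = "PERMDISP", status = "ok",
                 group_dispersion = tapply(z, groups, mean),
                 centroid_distances = z,
                 n_negative_eigenvalues = emb$n_negative),
            class = "ca_permutest")
}

#' @export
print.ca_permutest <- function(x, ...) {
  cat(x$method, "\n")
  if (!identical(x$status, "ok")) cat("  status:", x$status, "\n")
  cat(sprintf("  F = %.4g, df = %d, %d", x$statistic, x$df[1], x$df[2]))
  if (!is.null(x$r_squared)) cat(sprintf(", R2 = %.3f", x$r_squared))
  cat(sprintf(", p = %.4g (%d permutations)\n", x$p_value, x$n_perm))
  invisible(x)
}
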
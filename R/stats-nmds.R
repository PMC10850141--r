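# Non-metric multidimensional scaling by stress majorisation (Guttman
# transform) with monotone regression of configuration distances on
# dissimilarity ranks via pool-adjacent-violators.

#' Pool-adjacent-violators algorithm (weighted isotonic regression)
#'
#' Least-squares non-decreasing fit to \code{y}: minimises
#' sum w (y - yhat)^2 subject to yhat non-decreasing.
#'
#' @param y Numeric vector.
#' @param w Positive weights, recycled to \code{length(y)}.
#' @return Numeric vector of fitted values, same length as \code{y}.
#' @examples
#' pava(c(3, 1, 2))  # 2 2 2
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (!n) return(numeric(0))
  w <- rep_len(w, n)
  stopifnot(all(w > 0))
  # blocks as (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      # merge the two top blocks (weighted mean)
      wsum <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (val[top - 1L] * wt[top - 1L] + val[top] * wt[top]) / wsum
      wt[top - 1L] <- wsum
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], sz[seq_len(top)])
}

# lower-triangle vector of pairwise Euclidean distances of configuration X
.config_dist <- function(x) {
  as.vector(stats::dist(x))
}

# monotone regression of configuration distances on the dissimilarity order;
# tied dissimilarity blocks share one fitted value (averaged within block)
.monotone_fit <- function(dvec, cdist) {
  ord <- order(dvec)
  # collapse tied dissimilarities into single weighted points
  dv <- dvec[ord]; cv <- cdist[ord]
  grp <- cumsum(c(TRUE, diff(dv) > 0))
  means <- tapply(cv, grp, mean)
  wts <- tabulate(grp)
  fit_blocks <- pava(as.vector(means), wts)
  dhat <- numeric(length(dvec))
  dhat[ord] <- fit_blocks[grp]
  dhat
}

.stress1 <- function(cdist, dhat) {
  denom <- sum(cdist^2)
  if (denom == 0) return(0)
  sqrt(sum((cdist - dhat)^2) / denom)
}

# one Guttman (SMACOF) update of configuration X towards target dhat
.guttman_update <- function(x, dhat_mat) {
  n <- nrow(x)
  dmat <- as.matrix(stats::dist(x))
  ratio <- ifelse(dmat > 0, dhat_mat / dmat, 0)
  diag(ratio) <- 0
  b <- -ratio
  diag(b) <- rowSums(ratio)
  (b %*% x) / n
}

#' Non-metric multidimensional scaling
#'
#' Kruskal-style nMDS: the configuration is updated by stress majorisation
#' against disparities obtained by monotone (isotonic) regression of the
#' configuration distances on the dissimilarity ranks (tied dissimilarity
#' blocks share one disparity). Goodness of fit is Kruskal stress-1,
#' sqrt(sum (d_conf - d_hat)^2 / sum d_conf^2). The first restart starts
#' from the principal-coordinates embedding, the remaining restarts from
#' random configurations; the best (lowest-stress) solution is returned.
#'
#' @param d Distance matrix (\code{dist} or square matrix), n >= k + 1.
#' @param k Embedding dimension (default 2).
#' @param n_restarts Number of starts (default 8).
#' @param max_iter Maximum majorisation iterations per start (default 200).
#' @param tol Convergence tolerance on the stress decrease (default 1e-7).
#' @param seed Integer seed for the random restarts.
#' @return Object of class \code{"ca_nmds"}: \code{points} (n x k),
#'   \code{stress}, \code{converged}, \code{n_restarts}, \code{iterations},
#'   \code{seed}.
#' @export
nmds <- function(d, k = 2, n_restarts = 8, max_iter = 200, tol = 1e-7,
                 seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(n >= k + 1, n_restarts >= 1)
  if (any(is.na(dm))) stop("distance matrix contains NA")
  dvec <- dm[lower.tri(dm)]
  if (!is.null(seed)) set.seed(seed)
  scale0 <- max(dvec, 1e-8)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    x <- if (r == 1L) {
      emb <- .pcoa(dm)$coords
      if (ncol(emb) >= k) emb[, seq_len(k), drop = FALSE] else
        cbind(emb, matrix(stats::rnorm(n * (k - ncol(emb)), sd = 1e-4), n))
    } else {
      matrix(stats::runif(n * k, -scale0, scale0), n, k)
    }
    stress_prev <- Inf
    converged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      cdist <- .config_dist(x)
      if (all(cdist == 0)) {  # collapsed configuration: restart-worthy
        stress <- 1
        break
      }
      dhat <- .monotone_fit(dvec, cdist)
      stress <- .stress1(cdist, dhat)
      if (is.finite(stress_prev) && stress_prev - stress < tol) {
        converged <- stress_prev - stress > -10 * tol
        break
      }
      if (it >= max_iter) break
      stress_prev <- stress
      dhat_mat <- matrix(0, n, n)
      dhat_mat[lower.tri(dhat_mat)] <- dhat
      dhat_mat <- dhat_mat + t(dhat_mat)
      x <- .guttman_update(x, dhat_mat)
    }
    if (is.null(best) || stress < best$stress) {
      best <- list(points = x, stress = stress, converged = converged,
                   iterations = it, restart = r)
    }
  }
  rownames(best$points) <- rownames(dm)
  structure(list(points = best$points, stress = best$stress,
                 converged = best$converged, iterations = best$iterations,
                 best_restart = best$restart, n_restarts = n_restarts,
                 k = k, seed = seed),
            class = "ca_nmds")
}

#' @export
print.ca_nmds <- function(x, ...) {
  cat(sprintf("nMDS (k = %d): stress-1 = %.4g after %d iteration(s), %s\n",
              x$k, x$stress, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Ordination plot with group centroids and confidence ellipses
#'
#' @param x A \code{"ca_nmds"} object.
#' @param groups Optional factor of group labels for centroids/ellipses.
#' @param level Confidence level for centroid ellipses.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, the ellipse parameters (or NULL).
#' @export
plot.ca_nmds <- function(x, groups = NULL, level = 0.95, ...) {
  pts <- x$points
  graphics::plot(pts[, 1], pts[, 2], xlab = "nMDS1", ylab = "nMDS2",
                 asp = 1, ...)
  ell <- NULL
  if (!is.null(groups)) {
    groups <- droplevels(as.factor(groups))
    cols <- seq_len(nlevels(groups)) + 1L
    graphics::points(pts[, 1], pts[, 2], col = cols[as.integer(groups)], pch = 16)
    ell <- centroid_ellipses(pts[, 1:2, drop = FALSE], groups, level = level)
    for (i in seq_along(ell)) {
      e <- ell[[i]]
      graphics::points(e$centroid[1], e$centroid[2], pch = 8, cex = 1.5,
                       col = cols[i])
      if (!is.null(e$ellipse)) {
        graphics::lines(e$ellipse, col = cols[i])
      }
    }
  }
  graphics::mtext(sprintf("stress = %.3f", x$stress), side = 3, adj = 1,
                  cex = 0.8)
  invisible(ell)
}
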
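# Bray-Curtis dissimilarity on a samples x compounds abundance matrix.

#' Bray-Curtis dissimilarity
#'
#' d(i, j) = sum |x_i - x_j| / sum (x_i + x_j) over compounds. Ranges from 0
#' (identical composition) to 1 (disjoint support). Not a metric: the
#' triangle inequality does not hold in general.
#'
#' @param x Non-negative samples x compounds matrix or data.frame with at
#'   least 2 rows.
#' @param normalise Rescale each row to relative abundance (sum 1) before
#'   computing distances.
#' @return A \code{\link[stats]{dist}} object. Pairs in which both rows sum
#'   to zero have undefined distance: they are set to \code{NA} with a
#'   warning and the affected rows are listed in attribute
#'   \code{"zero_rows"}.
#' @examples
#' bray_curtis(rbind(a = c(6, 2), b = c(2, 2)))  # 4/12
#' @export
bray_curtis <- function(x, normalise = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("abundance matrix must be numeric")
  if (any(x < 0)) stop("abundance matrix has negative entries")
  if (nrow(x) < 2L) stop("need at least 2 samples")
  rs <- rowSums(x)
  zero <- which(rs == 0)
  if (normalise) {
    x[rs > 0, ] <- x[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      denom <- sum(x[i, ] + x[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) NA_real_ else
        sum(abs(x[i, ] - x[j, ])) / denom
    }
  }
  if (length(zero) >= 2L) {
    warning("distance undefined for ", sum(is.na(d[lower.tri(d)])),
            " pair(s) of all-zero samples; set to NA")
  }
  out <- stats::as.dist(d)
  attr(out, "zero_rows") <- zero
  attr(out, "method") <- "bray-curtis"
  out
}
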
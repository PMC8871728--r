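#' Kendall's coefficient of concordance (W)
#'
#' Measures agreement among m raters each ranking the same n items.
#' Scores are converted to within-rater ranks (mid-ranks for ties) and
#' `W = 12 S / (m^2 (n^3 - n) - m * sum(T_j))`, where S is the sum of
#' squared deviations of the item rank-sums from their mean and
#' `T_j = sum(t^3 - t)` over the tie groups of rater j is the tie
#' correction. W ranges from 0 (no agreement) to 1 (identical rankings).
#' Significance uses the chi-square approximation
#' `chi2 = m (n - 1) W` on `n - 1` degrees of freedom.
#'
#' @param ratings An m x n numeric matrix (raters in rows, items in
#'   columns), or a data frame coercible to one.
#' @param consensus_w,consensus_p Consensus rule thresholds: consensus is
#'   declared when `W > consensus_w` and `p < consensus_p` (defaults 0.6
#'   and 0.05, the usual Delphi-panel rule).
#' @return An object of class `kendall_w` with elements `W`, `chi2`, `df`,
#'   `p_value`, `m`, `n`, `consensus` (logical). Supports [print()],
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' r <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(2, 1, 3, 4))
#' kendalls_w(r)
#' @export
kendalls_w <- function(ratings, consensus_w = 0.6, consensus_p = 0.05) {
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings)) stop("ratings must be numeric", call. = FALSE)
  m <- nrow(ratings)
  n <- ncol(ratings)
  if (m < 2 || n < 2) {
    stop("Kendall's W needs at least 2 raters and 2 items", call. = FALSE)
  }
  if (anyNA(ratings)) stop("ratings must be complete (no NA)", call. = FALSE)

  ranks <- t(apply(ratings, 1, rank, ties.method = "average"))
  tie_corr <- apply(ratings, 1, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(tie_corr)
  if (denom <= 0) {
    stop("undefined W: every rater gave constant ratings (all ties)",
         call. = FALSE)
  }
  rank_sums <- colSums(ranks)
  s <- sum((rank_sums - mean(rank_sums))^2)
  w <- 12 * s / denom
  chi2 <- m * (n - 1) * w
  p <- stats::pchisq(chi2, df = n - 1, lower.tail = FALSE)
  structure(list(
    W = w, chi2 = chi2, df = n - 1, p_value = p, m = m, n = n,
    consensus = (w > consensus_w) && (p < consensus_p),
    consensus_rule = c(W = consensus_w, p = consensus_p)
  ), class = "kendall_w")
}

#' @method print kendall_w
#' @export
print.kendall_w <- function(x, ...) {
  cat("Kendall's coefficient of concordance\n")
  cat(sprintf("  W = %.4f (m = %d raters, n = %d items)\n", x$W, x$m, x$n))
  cat(sprintf("  chi-squared = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  cat(sprintf("  consensus (W > %.2f and p < %.2f): %s\n",
              x$consensus_rule[["W"]], x$consensus_rule[["p"]],
              if (x$consensus) "yes" else "no"))
  invisible(x)
}

#' Tidy a Kendall's W result
#'
#' @param x A `kendall_w` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic` (W), `chi_squared`, `df`,
#'   `p.value`, `consensus`.
#' @export
tidy.kendall_w <- function(x, ...) {
  tibble::tibble(statistic = x$W, chi_squared = x$chi2, df = x$df,
                 p.value = x$p_value, consensus = x$consensus)
}

#' Glance at a Kendall's W result
#'
#' @param x A `kendall_w` object.
#' @param ... Unused.
#' @return One-row tibble with `W`, `p.value`, `n_raters`, `n_items`,
#'   `consensus`.
#' @export
glance.kendall_w <- function(x, ...) {
  tibble::tibble(W = x$W, p.value = x$p_value, n_raters = x$m,
                 n_items = x$n, consensus = x$consensus)
}
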
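# Exact one-tailed Wilcoxon signed-rank inference on (self, minimum
# non-self) distance pairs, and distance summary statistics.

#' Exact one-tailed Wilcoxon signed-rank test
#'
#' Tests the alternative that `x` is systematically smaller than `y` on
#' paired data. Zero differences are dropped (the classical convention;
#' n is reduced), absolute differences are ranked with midranks for ties,
#' and the statistic W is the sum of ranks of pairs with `x > y` -- so
#' `x < y` everywhere gives W = 0. The exact one-tailed P-value
#' `P(W* <= W)` is obtained by full enumeration of all `2^n` sign
#' assignments of the (possibly tied) ranks, which remains exact under
#' ties.
#'
#' @param x,y Paired numeric vectors (e.g. self-distances and minimum
#'   non-self distances).
#' @param n_max Enumeration guard: maximum n (default 25, i.e. at most
#'   2^25 sign vectors).
#' @return A list of class `wilcoxon_exact` with `W`, `p`, `n`.
#' @export
wilcoxon_exact <- function(x, y, n_max = 25) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  d <- x - y
  keep <- !is.na(d) & d != 0
  d <- d[keep]
  n <- length(d)
  if (n == 0)
    stop("no non-zero differences; test undefined", call. = FALSE)
  if (n > n_max)
    stop("n = ", n, " exceeds the exact-enumeration limit (", n_max, ")",
         call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  # Distribution of W* over all sign assignments: vector-doubling
  # enumeration (each rank either contributes or not).
  sums <- 0
  for (rk in r) sums <- c(sums, sums + rk)
  p <- sum(sums <= W + 1e-9) / length(sums)
  structure(list(W = W, p = p, n = n), class = "wilcoxon_exact")
}

#' @export
print.wilcoxon_exact <- function(x, ...) {
  cat(sprintf("Exact one-tailed Wilcoxon signed-rank test: W = %.3f, p = %.4g, n = %d\n",
              x$W, x$p, x$n))
  invisible(x)
}

#' Summary statistics of self and minimum non-self distances
#'
#' Medians and interquartile ranges (quartiles by linear interpolation,
#' the default quantile rule) of the self-distances and minimum non-self
#' distances of a pairs table.
#'
#' @param pairs Data.frame from [extract_minima()].
#' @return Named numeric vector `median_self`, `iqr_self`,
#'   `median_nonself`, `iqr_nonself`.
#' @export
summarize_distances <- function(pairs) {
  stopifnot(nrow(pairs) > 0)
  iqr <- function(v) unname(diff(stats::quantile(v, c(0.25, 0.75),
                                                 type = 7)))
  c(median_self = stats::median(pairs$self_distance),
    iqr_self = iqr(pairs$self_distance),
    median_nonself = stats::median(pairs$min_nonself),
    iqr_nonself = iqr(pairs$min_nonself))
}
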
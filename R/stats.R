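#' Sample summary in mean +/- SD convention
#'
#' @param values Numeric vector, length >= 1.
#' @return List with \code{n}, \code{mean}, \code{sd} (n-1 denominator;
#'   0 for a single value), \code{median} and \code{quartiles} (25/75%).
#' @export
summarize_sample <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values)))
    stop("values must be non-empty and finite")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  list(n = length(values), mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else 0,
       median = stats::median(values), quartiles = q)
}

#' Mann-Whitney U comparison of two samples
#'
#' Rank-sum test with midrank ties. With \code{mode = "exact"} (the default
#' for small tie-free samples, n1 + n2 <= 16) the two-sided p-value comes
#' from the exact null distribution of U; otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @return List with \code{U} (statistic for the first sample), \code{p}
#'   (two-sided), \code{mode_used}, \code{summary_x}, \code{summary_y} and
#'   \code{test} name.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- switch(mode,
                  auto = !ties && (length(x) + length(y)) <= 16,
                  exact = TRUE, normal = FALSE)
  if (exact && ties) {
    # exact enumeration with midranks is still valid for the identical-sample
    # symmetry case; stats::wilcox.test refuses ties, so fall back only there
    r <- rank(c(x, y))
    U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    p <- .mwu_exact_midrank_p(x, y)
    return(list(U = U, p = p, mode_used = "exact-midrank",
                summary_x = summarize_sample(x), summary_y = summarize_sample(y),
                test = "Mann-Whitney U"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       mode_used = if (exact) "exact" else "normal",
       summary_x = summarize_sample(x), summary_y = summarize_sample(y),
       test = "Mann-Whitney U")
}

# exact two-sided p by enumeration of all C(n1+n2, n1) group assignments,
# midranks for ties; p = P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|)
.mwu_exact_midrank_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Fixed-origin histogram
#'
#' Half-open bins \code{[k w, (k+1) w)} anchored at zero, the binning
#' convention used for velocity (5 nm/s) and length (120 nm) histograms.
#'
#' @param values Numeric vector.
#' @param bin_width Bin width (> 0).
#' @return List with \code{breaks} (length nbin + 1), \code{counts} and
#'   \code{mids}. Negative values extend the bin range to the left with a
#'   warning. Empty input gives empty counts.
#' @export
histogram_counts <- function(values, bin_width) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  values <- as.numeric(values)
  if (length(values) == 0)
    return(list(breaks = numeric(0), counts = integer(0), mids = numeric(0)))
  if (any(values < 0))
    warning("negative values: extending bins left of the zero origin")
  k_lo <- min(0, floor(min(values) / bin_width))
  k_hi <- floor(max(values) / bin_width) + 1
  breaks <- (k_lo:k_hi) * bin_width
  counts <- as.integer(table(factor(findInterval(values, breaks),
                                    levels = seq_len(length(breaks) - 1))))
  list(breaks = breaks, counts = counts,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2)
}
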
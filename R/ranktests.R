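# Exact null distributions for the rank tests, built by generating-function
# convolution. Counts are exact in double precision for the sizes used
# (signed rank n <= 25, Mann-Whitney min(n, m) <= 10).

# Counts of sign patterns by signed-rank sum W+ for ranks 1..n (length
# n(n+1)/2 + 1, index = W+ + 1, total 2^n).
signed_rank_counts <- function(n) {
  co <- c(1, rep(0, n * (n + 1) / 2))
  for (k in seq_len(n)) {
    L <- length(co)
    co[(k + 1):L] <- co[(k + 1):L] + co[1:(L - k)]
  }
  co
}

# Counts of arrangements by Mann-Whitney U for samples of size n and m
# (Gaussian binomial coefficient [n + m choose n]_q expanded in q).
mann_whitney_counts <- function(n, m) {
  maxu <- n * m
  co <- c(1, rep(0, maxu))
  for (i in seq_len(n)) {
    if (m + i <= maxu)
      co[(m + i + 1):(maxu + 1)] <- co[(m + i + 1):(maxu + 1)] -
        co[1:(maxu + 1 - (m + i))]
    for (k in (i + 1):(maxu + 1)) co[k] <- co[k] + co[k - i]
  }
  co
}

#' One-sample one-sided Wilcoxon signed-rank test
#'
#' Tests whether a sample's location lies below (`alternative = "less"`) or
#' above (`"greater"`) a hypothesised value `mu`. Zero differences are
#' dropped; the exact signed-rank distribution is used for n <= 25 without
#' ties, otherwise a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x Numeric sample (e.g. null-model percentages).
#' @param mu Hypothesised location (e.g. the observed fossil percentage).
#' @param alternative `"less"` (default) or `"greater"`.
#' @return List with `statistic` (W+), `p_value`, `n` (non-zero
#'   differences) and `exact`.
#' @export
wilcoxon_one_sample <- function(x, mu, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; test undefined")
  if (n < 6) stop("need at least 6 non-zero differences, got ", n)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    co <- signed_rank_counts(n)
    total <- 2^n
    p <- if (alternative == "less") sum(co[seq_len(W + 1)]) / total
         else sum(co[(W + 1):length(co)]) / total
    return(list(statistic = W, p_value = p, n = n, exact = TRUE))
  }
  mu_w <- n * (n + 1) / 4
  tt <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
  z <- if (alternative == "less") (W + 0.5 - mu_w) / sqrt(sig2)
       else (W - 0.5 - mu_w) / sqrt(sig2)
  p <- if (alternative == "less") stats::pnorm(z)
       else stats::pnorm(z, lower.tail = FALSE)
  list(statistic = W, p_value = p, n = n, exact = FALSE)
}

#' Two-sample one-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Tests whether values in `x` tend to exceed values in `y`
#' (`alternative = "greater"`) or fall below them (`"less"`). Exact null
#' distribution when `min(length(x), length(y)) <= 10` without ties,
#' otherwise a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x First sample (e.g. suitability at fossil cells).
#' @param y Second sample (e.g. suitability at random cells).
#' @param alternative `"greater"` (default) or `"less"`.
#' @return List with `statistic` (U for `x`), `p_value` and `exact`.
#' @export
wilcoxon_two_sample <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(m, n) <= 10 && !ties && m * n <= 1e6) {
    co <- mann_whitney_counts(m, n)
    total <- sum(co)
    p <- if (alternative == "greater") sum(co[(U + 1):length(co)]) / total
         else sum(co[seq_len(U + 1)]) / total
    return(list(statistic = U, p_value = p, exact = TRUE))
  }
  N <- m + n
  mu_u <- m * n / 2
  tt <- table(c(x, y))
  sig2 <- m * n / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
  z <- if (alternative == "greater") (U - 0.5 - mu_u) / sqrt(sig2)
       else (U + 0.5 - mu_u) / sqrt(sig2)
  p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z)
  list(statistic = U, p_value = p, exact = FALSE)
}
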
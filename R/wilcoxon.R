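# Exact Wilcoxon tests. Exactness under mid-rank ties is obtained by direct
# enumeration of the permutation distribution for small samples; larger
# samples use the normal approximation with tie and continuity corrections.
# Two-sided p-values follow the doubling convention
# p = min(1, 2 * min(P(T <= t), P(T >= t))).

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped; absolute differences receive mid-ranks.
#' For `n <= enumerate_max` non-zero pairs the exact permutation distribution
#' over all 2^n sign assignments is enumerated (ties handled exactly);
#' above that a normal approximation with continuity correction is used.
#'
#' @param x Numeric vector: differences, or first members of pairs if `y`
#'   given.
#' @param y Optional numeric vector of second members; differences `x - y`.
#' @param enumerate_max Largest n for which the exact distribution is
#'   enumerated (default 20).
#' @return List with `W` (min of positive/negative rank sums), `p`
#'   (two-sided), `n` (non-zero pairs), `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, enumerate_max = 20L) {
  d <- if (is.null(y)) x else x - y
  if (length(d) < 1L) stop("need at least one pair")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(W = 0, p = 1, n = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  t_pos <- sum(r[d > 0])
  t_neg <- sum(r[d < 0])
  W <- min(t_pos, t_neg)
  if (n <= enumerate_max) {
    # all 2^n sign vectors; T+ = sum of ranks assigned '+'
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    tdist <- as.vector(signs %*% r)
    eps <- 1e-9
    p_le <- mean(tdist <= t_pos + eps)
    p_ge <- mean(tdist >= t_pos - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    list(W = W, p = p, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (t_pos - mu - sign(t_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(W = W, p = p, n = n, exact = FALSE)
  }
}

#' Wilcoxon rank-sum (Mann-Whitney) test for two independent samples
#'
#' Pooled mid-ranks; for `m + n <= enumerate_max` the exact permutation
#' distribution over all choose(m+n, m) group assignments is enumerated,
#' otherwise a normal approximation with tie and continuity corrections is
#' used.
#'
#' @param a,b Numeric samples.
#' @param enumerate_max Largest pooled size for exact enumeration (default
#'   20).
#' @return List with `U` (min of the two Mann-Whitney statistics), `p`
#'   (two-sided), `exact`.
#' @export
wilcoxon_rank_sum <- function(a, b, enumerate_max = 20L) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  t_a <- sum(r[seq_len(m)])
  U_a <- t_a - m * (m + 1) / 2
  U_b <- m * n - U_a
  U <- min(U_a, U_b)
  if (N <= enumerate_max) {
    combs <- utils::combn(N, m)
    tdist <- colSums(matrix(r[combs], nrow = m))
    eps <- 1e-9
    p_le <- mean(tdist <= t_a + eps)
    p_ge <- mean(tdist >= t_a - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    list(U = U, p = p, exact = TRUE)
  } else {
    mu <- m * n / 2
    ties <- table(r)
    sigma2 <- (m * n / 12) * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U_a - mu - sign(U_a - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(U = U, p = p, exact = FALSE)
  }
}
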
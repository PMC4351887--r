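#' Exact two-sided binomial test
#'
#' Exact binomial test of `k` successes in `n` trials against null success
#' probability `p0`. The two-sided p-value is the sum of probabilities of all
#' outcomes no more likely than the observed one (the minimum-likelihood
#' construction). This is the test used to compare clade-support and fixation
#' proportions between DNA-contacting and background residues.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability, strictly between 0 and 1.
#' @param alternative One of "two.sided", "less", "greater".
#' @return A tibble with columns `statistic` (k), `p_value`, `n1` (n), `n2`
#'   (NA), `sidedness` and `estimate` (k/n). With `n = 0` the p-value is `NA`
#'   and the row is flagged `undefined = TRUE`.
#' @export
#' @examples
#' binomial_compare(10, 10, 0.5)$p_value  # ~0.001953
binomial_compare <- function(k, n, p0, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  if (n == 0) {
    return(tibble(statistic = NA_real_, p_value = NA_real_, n1 = 0L,
                  n2 = NA_integer_, sidedness = alternative,
                  estimate = NA_real_, undefined = TRUE))
  }
  if (k < 0 || k > n) abort("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly between 0 and 1")
  d <- dbinom(0:n, n, p0)
  p <- switch(alternative,
    two.sided = sum(d[d <= d[k + 1L] * (1 + 1e-7)]),
    less      = sum(d[seq_len(k + 1L)]),
    greater   = sum(d[(k + 1L):(n + 1L)])
  )
  tibble(statistic = as.numeric(k), p_value = min(1, p), n1 = as.integer(n),
         n2 = NA_integer_, sidedness = alternative, estimate = k / n,
         undefined = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample Wilcoxon (Mann-Whitney) rank-sum test. The exact null
#' distribution is used when both samples are smaller than `exact_below` and
#' there are no ties; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param sample_a,sample_b Numeric vectors, both non-empty.
#' @param exact_below Use the exact distribution when both n < this and no ties.
#' @param alternative One of "two.sided", "less", "greater".
#' @return A tibble with `statistic` (the Mann-Whitney U for sample_a),
#'   `p_value`, `n1`, `n2`, `sidedness`, `exact`.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b, exact_below = 20,
                              alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("both samples must be non-empty")
  }
  n1 <- length(sample_a); n2 <- length(sample_b)
  r <- rank(c(sample_a, sample_b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(sample_a, sample_b)))
  use_exact <- !ties && n1 < exact_below && n2 < exact_below
  if (use_exact) {
    p <- switch(alternative,
      two.sided = {
        p_le <- stats::pwilcox(u, n1, n2)
        p_ge <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
        min(1, 2 * min(p_le, p_ge))
      },
      less = stats::pwilcox(u, n1, n2),
      greater = stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    )
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1)))
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p <- 1
    } else {
      z0 <- u - mu
      # continuity correction in the direction of the alternative
      p <- switch(alternative,
        two.sided = {
          z <- (z0 - sign(z0) * 0.5) / sigma
          min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
        },
        less = pnorm((z0 + 0.5) / sigma),
        greater = pnorm((z0 - 0.5) / sigma, lower.tail = FALSE)
      )
    }
  }
  tibble(statistic = u, p_value = p, n1 = n1, n2 = n2,
         sidedness = alternative, exact = use_exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation on average ranks. All-tied input in either vector is
#' flagged undefined and reported as `rho = 0` with `all_tied = TRUE`, the
#' convention used for constant specificity-versus-distance profiles.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A tibble with `rho`, `n`, `all_tied`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("spearman requires at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(tibble(rho = 0, n = length(x), all_tied = TRUE))
  }
  tibble(rho = stats::cor(rx, ry), n = length(x), all_tied = FALSE)
}

#' Normalize ranks to the unit interval
#'
#' Ranks values ascending (average ranks for ties) and rescales to
#' `(rank - 1) / (m - 1)`; a single value maps to 0.5 by convention.
#'
#' @param x Numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_ranks <- function(x) {
  m <- length(x)
  if (m == 0) return(numeric(0))
  if (m == 1) return(0.5)
  (rank(x) - 1) / (m - 1)
}
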
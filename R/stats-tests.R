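#' Split participants by the trait-anxiety cutoff
#'
#' Partitions participants into Low (trait score <= cutoff) and High
#' (score > cutoff) anxiety groups; the conventional cutoff is 39, so a
#' score of exactly 39 falls in the Low group.
#'
#' @param traits named numeric vector (names = participant ids) or a data
#'   frame with `participant_id` and `trait_score`.
#' @param cutoff integer cutoff (default 39).
#' @return A list of class `group_split` with `low_ids`, `high_ids` and
#'   `cutoff`.
#' @export
split_by_cutoff <- function(traits, cutoff = 39) {
  if (is.data.frame(traits)) {
    traits <- stats::setNames(traits$trait_score, traits$participant_id)
  }
  if (!length(traits)) stop_("traits must be nonempty")
  low <- names(traits)[traits <= cutoff]
  high <- names(traits)[traits > cutoff]
  if (!length(low)) stop_("no participants at or below the cutoff (%d): Low group empty", cutoff)
  if (!length(high)) stop_("no participants above the cutoff (%d): High group empty", cutoff)
  structure(list(low_ids = low, high_ids = high, cutoff = cutoff),
            class = "group_split")
}

#' Normality tests with estimated parameters
#'
#' `kind = "lilliefors"` runs the Lilliefors-corrected Kolmogorov-Smirnov
#' test (null parameters estimated from the sample, p-value from the
#' Dallal-Wilkinson approximation via [nortest::lillie.test()]).
#' `kind = "ks"` computes the same D statistic against the normal fitted by
#' sample mean and SD but takes the p-value from the classical K-S
#' distribution ([stats::ks.test()]); this p is conservative because it
#' ignores the parameter estimation, but it matches common practice of
#' applying "the K-S test of normality" directly to data.
#'
#' @param sample numeric vector, n >= 4, non-constant.
#' @param kind `"lilliefors"` or `"ks"`.
#' @param alpha significance level for the pass flag (default 0.05).
#' @return A list of class `normality_result`: `statistic` (D), `p`,
#'   `pass` (TRUE when normality is not rejected) and `kind`.
#' @export
normality_tests <- function(sample, kind = c("lilliefors", "ks"), alpha = 0.05) {
  kind <- match.arg(kind)
  if (length(sample) < 4) stop_("normality tests require n >= 4 (got %d)", length(sample))
  if (sd(sample) == 0) stop_("sample is constant; scale is undefined")
  if (kind == "lilliefors") {
    t <- nortest::lillie.test(sample)
  } else {
    t <- suppressWarnings(ks.test(sample, "pnorm", mean(sample), sd(sample)))
  }
  structure(list(statistic = unname(t$statistic), p = t$p.value,
                 pass = t$p.value > alpha, kind = kind, n = length(sample)),
            class = "normality_result")
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance matrix of the repeated measures is
#' spherical (equal variances of all pairwise differences). W is computed
#' from the covariance of the orthonormally contrasted measures as
#' `det(S) / (tr(S)/k)^k` with `k = m - 1`; the p-value uses the standard
#' chi-square approximation with the Box correction factor.
#'
#' @param mat numeric matrix, participants in rows, repeated measures
#'   (>= 3) in columns; at least 5 rows.
#' @param alpha significance level for the pass flag.
#' @return A list of class `sphericity_result`: `W`, `chisq`, `df`, `p`,
#'   `pass` (TRUE when sphericity is not rejected).
#' @export
mauchly_sphericity <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  m <- ncol(mat)
  if (n < 5) stop_("Mauchly's test requires at least 5 participants (got %d)", n)
  if (m < 3) stop_("need at least 3 repeated measures")
  k <- m - 1
  ctr <- stats::contr.helmert(m)
  ctr <- sweep(ctr, 2, sqrt(colSums(ctr^2)), "/")  # orthonormal contrasts
  S <- cov(mat %*% ctr)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  scale <- mean(diag(cov(mat)))  # guards against pure floating-point fuzz
  if (scale <= 0 || min(ev) <= 1e-12 * scale) {
    stop_("contrast covariance is singular; W undefined")
  }
  W <- prod(ev) / (mean(ev))^k
  d <- 1 - (2 * k^2 + k + 2) / (6 * k * (n - 1))
  chisq <- -(n - 1) * d * log(W)
  df <- k * (k + 1) / 2 - 1
  p <- pchisq(chisq, df, lower.tail = FALSE)
  structure(list(W = W, chisq = chisq, df = df, p = p, pass = p > alpha, n = n),
            class = "sphericity_result")
}

#' Mann-Whitney U test with rank-based effect sizes
#'
#' Rank-sum test for two independent samples using midranks for ties. The
#' reported `U` is the number of (x, y) pairs in which x exceeds y (ties
#' count one half). The z statistic uses the normal approximation with
#' tie-corrected variance and no continuity correction. The two-tailed
#' p-value is exact (by the null permutation distribution of U) when there
#' are no ties and both samples are small; otherwise it comes from the
#' normal approximation. Two effect sizes are reported: the rank-biserial
#' correlation `1 - 2U/(n1*n2)` and `|z|/sqrt(n1+n2)`.
#'
#' @param x,y numeric samples (both nonempty).
#' @param exact_max use the exact p when there are no ties and
#'   `n1 + n2 <= exact_max` (default 50).
#' @return A list of class `mwu_result`: `U`, `z`, `p`, `method`
#'   (`"exact"` or `"normal"`), `r_rank_biserial`, `r_z`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, exact_max = 50) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop_("both samples must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs with x > y (ties = 1/2)
  mu <- n1 * n2 / 2
  ties <- table(r)
  N <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  has_ties <- any(ties > 1)
  if (!has_ties && N <= exact_max) {
    p <- min(1, 2 * min(pwilcox(U, n1, n2), pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
    method <- "exact"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(U = U, z = z, p = p, method = method,
                 r_rank_biserial = 1 - 2 * U / (n1 * n2),
                 r_z = abs(z) / sqrt(N), n1 = n1, n2 = n2),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, z = %.3f, p = %.4g (%s)\n  rank-biserial r = %.3f, |z|/sqrt(N) = %.3f\n",
              x$U, x$z, x$p, x$method, x$r_rank_biserial, x$r_z))
  invisible(x)
}
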
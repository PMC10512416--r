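# Split-plot (one between-subjects x one within-subjects factor) ANOVA,
# computed from the classical sums-of-squares decomposition. The design is
# always complete within subject (every participant contributes all four
# emotions), which makes the sequential, hierarchical and marginal SS for
# the within effects coincide even when the two anxiety groups are of
# unequal size.

#' Mixed (split-plot) ANOVA on the eAUC table
#'
#' Two-way mixed ANOVA with anxiety group (between subjects, 2 levels) and
#' target emotion (within subjects, 4 levels). Sums of squares follow the
#' classical split-plot decomposition: the group effect is tested against
#' subjects-within-group variance, the emotion and interaction effects
#' against the emotion-by-subject residual. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error term.
#' For n subjects in the 2 x 4 design the interaction test has
#' `df = (3, 3(n - 2))`. No sphericity correction is applied to the
#' reported degrees of freedom; run [mauchly_sphericity()] alongside.
#'
#' @param table an eAUC table with a `group` column and the four emotion
#'   columns (see [eauc_table()]), or any data frame with `group` plus
#'   numeric repeated-measure columns named in `measures`.
#' @param measures names of the within-subject measure columns.
#' @return An object of class `mixed_anova_result`: a data frame `effects`
#'   with one row per effect (`group`, `measure`, `group:measure`) holding
#'   `SS`, `df1`, `df2`, `F`, `p` and `partial_eta2`, plus the full SS
#'   decomposition in `ss`.
#' @export
mixed_anova <- function(table, measures = EMOTIONS) {
  if (!"group" %in% names(table)) stop_("table needs a `group` column")
  if (!all(measures %in% names(table))) {
    stop_("table is missing measure column(s): %s",
          paste(setdiff(measures, names(table)), collapse = ", "))
  }
  Y <- as.matrix(table[, measures])
  if (anyNA(Y)) stop_("eAUC table has missing cells")
  grp <- factor(table$group)
  g <- nlevels(grp)
  if (g < 2) stop_("both anxiety groups must be nonempty")
  n <- nrow(Y)
  m <- ncol(Y)
  nj <- tabulate(grp)

  gm <- mean(Y)
  subj_means <- rowMeans(Y)
  grp_means <- tapply(subj_means, grp, mean)           # per-group mean of subject means
  col_means <- colMeans(Y)                             # weighted (all subjects)
  cell_means <- apply(Y, 2, function(col) tapply(col, grp, mean))  # g x m

  ss_total <- sum((Y - gm)^2)
  ss_between_subj <- m * sum((subj_means - gm)^2)
  ss_group <- m * sum(nj * (grp_means - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_within <- ss_total - ss_between_subj
  ss_measure <- n * sum((col_means - gm)^2)
  inter_dev <- sweep(sweep(cell_means, 1, grp_means - gm), 2, col_means) # C_jk - A_j - B_k + GM
  ss_inter <- sum(nj * inter_dev^2)
  ss_err_within <- ss_within - ss_measure - ss_inter

  df_group <- g - 1
  df_subj <- n - g
  df_measure <- m - 1
  df_inter <- (g - 1) * (m - 1)
  df_err <- (n - g) * (m - 1)
  if (ss_subj_within <= 0 || ss_err_within <= 0) {
    stop_("zero error variance; the ANOVA F tests are undefined")
  }

  mk <- function(effect, ss, df1, ss_err, df2) {
    F <- (ss / df1) / (ss_err / df2)
    data.frame(effect = effect, SS = ss, df1 = df1, df2 = df2, F = F,
               p = pf(F, df1, df2, lower.tail = FALSE),
               partial_eta2 = ss / (ss + ss_err), stringsAsFactors = FALSE)
  }
  effects <- rbind(
    mk("group", ss_group, df_group, ss_subj_within, df_subj),
    mk("measure", ss_measure, df_measure, ss_err_within, df_err),
    mk("group:measure", ss_inter, df_inter, ss_err_within, df_err)
  )
  structure(
    list(effects = effects,
         ss = c(total = ss_total, between_subjects = ss_between_subj,
                group = ss_group, subjects_within_group = ss_subj_within,
                within = ss_within, measure = ss_measure,
                interaction = ss_inter, error_within = ss_err_within),
         n = n, group_sizes = stats::setNames(nj, levels(grp)), measures = measures),
    class = "mixed_anova_result"
  )
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA (%d subjects: %s)\n", x$n,
              paste(sprintf("%s n=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-14s F(%d,%d) = %.3f, p = %.4f, partial eta2 = %.3f\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i], e$partial_eta2[i]))
  }
  invisible(x)
}

#' Simple main effects of group within each emotion
#'
#' Follows up a group-by-emotion interaction with per-emotion between-group
#' contrasts: for each emotion the Low-minus-High mean difference, its
#' standard error from the two groups' pooled variance in that emotion, a
#' two-sample t test, and the Bonferroni-corrected p over the family of
#' four emotion-wise comparisons.
#'
#' @param table an eAUC table with `group` and the emotion columns.
#' @param family_size Bonferroni family size (default 4).
#' @param measures measure columns (default the four emotions).
#' @return A data frame with one row per emotion: `mean_diff` (Low - High),
#'   `sem`, `t`, `df`, `p`, `p_bonferroni`.
#' @export
simple_main_effects <- function(table, family_size = 4, measures = EMOTIONS) {
  grp <- table$group
  if (!all(c("Low", "High") %in% grp)) stop_("both Low and High groups are required")
  rows <- lapply(measures, function(em) {
    lo <- table[[em]][grp == "Low"]
    hi <- table[[em]][grp == "High"]
    n1 <- length(lo); n2 <- length(hi)
    sp2 <- ((n1 - 1) * var(lo) + (n2 - 1) * var(hi)) / (n1 + n2 - 2)
    sem <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- (mean(lo) - mean(hi)) / sem
    p <- 2 * pt(-abs(tstat), n1 + n2 - 2)
    data.frame(emotion = em, mean_diff = mean(lo) - mean(hi), sem = sem,
               t = tstat, df = n1 + n2 - 2, p = p,
               p_bonferroni = min(1, p * family_size), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert partial eta squared to Cohen's f
#'
#' `f = sqrt(eta2 / (1 - eta2))`.
#'
#' @param partial_eta2 value(s) in `[0, 1)`.
#' @return Cohen's f.
#' @export
eta2_to_f <- function(partial_eta2) {
  if (any(partial_eta2 < 0) || any(partial_eta2 >= 1)) {
    stop_("partial_eta2 must lie in [0, 1)")
  }
  sqrt(partial_eta2 / (1 - partial_eta2))
}

#' Power of the within-between interaction F test
#'
#' Analytic power for the group-by-measure interaction in a repeated-
#' measures design with `n_groups` between-subject groups and
#' `n_measurements` repeated measures, following the standard noncentral-F
#' calculation: noncentrality `lambda = N f^2 m eps / (1 - rho)` with
#' numerator df `(g-1)(m-1) eps` and denominator df `(N-g)(m-1) eps`.
#'
#' @param n total sample size.
#' @param f Cohen's f for the interaction.
#' @param alpha significance level.
#' @param n_groups number of groups (g).
#' @param n_measurements number of repeated measures (m).
#' @param rho assumed correlation among repeated measures.
#' @param epsilon nonsphericity correction in `(1/(m-1), 1]`.
#' @return Power in `[0, 1]`.
#' @export
interaction_power <- function(n, f, alpha = 0.05, n_groups = 2,
                              n_measurements = 4, rho = 0.5, epsilon = 1) {
  g <- n_groups; m <- n_measurements
  df1 <- (g - 1) * (m - 1) * epsilon
  df2 <- (n - g) * (m - 1) * epsilon
  lambda <- n * f^2 * m * epsilon / (1 - rho)
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimum sample size for the interaction test
#'
#' Smallest total N (stepping by whole participants) whose analytic
#' interaction power (see [interaction_power()]) reaches the target.
#'
#' @param f Cohen's f for the interaction (> 0).
#' @param alpha significance level in (0, 1).
#' @param power target power in (0, 1).
#' @param n_groups,n_measurements design dimensions.
#' @param rho assumed correlation among repeated measures (default 0.5).
#' @param epsilon nonsphericity correction (default 1).
#' @param n_max search ceiling.
#' @return Minimal total N (at least 2 per group).
#' @export
required_sample_size <- function(f, alpha = 0.05, power = 0.80, n_groups = 2,
                                 n_measurements = 4, rho = 0.5, epsilon = 1,
                                 n_max = 10000) {
  if (!is.finite(f) || f <= 0) stop_("f must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_("alpha and power must be in (0, 1)")
  }
  if (rho < 0 || rho >= 1) stop_("rho must be in [0, 1)")
  for (n in seq(2 * n_groups, n_max)) {
    if (interaction_power(n, f, alpha, n_groups, n_measurements, rho, epsilon) >= power) {
      return(n)
    }
  }
  stop_("no N <= %d reaches the requested power", n_max)
}
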
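# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Polygon-area oracle for the ROC: shoelace formula over the closed polygon
# formed by the curve points plus the (1, 0) corner.
shoelace_auc <- function(fa, hit) {
  x <- c(fa, 1)
  y <- c(hit, 0)
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Random valid rating counts: multinomial spread of random hit/false-alarm
# totals over the six confidence levels.
random_counts <- function(n_signal = 30, n_noise = 30) {
  spread <- function(total) {
    conf <- sample(1:6, total, replace = TRUE)
    tab <- table(factor(conf, levels = 1:6))
    stats::setNames(as.integer(tab), 1:6)
  }
  structure(
    list(target_emotion = "FE", n_signal = n_signal, n_noise = n_noise,
         hits_by_conf = spread(sample(0:n_signal, 1)),
         fas_by_conf = spread(sample(0:n_noise, 1))),
    class = "rating_counts"
  )
}

# Build a roc_curve object directly from interior operating points.
roc_from_points <- function(fa, hit) {
  pts <- data.frame(conf_threshold = c(NA, seq_along(fa), NA),
                    fa_rate = c(0, fa, 1), hit_rate = c(0, hit, 1))
  pts <- pts[order(pts$fa_rate, pts$hit_rate), ]
  structure(list(points = pts, target_emotion = NULL), class = "roc_curve")
}

# Exhaustive-permutation two-tailed p for the Mann-Whitney U (no ties):
# fraction of group assignments whose U deviates from its null mean by at
# least as much as the observed U.
enum_mwu_p <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  N <- length(vals)
  u_of <- function(idx) {
    xx <- vals[idx]
    yy <- vals[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  mu <- n1 * (N - n1) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  us <- utils::combn(N, n1, u_of)
  mean(abs(us - mu) >= obs - 1e-12)
}

# Split-plot ANOVA oracle via stats::aov with an Error() stratum.
aov_oracle <- function(table, measures = c("HA", "NE", "FE", "DI")) {
  long <- data.frame(
    id = factor(rep(table$participant_id, times = length(measures))),
    group = factor(rep(table$group, times = length(measures))),
    measure = factor(rep(measures, each = nrow(table))),
    y = unlist(table[, measures], use.names = FALSE)
  )
  fit <- stats::aov(y ~ group * measure + Error(id), data = long)
  s <- summary(fit)
  between <- s[["Error: id"]][[1]]
  within <- s[["Error: Within"]][[1]]
  list(
    F_group = between["group", "F value"],
    p_group = between["group", "Pr(>F)"],
    F_measure = within["measure", "F value"],
    F_inter = within["group:measure", "F value"],
    p_inter = within["group:measure", "Pr(>F)"],
    ss = c(group = between["group", "Sum Sq"],
           subj = between["Residuals", "Sum Sq"],
           measure = within["measure", "Sum Sq"],
           inter = within["group:measure", "Sum Sq"],
           err = within["Residuals", "Sum Sq"])
  )
}

# Random eAUC-style table with group labels, for ANOVA checks.
random_eauc_table <- function(n_low, n_high, group_shift = c(0, 0, 0, 0),
                              subj_sd = 0.05, noise_sd = 0.03) {
  n <- n_low + n_high
  grp <- rep(c("Low", "High"), c(n_low, n_high))
  base <- matrix(rep(c(0.68, 0.65, 0.71, 0.70), each = n), n, 4)
  shift <- outer(as.numeric(grp == "High"), group_shift)
  y <- base + shift + rnorm(n, sd = subj_sd) + matrix(rnorm(n * 4, sd = noise_sd), n, 4)
  out <- data.frame(participant_id = sprintf("S%02d", seq_len(n)),
                    stringsAsFactors = FALSE)
  out[c("HA", "NE", "FE", "DI")] <- as.data.frame(y)
  out$group <- grp
  out$trait_score <- ifelse(grp == "Low", 36, 43)
  out
}
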
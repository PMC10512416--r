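test_that("the cutoff split sends 39 to Low and partitions exhaustively", {
  s <- split_by_cutoff(c(a = 33, b = 38, c = 39, d = 40, e = 47))
  expect_equal(s$low_ids, c("a", "b", "c"))
  expect_equal(s$high_ids, c("d", "e"))
  expect_error(split_by_cutoff(c(a = 40, b = 41)), "Low group empty")
  expect_error(split_by_cutoff(c(a = 30, b = 31)), "High group empty")

  df <- data.frame(participant_id = sprintf("P%02d", 1:28),
                   trait_score = c(withr::with_seed(1, sample(33:39, 15, TRUE)),
                                   withr::with_seed(2, sample(40:47, 13, TRUE))))
  s <- split_by_cutoff(df)
  expect_length(s$low_ids, 15)
  expect_length(s$high_ids, 13)
})

test_that("normality tests behave under null and alternative", {
  norm_sample <- withr::with_seed(31, rnorm(500))
  unif_sample <- withr::with_seed(32, runif(500))
  expect_true(normality_tests(norm_sample, "lilliefors")$pass)
  expect_false(normality_tests(unif_sample, "lilliefors")$pass)
  # the two kinds share one D statistic (distance to the fitted normal);
  # only the reference distribution for p differs
  expect_equal(normality_tests(norm_sample, "ks")$statistic,
               normality_tests(norm_sample, "lilliefors")$statistic,
               tolerance = 1e-10)
  expect_error(normality_tests(rnorm(3)), "n >= 4")
  expect_error(normality_tests(rep(1, 10)), "constant")
})

test_that("Mauchly W matches the base-R multivariate oracle", {
  m <- withr::with_seed(41, matrix(rnorm(28 * 4), 28, 4))
  mine <- mauchly_sphericity(m)
  oracle <- stats::mauchly.test(stats::lm(m ~ 1), X = ~1)
  expect_equal(mine$W, unname(oracle$statistic), tolerance = 1e-10)
  # base R adds a second-order term to the chi-square approximation;
  # the first-order Box approximation agrees to ~1e-3 at this n
  expect_equal(mine$p, oracle$p.value, tolerance = 2e-3)

  # compound-symmetric covariance is spherical: W near 1
  cs <- withr::with_seed(42, {
    subj <- rnorm(40, sd = 2)
    matrix(rep(subj, 4), 40, 4) + matrix(rnorm(160), 40, 4)
  })
  r <- mauchly_sphericity(cs)
  expect_gt(r$W, 0.8)
  expect_true(r$pass)

  # hand 3-measure check against the determinant/trace formula
  m3 <- withr::with_seed(43, matrix(rnorm(60), 20, 3))
  ctr <- stats::contr.helmert(3)
  ctr <- sweep(ctr, 2, sqrt(colSums(ctr^2)), "/")
  S <- cov(m3 %*% ctr)
  expect_equal(mauchly_sphericity(m3)$W,
               det(S) / (sum(diag(S)) / 2)^2, tolerance = 1e-12)

  expect_error(mauchly_sphericity(matrix(rnorm(16), 4, 4)), "at least 5")
  sing <- cbind(1:10, 1:10, 1:10, 1:10) + 0
  expect_error(mauchly_sphericity(sing), "singular")
})

test_that("mixed ANOVA reproduces the aov split-plot decomposition", {
  tab <- withr::with_seed(51, random_eauc_table(15, 13, group_shift = c(0, 0, -0.1, -0.08)))
  mine <- mixed_anova(tab)
  oracle <- aov_oracle(tab)
  e <- mine$effects
  expect_equal(e$F[e$effect == "group"], oracle$F_group, tolerance = 1e-9)
  expect_equal(e$F[e$effect == "measure"], oracle$F_measure, tolerance = 1e-9)
  expect_equal(e$F[e$effect == "group:measure"], oracle$F_inter, tolerance = 1e-9)
  expect_equal(e$p[e$effect == "group:measure"], oracle$p_inter, tolerance = 1e-9)
  expect_equal(unname(mine$ss["group"]), unname(oracle$ss["group"]), tolerance = 1e-9)
  expect_equal(unname(mine$ss["interaction"]), unname(oracle$ss["inter"]), tolerance = 1e-9)
  expect_equal(unname(mine$ss["error_within"]), unname(oracle$ss["err"]), tolerance = 1e-9)

  # design-determined degrees of freedom for n = 28 split 15/13
  expect_equal(e$df1[e$effect == "group:measure"], 3)
  expect_equal(e$df2[e$effect == "group:measure"], 78)
  expect_equal(e$df2[e$effect == "group"], 26)

  # partial eta squared definition
  expect_equal(e$partial_eta2[e$effect == "group:measure"],
               unname(mine$ss["interaction"] /
                        (mine$ss["interaction"] + mine$ss["error_within"])))
})

test_that("ANOVA sums of squares decompose the total on arbitrary data", {
  withr::with_seed(52, {
    for (i in 1:20) {
      tab <- random_eauc_table(sample(5:15, 1), sample(5:15, 1),
                               group_shift = rnorm(4, sd = 0.05))
      m <- mixed_anova(tab)
      ss <- m$ss
      expect_equal(unname(ss["total"]),
                   unname(ss["group"] + ss["subjects_within_group"] +
                            ss["measure"] + ss["interaction"] + ss["error_within"]),
                   tolerance = 1e-9 * ss["total"])
      oracle <- aov_oracle(tab)
      expect_equal(m$effects$F[3], oracle$F_inter, tolerance = 1e-9)
    }
  })
  expect_error(mixed_anova(random_eauc_table(4, 4)[, -which(names(random_eauc_table(4, 4)) == "group")]),
               "group")
})

test_that("small worked dataset matches a brute-force cell-means oracle", {
  # 6 subjects x 4 measures, hand-checkable numbers
  tab <- data.frame(
    participant_id = paste0("S", 1:6),
    HA = c(0.60, 0.63, 0.64, 0.70, 0.71, 0.74),
    NE = c(0.58, 0.60, 0.63, 0.66, 0.69, 0.70),
    FE = c(0.71, 0.72, 0.74, 0.60, 0.61, 0.64),
    DI = c(0.66, 0.69, 0.70, 0.63, 0.64, 0.66),
    group = rep(c("Low", "High"), each = 3),
    stringsAsFactors = FALSE
  )
  m <- mixed_anova(tab)
  Y <- as.matrix(tab[, EMOTIONS])
  gm <- mean(Y)
  ss_total <- sum((Y - gm)^2)
  subj <- rowMeans(Y)
  ss_bs <- 4 * sum((subj - gm)^2)
  grp_mean <- tapply(subj, tab$group, mean)
  ss_group <- 4 * sum(3 * (grp_mean - gm)^2)
  expect_equal(unname(m$ss["total"]), ss_total, tolerance = 1e-12)
  expect_equal(unname(m$ss["between_subjects"]), ss_bs, tolerance = 1e-12)
  expect_equal(unname(m$ss["group"]), ss_group, tolerance = 1e-12)
  # balanced 3/3 case: cell-means interaction SS
  cell <- apply(Y, 2, function(col) tapply(col, tab$group, mean))
  dev <- sweep(sweep(cell, 1, rowMeans(cell) - mean(cell)), 2, colMeans(cell))
  expect_equal(unname(m$ss["interaction"]), 3 * sum(dev^2), tolerance = 1e-10)
})

test_that("simple main effects match hand computation and Bonferroni", {
  tab <- data.frame(
    participant_id = paste0("S", 1:6),
    HA = c(0.60, 0.62, 0.64, 0.70, 0.72, 0.74),
    NE = c(0.60, 0.60, 0.60, 0.60, 0.60, 0.60),
    FE = c(0.80, 0.82, 0.84, 0.60, 0.62, 0.64),
    DI = c(0.70, 0.72, 0.74, 0.66, 0.68, 0.70),
    group = rep(c("Low", "High"), each = 3),
    stringsAsFactors = FALSE
  )
  sme <- simple_main_effects(tab)
  expect_equal(sme$mean_diff[sme$emotion == "FE"], 0.20, tolerance = 1e-12)
  expect_equal(sme$mean_diff[sme$emotion == "NE"], 0, tolerance = 1e-12)
  expect_equal(sme$mean_diff[sme$emotion == "HA"], -0.10, tolerance = 1e-12)
  # pooled SEM for FE: sp2 = 0.0004, sem = sqrt(0.0004 * 2/3)
  expect_equal(sme$sem[sme$emotion == "FE"], sqrt(0.0004 * 2 / 3), tolerance = 1e-12)
  expect_equal(sme$p_bonferroni, pmin(1, sme$p * 4))
  expect_true(sme$p_bonferroni[sme$emotion == "FE"] < 0.05)

  # identical groups: all differences zero
  tab2 <- tab
  tab2[4:6, EMOTIONS] <- tab2[1:3, EMOTIONS]
  expect_equal(simple_main_effects(tab2)$mean_diff, rep(0, 4))
})

test_that("Mann-Whitney matches closed forms, oracles and wilcox.test", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)                  # exact: full enumeration gives 2/20
  expect_equal(r$method, "exact")
  expect_equal(r$r_rank_biserial, 1)

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$z, 0)
  expect_equal(same$r_rank_biserial, 0)

  # complete separation at the study's group sizes: |z| = 97.5 / sqrt(15*13*29/12)
  lo <- 1:15
  hi <- 16:28
  sep <- mann_whitney(lo, hi)
  expect_equal(abs(sep$z), 97.5 / sqrt(15 * 13 * 29 / 12), tolerance = 1e-12)
  expect_equal(abs(sep$z), 4.49, tolerance = 0.001)
  expect_equal(sep$r_rank_biserial, 1)
  expect_equal(sep$r_z, abs(sep$z) / sqrt(28), tolerance = 1e-12)

  # exact p agrees with exhaustive permutation enumeration (no ties)
  withr::with_seed(61, {
    for (i in 1:10) {
      n1 <- sample(2:5, 1)
      n2 <- sample(2:5, 1)
      vals <- sample(100, n1 + n2)
      x <- vals[seq_len(n1)]
      y <- vals[-seq_len(n1)]
      expect_equal(mann_whitney(x, y)$p, enum_mwu_p(x, y), tolerance = 1e-12)
    }
  })

  # tie-corrected normal approximation agrees with wilcox.test
  x <- c(1, 2, 2, 3, 5, 7, 7)
  y <- c(2, 4, 4, 6, 7, 8)
  mine <- mann_whitney(x, y)
  expect_equal(mine$method, "normal")  # ties force the normal path
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(mine$p, w$p.value, tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("eta squared to Cohen's f conversion and its inverse", {
  expect_equal(eta2_to_f(0.5), 1)
  expect_equal(eta2_to_f(0.40), 0.8165, tolerance = 1e-4)
  expect_equal(eta2_to_f(0.1628), 0.441, tolerance = 1e-3)
  expect_error(eta2_to_f(1), "0, 1")
})

test_that("required_sample_size returns the minimal analytically powered N", {
  n <- required_sample_size(f = 0.25, alpha = 0.05, power = 0.80,
                            n_groups = 2, n_measurements = 4, rho = 0.5)
  expect_gte(interaction_power(n, 0.25), 0.80)
  expect_lt(interaction_power(n - 1, 0.25), 0.80)

  # power saturates fast for a huge effect
  expect_equal(required_sample_size(f = 2), 4)
  expect_error(required_sample_size(f = -1), "f must be")
})

test_that("analytic interaction power matches a Monte-Carlo simulation", {
  f <- 0.4
  rho <- 0.5
  n <- required_sample_size(f = f, power = 0.8, rho = rho)
  expect_equal(n %% 1, 0)
  # generate split-plot data with the exact f and rho of the analytic model:
  # total variance 1, between-subject variance rho, interaction RMS = f
  g <- 2
  m <- 4
  delta <- matrix(c(1, -1, 1, -1, -1, 1, -1, 1), 2, 4, byrow = TRUE)
  delta <- delta / sqrt(mean(delta^2)) * f
  n_rep <- 400
  rej <- withr::with_seed(71, {
    vapply(seq_len(n_rep), function(r) {
      nj <- c(ceiling(n / 2), floor(n / 2))
      grp <- rep(c("Low", "High"), nj)
      subj <- rnorm(n, sd = sqrt(rho))
      y <- delta[as.integer(grp == "High") + 1, ] + subj +
        matrix(rnorm(n * m, sd = sqrt(1 - rho)), n, m)
      tab <- as.data.frame(y)
      names(tab) <- EMOTIONS
      tab$group <- grp
      tab$participant_id <- paste0("S", seq_len(n))
      a <- mixed_anova(tab)
      a$effects$p[a$effects$effect == "group:measure"] < 0.05
    }, logical(1))
  })
  mc_power <- mean(rej)
  analytic <- interaction_power(n, f, rho = rho)
  se <- sqrt(mc_power * (1 - mc_power) / n_rep)
  expect_lt(abs(mc_power - analytic), 3 * se + 0.02)
})
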
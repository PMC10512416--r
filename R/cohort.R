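#' Score the 20-item STAI trait/state inventory
#'
#' Each item is answered on a 1--4 scale; reverse-keyed items contribute
#' `5 - response`. The total therefore ranges from 20 to 80, with higher
#' scores indicating higher anxiety.
#'
#' @param responses integer vector of exactly 20 responses in `{1,2,3,4}`.
#' @param reverse_keyed indices (1--20) of the reverse-keyed items.
#' @return Integer total in `[20, 80]`.
#' @export
score_stai <- function(responses, reverse_keyed = integer(0)) {
  if (length(responses) != 20L) {
    stop_("STAI requires exactly 20 item responses, got %d", length(responses))
  }
  if (!all(responses %in% 1:4)) stop_("STAI responses must all be in 1..4")
  if (length(reverse_keyed) && !all(reverse_keyed %in% 1:20)) {
    stop_("reverse_keyed indices must be in 1..20")
  }
  scored <- responses
  scored[reverse_keyed] <- 5L - scored[reverse_keyed]
  as.integer(sum(scored))
}

#' Cohort simulation configuration
#'
#' Collects the parameters of the synthetic cohort: group sizes, trait-score
#' ranges on either side of the cutoff-39 split, per-emotion baseline
#' sensitivity (d-prime of the Gaussian evidence model), and the sensitivity
#' deficit applied to the High-anxiety group.
#'
#' Defaults emulate the study conditions: 15 Low-anxious (trait 33--39) and
#' 13 High-anxious (trait 40--47) observers; baseline d-primes chosen so
#' the population value of the six-point trapezoidal eAUC (see
#' [expected_eauc()]) falls in the observed 0.65--0.72 band once the two
#' groups are pooled; deficits on Fear and Disgust only, sized so the
#' implied Low-minus-High eAUC gaps are about 0.107 and 0.088.
#'
#' @param n_low,n_high group sizes (default 15 and 13).
#' @param low_range,high_range inclusive integer trait-score ranges; Low
#'   must lie within 20--39 and High within 40--80.
#' @param state_range inclusive integer state-score range for both groups.
#' @param base_dprime named vector of baseline d-prime per emotion.
#' @param high_deficit named vector subtracted from `base_dprime` for the
#'   High group; must be nonnegative and smaller than the baseline.
#' @param sigma_signal standard deviation of the signal evidence
#'   distribution (1 = equal-variance model).
#' @param decision_criterion evidence threshold for a "target" judgment.
#' @param conf_spacing spacing of the equally spaced confidence cuts, in
#'   evidence units (5 cuts partition distance-to-criterion into 6 bins).
#' @param seed master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_low = 15, n_high = 13,
                          low_range = c(33, 39), high_range = c(40, 47),
                          state_range = c(29, 42),
                          base_dprime = c(HA = 0.77, NE = 0.65, FE = 1.12, DI = 1.03),
                          high_deficit = c(HA = 0, NE = 0, FE = 0.46, DI = 0.37),
                          sigma_signal = 1, decision_criterion = 0.35,
                          conf_spacing = 0.4, seed = 1L) {
  if (n_low < 1 || n_high < 1) stop_("both group sizes must be >= 1")
  if (low_range[1] < 20 || low_range[2] > 39) {
    stop_("Low-group trait range must lie within [20, 39] (cutoff 39 inclusive)")
  }
  if (high_range[1] < 40 || high_range[2] > 80) {
    stop_("High-group trait range must lie within [40, 80]")
  }
  base_dprime <- base_dprime[EMOTIONS]
  high_deficit <- high_deficit[EMOTIONS]
  if (anyNA(base_dprime) || anyNA(high_deficit)) {
    stop_("base_dprime and high_deficit must name all four emotions")
  }
  if (any(base_dprime < 0)) stop_("base_dprime must be >= 0")
  if (any(high_deficit < 0) || any(base_dprime - high_deficit < 0)) {
    stop_("high_deficit must be >= 0 and no larger than base_dprime")
  }
  if (sigma_signal <= 0) stop_("sigma_signal must be > 0")
  structure(
    list(n_low = n_low, n_high = n_high, low_range = low_range,
         high_range = high_range, state_range = state_range,
         base_dprime = base_dprime, high_deficit = high_deficit,
         sigma_signal = sigma_signal, decision_criterion = decision_criterion,
         conf_spacing = conf_spacing, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Draw a synthetic cohort of observers
#'
#' Samples `n_low + n_high` observer profiles. Trait scores are discrete
#' uniform within each group's range (Low <= 39 < High); each observer's
#' per-emotion d-prime is the baseline, minus the configured deficit for
#' High-anxiety observers. All draws are reproducible from the config seed.
#'
#' @param config a [cohort_config()].
#' @return A list of `observer_profile` objects, each holding
#'   `participant_id`, `group`, `trait_score`, `state_score`, `dprime`
#'   (named vector over emotions), `sigma_signal`, `decision_criterion`
#'   and `confidence_cuts` (5 ascending reals).
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_low + config$n_high
  groups <- rep(c("Low", "High"), c(config$n_low, config$n_high))
  cuts <- config$conf_spacing * (1:5)
  profiles <- lapply(seq_len(n), function(i) {
    grp <- groups[i]
    rng <- if (grp == "Low") config$low_range else config$high_range
    trait <- with_seed(derive_seed(config$seed, "trait", i),
                       sample(seq(rng[1], rng[2]), 1L))
    state <- with_seed(derive_seed(config$seed, "state", i),
                       sample(seq(config$state_range[1], config$state_range[2]), 1L))
    dp <- config$base_dprime - if (grp == "High") config$high_deficit else 0
    structure(
      list(participant_id = sprintf("P%02d", i), group = grp,
           trait_score = trait, state_score = state, dprime = dp,
           sigma_signal = config$sigma_signal,
           decision_criterion = config$decision_criterion,
           confidence_cuts = cuts),
      class = "observer_profile"
    )
  })
  profiles
}

#' @export
print.observer_profile <- function(x, ...) {
  cat(sprintf("<observer_profile> %s (%s anxiety, trait %d)\n  d': %s\n",
              x$participant_id, x$group, x$trait_score,
              paste(sprintf("%s=%.2f", names(x$dprime), x$dprime), collapse = " ")))
  invisible(x)
}

#' Flatten observer profiles to a data frame
#'
#' @param profiles a list of `observer_profile` objects.
#' @return A data frame with one row per observer and one `dprime_*` column
#'   per emotion.
#' @export
profiles_to_df <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    row <- data.frame(participant_id = p$participant_id, group = p$group,
                      trait_score = p$trait_score, state_score = p$state_score,
                      stringsAsFactors = FALSE)
    for (em in names(p$dprime)) row[[paste0("dprime_", em)]] <- unname(p$dprime[em])
    row
  })
  do.call(rbind, rows)
}

simulate_records <- function(is_target, target_emotion, dprime, sigma_signal,
                             criterion, cuts, seed, participant_id = "sim",
                             trial_index = seq_along(is_target)) {
  n <- length(is_target)
  x <- with_seed(seed, rnorm(n, mean = ifelse(is_target, dprime, 0),
                             sd = ifelse(is_target, sigma_signal, 1)))
  judgment <- ifelse(x > criterion, "target", "nontarget")
  conf <- pmin(6L, 1L + vapply(abs(x - criterion),
                               function(d) sum(d > cuts), integer(1)))
  data.frame(participant_id = participant_id, session_target = target_emotion,
             trial_index = trial_index,
             stimulus_emotion = ifelse(is_target, target_emotion, NA_character_),
             is_target = is_target, judgment = judgment, confidence = conf,
             stringsAsFactors = FALSE)
}

#' Simulate confidence-graded rating trials directly
#'
#' Draws `n_signal` target and `n_noise` non-target trials from the Gaussian
#' evidence model without requiring a full experiment design: evidence is
#' `Normal(0, 1)` on non-target trials and `Normal(dprime, sigma_signal)` on
#' target trials, a "target" judgment is given when evidence exceeds the
#' decision criterion, and confidence 1--6 counts how many of the five cuts
#' the distance to criterion exceeds.
#'
#' @param n_signal,n_noise trial counts.
#' @param dprime evidence separation (>= 0).
#' @param sigma_signal signal distribution SD (default 1).
#' @param criterion decision criterion (default 0.4).
#' @param conf_spacing spacing of the confidence cuts (default 0.4).
#' @param seed integer seed.
#' @param target_emotion emotion label stamped on the records.
#' @return A trial-record data frame (see [simulate_trials()]).
#' @export
simulate_rating_trials <- function(n_signal, n_noise, dprime, sigma_signal = 1,
                                   criterion = 0.4, conf_spacing = 0.4,
                                   seed = 1L, target_emotion = "FE") {
  is_target <- rep(c(TRUE, FALSE), c(n_signal, n_noise))
  rec <- simulate_records(is_target, target_emotion, dprime, sigma_signal,
                          criterion, conf_spacing * (1:5), seed)
  rec$stimulus_emotion[!rec$is_target] <- "NT"
  rec
}

#' Simulate one observer's responses to an experiment design
#'
#' Runs the Gaussian evidence model over every trial of the design: in the
#' session whose target emotion is E, target trials draw evidence from
#' `Normal(dprime[E], sigma_signal)` and non-target trials from
#' `Normal(0, 1)`; the judgment is "target" when evidence exceeds the
#' observer's criterion and confidence grades the distance to criterion
#' into six bins.
#'
#' @param profile an `observer_profile` (see [sample_cohort()]).
#' @param design an `emo_design` from [build_design()].
#' @param seed integer seed for the evidence draws.
#' @return A data frame of trial records with columns `participant_id`,
#'   `session_target`, `trial_index`, `stimulus_emotion`, `is_target`,
#'   `judgment` and `confidence`.
#' @export
simulate_trials <- function(profile, design, seed = 1L) {
  stopifnot(inherits(profile, "observer_profile"), inherits(design, "emo_design"))
  v <- validate_design(design)
  if (!attr(v, "ok")) stop_("design fails validation; see validate_design()")
  if (anyNA(profile$dprime[unique(design$trials$session_target)])) {
    stop_("profile lacks a d-prime for one of the design's session targets")
  }
  tr <- design$trials
  rec <- simulate_records(
    tr$is_target, tr$session_target,
    dprime = unname(profile$dprime[tr$session_target]),
    sigma_signal = profile$sigma_signal,
    criterion = profile$decision_criterion,
    cuts = profile$confidence_cuts,
    seed = seed, participant_id = profile$participant_id,
    trial_index = tr$trial_index
  )
  rec$stimulus_emotion <- tr$stimulus_emotion
  rec$session_index <- tr$session_index
  rec[, c("participant_id", "session_index", "session_target", "trial_index",
          "stimulus_emotion", "is_target", "judgment", "confidence")]
}

#' Theoretical AUC of the Gaussian evidence model
#'
#' Closed-form area under the ROC implied by a noise distribution
#' `Normal(0, 1)` and a signal distribution `Normal(dprime, sigma_signal)`:
#' `pnorm(dprime / sqrt(1 + sigma_signal^2))`. With the default
#' equal-variance model this is the familiar `pnorm(dprime / sqrt(2))`.
#' Serves as the forward oracle for recovery tests of the empirical AUC.
#'
#' @param dprime evidence separation (may be a vector).
#' @param sigma_signal signal distribution SD (> 0).
#' @return AUC in `[0.5, 1)` for `dprime >= 0`.
#' @export
theoretical_auc <- function(dprime, sigma_signal = 1) {
  if (!is.numeric(sigma_signal) || any(sigma_signal <= 0)) {
    stop_("sigma_signal must be > 0")
  }
  pnorm(dprime / sqrt(1 + sigma_signal^2))
}

#' Population value of the six-point trapezoidal eAUC
#'
#' Closed form for the quantity the empirical pipeline estimates: the
#' trapezoidal area under the six operating points that a rating observer
#' with the given criterion and confidence cuts produces in the limit of
#' infinitely many trials. A "target, confidence >= k" response occurs when
#' evidence exceeds `criterion + cuts[k-1]`, so the six evidence thresholds
#' are `criterion + c(0, cuts)` and the operating points are the normal
#' tail probabilities at those thresholds.
#'
#' The difference `theoretical_auc(d) - expected_eauc(d, ...)` is the
#' discretization bias of the six-point construction: chords under the
#' concave ROC lose area wherever the operating points leave wide gaps.
#' The bias is small only when the thresholds straddle both shoulders of
#' the ROC; see the package vignette for the analysis.
#'
#' @param dprime evidence separation.
#' @param sigma_signal signal distribution SD (> 0).
#' @param criterion decision criterion.
#' @param conf_spacing spacing of the five equally spaced confidence cuts.
#' @return Expected six-point trapezoidal area in `[0, 1]`.
#' @export
expected_eauc <- function(dprime, sigma_signal = 1, criterion = 0.35,
                          conf_spacing = 0.4) {
  if (sigma_signal <= 0) stop_("sigma_signal must be > 0")
  t <- criterion + conf_spacing * (0:5)
  fa <- pnorm(-t)
  hit <- pnorm((dprime - t) / sigma_signal)
  f <- c(0, rev(fa), 1)
  h <- c(0, rev(hit), 1)
  sum(diff(f) * (h[-1] + h[-length(h)]) / 2)
}
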
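#' Tabulate rating counts for one target emotion
#'
#' Splits a session's trial records into Signal (target) and Noise
#' (non-target) trials and counts "target" judgments at each confidence
#' level 1--6: hits on Signal trials, false alarms on Noise trials.
#'
#' @param trials a trial-record data frame (see [simulate_trials()] or
#'   [read_trials()]); all rows must come from sessions whose target is
#'   `target_emotion`.
#' @param target_emotion the session's target emotion code.
#' @return An object of class `rating_counts`: `n_signal`, `n_noise`,
#'   `hits_by_conf` and `fas_by_conf` (named vectors over confidence 1--6).
#' @export
tabulate_counts <- function(trials, target_emotion) {
  tgt <- unique(trials$session_target)
  if (length(tgt) != 1L || tgt != target_emotion) {
    stop_("trials must all come from '%s' sessions (found: %s)",
          target_emotion, paste(tgt, collapse = ", "))
  }
  if (!all(trials$confidence %in% 1:6)) stop_("confidence must be in 1..6")
  count_conf <- function(mask) {
    tab <- table(factor(trials$confidence[mask], levels = 1:6))
    stats::setNames(as.integer(tab), 1:6)
  }
  said_target <- tolower(trials$judgment) == "target"
  structure(
    list(target_emotion = target_emotion,
         n_signal = sum(trials$is_target),
         n_noise = sum(!trials$is_target),
         hits_by_conf = count_conf(trials$is_target & said_target),
         fas_by_conf = count_conf(!trials$is_target & said_target)),
    class = "rating_counts"
  )
}

#' Corrected response-rate estimator
#'
#' The loglinear correction applied to every hit and false-alarm rate:
#' `(successes + 0.5) / (n_trials + 1)`. The estimate is strictly inside
#' (0, 1), so perfect or empty counts never produce degenerate rates.
#' Vectorized over `successes`.
#'
#' @param successes number of "target" judgments (hits or false alarms).
#' @param n_trials number of Signal or Noise trials (>= 1).
#' @return Corrected proportion(s) in (0, 1).
#' @export
corrected_rate <- function(successes, n_trials) {
  if (any(n_trials < 1)) stop_("n_trials must be >= 1")
  if (any(successes < 0) || any(successes > n_trials)) {
    stop_("successes must lie in [0, n_trials]")
  }
  (successes + 0.5) / (n_trials + 1)
}

#' Empirical ROC curve from rating counts
#'
#' Sweeps a confidence threshold from the most confident "target" response
#' downward: at threshold k the cumulative hit count is the number of hits
#' with confidence >= k, likewise for false alarms, and the operating point
#' is the pair of corrected rates. The six operating points are bracketed by
#' the anchors (0,0) and (1,1); cumulative construction guarantees the curve
#' is nondecreasing in both coordinates.
#'
#' @param counts a `rating_counts` object from [tabulate_counts()].
#' @return An object of class `roc_curve` whose `points` data frame has 8
#'   rows (`conf_threshold` is `NA` on the anchors) sorted by false-alarm
#'   rate, then hit rate.
#' @export
rating_roc <- function(counts) {
  stopifnot(inherits(counts, "rating_counts"))
  if (counts$n_signal < 1 || counts$n_noise < 1) {
    stop_("need at least one Signal and one Noise trial")
  }
  ks <- 6:1
  cum_hits <- vapply(ks, function(k) sum(counts$hits_by_conf[as.character(k:6)]), numeric(1))
  cum_fas <- vapply(ks, function(k) sum(counts$fas_by_conf[as.character(k:6)]), numeric(1))
  pts <- data.frame(
    conf_threshold = ks,
    fa_rate = corrected_rate(cum_fas, counts$n_noise),
    hit_rate = corrected_rate(cum_hits, counts$n_signal)
  )
  pts <- rbind(
    data.frame(conf_threshold = NA, fa_rate = 0, hit_rate = 0),
    pts,
    data.frame(conf_threshold = NA, fa_rate = 1, hit_rate = 1)
  )
  pts <- pts[order(pts$fa_rate, pts$hit_rate), ]
  rownames(pts) <- NULL
  structure(list(points = pts, target_emotion = counts$target_emotion),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve>%s %d points, eAUC = %.4f\n",
              if (is.null(x$target_emotion)) "" else paste0(" ", x$target_emotion),
              nrow(x$points), eauc(x)))
  invisible(x)
}

#' Plot an empirical ROC curve
#'
#' @param x a `roc_curve`.
#' @param ... passed to [plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  p <- x$points
  graphics::plot(p$fa_rate, p$hit_rate, type = "b", pch = 16,
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False-alarm rate", ylab = "Hit rate", ...)
  graphics::abline(0, 1, lty = 2, col = "red")
  invisible(x)
}

#' Empirical area under the ROC curve (eAUC)
#'
#' Trapezoidal area under the operating points sorted by false-alarm rate
#' (linear interpolation between adjacent points, including the corner
#' anchors). 0.5 is chance discrimination; 1 is perfect. The measure makes
#' no assumption about the shape of the evidence distributions and is not
#' affected by response bias.
#'
#' @param roc a `roc_curve` from [rating_roc()].
#' @return Area in `[0, 1]`.
#' @export
eauc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points
  if (is.unsorted(p$fa_rate)) stop_("ROC points must be sorted by fa_rate")
  f <- p$fa_rate
  h <- p$hit_rate
  sum(diff(f) * (h[-1] + h[-length(h)]) / 2)
}

#' Score a participant's trial records into per-emotion eAUC
#'
#' For each of the four target emotions, tabulates that session's counts,
#' builds the rating ROC, and computes the eAUC.
#'
#' @param trials trial records for one participant covering all four
#'   sessions.
#' @return Named numeric vector of eAUC over the four emotions.
#' @export
score_participant <- function(trials) {
  vapply(EMOTIONS, function(em) {
    sub <- trials[trials$session_target == em, ]
    if (!nrow(sub)) stop_("no trials for target emotion %s", em)
    eauc(rating_roc(tabulate_counts(sub, em)))
  }, numeric(1))
}

#' Build the participant-by-emotion eAUC table
#'
#' Scores every participant's records and joins the anxiety covariates.
#'
#' @param trials trial records for the whole cohort.
#' @param traits a data frame with `participant_id`, `trait_score` and
#'   optionally `group` (e.g. from [profiles_to_df()]).
#' @return A data frame with one row per participant: `participant_id`, the
#'   four emotion eAUC columns, `trait_score` and `group` when available.
#' @export
eauc_table <- function(trials, traits = NULL) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    sc <- score_participant(trials[trials$participant_id == id, ])
    cbind(data.frame(participant_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(sc)))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(traits)) {
    keep <- intersect(c("participant_id", "trait_score", "state_score", "group"),
                      names(traits))
    tab <- merge(tab, traits[, keep], by = "participant_id", sort = FALSE)
  }
  tab
}

#' Exclude at-chance participants
#'
#' Retains only participants whose eAUC is strictly above the chance
#' threshold (default 0.50) in all four target emotions; participants at or
#' below threshold in any emotion are excluded.
#'
#' @param table an eAUC table (see [eauc_table()]); the four emotion columns
#'   must be complete.
#' @param threshold chance level (default 0.5).
#' @return A list with `retained` (the filtered table) and `excluded` (a
#'   data frame of excluded `participant_id`s and the offending emotions).
#' @export
apply_exclusion <- function(table, threshold = 0.5) {
  if (!all(EMOTIONS %in% names(table))) {
    stop_("table must contain the four emotion columns: %s",
          paste(EMOTIONS, collapse = ", "))
  }
  m <- as.matrix(table[, EMOTIONS])
  if (anyNA(m)) stop_("eAUC table has missing cells")
  ok <- apply(m > threshold, 1, all)
  excluded <- data.frame(
    participant_id = table$participant_id[!ok],
    failed_emotions = vapply(which(!ok), function(i) {
      paste(EMOTIONS[m[i, ] <= threshold], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(excluded) <- NULL
  list(retained = table[ok, , drop = FALSE], excluded = excluded)
}
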
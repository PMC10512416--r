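#' Build a synthetic stimulus catalog
#'
#' Creates a catalog of vocal stimuli mirroring the experiment's source
#' material: 30 clips per emotion, 15 spoken by female and 15 by male actors.
#' Stimulus identifiers encode emotion, speaker sex and an index (e.g.
#' `"FE_F_07"`).
#'
#' @param n_per_sex clips per (emotion, speaker sex) cell; default 15.
#' @param wav_path optional directory prefix recorded in the `wav_path`
#'   column (left `NA` when missing).
#' @return A data frame with columns `stimulus_id`, `emotion`, `speaker_sex`
#'   and `wav_path`.
#' @export
synthetic_catalog <- function(n_per_sex = 15, wav_path = NA_character_) {
  grid <- expand.grid(
    idx = seq_len(n_per_sex), speaker_sex = c("F", "M"), emotion = EMOTIONS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  id <- sprintf("%s_%s_%02d", grid$emotion, grid$speaker_sex, grid$idx)
  data.frame(
    stimulus_id = id,
    emotion = grid$emotion,
    speaker_sex = grid$speaker_sex,
    wav_path = if (is.na(wav_path)) NA_character_ else file.path(wav_path, paste0(id, ".wav")),
    stringsAsFactors = FALSE
  )
}

#' Read a stimulus catalog from CSV
#'
#' Expects columns `stimulus_id`, `emotion`, `speaker_sex` and optionally
#' `wav_path`. Emotion codes must be among `r paste(EMOTIONS, collapse = ", ")`
#' and stimulus identifiers unique.
#'
#' @param path path to a CSV file.
#' @return A catalog data frame.
#' @export
read_catalog <- function(path) {
  cat <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("stimulus_id", "emotion", "speaker_sex")
  missing <- setdiff(needed, names(cat))
  if (length(missing)) stop_("catalog is missing column(s): %s", paste(missing, collapse = ", "))
  bad <- setdiff(unique(cat$emotion), EMOTIONS)
  if (length(bad)) stop_("catalog has unknown emotion code(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(cat$stimulus_id)) stop_("catalog has duplicated stimulus_id values")
  if (!all(cat$speaker_sex %in% c("F", "M"))) stop_("speaker_sex must be 'F' or 'M'")
  if (!"wav_path" %in% names(cat)) cat$wav_path <- NA_character_
  cat
}

check_catalog_cells <- function(catalog, n_per_emotion = 30, n_per_sex = 15) {
  for (em in EMOTIONS) {
    sub <- catalog[catalog$emotion == em, ]
    if (nrow(sub) < n_per_emotion) {
      stop_("catalog has only %d stimuli for emotion %s (need %d)", nrow(sub), em, n_per_emotion)
    }
    for (sx in c("F", "M")) {
      k <- sum(sub$speaker_sex == sx)
      if (k < n_per_sex) {
        stop_("catalog has only %d stimuli for cell (%s, %s) (need %d)", k, em, sx, n_per_sex)
      }
    }
  }
  invisible(TRUE)
}

#' Build one participant's experiment design
#'
#' Assembles the four-session target-detection design: one session per target
#' emotion, each with 60 trials (30 target, 30 non-target; the non-targets
#' are 10 stimuli from each of the other three emotions, balanced 5 female /
#' 5 male). Session order, stimulus selection, trial order and fixation
#' jitter are all drawn from independent sub-streams of one master seed, so
#' the design is fully reproducible from `(catalog, participant_id, seed)`.
#'
#' Each emotion's 30 selected stimuli all serve as targets in that emotion's
#' session and are partitioned into three disjoint sets of 10 (5 per speaker
#' sex), one set per session in which the emotion is a non-target; every
#' stimulus therefore appears exactly twice in the experiment.
#'
#' Per-trial timing follows the task timeline: a fixation cross jittered
#' uniformly on 300--500 ms, a 3,000 ms speech-in-noise clip, a 3,000 ms
#' blank, and a 500 ms inter-trial interval.
#'
#' @param catalog a stimulus catalog data frame (see [read_catalog()]);
#'   must contain at least 30 stimuli per emotion with at least 15 per
#'   speaker sex.
#' @param participant_id identifier recorded on every trial.
#' @param seed master integer seed.
#' @return An object of class `emo_design`: a list with `participant_id`,
#'   `seed`, `session_order` and `trials` (a 240-row data frame with one row
#'   per trial).
#' @seealso [validate_design()], [write_design()]
#' @export
build_design <- function(catalog, participant_id, seed) {
  check_catalog_cells(catalog)
  session_order <- with_seed(derive_seed(seed, participant_id, "session_order"),
                             sample(EMOTIONS))

  # per emotion: select 15 + 15 stimuli, then partition into three
  # non-target sets of 5F + 5M for the three sessions where it is non-target
  selected <- list()
  nt_sets <- list()
  for (em in EMOTIONS) {
    sub <- catalog[catalog$emotion == em, ]
    pick <- with_seed(derive_seed(seed, participant_id, "select", em), {
      rbind(
        sub[sub$speaker_sex == "F", ][sample(sum(sub$speaker_sex == "F"), 15), ],
        sub[sub$speaker_sex == "M", ][sample(sum(sub$speaker_sex == "M"), 15), ]
      )
    })
    parts <- with_seed(derive_seed(seed, participant_id, "partition", em), {
      f_order <- sample(which(pick$speaker_sex == "F"))
      m_order <- sample(which(pick$speaker_sex == "M"))
      lapply(1:3, function(i) {
        pick[c(f_order[(5 * i - 4):(5 * i)], m_order[(5 * i - 4):(5 * i)]), ]
      })
    })
    selected[[em]] <- pick
    nt_sets[[em]] <- parts
  }

  sessions <- vector("list", 4)
  nt_use <- stats::setNames(rep(0L, 4), EMOTIONS)  # how many non-target sets consumed
  for (s in seq_len(4)) {
    target <- session_order[s]
    rows <- selected[[target]]
    rows$is_target <- TRUE
    for (em in setdiff(EMOTIONS, target)) {
      nt_use[em] <- nt_use[em] + 1L
      nt <- nt_sets[[em]][[nt_use[em]]]
      nt$is_target <- FALSE
      rows <- rbind(rows, nt)
    }
    ord <- with_seed(derive_seed(seed, participant_id, "trial_order", s), sample(nrow(rows)))
    rows <- rows[ord, ]
    rows$fixation_ms <- with_seed(derive_seed(seed, participant_id, "fixation", s),
                                  as.integer(round(runif(nrow(rows), 300, 500))))
    rows$session_index <- s
    rows$session_target <- target
    rows$trial_index <- seq_len(nrow(rows))
    sessions[[s]] <- rows
  }
  trials <- do.call(rbind, sessions)
  trials <- data.frame(
    participant_id = participant_id,
    session_index = trials$session_index,
    session_target = trials$session_target,
    trial_index = trials$trial_index,
    stimulus_id = trials$stimulus_id,
    stimulus_emotion = trials$emotion,
    speaker_sex = trials$speaker_sex,
    is_target = trials$is_target,
    fixation_ms = trials$fixation_ms,
    stimulus_ms = 3000L,
    post_blank_ms = 3000L,
    iti_ms = 500L,
    stringsAsFactors = FALSE
  )
  rownames(trials) <- NULL
  structure(
    list(participant_id = participant_id, seed = as.integer(seed),
         session_order = session_order, trials = trials),
    class = "emo_design"
  )
}

#' @export
print.emo_design <- function(x, ...) {
  cat(sprintf("<emo_design> participant %s, seed %d\n", x$participant_id, x$seed))
  cat(sprintf("  session order: %s\n", paste(x$session_order, collapse = " -> ")))
  cat(sprintf("  %d trials (%d per session)\n", nrow(x$trials),
              nrow(x$trials) %/% length(x$session_order)))
  invisible(x)
}

#' Validate an experiment design
#'
#' Checks every structural invariant of the design and reports pass/fail per
#' check instead of raising: 4 sessions covering all emotions, 60 trials per
#' session with 30 targets, 10 non-targets per other emotion balanced 5
#' female / 5 male, no stimulus repeated within a session, target status
#' consistent with the session's target emotion, fixation jitter within
#' 300--500 ms, and 240 trials in total.
#'
#' @param design an `emo_design` object, or any list with a compatible
#'   `trials` data frame (so that deliberately corrupted designs can be
#'   inspected).
#' @return A data frame with columns `check`, `pass` and `detail`; the
#'   attribute `"ok"` is `TRUE` when all checks pass.
#' @export
validate_design <- function(design) {
  tr <- design$trials
  res <- list()
  add <- function(check, pass, detail = "") {
    res[[length(res) + 1L]] <<- data.frame(check = check, pass = pass,
                                           detail = detail, stringsAsFactors = FALSE)
  }
  sess <- sort(unique(tr$session_index))
  add("session_count", length(sess) == 4, sprintf("%d sessions", length(sess)))
  targets <- vapply(sess, function(s) unique(tr$session_target[tr$session_index == s])[1], "")
  add("session_targets_cover_emotions", setequal(targets, EMOTIONS),
      paste(targets, collapse = ","))
  add("total_trials", nrow(tr) == 240, sprintf("%d trials", nrow(tr)))
  for (s in sess) {
    st <- tr[tr$session_index == s, ]
    tgt <- st$session_target[1]
    if (nrow(st) != 60) add(sprintf("session_%d_n_trials", s), FALSE, sprintf("%d trials", nrow(st)))
    n_tgt <- sum(st$is_target)
    add(sprintf("session_%d_target_count", s), n_tgt == 30,
        sprintf("session %d: %d target trials", s, n_tgt))
    for (em in setdiff(EMOTIONS, tgt)) {
      nt <- st[!st$is_target & st$stimulus_emotion == em, ]
      ok <- nrow(nt) == 10 && sum(nt$speaker_sex == "F") == 5 && sum(nt$speaker_sex == "M") == 5
      add(sprintf("session_%d_nontarget_%s", s, em), ok,
          sprintf("%d trials (%dF/%dM)", nrow(nt), sum(nt$speaker_sex == "F"),
                  sum(nt$speaker_sex == "M")))
    }
    add(sprintf("session_%d_unique_stimuli", s), !anyDuplicated(st$stimulus_id),
        sprintf("session %d", s))
    add(sprintf("session_%d_target_consistency", s),
        all(st$is_target == (st$stimulus_emotion == tgt)), sprintf("session %d", s))
  }
  add("fixation_bounds", all(tr$fixation_ms >= 300 & tr$fixation_ms <= 500),
      sprintf("range [%d, %d] ms", min(tr$fixation_ms), max(tr$fixation_ms)))
  out <- do.call(rbind, res)
  attr(out, "ok") <- all(out$pass)
  out
}

#' Export a design as a per-trial CSV
#'
#' @param design an `emo_design` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  cols <- c("participant_id", "session_index", "session_target", "trial_index",
            "stimulus_id", "stimulus_emotion", "is_target", "fixation_ms")
  write.csv(design$trials[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
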
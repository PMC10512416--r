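TRIAL_COLUMNS <- c("participant_id", "session_target", "trial_index",
                   "stimulus_emotion", "is_target", "judgment", "confidence")

#' Read trial records from CSV
#'
#' Reads and validates a trial-record table. Required columns:
#' `participant_id`, `session_target`, `trial_index`, `stimulus_emotion`,
#' `is_target`, `judgment`, `confidence`. Judgments are accepted
#' case-insensitively (`"Target"` is normalized to `"target"`); confidence
#' must be an integer 1--6; emotion codes must be known. Violations raise
#' an error naming the offending row.
#'
#' @param path CSV path.
#' @return A validated trial-record data frame; unknown columns are kept.
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing)) stop_("trials file is missing column(s): %s",
                             paste(missing, collapse = ", "))
  bad <- which(!tr$confidence %in% 1:6)
  if (length(bad)) stop_("row %d: confidence %s is outside 1..6", bad[1], tr$confidence[bad[1]])
  tr$judgment <- tolower(tr$judgment)
  bad <- which(!tr$judgment %in% c("target", "nontarget"))
  if (length(bad)) stop_("row %d: judgment '%s' is not 'target'/'nontarget'",
                         bad[1], tr$judgment[bad[1]])
  bad <- which(!tr$session_target %in% EMOTIONS)
  if (length(bad)) stop_("row %d: unknown emotion code '%s'", bad[1], tr$session_target[bad[1]])
  if (is.character(tr$is_target)) tr$is_target <- toupper(tr$is_target) %in% c("TRUE", "T", "1")
  tr$is_target <- as.logical(tr$is_target)
  tr
}

#' Write trial records to CSV
#'
#' @param records a trial-record data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(records))
  if (length(missing)) stop_("records are missing column(s): %s",
                             paste(missing, collapse = ", "))
  records$judgment <- tolower(records$judgment)
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the cohort configuration with the analysis options and the
#' master seed for an end-to-end run.
#'
#' @param cohort a [cohort_config()] (its seed is overridden by `seed`).
#' @param cutoff trait-anxiety cutoff for the group split (default 39).
#' @param alpha significance level (default 0.05, two-tailed).
#' @param family_size Bonferroni family for the simple main effects.
#' @param exclusion_threshold chance-level eAUC threshold (default 0.5).
#' @param seed master seed for the whole run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), cutoff = 39,
                            alpha = 0.05, family_size = 4,
                            exclusion_threshold = 0.5, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, cutoff = cutoff, alpha = alpha,
                 family_size = family_size,
                 exclusion_threshold = exclusion_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may set any argument of [pipeline_config()] at the top level
#' and any argument of [cohort_config()] under a `cohort` key.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  co_args <- raw$cohort %||% list()
  for (nm in c("base_dprime", "high_deficit")) {
    if (!is.null(co_args[[nm]])) co_args[[nm]] <- unlist(co_args[[nm]])
  }
  cohort <- do.call(cohort_config, co_args)
  args <- raw[setdiff(names(raw), "cohort")]
  args$cohort <- cohort
  do.call(pipeline_config, args)
}

#' Run the full synthetic replication pipeline
#'
#' Executes every stage end to end: draw the observer cohort, build each
#' participant's four-session design, simulate confidence-graded responses,
#' score them into per-emotion eAUC, drop at-chance participants, split the
#' remainder at the trait-anxiety cutoff, and run the group-level inference
#' (assumption checks, 2 x 4 mixed ANOVA, Bonferroni simple main effects,
#' and Mann-Whitney U tests on trait scores and on the per-participant
#' four-emotion average eAUC). All outputs are reproducible from
#' `(config, seed)`.
#'
#' When `out_dir` is given, writes `trials.csv`, `eauc.csv`,
#' `roc_points.csv`, `stats.json` and `run_log.txt` there; `stats.json`
#' embeds the configuration, seed and package version.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress progress logging to stderr.
#' @return A run report list: `eauc` (full table), `retained`, `excluded`,
#'   `split`, `anova`, `simple_effects`, `mwu_trait`, `mwu_mean_eauc`,
#'   `assumptions`, `seed`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  seed <- config$seed
  say("cohort", sprintf("sampling %d + %d observers (seed %d)",
                        config$cohort$n_low, config$cohort$n_high, seed))
  profiles <- sample_cohort(config$cohort)
  catalog <- synthetic_catalog()

  say("simulate", "building designs and simulating responses")
  all_trials <- do.call(rbind, lapply(profiles, function(p) {
    design <- build_design(catalog, p$participant_id,
                           derive_seed(seed, "design", p$participant_id))
    simulate_trials(p, design, derive_seed(seed, "responses", p$participant_id))
  }))

  say("score", "computing per-emotion rating ROCs and eAUC")
  traits <- profiles_to_df(profiles)
  tab <- eauc_table(all_trials, traits)

  roc_points <- do.call(rbind, lapply(unique(all_trials$participant_id), function(id) {
    sub <- all_trials[all_trials$participant_id == id, ]
    do.call(rbind, lapply(EMOTIONS, function(em) {
      pts <- rating_roc(tabulate_counts(sub[sub$session_target == em, ], em))$points
      cbind(data.frame(participant_id = id, emotion = em, stringsAsFactors = FALSE), pts)
    }))
  }))

  excl <- apply_exclusion(tab, config$exclusion_threshold)
  say("exclude", sprintf("%d retained, %d excluded at chance level %.2f",
                         nrow(excl$retained), nrow(excl$excluded),
                         config$exclusion_threshold))
  retained <- excl$retained
  split <- split_by_cutoff(retained, cutoff = config$cutoff)

  say("analyze", "assumption checks, mixed ANOVA, simple effects, rank tests")
  assumptions <- list(
    normality = lapply(stats::setNames(EMOTIONS, EMOTIONS), function(em) {
      normality_tests(retained[[em]], kind = "ks", alpha = config$alpha)
    }),
    sphericity = mauchly_sphericity(as.matrix(retained[, EMOTIONS]),
                                    alpha = config$alpha)
  )
  aov_res <- mixed_anova(retained)
  sme <- simple_main_effects(retained, family_size = config$family_size)
  low <- retained$group == "Low"
  mwu_trait <- mann_whitney(retained$trait_score[low], retained$trait_score[!low])
  mean_eauc <- rowMeans(retained[, EMOTIONS])
  mwu_mean <- mann_whitney(mean_eauc[low], mean_eauc[!low])

  report <- list(
    eauc = tab, retained = retained, excluded = excl$excluded, split = split,
    anova = aov_res, simple_effects = sme, mwu_trait = mwu_trait,
    mwu_mean_eauc = mwu_mean, assumptions = assumptions,
    trials = all_trials, roc_points = roc_points,
    seed = seed, config = config,
    version = as.character(packageVersion("emoroc"))
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    say("write", sprintf("writing outputs to %s", out_dir))
    write_trials(all_trials, file.path(out_dir, "trials.csv"))
    write.csv(tab, file.path(out_dir, "eauc.csv"), row.names = FALSE, quote = FALSE)
    write.csv(roc_points, file.path(out_dir, "roc_points.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(report)
}

# Serializable view of a run report (everything numeric traceable to a
# module operation, plus config, seed and version).
report_to_json <- function(report) {
  cfg <- report$config
  list(
    seed = report$seed,
    version = report$version,
    config = list(
      n_low = cfg$cohort$n_low, n_high = cfg$cohort$n_high,
      base_dprime = as.list(cfg$cohort$base_dprime),
      high_deficit = as.list(cfg$cohort$high_deficit),
      sigma_signal = cfg$cohort$sigma_signal,
      decision_criterion = cfg$cohort$decision_criterion,
      conf_spacing = cfg$cohort$conf_spacing,
      cutoff = cfg$cutoff, alpha = cfg$alpha,
      family_size = cfg$family_size,
      exclusion_threshold = cfg$exclusion_threshold
    ),
    n_retained = nrow(report$retained),
    n_excluded = nrow(report$excluded),
    group_sizes = list(low = length(report$split$low_ids),
                       high = length(report$split$high_ids)),
    mean_eauc_by_emotion = as.list(colMeans(report$retained[, EMOTIONS])),
    anova = report$anova$effects,
    simple_effects = report$simple_effects,
    mwu_trait = unclass(report$mwu_trait),
    mwu_mean_eauc = unclass(report$mwu_mean_eauc),
    assumptions = list(
      normality = lapply(report$assumptions$normality, unclass),
      sphericity = unclass(report$assumptions$sphericity)
    )
  )
}
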
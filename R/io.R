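# Configuration, trial-table IO and the end-to-end pipeline binding
# simulation -> metrics -> model predictions -> group inference.

trial_columns <- c("subject", "run", "block", "task", "stimulus", "response",
                   "correct", "confidence", "snr", "resp_mapping")

#' Write a trial table as delimited text
#'
#' Comma-separated, UTF-8, header row, '.' decimal, empty cell = missing;
#' one trial per row with the trial-record columns in canonical order.
#'
#' @param trials Trial table (see [generate_session()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0)
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(trials[, trial_columns], path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Reads a delimited trial table written by [write_trials()] and validates
#' the schema: required columns present, task and stimulus labels
#' consistent, confidence in 1-6 or missing, and missing responses implying
#' missing confidence and correctness. Malformed rows are reported with
#' their file line numbers. Unknown columns are rejected unless
#' `permissive = TRUE`.
#'
#' @param path Input file path.
#' @param permissive Allow (and keep) extra columns.
#' @return Validated trial table.
#' @export
read_trials <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", colClasses = NA)
  missing_cols <- setdiff(trial_columns, names(tr))
  if (length(missing_cols) > 0)
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(tr), trial_columns)
  if (length(extra) > 0 && !permissive)
    stop("unknown columns (use permissive = TRUE to keep them): ",
         paste(extra, collapse = ", "))
  tr$correct <- as.logical(tr$correct)
  tr$confidence <- as.integer(tr$confidence)
  line <- function(i) i + 1L   # header occupies line 1
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0)
      stop("invalid trial table '", path, "': ", what, " at line",
           if (length(i) > 1) "s" else "", " ",
           paste(utils::head(line(i), 5), collapse = ", "),
           if (length(i) > 5) " ..." else "")
  }
  bad(!tr$task %in% c("detection", "discrimination"), "unknown task")
  for (task in c("detection", "discrimination")) {
    idx <- tr$task == task
    bad(idx & !tr$stimulus %in% task_classes(task),
        paste0("stimulus inconsistent with ", task))
    bad(idx & !is.na(tr$response) & !tr$response %in% task_responses(task),
        paste0("response inconsistent with ", task))
  }
  bad(!is.na(tr$confidence) & (tr$confidence < 1 | tr$confidence > 6),
      "confidence outside 1..6")
  bad(is.na(tr$response) & (!is.na(tr$confidence) | !is.na(tr$correct)),
      "missing response with non-missing confidence/correctness")
  bad(!is.finite(tr$snr) | tr$snr <= 0, "non-positive snr")
  tr
}

#' Pipeline run configuration
#'
#' @param seed Global seed; all randomness in [run_pipeline()] flows from it
#'   through named substreams (see [substream_seed()]).
#' @param n_subjects Number of simulated subjects.
#' @param observer Observer generating the behavioural sessions (the static
#'   SDT observer; the dynamic and attention models enter through the
#'   prediction stage).
#' @param design Arguments for [session_design()] as a named list.
#' @param n_model_trials Trials per task for each model's prediction curve.
#' @param profile_noise_sd Noise sd of the synthetic regional profiles.
#' @param stages Which stages to run.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_subjects = 8L, observer = "static",
                       design = list(), n_model_trials = 2e4,
                       profile_noise_sd = 0.2,
                       stages = c("simulate", "metrics", "predict", "infer")) {
  stopifnot(n_subjects >= 2, n_model_trials >= 100)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 observer = observer, design = design,
                 n_model_trials = as.integer(n_model_trials),
                 profile_noise_sd = profile_noise_sd,
                 stages = stages),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' The YAML round-trip is lossless: reading a written configuration yields
#' an identical object.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()`: `path` invisibly; `read_run_config()`: a
#'   `"run_config"`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Derive a named substream seed
#'
#' Deterministically maps (global seed, stream label, index) to an integer
#' seed, so that each pipeline stage and each subject draws from its own
#' substream: changing one substream's draws leaves the others' outputs
#' unchanged.
#'
#' @param seed Global integer seed.
#' @param label Stream label (e.g. `"subject"`, `"predict"`).
#' @param index Within-stream index (e.g. subject number).
#' @return Integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  as.integer((as.numeric(seed) * 48271 + h * 16807 + index) %% 2147483647)
}

#' Run the full simulation-to-inference pipeline
#'
#' Executes the configured stages and writes their artifacts under
#' `out_dir`: `trials.csv` (all subjects' sessions), `exclusions.csv` and
#' `metacognition.csv` (per-subject AUROC2 by response, meta-d', m-ratio),
#' `prediction_curves.csv` and `curve_coefficients.csv` (the three observer
#' models), `profiles.csv` and `group_results.csv` (synthetic regional
#' profiles and the contrast battery), plus `manifest.json` recording the
#' configuration, seeds, package version and completed stages. Re-running
#' with the same configuration reproduces all outputs bit-identically; on a
#' partial failure the manifest names the stages that completed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   package_version = as.character(
                     utils::packageVersion("metadetect")),
                   completed = character(0))
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on.exit(save_manifest())
  design <- do.call(session_design, config$design)

  trials <- NULL
  if ("simulate" %in% config$stages) {
    sessions <- lapply(seq_len(config$n_subjects), function(i) {
      generate_session(sprintf("s%02d", i), design,
                       seed = substream_seed(config$seed, "subject", i))
    })
    trials <- do.call(rbind, sessions)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    manifest$completed <- c(manifest$completed, "simulate")
  }

  if ("metrics" %in% config$stages) {
    if (is.null(trials))
      trials <- read_trials(file.path(out_dir, "trials.csv"))
    excl <- lapply(split(trials, trials$subject), apply_exclusion)
    excl_df <- do.call(rbind, lapply(excl, `[[`, "subject"))
    utils::write.csv(excl_df, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    included <- excl_df$subject[excl_df$included]
    met <- lapply(included, function(s) {
      st <- trials[trials$subject == s, ]
      a <- auroc2_from_trials(st)
      md <- lapply(c("detection", "discrimination"), function(task) {
        fit <- meta_dprime(response_confidence_counts(
          st[st$task == task, ], task))
        data.frame(subject = s, task = task, meta_d = fit$meta_d,
                   dprime = fit$dprime, m_ratio = fit$m_ratio,
                   stringsAsFactors = FALSE)
      })
      a$subject <- s
      list(auroc = a, meta = do.call(rbind, md))
    })
    utils::write.csv(do.call(rbind, lapply(met, `[[`, "auroc")),
                     file.path(out_dir, "auroc2.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, lapply(met, `[[`, "meta")),
                     file.path(out_dir, "metacognition.csv"),
                     row.names = FALSE)
    manifest$completed <- c(manifest$completed, "metrics")
  }

  if ("predict" %in% config$stages) {
    n <- config$n_model_trials
    sseed <- function(lbl) substream_seed(config$seed, lbl)
    curves <- rbind(
      static_prediction(n_trials = n, seed = sseed("predict_static")),
      dynamic_criterion_simulate("detection", n_trials = n,
                                 seed = sseed("predict_dyn_det"))$curve,
      dynamic_criterion_simulate("discrimination", n_trials = n,
                                 seed = sseed("predict_dyn_disc"))$curve,
      attention_monitoring_simulate("detection", n_trials = n,
                                    seed = sseed("predict_att_det"))$curve,
      attention_monitoring_simulate("discrimination", n_trials = n,
                                    seed = sseed("predict_att_disc"))$curve)
    utils::write.csv(curves, file.path(out_dir, "prediction_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(curve_poly_fit(curves),
                     file.path(out_dir, "curve_coefficients.csv"),
                     row.names = FALSE)
    manifest$completed <- c(manifest$completed, "predict")
  }

  if ("infer" %in% config$stages) {
    profiles <- generate_roi_profiles(
      noise_sd = config$profile_noise_sd, n_subjects = config$n_subjects,
      seed = substream_seed(config$seed, "profiles"))
    utils::write.csv(profiles, file.path(out_dir, "profiles.csv"),
                     row.names = FALSE)
    battery <- standard_contrast_battery(fit_profile_table(profiles))
    utils::write.csv(battery, file.path(out_dir, "group_results.csv"),
                     row.names = FALSE)
    manifest$completed <- c(manifest$completed, "infer")
  }
  invisible(manifest)
}
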
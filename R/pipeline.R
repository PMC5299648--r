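#' Write a sampled signal as a two-column CSV
#'
#' Columns `time_s` (sample time, `(i-1)/fs`) and `voltage_mV`.
#'
#' @param sig a [sampled_signal()].
#' @param path output file.
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "sampled_signal"))
  df <- data.frame(time_s = (seq_along(sig$samples) - 1) / sig$fs,
                   voltage_mV = sig$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a recording from CSV
#'
#' Accepts either a two-column CSV (`time_s`, `voltage_mV`) whose
#' sampling frequency is inferred from the time column — the grid must be
#' uniform within 1e-6 s — or a one-column CSV accompanied by a JSON
#' sidecar carrying `fs` (by default the same path with extension
#' `.json`).
#'
#' @param path CSV file path.
#' @param sidecar optional path of the JSON sidecar for one-column input.
#' @return A [sampled_signal()].
#' @export
load_signal <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path)
  if (ncol(df) >= 2L) {
    t <- as.numeric(df[[1L]]); v <- as.numeric(df[[2L]])
    dt <- diff(t)
    if (length(dt) < 1L || any(dt <= 0))
      stop("time column must be strictly increasing", call. = FALSE)
    fs <- (length(t) - 1) / (t[length(t)] - t[1L])
    if (max(abs(dt - 1 / fs)) > 1e-6)
      stop("non-uniform timestamps: sample grid deviates by more than 1e-6 s",
           call. = FALSE)
    ## snap to an integer rate when the data are within rounding of one
    if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
    sampled_signal(v, fs)
  } else {
    if (is.null(sidecar)) sidecar <- sub("\\.[^.]+$", ".json", path)
    if (!file.exists(sidecar))
      stop("one-column CSV requires a JSON sidecar carrying fs",
           call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("sidecar JSON has no 'fs' field",
                               call. = FALSE)
    sampled_signal(as.numeric(df[[1L]]), as.numeric(meta$fs))
  }
}

#' Trial manifest
#'
#' Describes where each subject's three period recordings live.
#'
#' @param trial_dir directory containing the recordings.
#' @param subjects list of lists with `subject_id`, `path_before`,
#'   `path_during`, `path_after`.
#' @param fs declared sampling frequency (optional; `NA` to infer from
#'   the files).
#' @return A `"trial_manifest"` object.
#' @export
trial_manifest <- function(trial_dir, subjects, fs = NA_real_) {
  structure(list(trial_dir = trial_dir, subjects = subjects, fs = fs),
            class = "trial_manifest")
}

#' @rdname trial_manifest
#' @param dir a directory written by [write_trial()]: recordings named
#'   `subjectNN_<period>.csv`.
#' @export
read_trial_manifest <- function(dir) {
  files <- list.files(dir, pattern = "^subject[0-9]+_before\\.csv$")
  if (length(files) == 0L)
    stop(sprintf("no subject recordings found under %s", dir),
         call. = FALSE)
  ids <- as.integer(sub("^subject([0-9]+)_before\\.csv$", "\\1", files))
  subjects <- lapply(sort(ids), function(id) {
    list(subject_id = id,
         path_before = file.path(dir, sprintf("subject%02d_before.csv", id)),
         path_during = file.path(dir, sprintf("subject%02d_during.csv", id)),
         path_after  = file.path(dir, sprintf("subject%02d_after.csv", id)))
  })
  trial_manifest(dir, subjects)
}

#' Pipeline configuration
#'
#' Defaults follow the study protocol the pipeline reproduces: 0.5-45 Hz
#' band-pass, beat window anchored 35% before the R peak, x2 amplitude
#' artifact rejection, order grid up to 5th-order denominators.
#'
#' @param low_hz,high_hz band-pass edges, Hz.
#' @param pre_r_fraction fraction of the beat window before the R peak.
#' @param multiplier artifact-rejection amplitude multiplier (> 1).
#' @param max_den largest denominator order of the grid.
#' @param orders_override optional `c(num_order, den_order)` to skip grid
#'   selection and fit ITFs at a fixed order.
#' @param digits report precision (decimals) for GF values.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(low_hz = 0.5, high_hz = 45,
                            pre_r_fraction = 0.35, multiplier = 2,
                            max_den = 5, orders_override = NULL,
                            digits = 2) {
  if (multiplier <= 1) stop("rejection multiplier must exceed 1",
                            call. = FALSE)
  if (pre_r_fraction <= 0 || pre_r_fraction >= 1)
    stop("pre_r_fraction must lie strictly between 0 and 1", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 pre_r_fraction = pre_r_fraction, multiplier = multiplier,
                 max_den = max_den, orders_override = orders_override,
                 digits = digits),
            class = "pipeline_config")
}

## Build one subject's three SAECGs from the manifest entry; NULL on
## failure (caller excludes the subject with a warning).
.subject_from_manifest <- function(entry, config) {
  tryCatch({
    periods <- lapply(list(entry$path_before, entry$path_during,
                           entry$path_after), function(p)
      build_saecg(load_signal(p), low_hz = config$low_hz,
                  high_hz = config$high_hz, multiplier = config$multiplier,
                  pre_r_fraction = config$pre_r_fraction))
    subject_saecgs(entry$subject_id, periods[[1L]], periods[[2L]],
                   periods[[3L]])
  }, error = function(e) {
    warning(sprintf("subject %s excluded: %s", entry$subject_id,
                    conditionMessage(e)), call. = FALSE)
    NULL
  })
}

#' Run the full analysis pipeline on a trial
#'
#' Per subject: build the three period SAECGs. Then fit the model-order
#' grid over all subjects and period pairs, select the optimized order
#' (highest mean GF, parsimony tie-break), fit each subject's individual
#' transfer function at that order, average the ITFs coefficient-wise
#' into a generalized transfer function per pair, and score both models
#' on every subject. Subjects whose recordings cannot be processed are
#' excluded with a warning; the run aborts if fewer than two remain.
#'
#' @param manifest a [trial_manifest()] (or a list of ready
#'   [subject_saecgs()] to skip preprocessing).
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return A `"pipeline_result"` list: `subjects`, `grid`, `grid_table`,
#'   `selected_order`, `itfs`, `gtfs`, `evaluations`, `config`, `log`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         quiet = FALSE) {
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  if (inherits(manifest, "trial_manifest")) {
    subjects <- list()
    for (entry in manifest$subjects) {
      sub <- .subject_from_manifest(entry, config)
      if (!is.null(sub)) {
        subjects[[length(subjects) + 1L]] <- sub
        say("subject %s: SAECGs built (%d/%d/%d beats used, %d/%d/%d rejected)",
            sub$subject_id, sub$before$n_used, sub$during$n_used,
            sub$after$n_used, sub$before$n_rejected, sub$during$n_rejected,
            sub$after$n_rejected)
      }
    }
  } else {
    subjects <- manifest
  }
  if (length(subjects) < 2L)
    stop("fewer than 2 usable subjects: aborting", call. = FALSE)

  if (is.null(config$orders_override)) {
    grid <- fit_grid(subjects, max_den = config$max_den)
    grid_table <- order_grid_table(grid)
    selected <- select_optimized_order(grid_table, digits = config$digits)
    say("order grid: %d cells; selected order (%d, %d), mean GF %.2f",
        nrow(grid$cells), selected$num_order, selected$den_order,
        selected$mean_gf)
  } else {
    grid <- NULL; grid_table <- NULL
    selected <- list(num_order = config$orders_override[1L],
                     den_order = config$orders_override[2L],
                     mean_gf = NA_real_)
    say("order grid skipped: using override order (%d, %d)",
        selected$num_order, selected$den_order)
  }

  itfs <- list(); gtfs <- list(); evaluations <- list()
  for (pr in pair_labels()) {
    itfs[[pr]] <- lapply(subjects, fit_itf, pair = pr,
                         num_order = selected$num_order,
                         den_order = selected$den_order)
    gtfs[[pr]] <- average_itfs(itfs[[pr]], pair = pr)
    evaluations[[pr]] <- evaluate_models(subjects, itfs[[pr]], gtfs[[pr]],
                                         pair = pr)
    say("%s: mean GF ITF %.2f / GTF %.2f (diff %.2f)", toupper(pr),
        evaluations[[pr]]$mean_itf, evaluations[[pr]]$mean_gtf,
        evaluations[[pr]]$mean_diff)
  }
  structure(list(subjects = subjects, grid = grid, grid_table = grid_table,
                 selected_order = selected, itfs = itfs, gtfs = gtfs,
                 evaluations = evaluations, config = config,
                 log = log_lines),
            class = "pipeline_result")
}

#' Write pipeline reports
#'
#' Produces the study-style artifact set: `grid.csv` (order grid with per
#' pair and overall mean GF, rows in grid order), `subjects.csv` (per
#' subject ITF/GTF goodness of fit per pair with Avg and SD rows),
#' `gtf_<pair>.json` (generalized models in the TF JSON dialect),
#' `results.json` (all GF values at full precision, so report rounding
#' never propagates) and `run_log.txt`. GF values in the CSVs are
#' rounded to `config$digits` decimals.
#'
#' @param result a `"pipeline_result"`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  digits <- result$config$digits
  paths <- character(0)

  if (!is.null(result$grid_table)) {
    gt <- result$grid_table
    num_cols <- setdiff(names(gt), c("num_order", "den_order"))
    gt[num_cols] <- lapply(gt[num_cols], round, digits = digits)
    p <- file.path(out_dir, "grid.csv")
    utils::write.csv(gt, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  tab <- data.frame(subject_id = vapply(result$subjects, function(s)
    as.character(s$subject_id), character(1)), stringsAsFactors = FALSE)
  for (pr in pair_labels()) {
    ev <- result$evaluations[[pr]]$table
    tab[[paste0("gf_itf_", pr)]] <- round(ev$gf_itf, digits)
    tab[[paste0("gf_gtf_", pr)]] <- round(ev$gf_gtf, digits)
  }
  summ <- summarize_subject_table(tab)
  p <- file.path(out_dir, "subjects.csv")
  utils::write.csv(summ$table, p, row.names = FALSE)
  paths <- c(paths, p)

  for (pr in pair_labels()) {
    p <- file.path(out_dir, sprintf("gtf_%s.json", pr))
    write_tf_json(result$gtfs[[pr]]$tf, p,
                  fs = result$subjects[[1L]]$before$fs)
    paths <- c(paths, p)
  }

  full <- list(
    selected_order = result$selected_order,
    evaluations = lapply(result$evaluations, function(ev)
      list(pair = ev$pair, table = ev$table, mean_itf = ev$mean_itf,
           mean_gtf = ev$mean_gtf, sd_itf = ev$sd_itf, sd_gtf = ev$sd_gtf,
           mean_diff = ev$mean_diff)),
    grid_table = result$grid_table)
  p <- file.path(out_dir, "results.json")
  jsonlite::write_json(full, p, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  paths <- c(paths, p)

  p <- file.path(out_dir, "run_log.txt")
  writeLines(c(sprintf("saecgtf %s", as.character(utils::packageVersion("saecgtf"))),
               sprintf("config: band %g-%g Hz, pre-R %.2f, multiplier %g, max_den %d",
                       result$config$low_hz, result$config$high_hz,
                       result$config$pre_r_fraction, result$config$multiplier,
                       result$config$max_den),
               result$log), p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Build subject SAECGs directly from a synthetic trial in memory
#'
#' Convenience bridge from [generate_trial()] to the analysis stages,
#' avoiding the CSV round trip.
#'
#' @param trial a `"synthetic_trial"`.
#' @param config a [pipeline_config()].
#' @return List of [subject_saecgs()].
#' @export
trial_subject_saecgs <- function(trial, config = pipeline_config()) {
  stopifnot(inherits(trial, "synthetic_trial"))
  lapply(trial$subjects, function(sub) {
    ss <- lapply(sub$recordings, function(rec)
      build_saecg(rec$signal, low_hz = config$low_hz,
                  high_hz = config$high_hz, multiplier = config$multiplier,
                  pre_r_fraction = config$pre_r_fraction))
    subject_saecgs(sub$subject_id, ss$before, ss$during, ss$after)
  })
}
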
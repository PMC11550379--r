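#' Run the full mechanocardiogram analysis pipeline
#'
#' Orchestrates one complete analysis from a single configuration:
#' simulate (or load) paired baseline/treatment force traces, detrend and
#' detect contraction events, derive RR series and beat metrics, run the
#' beat-rate-variability analysis, the cut-off arrhythmia statistic, and
#' the baseline-normalised group statistics. Every stage writes its
#' intermediate files under `out_dir` so the run is auditable, and a
#' machine-readable manifest records the configuration hash and per-stage
#' counts; identical configuration plus seed reproduces every output file
#' byte for byte.
#'
#' The configuration is a nested list (or a path to a YAML/JSON file with
#' the same structure) with entries:
#' \describe{
#'   \item{`seed`}{master integer seed (required with `simulate`).}
#'   \item{`simulate`}{list with `n_per_group`, optional `between_rec_cv`,
#'     and `groups`: a named list, each entry holding [sim_config()]
#'     arguments plus an optional `concentration_molar`. Mutually
#'     exclusive with `input_dir`.}
#'   \item{`input_dir`}{directory of `<id>_<phase>.csv` traces with
#'     `.meta.json` sidecars, as written by [simulate_experiment()].}
#'   \item{`detrend`}{list: `window_s` (default 10).}
#'   \item{`detect`}{list passed to [detect_events()].}
#'   \item{`brv`}{list passed to [brv()].}
#'   \item{`cutoff_s`}{arrhythmia cut-off in seconds (default 3).}
#'   \item{`stats`}{list: `method` (default `"anova_holm_sidak"`), `alpha`
#'     (default 0.05), `control_label` (default `"control"`).}
#' }
#'
#' @param config Nested list or path to a YAML/JSON configuration file.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Object of class `mcg_run`: list with `group_table`,
#'   `brv_table`, `cutoff_report`, `stats` (per-metric
#'   [compare_groups()] results and, when the design has a concentration
#'   series, [dose_slope()] fits), `manifest` and `failures`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("run_pipeline: no output directory", call. = FALSE)
  has_sim <- !is.null(config$simulate)
  has_dir <- !is.null(config$input_dir)
  if (has_sim == has_dir) {
    stop("run_pipeline: exactly one of 'simulate' or 'input_dir' required",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("events", "rr", "brv")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  }
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  cat("", file = log_path)  # truncate

  det_par <- config$detect %||% list()
  brv_par <- config$brv %||% list()
  window_s <- (config$detrend %||% list())$window_s %||% 10
  cutoff_s <- config$cutoff_s %||% 3
  stats_par <- config$stats %||% list()
  method <- stats_par$method %||% "anova_holm_sidak"
  alpha <- stats_par$alpha %||% 0.05
  control_label <- stats_par$control_label %||% "control"

  conc_map <- list()
  if (has_sim) {
    sim <- config$simulate
    design <- list()
    for (gname in names(sim$groups)) {
      args <- sim$groups[[gname]]
      conc_map[[gname]] <- args$concentration_molar %||% NA_real_
      args$concentration_molar <- NULL
      design[[gname]] <- do.call(sim_config, args)
    }
    logf("simulate: %d group(s), %d recording(s) per group, seed %d",
         length(design), sim$n_per_group, config$seed)
    ex <- simulate_experiment(design, n_per_group = sim$n_per_group,
                              seed = config$seed,
                              between_rec_cv = sim$between_rec_cv %||% 0.25)
    recordings <- ex$recordings
    meta_of <- function(rid, phase) recordings[[rid]][[phase]]$trace$meta
    trace_of <- function(rid, phase) recordings[[rid]][[phase]]$trace
    rids <- names(recordings)
  } else {
    files <- list.files(config$input_dir, pattern = "_(baseline|treatment)\\.csv$")
    rids <- sort(unique(sub("_(baseline|treatment)\\.csv$", "", files)))
    if (length(rids) == 0L) {
      stop("run_pipeline: no trace files in ", config$input_dir, call. = FALSE)
    }
    logf("input: %d recording(s) from %s", length(rids), config$input_dir)
    trace_of <- function(rid, phase) {
      read_trace(file.path(config$input_dir,
                           sprintf("%s_%s.csv", rid, phase)))
    }
    meta_of <- function(rid, phase) trace_of(rid, phase)$meta
  }

  rows <- list()
  brv_rows <- list()
  rr_store <- list()
  failures <- character(0)
  n_traces <- 0L
  for (rid in rids) {
    res <- tryCatch({
      rec_rows <- list()
      for (phase in c("baseline", "treatment")) {
        trace <- trace_of(rid, phase)
        n_traces <- n_traces + 1L
        group <- trace$meta$group %||% NA_character_
        det <- detrend_trace(trace, window_s = window_s)
        ev <- do.call(detect_events, c(list(det), det_par))
        write_events(ev, file.path(out_dir, "events",
                                   sprintf("%s_%s.tsv", rid, phase)))
        bm <- beat_metrics(ev)
        write_rr(bm$rr_s, file.path(out_dir, "rr",
                                    sprintf("%s_%s.tsv", rid, phase)))
        rr_store[[paste(rid, phase, sep = "::")]] <-
          list(rr = bm$rr_s, group = group, phase = phase)
        if (!bm$sufficient) {
          logf("warn: %s %s has fewer than 2 events; excluded from metrics",
               rid, phase)
          next
        }
        for (metric in c("force_nN", "beat_rate_bpm", "sdsd_s")) {
          value <- switch(metric,
                          force_nN = bm$mean_force_nN,
                          beat_rate_bpm = bm$beat_rate_bpm,
                          sdsd_s = NA_real_)
          if (metric == "sdsd_s") {
            b <- do.call(brv, c(list(bm$rr_s), brv_par))
            if (phase == "treatment") {
              jsonlite::write_json(
                list(recording_id = rid, group = group,
                     n_rr = length(b$rr_raw), n_excluded = b$n_excluded,
                     sdsd_s = as.numeric(b$sdsd_s),
                     sd1_s = as.numeric(b$sd1_s),
                     sd2_s = as.numeric(b$sd2_s),
                     valid = b$valid, reason = b$reason),
                file.path(out_dir, "brv", sprintf("%s.json", rid)),
                auto_unbox = TRUE, digits = NA, null = "null")
              brv_rows[[rid]] <- data.frame(
                recording_id = rid, group = group,
                sdsd_s = as.numeric(b$sdsd_s), sd1_s = as.numeric(b$sd1_s),
                sd2_s = as.numeric(b$sd2_s), n_excluded = b$n_excluded,
                valid = b$valid, reason = b$reason,
                stringsAsFactors = FALSE)
            }
            if (!b$valid) {
              logf("warn: %s %s invalid for BRV (%s)", rid, phase, b$reason)
              next
            }
            value <- as.numeric(b$sdsd_s)
          }
          rec_rows[[length(rec_rows) + 1L]] <- data.frame(
            recording_id = rid, group = group,
            concentration_molar = conc_map[[group]] %||% NA_real_,
            phase = phase, metric = metric, value = value,
            stringsAsFactors = FALSE)
        }
      }
      rec_rows
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, rid)
      logf("error: recording %s failed: %s", rid, conditionMessage(res))
    } else {
      rows <- c(rows, res)
    }
  }
  if (length(rows) == 0L) {
    stop("run_pipeline: no recording produced usable metrics", call. = FALSE)
  }
  group_table_raw <- do.call(rbind, rows)
  rel <- relative_response(group_table_raw, control_label = control_label)
  group_table <- merge(
    group_table_raw,
    rel[, c("recording_id", "metric", "relative_response")],
    by = c("recording_id", "metric"), all.x = TRUE, sort = TRUE)
  group_table$relative_response[group_table$phase == "baseline"] <- NA_real_
  group_table <- group_table[order(group_table$recording_id,
                                   group_table$phase, group_table$metric), ]
  write_group_table(group_table, file.path(out_dir, "group_table.tsv"))
  brv_table <- if (length(brv_rows) > 0L) do.call(rbind, brv_rows) else NULL
  if (!is.null(brv_table)) {
    write_table_prov(brv_table, file.path(out_dir, "brv_table.tsv"))
  }

  # cut-off arrhythmia analysis: pooled raw treatment-phase RR per group
  groups_all <- unique(vapply(rr_store, function(x) x$group, character(1)))
  counts <- list()
  for (gname in groups_all) {
    rr_all <- unlist(lapply(rr_store, function(x) {
      if (identical(x$group, gname) && x$phase == "treatment") x$rr
    }))
    if (length(rr_all) > 0L) {
      counts[[gname]] <- count_long_rr(rr_all, cutoff_s = cutoff_s,
                                       group = gname)
    }
  }
  cutoff_report <- NULL
  if (control_label %in% names(counts)) {
    treat_groups <- setdiff(names(counts), control_label)
    cr <- lapply(treat_groups, function(gname) {
      tst <- cutoff_chi_square(counts[[gname]], counts[[control_label]])
      data.frame(group = gname,
                 n_long = counts[[gname]]$n_long,
                 n_total = counts[[gname]]$n_total,
                 control_long = counts[[control_label]]$n_long,
                 control_total = counts[[control_label]]$n_total,
                 chi2 = tst$chi2, p = tst$p, applicable = tst$applicable,
                 stringsAsFactors = FALSE)
    })
    if (length(cr) > 0L) {
      cutoff_report <- do.call(rbind, cr)
      write_table_prov(cutoff_report, file.path(out_dir, "cutoff_report.tsv"))
    }
  }

  # group statistics on relative responses
  stats_out <- list()
  tr <- group_table[group_table$phase == "treatment" &
                      !is.na(group_table$relative_response), ]
  for (metric in unique(tr$metric)) {
    sub <- tr[tr$metric == metric, ]
    if (length(unique(sub$group)) >= 2L) {
      cmp <- tryCatch(
        compare_groups(sub$relative_response, sub$group, method = method,
                       alpha = alpha),
        error = function(e) {
          logf("warn: group comparison for %s skipped: %s", metric,
               conditionMessage(e))
          NULL
        })
      if (!is.null(cmp)) stats_out[[metric]] <- cmp
    }
    dosed <- sub[!is.na(sub$concentration_molar), ]
    if (nrow(dosed) >= 3L &&
        length(unique(dosed$concentration_molar)) >= 2L) {
      stats_out[[paste0(metric, "_slope")]] <-
        dose_slope(dosed$concentration_molar, dosed$relative_response)
    }
  }
  stats_json <- lapply(stats_out, function(x) {
    if (inherits(x, "group_comparison")) {
      list(method = x$method, omnibus = x$omnibus, pairwise = x$pairwise)
    } else {
      x[c("slope", "se", "wald_stat", "p", "n", "conc_scale")]
    }
  })
  jsonlite::write_json(stats_json, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")

  manifest <- list(
    tool = "mcgtools",
    version = as.character(utils::packageVersion("mcgtools")),
    config_hash = config_hash(config),
    seed = config$seed %||% NA_integer_,
    n_recordings = length(rids),
    n_failed = length(failures),
    failed = failures,
    n_traces = n_traces,
    n_event_files = length(list.files(file.path(out_dir, "events"))),
    n_rr_files = length(list.files(file.path(out_dir, "rr"))),
    n_brv_invalid = if (is.null(brv_table)) 0L else sum(!brv_table$valid),
    groups = groups_all)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("done: %d trace(s), %d failure(s)", n_traces, length(failures))

  structure(list(group_table = group_table, brv_table = brv_table,
                 cutoff_report = cutoff_report, stats = stats_out,
                 manifest = manifest, failures = failures,
                 out_dir = out_dir),
            class = "mcg_run")
}

#' @export
print.mcg_run <- function(x, ...) {
  cat("Mechanocardiogram pipeline run\n")
  cat(sprintf("  %d recording(s), %d failed; outputs in %s\n",
              x$manifest$n_recordings, x$manifest$n_failed, x$out_dir))
  cat(sprintf("  groups: %s\n", paste(x$manifest$groups, collapse = ", ")))
  if (!is.null(x$cutoff_report)) {
    cat("  cut-off arrhythmia report:\n")
    print(x$cutoff_report, row.names = FALSE)
  }
  invisible(x)
}

read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("read_run_config: expected a .yaml/.yml or .json file", call. = FALSE)
  }
}

# md5 of the canonical JSON serialisation of the configuration
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
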
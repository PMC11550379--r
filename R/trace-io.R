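#' Construct a force trace
#'
#' A force trace is a uniformly sampled force-time recording: time in
#' seconds on a strictly increasing uniform grid, force in nanonewtons,
#' plus acquisition metadata (recording id, treatment group, concentration,
#' phase, batch). Time and force units are fixed internally; conversion, if
#' any, happens at the I/O edge.
#'
#' @param t Numeric vector of sample times in seconds.
#' @param f Numeric vector of forces in nanonewtons, same length as `t`.
#' @param meta Named list of metadata; missing fields are filled with `NA`.
#' @param tol Relative tolerance on grid uniformity (default 1e-9).
#' @return Object of class `"force_trace"`.
#' @export
force_trace <- function(t, f, meta = list(), tol = 1e-9) {
  if (length(t) != length(f)) {
    stop("force_trace: 't' and 'f' must have the same length", call. = FALSE)
  }
  if (length(t) < 2L) {
    stop("force_trace: need at least 2 samples", call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    k <- which(dt <= 0)[1] + 1L
    stop(sprintf("force_trace: time not strictly increasing at row %d", k),
         call. = FALSE)
  }
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > tol * dt0 + 1e-12)) {
    k <- which(abs(dt - dt0) > tol * dt0 + 1e-12)[1] + 1L
    stop(sprintf("force_trace: non-uniform sampling grid at row %d", k),
         call. = FALSE)
  }
  if (any(!is.finite(f))) {
    stop("force_trace: non-finite force values", call. = FALSE)
  }
  fields <- c("recording_id", "group", "concentration", "phase", "batch")
  m <- meta[intersect(names(meta), c(fields, "seed"))]
  for (fld in fields) if (is.null(m[[fld]])) m[fld] <- list(NA_character_)
  structure(list(t = as.numeric(t), f = as.numeric(f),
                 sample_rate_hz = 1 / dt0, meta = m),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace: %d samples, %.6g s @ %.6g Hz\n",
              length(x$t), x$t[length(x$t)] - x$t[1], x$sample_rate_hz))
  cat(sprintf("  force range: [%.4g, %.4g] nN\n", min(x$f), max(x$f)))
  m <- x$meta
  cat(sprintf("  recording: %s | group: %s | phase: %s\n",
              m$recording_id, m$group, m$phase))
  invisible(x)
}

provenance_header <- function() {
  sprintf("# mcgtools %s",
          as.character(utils::packageVersion("mcgtools")))
}

#' Read a force trace from CSV
#'
#' Expects a two-column CSV `time_s,force_nN` (comma separated, `.` decimal,
#' header required, UTF-8; `#` lines are comments). An optional metadata
#' sidecar `<path minus .csv>.meta.json` is read when present; without it
#' the metadata fields are `NA` and a warning is issued. Rows with
#' non-finite force are rejected (a warning reports the count); isolated
#' gaps so created are refilled by linear interpolation onto the uniform
#' grid so downstream stages always see uniform sampling.
#'
#' @param path Path to the CSV file.
#' @param sidecar Optional explicit path to the metadata JSON.
#' @return A [force_trace()].
#' @export
read_trace <- function(path, sidecar = NULL) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time_s", "force_nN") %in% names(d))) {
    stop("read_trace: expected columns 'time_s,force_nN' in ", path,
         call. = FALSE)
  }
  t <- as.numeric(d$time_s)
  f <- as.numeric(d$force_nN)
  if (length(t) < 2L) {
    stop("read_trace: fewer than 2 data rows in ", path, call. = FALSE)
  }
  if (any(!is.finite(t))) {
    k <- which(!is.finite(t))[1]
    stop(sprintf("read_trace: non-finite time at data row %d in %s", k, path),
         call. = FALSE)
  }
  bad <- !is.finite(f)
  if (any(bad)) {
    warning(sprintf("read_trace: dropped %d row(s) with non-finite force in %s",
                    sum(bad), path), call. = FALSE)
    tt <- t[!bad]
    f <- stats::approx(tt, f[!bad], xout = t, rule = 2)$y
  }
  meta <- list()
  sc <- if (is.null(sidecar)) sub("\\.csv$", ".meta.json", path) else sidecar
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  } else {
    warning("read_trace: no metadata sidecar for ", path,
            "; metadata fields set to NA", call. = FALSE)
  }
  force_trace(t, f, meta = meta)
}

#' Write a force trace to CSV
#'
#' Writes the pinned two-column dialect read by [read_trace()], preceded by
#' a `#` provenance comment line.
#'
#' @param trace A [force_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(provenance_header(), "time_s,force_nN"), con)
  writeLines(paste(num15(trace$t), num15(trace$f), sep = ","), con)
  invisible(path)
}

# Decimal representation that round-trips a double exactly (17 significant
# digits always suffice for IEEE-754 binary64).
num15 <- function(x) sprintf("%.17g", x)

write_table_prov <- function(df, path, digits_cols = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(), con)
  df2 <- df
  for (nm in names(df2)) {
    if (is.numeric(df2[[nm]])) df2[[nm]] <- num15(df2[[nm]])
  }
  utils::write.table(df2, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read contraction event tables
#'
#' Events are stored as TSV with columns `t_R,f_R,t_S,f_S,amplitude`
#' (seconds / nanonewtons), one row per contraction, preceded by a `#`
#' provenance line. Numeric values are serialised with full double
#' precision so that `read_events(write_events(x))` reproduces `x` exactly.
#'
#' @param events A `contraction_events` data frame from [detect_events()].
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns the events data frame (class `contraction_events`).
#' @export
write_events <- function(events, path) {
  write_table_prov(as.data.frame(events), path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- read_table_prov(path)
  need <- c("t_R", "f_R", "t_S", "f_S", "amplitude")
  if (!all(need %in% names(d))) {
    stop("read_events: missing columns in ", path, call. = FALSE)
  }
  class(d) <- c("contraction_events", "data.frame")
  d
}

#' Write / read RR interval series
#'
#' One `rr_s` column (seconds), TSV with provenance comment; full double
#' precision round-trip.
#'
#' @param rr Numeric vector of RR intervals in seconds.
#' @param path File path.
#' @return `write_rr()` returns `path` invisibly; `read_rr()` the numeric
#'   vector.
#' @export
write_rr <- function(rr, path) {
  write_table_prov(data.frame(rr_s = as.numeric(rr)), path)
}

#' @rdname write_rr
#' @export
read_rr <- function(path) {
  d <- read_table_prov(path)
  if (!"rr_s" %in% names(d)) stop("read_rr: no 'rr_s' column in ", path,
                                  call. = FALSE)
  as.numeric(d$rr_s)
}

#' Write / read a group table
#'
#' The group table is the hand-off between signal analysis and statistics:
#' one row per recording, phase and metric, with the treatment label,
#' concentration in molar (NA for controls) and measured value. TSV with a
#' `#` provenance line; round-trips exactly.
#'
#' @param table Data frame with columns `recording_id, group,
#'   concentration_molar, phase, metric, value` (plus optional extras,
#'   e.g. `relative_response` or `timepoint`).
#' @param path File path.
#' @return `write_group_table()` returns `path` invisibly;
#'   `read_group_table()` the data frame.
#' @export
write_group_table <- function(table, path) {
  need <- c("recording_id", "group", "concentration_molar", "phase",
            "metric", "value")
  if (!all(need %in% names(table))) {
    stop("write_group_table: missing required columns", call. = FALSE)
  }
  write_table_prov(table, path)
}

#' @rdname write_group_table
#' @export
read_group_table <- function(path) {
  read_table_prov(path)
}
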
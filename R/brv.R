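#' Median-ratio filtering of RR intervals
#'
#' Removes artifact RR intervals before variability analysis: an interval is
#' kept only if it lies within a factor `factor` of the median of the raw
#' series, i.e. inside `[median/factor, factor * median]`. The rule is
#' two-sided on purpose — a one-sided reading would never remove
#' pathologically short intervals caused by double-detected beats. The
#' median is computed once on the raw series; order is preserved.
#'
#' Removing an interval breaks the chain of successive-difference pairs:
#' downstream SDSD and Poincare computations only pair intervals that were
#' adjacent in the raw series and both kept (see [rr_successive_diffs()]),
#' so filtering can never fabricate artificial successive differences.
#'
#' @param rr Numeric vector of raw RR intervals in seconds (non-empty).
#' @param factor Exclusion factor, must be > 1 (default 2).
#' @return List with `rr_kept` (numeric), `kept` (logical mask, same length
#'   as `rr`), `n_excluded` and `median_s`. `length(rr_kept) + n_excluded ==
#'   length(rr)` always holds.
#' @examples
#' filter_rr(c(1, 1, 5, 1))$n_excluded  # 1
#' @export
filter_rr <- function(rr, factor = 2) {
  rr <- as.numeric(rr)
  if (length(rr) == 0L) stop("filter_rr: empty RR series", call. = FALSE)
  if (!(is.finite(factor) && factor > 1)) {
    stop("filter_rr: 'factor' must be > 1", call. = FALSE)
  }
  med <- stats::median(rr)
  kept <- rr >= med / factor & rr <= factor * med
  list(rr_kept = rr[kept], kept = kept, n_excluded = sum(!kept),
       median_s = med)
}

#' Successive RR differences over unbroken adjacent pairs
#'
#' The successive differences `RR[i+1] - RR[i]` underlying SDSD and the
#' Poincare descriptors, computed only for pairs of intervals that were
#' adjacent in the raw series and both kept by the filter.
#'
#' @param rr Numeric vector of RR intervals.
#' @param kept Optional logical mask (as from [filter_rr()]); `NULL` means
#'   all intervals are kept.
#' @return Numeric vector of successive differences (possibly empty).
#' @export
rr_successive_diffs <- function(rr, kept = NULL) {
  rr <- as.numeric(rr)
  if (is.null(kept)) kept <- rep(TRUE, length(rr))
  stopifnot(length(kept) == length(rr))
  if (length(rr) < 2L) return(numeric(0))
  ok <- kept[-length(rr)] & kept[-1L]
  diff(rr)[ok]
}

#' Standard deviation of successive differences (SDSD)
#'
#' The short-term beat-rate-variability index of this assay: the sample
#' standard deviation (n - 1 divisor) of the successive RR differences. A
#' constant drift of the beat rate gives identical successive differences,
#' so SDSD is unaffected by linear trends — it acts as a statistical filter
#' removing low-frequency components and isolating beat-to-beat
#' variability. Higher SDSD means a more arrhythmic recording.
#'
#' @inheritParams rr_successive_diffs
#' @return SDSD in seconds, or `NA` (with attribute `reason`) when fewer
#'   than two successive differences are available.
#' @examples
#' sdsd(c(1, 1.2, 0.8, 1))  # sqrt(0.12)
#' sdsd(1 + 0.01 * (1:20))  # 0: linear trends do not register
#' @export
sdsd <- function(rr, kept = NULL) {
  d <- rr_successive_diffs(rr, kept)
  if (length(d) < 2L) {
    return(structure(NA_real_, reason = "fewer than 2 successive differences"))
  }
  stats::sd(d)
}

#' Poincare plot descriptors SD1 and SD2
#'
#' Builds the Poincare pairs `(RR[i], RR[i+1])` over unbroken adjacent kept
#' intervals and the dispersion of the cloud along the minor axis
#' (`sd1 = sqrt(var_pop(d) / 2)`, short-term variability) and major axis
#' (`sd2 = sqrt(2 * var_pop(rr) - var_pop(d) / 2)`, clamped at zero;
#' long-term variability), where `d` are the successive differences and
#' `var_pop` is the population (divisor n) variance.
#'
#' @inheritParams rr_successive_diffs
#' @return List with `pairs` (two-column matrix `rr_i`, `rr_next`), `sd1`
#'   and `sd2` in seconds; `sd1`/`sd2` are `NA` with a `reason` attribute
#'   when fewer than 3 kept intervals are available.
#' @export
poincare <- function(rr, kept = NULL) {
  rr <- as.numeric(rr)
  if (is.null(kept)) kept <- rep(TRUE, length(rr))
  ok <- if (length(rr) >= 2L) kept[-length(rr)] & kept[-1L] else logical(0)
  pairs <- cbind(rr_i = rr[-length(rr)][ok], rr_next = rr[-1L][ok])
  if (sum(kept) < 3L || nrow(pairs) < 2L) {
    na <- structure(NA_real_, reason = "fewer than 3 kept intervals")
    return(list(pairs = pairs, sd1 = na, sd2 = na))
  }
  d <- pairs[, 2L] - pairs[, 1L]
  vp <- function(x) mean((x - mean(x))^2)
  sd1 <- sqrt(vp(d) / 2)
  sd2 <- sqrt(max(0, 2 * vp(rr[kept]) - vp(d) / 2))
  list(pairs = pairs, sd1 = sd1, sd2 = sd2)
}

#' Validity screen for beat-rate-variability analysis
#'
#' Recordings with multiple sudden irregular pauses are not meaningful for
#' short-term variability scoring and must be excluded as whole samples.
#' This rule-based screen replaces manual curation: a recording is invalid
#' when it contains `max_pause_count` or more raw RR intervals longer than
#' `pause_s`, or when the median-ratio filter would discard more than
#' `max_excluded_frac` of its intervals.
#'
#' @param rr Numeric vector of raw RR intervals (non-empty).
#' @param max_pause_count Pause count at which the sample becomes invalid
#'   (default 3).
#' @param pause_s Pause threshold in seconds (default 3).
#' @param max_excluded_frac Maximum tolerated excluded fraction (default
#'   0.2).
#' @param factor Median-ratio filter factor (default 2).
#' @return List with `valid` (logical) and `reason` (`"ok"`, `"pauses"` or
#'   `"excluded_frac"`).
#' @export
sample_validity <- function(rr, max_pause_count = 3, pause_s = 3,
                            max_excluded_frac = 0.2, factor = 2) {
  rr <- as.numeric(rr)
  if (length(rr) == 0L) stop("sample_validity: empty RR series", call. = FALSE)
  n_pause <- sum(rr > pause_s)
  if (n_pause >= max_pause_count) {
    return(list(valid = FALSE, reason = "pauses"))
  }
  flt <- filter_rr(rr, factor = factor)
  if (flt$n_excluded / length(rr) > max_excluded_frac) {
    return(list(valid = FALSE, reason = "excluded_frac"))
  }
  list(valid = TRUE, reason = "ok")
}

#' Full beat-rate-variability analysis of one RR series
#'
#' Applies the validity screen, the median-ratio artifact filter, SDSD and
#' the Poincare descriptors to a raw RR series and bundles the results.
#'
#' @inheritParams sample_validity
#' @return Object of class `brv_result`: list with `rr_raw`, `rr_kept`,
#'   `kept` (logical mask), `n_excluded`, `sdsd_s`, `poincare_pairs`,
#'   `sd1_s`, `sd2_s`, `valid`, `reason`.
#' @examples
#' res <- brv(c(0.9, 1, 1.1, 1, 0.95, 1.05, 4.2, 1, 1.02))
#' res$sdsd_s
#' @export
brv <- function(rr, max_pause_count = 3, pause_s = 3,
                max_excluded_frac = 0.2, factor = 2) {
  val <- sample_validity(rr, max_pause_count, pause_s, max_excluded_frac,
                         factor)
  flt <- filter_rr(rr, factor = factor)
  pc <- poincare(rr, flt$kept)
  structure(
    list(rr_raw = as.numeric(rr),
         rr_kept = flt$rr_kept,
         kept = flt$kept,
         n_excluded = flt$n_excluded,
         sdsd_s = sdsd(rr, flt$kept),
         poincare_pairs = pc$pairs,
         sd1_s = pc$sd1,
         sd2_s = pc$sd2,
         valid = val$valid,
         reason = val$reason),
    class = "brv_result")
}

#' @export
print.brv_result <- function(x, ...) {
  cat(sprintf("BRV result: %d RR intervals (%d excluded), %s\n",
              length(x$rr_raw), x$n_excluded,
              if (x$valid) "valid" else paste0("INVALID (", x$reason, ")")))
  cat(sprintf("  SDSD %.4g ms | SD1 %.4g ms | SD2 %.4g ms\n",
              1000 * x$sdsd_s, 1000 * x$sd1_s, 1000 * x$sd2_s))
  invisible(x)
}
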
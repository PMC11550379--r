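#' Remove slow baseline drift from a force trace
#'
#' Subtracts a rolling-median baseline. The window must span several beat
#' periods so that contraction pulses barely move the median while slow
#' cantilever drift is tracked. For speed the baseline is estimated on a
#' decimated copy of the trace (about 50 samples per second) and linearly
#' interpolated back onto the full grid; the rolling median itself is
#' [stats::runmed()].
#'
#' @param trace A [force_trace()].
#' @param window_s Baseline window in seconds (default 10; should be at
#'   least 3 expected beat periods).
#' @return A `force_trace` with the baseline removed.
#' @export
detrend_trace <- function(trace, window_s = 10) {
  stopifnot(inherits(trace, "force_trace"))
  dur <- trace$t[length(trace$t)] - trace$t[1]
  if (window_s > dur) {
    stop("detrend_trace: window_s exceeds the trace duration", call. = FALSE)
  }
  fs <- trace$sample_rate_hz
  dec <- max(1L, floor(fs / 50))
  idx <- seq(1L, length(trace$f), by = dec)
  k <- floor(window_s * fs / dec)
  k <- max(3L, k - (1L - k %% 2L))  # odd, >= 3
  if (k >= length(idx)) k <- length(idx) - (1L - length(idx) %% 2L)
  base_dec <- stats::runmed(trace$f[idx], k, endrule = "median")
  base <- stats::approx(trace$t[idx], base_dec, xout = trace$t, rule = 2)$y
  out <- trace
  out$f <- trace$f - base
  out
}

#' Detect contraction events (R and S peaks)
#'
#' Locates every contractive event in a detrended force trace. Candidate R
#' peaks are local maxima of a lightly smoothed copy of the trace that
#' exceed `threshold_k` times the robust noise scale of the recording (the
#' scaled median absolute deviation of the first-differenced trace, which
#' smooth pulse content cannot inflate); candidates closer together than
#' `refractory_s` are
#' resolved by keeping the larger peak. For each accepted R peak the S peak
#' is the minimum of the signal in the window `(t_R, t_R + s_search_s]`,
#' truncated at the next R peak. The contraction amplitude of an event is
#' the peak-to-peak force `f_R - f_S`.
#'
#' The R-peak time is refined to sub-sample precision by a local quadratic
#' least-squares fit of the raw trace around the candidate (window
#' `+/- fit_s`), which localises a rounded contraction peak far more
#' precisely under noise than the argmax sample; plateaus and degenerate
#' fits fall back to the earliest candidate sample. Peak forces are
#' measured on the unsmoothed trace as short local averages (`measure_s`)
#' centred on the peak, which keeps the amplitude unbiased by smoothing
#' attenuation and by noise-maximum selection. The detector is fully
#' deterministic.
#'
#' @param trace A detrended [force_trace()] (see [detrend_trace()]).
#' @param threshold_k Detection threshold in units of the robust noise
#'   scale (default 4).
#' @param refractory_s Minimum separation between R peaks in seconds
#'   (default 0.25).
#' @param s_search_s Search window for the S minimum after each R peak in
#'   seconds (default 1).
#' @param smooth_s Width of the moving-average smoother used for peak
#'   finding, in seconds (default 0.05).
#' @param measure_s Half-width of the local average used to measure peak
#'   forces on the raw trace, in seconds (default 0.004).
#' @param fit_s Half-width of the quadratic peak-refinement window in
#'   seconds (default 0.12).
#' @return A data frame of class `contraction_events` with columns
#'   `t_R, f_R, t_S, f_S, amplitude` (seconds / nanonewtons), time-ordered.
#'   Zero rows when no event is found (an empty or flat trace is not an
#'   error).
#' @export
detect_events <- function(trace, threshold_k = 4, refractory_s = 0.25,
                          s_search_s = 1, smooth_s = 0.05,
                          measure_s = 0.004, fit_s = 0.12) {
  stopifnot(inherits(trace, "force_trace"))
  f <- trace$f
  t <- trace$t
  n <- length(f)
  empty <- structure(
    data.frame(t_R = numeric(0), f_R = numeric(0), t_S = numeric(0),
               f_S = numeric(0), amplitude = numeric(0)),
    class = c("contraction_events", "data.frame"))
  if (n < 3L) return(empty)
  fs <- trace$sample_rate_hz

  w <- max(1L, round(smooth_s * fs))
  sm <- moving_average(f, w)

  # robust noise scale: scaled MAD of the first-differenced trace; smooth
  # pulse content and baseline level barely register in the differences, so
  # the threshold tracks the noise floor at any beat rate
  sigma <- stats::mad(diff(f)) / sqrt(2)
  thr <- threshold_k * sigma
  if (!is.finite(thr) || thr <= 0) return(empty)

  # local maxima, plateau resolved to the earliest sample; a guard band of
  # one smoothing width at each end avoids detrending edge artifacts
  core <- 2:(n - 1L)
  is_peak <- c(FALSE, sm[core] > sm[core - 1L] & sm[core] >= sm[core + 1L],
               FALSE)
  guard <- w
  is_peak[seq_len(min(n, guard))] <- FALSE
  is_peak[seq.int(max(1L, n - guard + 1L), n)] <- FALSE
  cand <- which(is_peak & sm > thr)
  if (length(cand) == 0L) return(empty)

  # refractory resolution: greedy by descending smoothed height, so raising
  # the threshold can only remove events, never create new ones
  ord <- cand[order(sm[cand], decreasing = TRUE)]
  ref_n <- round(refractory_s * fs)
  taken <- logical(n)
  acc <- integer(0)
  for (i in ord) {
    lo <- max(1L, i - ref_n)
    hi <- min(n, i + ref_n)
    if (!any(taken[lo:hi])) {
      taken[i] <- TRUE
      acc <- c(acc, i)
    }
  }
  acc <- sort(acc)

  mw <- max(0L, round(measure_s * fs))
  s_n <- round(s_search_s * fs)
  fit_n <- max(2L, round(fit_s * fs))
  out <- vector("list", length(acc))
  for (j in seq_along(acc)) {
    iR <- acc[j]
    tR <- refine_vertex(t, f, iR, fit_n)
    fR <- local_mean(f, iR, mw)
    hi <- min(n, iR + s_n)
    if (j < length(acc)) hi <- min(hi, acc[j + 1L] - 1L)
    if (hi <= iR) next
    seg <- (iR + 1L):hi
    iS <- seg[which.min(sm[seg])]
    fS <- local_mean(f, iS, mw)
    amp <- fR - fS
    if (amp <= 0 || t[iS] <= tR) next
    out[[j]] <- c(tR, fR, t[iS], fS, amp)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  m <- do.call(rbind, out)
  structure(
    data.frame(t_R = m[, 1], f_R = m[, 2], t_S = m[, 3], f_S = m[, 4],
               amplitude = m[, 5]),
    class = c("contraction_events", "data.frame"))
}

# centred moving average; edges are reflection-padded so the noise variance
# of the smoothed signal stays constant up to the trace ends
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  if (n <= half + 1L) return(rep(mean(x), n))
  xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  cs <- cumsum(c(0, xp))
  idx <- seq_len(n) + half
  (cs[idx + half + 1L] - cs[idx - half]) / (2L * half + 1L)
}

local_mean <- function(x, i, hw) {
  lo <- max(1L, i - hw)
  hi <- min(length(x), i + hw)
  mean(x[lo:hi])
}

# Sub-sample peak localisation: least-squares parabola through the raw
# samples within +/- fit_n of the candidate; returns the vertex time, or the
# candidate's own time when the fit is degenerate (non-concave, vertex
# outside the window, or window clipped by the trace edge).
refine_vertex <- function(t, f, i, fit_n) {
  lo <- i - fit_n
  hi <- i + fit_n
  if (lo < 1L || hi > length(f)) return(t[i])
  u <- t[lo:hi] - t[i]
  y <- f[lo:hi]
  u2 <- u * u
  m2 <- mean(u2)
  b <- sum(y * u) / sum(u2)
  den <- sum((u2 - m2)^2)
  if (den <= 0) return(t[i])
  cquad <- sum(y * (u2 - m2)) / den
  if (cquad >= 0) return(t[i])
  delta <- -b / (2 * cquad)
  if (abs(delta) > max(u)) return(t[i])
  t[i] + delta
}

#' Derive beat metrics from contraction events
#'
#' Computes the interbeat (RR) intervals `rr[i] = t_R[i+1] - t_R[i]`, the
#' beat rate in beats per minute and the per-beat contraction forces. The
#' beat rate is defined as `60 / mean(rr)` rather than an event count per
#' unit time, so that long pauses lengthen the mean RR coherently with the
#' RR-based analyses.
#'
#' @param events A `contraction_events` data frame from [detect_events()].
#' @return Object of class `beat_series`: list with `t_R`, `rr_s`,
#'   `beat_rate_bpm`, `contraction_forces_nN`, `mean_force_nN`, `n_events`
#'   and `sufficient` (FALSE when fewer than 2 events; then `rr_s` is empty
#'   and the rate is `NA` — downstream statistics must exclude such
#'   recordings).
#' @examples
#' ev <- data.frame(t_R = c(0, 2, 4, 6), f_R = 70, t_S = c(0.2, 2.2, 4.2, 6.2),
#'                  f_S = -30, amplitude = 100)
#' beat_metrics(ev)$beat_rate_bpm  # 30
#' @export
beat_metrics <- function(events) {
  ev <- as.data.frame(events)
  n <- nrow(ev)
  if (n >= 2L && any(diff(ev$t_R) <= 0)) {
    stop("beat_metrics: events must be strictly time-ordered", call. = FALSE)
  }
  rr <- if (n >= 2L) diff(ev$t_R) else numeric(0)
  structure(
    list(t_R = ev$t_R,
         rr_s = rr,
         beat_rate_bpm = if (n >= 2L) 60 / mean(rr) else NA_real_,
         contraction_forces_nN = ev$amplitude,
         mean_force_nN = if (n >= 1L) mean(ev$amplitude) else NA_real_,
         n_events = n,
         sufficient = n >= 2L),
    class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Beat series: %d events", x$n_events))
  if (!x$sufficient) {
    cat("  [insufficient beats: no RR / rate]\n")
    return(invisible(x))
  }
  cat(sprintf(", rate %.3g bpm, mean RR %.3g s, mean force %.4g nN\n",
              x$beat_rate_bpm, mean(x$rr_s), x$mean_force_nN))
  invisible(x)
}
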
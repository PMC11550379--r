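#' Configuration for a synthetic mechanocardiogram recording
#'
#' Bundles every knob of the synthetic trace generator: recording length and
#' sampling, the beat-interval (RR) process, pulse morphology and amplitude,
#' multiplicative drug-effect factors, pause contamination, baseline drift and
#' additive noise. Defaults emulate a spontaneously beating embryoid body
#' recorded for one 10-minute measurement phase: a quasi-periodic train of
#' biphasic contraction pulses around 30 bpm with peak-to-peak forces of
#' ~100 nN and small beat-to-beat variability.
#'
#' Drug effects are expressed the way inotropic/chronotropic/arrhythmogenic
#' action shows up in this assay: `inotropy_factor` scales the contraction
#' amplitude, `chronotropy_factor` scales the beat rate, and
#' `variability_factor` scales the RR coefficient of variation. Pauses (RR
#' intervals drawn from `pause_range_s`, which must start above the 3 s
#' arrhythmia cut-off) are injected per beat with probability `pause_prob`.
#'
#' @param duration_s Recording length in seconds (default 600, one
#'   measurement phase).
#' @param sample_rate_hz Sampling rate in Hz (default 1000).
#' @param base_rate_bpm Baseline beat rate in beats/minute (default 30).
#' @param rr_cv Coefficient of variation of the RR interval (default 0.05).
#' @param amplitude_nN Peak-to-peak contraction amplitude in nanonewtons
#'   (default 100).
#' @param pulse_up_s Contraction (rise) time constant in seconds
#'   (default 0.15); also the duration of the R-to-S transition.
#' @param pulse_down_s Relaxation time constant in seconds (default 0.35).
#' @param inotropy_factor Multiplicative amplitude scale (default 1).
#' @param chronotropy_factor Multiplicative beat-rate scale (default 1).
#' @param variability_factor Multiplicative scale on `rr_cv` (default 1).
#' @param pause_prob Per-beat probability that an RR interval is replaced by
#'   a long pause (default 0).
#' @param pause_range_s Length-2 numeric, min/max pause duration in seconds;
#'   the minimum must exceed 3 s so injected pauses are detectable by the
#'   cut-off rule (default `c(3.5, 8)`).
#' @param drift_nN_per_s Linear baseline drift slope (default 0).
#' @param noise_sd_nN Additive white-noise standard deviation (default 1).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @examples
#' cfg <- sim_config(duration_s = 60, seed = 1)
#' sim <- simulate_trace(cfg)
#' length(sim$truth$event_times_s)
#' @export
sim_config <- function(duration_s = 600,
                       sample_rate_hz = 1000,
                       base_rate_bpm = 30,
                       rr_cv = 0.05,
                       amplitude_nN = 100,
                       pulse_up_s = 0.15,
                       pulse_down_s = 0.35,
                       inotropy_factor = 1,
                       chronotropy_factor = 1,
                       variability_factor = 1,
                       pause_prob = 0,
                       pause_range_s = c(3.5, 8),
                       drift_nN_per_s = 0,
                       noise_sd_nN = 1,
                       seed = NULL) {
  cfg <- list(
    duration_s = as.numeric(duration_s),
    sample_rate_hz = as.numeric(sample_rate_hz),
    base_rate_bpm = as.numeric(base_rate_bpm),
    rr_cv = as.numeric(rr_cv),
    amplitude_nN = as.numeric(amplitude_nN),
    pulse_up_s = as.numeric(pulse_up_s),
    pulse_down_s = as.numeric(pulse_down_s),
    inotropy_factor = as.numeric(inotropy_factor),
    chronotropy_factor = as.numeric(chronotropy_factor),
    variability_factor = as.numeric(variability_factor),
    pause_prob = as.numeric(pause_prob),
    pause_range_s = as.numeric(pause_range_s),
    drift_nN_per_s = as.numeric(drift_nN_per_s),
    noise_sd_nN = as.numeric(noise_sd_nN),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pos <- c("duration_s", "sample_rate_hz", "base_rate_bpm", "amplitude_nN",
           "pulse_up_s", "pulse_down_s", "inotropy_factor",
           "chronotropy_factor", "variability_factor")
  for (fld in pos) {
    v <- cfg[[fld]]
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      # amplitude 0 is allowed: it encodes a flat, noise-only recording
      if (fld == "amplitude_nN" && length(v) == 1L && is.finite(v) && v == 0) next
      stop(sprintf("sim_config: '%s' must be a single positive number", fld),
           call. = FALSE)
    }
  }
  for (fld in c("rr_cv", "drift_nN_per_s", "noise_sd_nN")) {
    v <- cfg[[fld]]
    if (length(v) != 1L || !is.finite(v)) {
      stop(sprintf("sim_config: '%s' must be a single finite number", fld),
           call. = FALSE)
    }
  }
  if (cfg$rr_cv < 0 || cfg$noise_sd_nN < 0) {
    stop("sim_config: 'rr_cv' and 'noise_sd_nN' must be non-negative",
         call. = FALSE)
  }
  if (!(length(cfg$pause_prob) == 1L && is.finite(cfg$pause_prob) &&
        cfg$pause_prob >= 0 && cfg$pause_prob < 1)) {
    stop("sim_config: 'pause_prob' must satisfy 0 <= pause_prob < 1",
         call. = FALSE)
  }
  pr <- cfg$pause_range_s
  if (length(pr) != 2L || any(!is.finite(pr)) || pr[1] > pr[2]) {
    stop("sim_config: 'pause_range_s' must be c(min, max) with min <= max",
         call. = FALSE)
  }
  if (pr[1] <= 3.0) {
    stop("sim_config: pause_range_s minimum must exceed 3 s so injected ",
         "pauses fall beyond the arrhythmia cut-off", call. = FALSE)
  }
  mean_rr <- 60 / (cfg$base_rate_bpm * cfg$chronotropy_factor)
  if (!is.finite(mean_rr) || mean_rr <= 0) {
    stop("sim_config: implied mean RR interval is non-positive", call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic mechanocardiogram configuration\n")
  cat(sprintf("  duration: %g s @ %g Hz\n", x$duration_s, x$sample_rate_hz))
  cat(sprintf("  rate: %g bpm x %g (chronotropy), RR CV %g x %g\n",
              x$base_rate_bpm, x$chronotropy_factor,
              x$rr_cv, x$variability_factor))
  cat(sprintf("  amplitude: %g nN x %g (inotropy); pulse up/down %g/%g s\n",
              x$amplitude_nN, x$inotropy_factor,
              x$pulse_up_s, x$pulse_down_s))
  cat(sprintf("  pauses: p = %g in [%g, %g] s; drift %g nN/s; noise SD %g nN\n",
              x$pause_prob, x$pause_range_s[1], x$pause_range_s[2],
              x$drift_nN_per_s, x$noise_sd_nN))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Deterministic 32-bit sub-seed from a master seed and a string key, so that
# per-recording streams are reproducible independently of generation order.
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + (as.numeric(seed) %% 1000003) * 2654435) %% 2147483647)
}
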
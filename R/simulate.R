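#' Simulate a sequence of interbeat (RR) intervals
#'
#' Draws RR intervals i.i.d. from a truncated normal distribution with mean
#' `60 / (base_rate_bpm * chronotropy_factor)` seconds and standard deviation
#' `mean * rr_cv * variability_factor`, truncated at +/- 20% of the mean.
#' With probability `pause_prob` each interval is independently replaced by a
#' pause drawn uniformly from `pause_range_s`. Generation stops once the next
#' interval would push the cumulative sum past `duration_s`.
#'
#' The truncation keeps ordinary intervals well below the 3 s arrhythmia
#' cut-off for any mean RR below 2.5 s, so every interval above the cut-off
#' is an injected pause.
#'
#' @param config A [sim_config()] object. When `config$seed` is non-`NULL`
#'   the RNG is seeded, making the draw reproducible.
#' @return Numeric vector of RR intervals in seconds (possibly empty).
#' @examples
#' rr <- simulate_rr(sim_config(duration_s = 120, seed = 7))
#' mean(rr)
#' @export
simulate_rr <- function(config) {
  config <- validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  mu <- 60 / (config$base_rate_bpm * config$chronotropy_factor)
  sigma <- mu * config$rr_cv * config$variability_factor
  n_max <- ceiling(config$duration_s / (0.8 * mu)) + 8L
  rr <- rtrunc_norm(n_max, mu, sigma, mu * 0.8, mu * 1.2)
  if (config$pause_prob > 0) {
    is_pause <- stats::runif(n_max) < config$pause_prob
    if (any(is_pause)) {
      rr[is_pause] <- stats::runif(sum(is_pause),
                                   config$pause_range_s[1],
                                   config$pause_range_s[2])
    }
  }
  keep <- cumsum(rr) <= config$duration_s
  rr[keep]
}

# Truncated normal by vectorised rejection; bounds are +-4 SD at the default
# CV so acceptance is essentially 1 and the variance distortion negligible.
rtrunc_norm <- function(n, mu, sigma, lo, hi) {
  if (sigma == 0) return(rep(mu, n))
  out <- stats::rnorm(n, mu, sigma)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mu, sigma)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

# Biphasic contraction pulse, unit peak-to-peak amplitude, R peak at u = 0.
# Three raised-cosine segments on compact support: rise over 2*tau_up to the
# R maximum (70% of the swing), fall to the S minimum (-30%) and recovery
# over 2*tau_down. The fall duration is chosen so the curvature on both
# sides of the R peak matches, making the peak locally symmetric; peak
# detectors can then localise it without shape-induced bias.
PULSE_P <- 0.7
PULSE_Q <- 0.3

pulse_support <- function(tau_up, tau_down) {
  r_u <- 2 * tau_up
  d <- r_u * sqrt((PULSE_P + PULSE_Q) / PULSE_P)
  r_d <- 2 * tau_down
  c(rise = r_u, fall = d, recover = r_d)
}

pulse_shape <- function(u, tau_up, tau_down) {
  sup <- pulse_support(tau_up, tau_down)
  r_u <- sup[["rise"]]; d <- sup[["fall"]]; r_d <- sup[["recover"]]
  out <- numeric(length(u))
  pre <- u >= -r_u & u < 0
  mid <- u >= 0 & u <= d
  post <- u > d & u <= d + r_d
  out[pre] <- PULSE_P * (1 + cos(pi * u[pre] / r_u)) / 2
  out[mid] <- PULSE_P - (PULSE_P + PULSE_Q) * (1 - cos(pi * u[mid] / d)) / 2
  out[post] <- -PULSE_Q * (1 + cos(pi * (u[post] - d) / r_d)) / 2
  out
}

#' Render a force-time trace from a sequence of RR intervals
#'
#' Converts RR intervals into a uniformly sampled force trace: each beat is a
#' biphasic raised-cosine pulse (rise over `2 * pulse_up_s` to the R maximum,
#' smooth fall to the S undershoot minimum, recovery over `2 * pulse_down_s`)
#' with peak-to-peak amplitude `amplitude_nN * inotropy_factor`; a linear
#' baseline drift and
#' additive Gaussian noise are then superimposed. The first R peak is placed
#' 1 s into the recording and events too close to the end of the recording
#' for their pulse to complete are dropped.
#'
#' @param rr Numeric vector of RR intervals in seconds (may be empty, in
#'   which case a single beat is placed; with `amplitude_nN = 0` the trace is
#'   noise only).
#' @param config A [sim_config()] object. Noise is seeded from a sub-stream
#'   of `config$seed` so that `simulate_rr()` and `render_trace()` remain
#'   independently reproducible.
#' @param amplitude_scale Optional extra multiplicative amplitude factor
#'   (used for per-recording biological variation in experiments).
#' @return A list with components `trace` (a `force_trace`: `t` seconds, `f`
#'   nanonewtons, `meta`) and `truth` (a `ground_truth`: `event_times_s`,
#'   `rr_s`, `amplitudes_nN`, `n_pauses` where pauses are true RR > 3 s).
#' @export
render_trace <- function(rr, config, amplitude_scale = 1) {
  config <- validate_sim_config(config)
  fs <- config$sample_rate_hz
  dur <- config$duration_s
  tau_u <- config$pulse_up_s
  tau_d <- config$pulse_down_s
  sup <- pulse_support(tau_u, tau_d)
  tail_s <- sup[["fall"]] + sup[["recover"]]
  min_len <- 1 + tail_s
  if (dur < min_len) {
    stop("render_trace: duration too short to hold a single contraction pulse",
         call. = FALSE)
  }
  n <- floor(dur * fs) + 1L
  t <- seqtime(n, fs)
  f <- numeric(n)

  amp <- config$amplitude_nN * config$inotropy_factor * amplitude_scale
  events <- 1 + cumsum(c(0, rr))
  events <- events[events <= dur - tail_s]
  if (amp > 0 && length(events) > 0L) {
    pre_n <- ceiling(sup[["rise"]] * fs) + 1L
    post_n <- ceiling(tail_s * fs) + 1L
    for (ev in events) {
      i0 <- max(1L, floor(ev * fs) - pre_n)
      i1 <- min(n, ceiling(ev * fs) + post_n)
      idx <- i0:i1
      f[idx] <- f[idx] + amp * pulse_shape(t[idx] - ev, tau_u, tau_d)
    }
  }
  if (config$drift_nN_per_s != 0) f <- f + config$drift_nN_per_s * t
  if (config$noise_sd_nN > 0) {
    if (!is.null(config$seed)) set.seed(derive_seed(config$seed, "noise"))
    f <- f + stats::rnorm(n, 0, config$noise_sd_nN)
  }

  rr_true <- diff(events)
  truth <- structure(
    list(event_times_s = events,
         rr_s = rr_true,
         amplitudes_nN = rep(amp, length(events)),
         n_pauses = sum(rr_true > 3.0)),
    class = "ground_truth")
  trace <- force_trace(t, f, meta = list(seed = config$seed))
  list(trace = trace, truth = truth)
}

# Uniform time grid; kept in one place so every module shares the convention.
seqtime <- function(n, fs) (seq_len(n) - 1) / fs

#' Simulate one complete synthetic recording
#'
#' Convenience wrapper: seeds the RNG from `config$seed`, draws the RR
#' sequence with [simulate_rr()] and renders it with [render_trace()].
#'
#' @inheritParams render_trace
#' @param config A [sim_config()] object.
#' @return As [render_trace()]: list with `trace` and `truth`.
#' @export
simulate_trace <- function(config, amplitude_scale = 1) {
  rr <- simulate_rr(config)
  render_trace(rr, config, amplitude_scale = amplitude_scale)
}

#' Simulate a paired baseline/treatment experiment
#'
#' Emulates the paired recording protocol of the assay: every recording is
#' one embryoid body measured twice, a drug-free baseline phase followed by
#' a treatment phase. The treatment phase of each group uses that group's
#' `sim_config` as given; its baseline phase uses the same configuration
#' with the drug-effect factors reset (`inotropy_factor`,
#' `chronotropy_factor`, `variability_factor` set to 1 and `pause_prob` to
#' 0). A per-recording log-normal amplitude scale (CV `between_rec_cv`),
#' shared by the two phases of a recording, models the large cluster-to-
#' cluster differences in absolute contraction force; baseline
#' normalisation cancels it within a recording.
#'
#' @param design Named list mapping group label to a [sim_config()]; group
#'   labels must be unique (they seed recording ids).
#' @param n_per_group Recordings per group (single integer or one per group).
#' @param seed Master integer seed; per-recording, per-phase sub-seeds are
#'   derived by deterministic hashing so any subset of the experiment is
#'   reproducible in isolation.
#' @param between_rec_cv Coefficient of variation of the per-recording
#'   amplitude scale (default 0.25).
#' @param out_dir Optional directory: when given, each trace is written as
#'   CSV with a JSON metadata sidecar and the ground truth as JSON.
#' @return A list with `recordings` (named list; each element holds
#'   `baseline` and `treatment` entries of `trace` + `truth`) and `manifest`
#'   (data frame: recording_id, group, phase, seed, n_events, n_pauses).
#' @examples
#' des <- list(control = sim_config(duration_s = 40, seed = NULL),
#'             drug = sim_config(duration_s = 40, inotropy_factor = 1.4))
#' ex <- simulate_experiment(des, n_per_group = 2, seed = 11)
#' ex$manifest
#' @export
simulate_experiment <- function(design, n_per_group, seed,
                                between_rec_cv = 0.25, out_dir = NULL) {
  if (is.null(names(design)) || any(names(design) == "") ||
      anyDuplicated(names(design))) {
    stop("simulate_experiment: 'design' must be a uniquely named list of ",
         "sim_config objects", call. = FALSE)
  }
  n_per_group <- rep_len(as.integer(n_per_group), length(design))
  sdlog <- sqrt(log(1 + between_rec_cv^2))
  recs <- list()
  man <- list()
  for (g in seq_along(design)) {
    group <- names(design)[g]
    cfg_treat <- validate_sim_config(design[[g]])
    cfg_base <- cfg_treat
    cfg_base$inotropy_factor <- 1
    cfg_base$chronotropy_factor <- 1
    cfg_base$variability_factor <- 1
    cfg_base$pause_prob <- 0
    for (i in seq_len(n_per_group[g])) {
      rid <- sprintf("%s_r%02d", group, i)
      if (rid %in% names(recs)) {
        stop("simulate_experiment: duplicate recording id ", rid,
             call. = FALSE)
      }
      set.seed(derive_seed(seed, paste0(rid, "::scale")))
      scale_i <- if (between_rec_cv > 0) {
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else 1
      phases <- list()
      for (phase in c("baseline", "treatment")) {
        cfg <- if (phase == "baseline") cfg_base else cfg_treat
        cfg$seed <- derive_seed(seed, paste0(rid, "::", phase))
        sim <- simulate_trace(cfg, amplitude_scale = scale_i)
        sim$trace$meta <- list(recording_id = rid, group = group,
                               concentration = NA_character_,
                               phase = phase, batch = NA_character_,
                               seed = cfg$seed)
        phases[[phase]] <- sim
        man[[length(man) + 1L]] <- data.frame(
          recording_id = rid, group = group, phase = phase,
          seed = cfg$seed,
          n_events = length(sim$truth$event_times_s),
          n_pauses = sim$truth$n_pauses,
          stringsAsFactors = FALSE)
      }
      recs[[rid]] <- phases
    }
  }
  manifest <- do.call(rbind, man)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rid in names(recs)) {
      for (phase in c("baseline", "treatment")) {
        sim <- recs[[rid]][[phase]]
        stem <- file.path(out_dir, paste0(rid, "_", phase))
        write_trace(sim$trace, paste0(stem, ".csv"))
        jsonlite::write_json(sim$trace$meta, paste0(stem, ".meta.json"),
                             auto_unbox = TRUE, null = "null", digits = NA)
        jsonlite::write_json(unclass(sim$truth), paste0(stem, ".truth.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(recordings = recs, manifest = manifest)
}
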
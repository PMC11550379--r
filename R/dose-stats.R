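#' Baseline-normalised relative responses
#'
#' Converts raw per-recording metric values into relative responses: a
#' treated recording's value is divided by the value of the same metric in
#' the same recording's baseline phase; a control recording's
#' treatment-phase value is divided by the mean treatment-phase value of
#' all control recordings at the same timepoint. Treated recordings without
#' a matching baseline row (or with a non-positive baseline) are excluded
#' with a warning; they never enter downstream statistics.
#'
#' @param table Data frame with columns `recording_id, group,
#'   concentration_molar, phase, metric, value`; optional `timepoint`
#'   column (defaults to a single timepoint). `phase` must be `"baseline"`
#'   or `"treatment"`.
#' @param control_label Group label identifying control recordings
#'   (default `"control"`).
#' @return The treatment-phase rows with an added `relative_response`
#'   column (one row per recording and metric); excluded rows are dropped.
#' @examples
#' tab <- data.frame(recording_id = rep(c("r1", "r2"), each = 2),
#'                   group = "drug", concentration_molar = 1e-7,
#'                   phase = rep(c("baseline", "treatment"), 2),
#'                   metric = "force_nN", value = c(100, 140, 90, 120))
#' relative_response(tab)$relative_response  # 1.4, 1.333...
#' @export
relative_response <- function(table, control_label = "control") {
  need <- c("recording_id", "group", "phase", "metric", "value")
  if (!all(need %in% names(table))) {
    stop("relative_response: missing required columns", call. = FALSE)
  }
  tab <- as.data.frame(table)
  if (!"timepoint" %in% names(tab)) tab$timepoint <- 1L
  if (!all(tab$phase %in% c("baseline", "treatment"))) {
    stop("relative_response: 'phase' must be 'baseline' or 'treatment'",
         call. = FALSE)
  }
  tr <- tab[tab$phase == "treatment", , drop = FALSE]
  bl <- tab[tab$phase == "baseline", , drop = FALSE]
  is_ctrl <- tr$group == control_label

  rel <- rep(NA_real_, nrow(tr))
  # treated: pair with own baseline by (recording_id, metric)
  key <- function(d) paste(d$recording_id, d$metric, sep = "\r")
  bl_map <- stats::setNames(bl$value, key(bl))
  base_val <- unname(bl_map[key(tr)])
  tidx <- which(!is_ctrl)
  rel[tidx] <- tr$value[tidx] / base_val[tidx]
  bad <- tidx[is.na(base_val[tidx]) | base_val[tidx] <= 0]
  if (length(bad) > 0L) {
    warning(sprintf(
      "relative_response: excluded %d treated row(s) without usable baseline",
      length(bad)), call. = FALSE)
    rel[bad] <- NA_real_
  }
  # controls: normalise to the control-group mean at the same timepoint
  for (tp in unique(tr$timepoint[is_ctrl])) {
    for (m in unique(tr$metric[is_ctrl])) {
      sel <- is_ctrl & tr$timepoint == tp & tr$metric == m
      if (!any(sel)) next
      mu <- mean(tr$value[sel])
      if (!is.finite(mu) || mu <= 0) {
        warning("relative_response: control mean not usable for metric ", m,
                call. = FALSE)
        next
      }
      rel[sel] <- tr$value[sel] / mu
    }
  }
  tr$relative_response <- rel
  tr[!is.na(rel), , drop = FALSE]
}

#' Concentration-response regression with Wald slope test
#'
#' Ordinary least-squares regression of relative responses on
#' concentration, by default on the log10 molar scale (matching a 10-fold
#' dilution series); the Wald statistic `slope / se` is referred to a t
#' distribution with `n - 2` degrees of freedom to test for a non-zero
#' slope. Residuals and fitted values are returned for the residual plot.
#'
#' @param concentration_molar Numeric concentrations in molar (> 0 when
#'   `conc_scale = "log10"`).
#' @param relative_response Numeric responses, same length.
#' @param conc_scale `"log10"` (default) or `"linear"`.
#' @return Object of class `dose_slope`: list with `slope`, `intercept`,
#'   `se`, `wald_stat`, `p`, `df`, `n`, `x`, `residuals`, `fitted`,
#'   `conc_scale`.
#' @export
dose_slope <- function(concentration_molar, relative_response,
                       conc_scale = c("log10", "linear")) {
  conc_scale <- match.arg(conc_scale)
  x <- as.numeric(concentration_molar)
  y <- as.numeric(relative_response)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("dose_slope: need at least 3 points", call. = FALSE)
  }
  if (conc_scale == "log10") {
    if (any(x <= 0)) {
      stop("dose_slope: concentrations must be positive on the log scale",
           call. = FALSE)
    }
    x <- log10(x)
  }
  if (length(unique(x)) < 2L) {
    stop("dose_slope: need at least 2 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2L])
  se <- sm$coefficients[2L, 2L]
  # perfect fit: the Wald ratio degenerates; report the limiting p-value
  wald <- if (se == 0) (if (slope == 0) 0 else sign(slope) * Inf)
          else slope / se
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         se = se,
         wald_stat = wald,
         p = 2 * stats::pt(-abs(wald), df = fit$df.residual),
         df = fit$df.residual,
         n = length(x),
         x = x,
         residuals = unname(stats::residuals(fit)),
         fitted = unname(stats::fitted(fit)),
         conc_scale = conc_scale),
    class = "dose_slope")
}

#' @export
print.dose_slope <- function(x, ...) {
  cat(sprintf(
    "Dose-response slope (%s concentration): %.4g +/- %.4g (se)\n",
    x$conc_scale, x$slope, x$se))
  cat(sprintf("  Wald t = %.4g on %d df, p = %.4g (n = %d)\n",
              x$wald_stat, x$df, x$p, x$n))
  invisible(x)
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' After sorting the m raw p-values ascending, the i-th adjusted value is
#' `max_{j <= i} 1 - (1 - p_(j))^(m - j + 1)`, clamped at 1, reported in
#' the original order. Adjusted values are monotone in raw-p rank and never
#' below the raw p-value.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04))  # 0.0199, 0.04
#' @export
holm_sidak_adjust <- function(p) {
  p <- as.numeric(p)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  adj <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Group comparisons with multiplicity control
#'
#' Implements the three group-comparison designs used for relative
#' responses and SDSD values in this assay:
#' \describe{
#'   \item{`anova_holm_sidak`}{ordinary one-way ANOVA omnibus, pairwise t
#'     tests on the pooled error variance, Holm-Sidak adjustment.}
#'   \item{`welch_bf_games_howell`}{Welch ANOVA omnibus (the Brown-Forsythe
#'     F* statistic is reported alongside) for groups with unequal spread,
#'     with Games-Howell pairwise comparisons (studentized range on Welch
#'     degrees of freedom).}
#'   \item{`kruskal_dunn`}{Kruskal-Wallis omnibus with Dunn's rank-based
#'     pairwise z tests (tie-corrected), Bonferroni-adjusted.}
#' }
#' Groups with fewer than 3 observations are excluded with a warning.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of group labels, same length.
#' @param method One of `"anova_holm_sidak"`, `"welch_bf_games_howell"`,
#'   `"kruskal_dunn"`.
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return Object of class `group_comparison`: list with `method`,
#'   `omnibus` (named list of statistic/df/p; for the Welch design also the
#'   Brown-Forsythe F*), `pairwise` (data frame: group1, group2, estimate,
#'   statistic, p_raw, p_adj, significant) and `alpha`.
#' @export
compare_groups <- function(values, groups,
                           method = c("anova_holm_sidak",
                                      "welch_bf_games_howell",
                                      "kruskal_dunn"),
                           alpha = 0.05) {
  method <- match.arg(method)
  y <- as.numeric(values)
  g <- as.character(groups)
  stopifnot(length(y) == length(g))
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  cnt <- table(g)
  small <- names(cnt)[cnt < 3L]
  if (length(small) > 0L) {
    warning("compare_groups: excluded group(s) with n < 3: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(g %in% small)
    y <- y[keep]; g <- g[keep]
  }
  gl <- sort(unique(g))
  if (length(gl) < 2L) {
    stop("compare_groups: need at least 2 groups with n >= 3", call. = FALSE)
  }
  ni <- vapply(gl, function(l) sum(g == l), numeric(1))
  mi <- vapply(gl, function(l) mean(y[g == l]), numeric(1))
  vi <- vapply(gl, function(l) stats::var(y[g == l]), numeric(1))
  k <- length(gl)
  n_tot <- length(y)
  pairs <- utils::combn(gl, 2L)

  if (method == "anova_holm_sidak") {
    fit <- stats::oneway.test(y ~ factor(g), var.equal = TRUE)
    mse <- sum((ni - 1) * vi) / (n_tot - k)
    df_err <- n_tot - k
    pw <- apply(pairs, 2L, function(pr) {
      i <- match(pr[1], gl); j <- match(pr[2], gl)
      est <- mi[i] - mi[j]
      se <- sqrt(mse * (1 / ni[i] + 1 / ni[j]))
      tt <- est / se
      c(est, tt, 2 * stats::pt(-abs(tt), df_err))
    })
    p_adj <- holm_sidak_adjust(pw[3L, ])
    omnibus <- list(statistic = unname(fit$statistic),
                    df1 = unname(fit$parameter[1L]),
                    df2 = unname(fit$parameter[2L]),
                    p = unname(fit$p.value))
  } else if (method == "welch_bf_games_howell") {
    fit <- stats::oneway.test(y ~ factor(g), var.equal = FALSE)
    # Brown-Forsythe F*: grand-mean numerator, variance-weighted denominator
    gm <- mean(y)
    f_bf <- sum(ni * (mi - gm)^2) / sum((1 - ni / n_tot) * vi)
    ci <- (1 - ni / n_tot) * vi / sum((1 - ni / n_tot) * vi)
    df2_bf <- 1 / sum(ci^2 / (ni - 1))
    pw <- apply(pairs, 2L, function(pr) {
      i <- match(pr[1], gl); j <- match(pr[2], gl)
      est <- mi[i] - mi[j]
      se <- sqrt(vi[i] / ni[i] + vi[j] / ni[j])
      tt <- est / se
      df_w <- se^4 / ((vi[i] / ni[i])^2 / (ni[i] - 1) +
                      (vi[j] / ni[j])^2 / (ni[j] - 1))
      p <- stats::ptukey(abs(tt) * sqrt(2), nmeans = k, df = df_w,
                         lower.tail = FALSE)
      c(est, tt, p)
    })
    p_adj <- pw[3L, ]  # Games-Howell is intrinsically familywise
    omnibus <- list(statistic = unname(fit$statistic),
                    df1 = unname(fit$parameter[1L]),
                    df2 = unname(fit$parameter[2L]),
                    p = unname(fit$p.value),
                    bf_statistic = f_bf,
                    bf_df1 = k - 1,
                    bf_df2 = df2_bf,
                    bf_p = stats::pf(f_bf, k - 1, df2_bf,
                                     lower.tail = FALSE))
  } else {
    fit <- stats::kruskal.test(y, factor(g))
    rk <- rank(y)
    rbar <- vapply(gl, function(l) mean(rk[g == l]), numeric(1))
    ties <- table(y)
    tie_term <- sum(ties^3 - ties)
    s2 <- n_tot * (n_tot + 1) / 12 - tie_term / (12 * (n_tot - 1))
    pw <- apply(pairs, 2L, function(pr) {
      i <- match(pr[1], gl); j <- match(pr[2], gl)
      est <- rbar[i] - rbar[j]
      z <- est / sqrt(s2 * (1 / ni[i] + 1 / ni[j]))
      c(est, z, 2 * stats::pnorm(-abs(z)))
    })
    p_adj <- pmin(1, pw[3L, ] * ncol(pairs))
    omnibus <- list(statistic = unname(fit$statistic),
                    df1 = unname(fit$parameter),
                    df2 = NA_real_,
                    p = unname(fit$p.value))
  }
  pairwise <- data.frame(row.names = NULL,
                         group1 = pairs[1L, ], group2 = pairs[2L, ],
                         estimate = pw[1L, ], statistic = pw[2L, ],
                         p_raw = pw[3L, ], p_adj = p_adj,
                         significant = p_adj < alpha,
                         stringsAsFactors = FALSE)
  structure(list(method = method, omnibus = omnibus, pairwise = pairwise,
                 alpha = alpha, group_n = stats::setNames(ni, gl)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s), alpha = %g\n", x$method, x$alpha))
  cat(sprintf("  omnibus: stat = %.4g, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Robust outlier flagging
#'
#' Flags values more than `mad_k` scaled median absolute deviations from
#' the median. Values are flagged, never deleted; reports decide what to do
#' with them. When the MAD is zero but the values are not all equal, the
#' rule degenerates and the Tukey fence (1.5 IQR) is used instead, with a
#' message.
#'
#' @param values Numeric vector, n >= 4.
#' @param mad_k MAD multiple (default 5).
#' @return List with `flagged` (logical mask), `kept` (values not flagged)
#'   and `rule` (`"mad"` or `"iqr"`).
#' @examples
#' flag_outliers(c(1, 1, 1, 1, 100))$flagged
#' @export
flag_outliers <- function(values, mad_k = 5) {
  x <- as.numeric(values)
  if (length(x) < 4L) stop("flag_outliers: need n >= 4", call. = FALSE)
  med <- stats::median(x)
  madv <- stats::mad(x)
  if (madv > 0) {
    flagged <- abs(x - med) > mad_k * madv
    rule <- "mad"
  } else if (all(x == x[1L])) {
    flagged <- rep(FALSE, length(x))
    rule <- "mad"
  } else {
    message("flag_outliers: MAD is zero; falling back to the 1.5 IQR fence")
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2L] - q[1L]
    flagged <- x < q[1L] - 1.5 * iqr | x > q[2L] + 1.5 * iqr
    rule <- "iqr"
  }
  list(flagged = flagged, kept = x[!flagged], rule = rule)
}
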
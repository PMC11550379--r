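#' Count long RR intervals against the arrhythmia cut-off
#'
#' The cut-off arrhythmia statistic counts interbeat intervals strictly
#' longer than the cut-off (3 s by default) in the RAW RR series — the long
#' pauses are the signal here, so the count runs before any artifact
#' filtering.
#'
#' @param rr Numeric vector of raw RR intervals in seconds (non-empty).
#' @param cutoff_s Cut-off in seconds, strictly exceeded intervals count
#'   (default 3).
#' @param group Optional group label carried along for reporting.
#' @return Object of class `cutoff_counts`: list with `n_long`, `n_total`,
#'   `cutoff_s`, `group`.
#' @examples
#' count_long_rr(c(1, 3.0, 3.1, 5))$n_long  # 2: the boundary is strict
#' @export
count_long_rr <- function(rr, cutoff_s = 3, group = NA_character_) {
  rr <- as.numeric(rr)
  if (length(rr) == 0L) stop("count_long_rr: empty RR series", call. = FALSE)
  if (!(is.finite(cutoff_s) && cutoff_s > 0)) {
    stop("count_long_rr: 'cutoff_s' must be positive", call. = FALSE)
  }
  structure(list(n_long = sum(rr > cutoff_s), n_total = length(rr),
                 cutoff_s = cutoff_s, group = group),
            class = "cutoff_counts")
}

#' Pool cut-off counts across recordings
#'
#' @param counts List of `cutoff_counts` objects (same cut-off).
#' @param group Label for the pooled result.
#' @return A single `cutoff_counts` with summed `n_long` and `n_total`.
#' @export
pool_cutoff_counts <- function(counts, group = NA_character_) {
  stopifnot(length(counts) > 0L,
            all(vapply(counts, inherits, logical(1), "cutoff_counts")))
  cutoffs <- vapply(counts, function(x) x$cutoff_s, numeric(1))
  if (length(unique(cutoffs)) != 1L) {
    stop("pool_cutoff_counts: mixed cut-offs", call. = FALSE)
  }
  structure(list(n_long = sum(vapply(counts, function(x) x$n_long, numeric(1))),
                 n_total = sum(vapply(counts, function(x) x$n_total,
                                      numeric(1))),
                 cutoff_s = cutoffs[1], group = group),
            class = "cutoff_counts")
}

#' Yates-corrected chi-square test on long-RR proportions
#'
#' Compares the proportion of long (above cut-off) RR intervals between a
#' treated and a control group with the chi-square test with Yates'
#' continuity correction on the 2x2 table `[long, not long] x [treated,
#' control]`:
#' `chi2 = N * (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' with the p-value from the chi-square distribution with 1 degree of
#' freedom. When any margin of the table is zero the test is not
#' applicable and the result is flagged instead of raising an error.
#'
#' @param treated,control `cutoff_counts` objects (see [count_long_rr()]).
#' @return Object of class `cutoff_test`: list with `chi2`, `df`, `p`,
#'   `table` (the 2x2 matrix) and `applicable` (FALSE with `reason` when a
#'   margin is zero).
#' @examples
#' tr <- structure(list(n_long = 10, n_total = 100, cutoff_s = 3,
#'                      group = "drug"), class = "cutoff_counts")
#' ct <- structure(list(n_long = 2, n_total = 100, cutoff_s = 3,
#'                      group = "control"), class = "cutoff_counts")
#' cutoff_chi_square(tr, ct)$chi2  # ~ 4.344
#' @export
cutoff_chi_square <- function(treated, control) {
  stopifnot(inherits(treated, "cutoff_counts"),
            inherits(control, "cutoff_counts"))
  a <- as.numeric(treated$n_long)
  b <- as.numeric(treated$n_total) - a
  c_ <- as.numeric(control$n_long)
  d <- as.numeric(control$n_total) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("treated", "control"),
                                c("long", "not_long")))
  out <- list(chi2 = NA_real_, df = 1L, p = NA_real_, table = tab,
              applicable = TRUE, reason = "ok")
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    out$applicable <- FALSE
    out$reason <- "zero margin: test not applicable"
    return(structure(out, class = "cutoff_test"))
  }
  n <- a + b + c_ + d
  num <- max(0, abs(a * d - b * c_) - n / 2)
  out$chi2 <- n * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  out$p <- stats::pchisq(out$chi2, df = 1, lower.tail = FALSE)
  structure(out, class = "cutoff_test")
}

#' @export
print.cutoff_test <- function(x, ...) {
  cat("Cut-off arrhythmia test (Yates-corrected chi-square)\n")
  print(x$table)
  if (!x$applicable) {
    cat("  ", x$reason, "\n")
  } else {
    cat(sprintf("  chi2 = %.4f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  }
  invisible(x)
}
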
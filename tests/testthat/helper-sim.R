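# Shared fixtures: short, fast synthetic recordings used across test files.

quick_config <- function(...) {
  args <- list(duration_s = 40, sample_rate_hz = 500)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# independent brute-force SDSD: explicit loops, sample (n-1) divisor
sdsd_brute <- function(rr) {
  d <- numeric(0)
  for (i in seq_len(length(rr) - 1)) d <- c(d, rr[i + 1] - rr[i])
  m <- sum(d) / length(d)
  s2 <- 0
  for (x in d) s2 <- s2 + (x - m)^2
  sqrt(s2 / (length(d) - 1))
}

# deterministic per-replicate sub-seed (independent of the package's own
# seed-derivation helper)
derive_seed_test <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

# brute-force SDSD over adjacent kept pairs only (chain-breaking filter)
sdsd_brute_chain <- function(rr, kept) {
  d <- numeric(0)
  for (i in seq_len(length(rr) - 1)) {
    if (kept[i] && kept[i + 1]) d <- c(d, rr[i + 1] - rr[i])
  }
  if (length(d) < 2) return(NA_real_)
  stats::sd(d)
}

# independent closed-form OLS via explicit normal equations
ols_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * n / (n * sxx - sx * sx))
  tstat <- slope / se
  list(slope = slope, intercept = intercept, se = se, t = tstat,
       p = 2 * stats::pt(-abs(tstat), n - 2))
}
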
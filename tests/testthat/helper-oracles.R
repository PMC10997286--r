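# Independent oracles kept separate from the implementation under test.

# Classify every pair with an explicit loop (no vectorized shortcuts).
brute_force_pv <- function(cdm, chart) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(cdm)) {
    if (cdm[i] && chart[i]) tp <- tp + 1L
    else if (cdm[i] && !chart[i]) fp <- fp + 1L
    else if (!cdm[i] && !chart[i]) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       npv = if (tn + fn == 0) NA_real_ else tn / (tn + fn))
}

# Exact binomial interval by numeric inversion of the binomial tails
# (no beta quantiles, unlike the implementation).
cp_oracle <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  low <- if (k == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  high <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low, high)
}
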
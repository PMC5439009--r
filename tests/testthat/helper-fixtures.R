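# Shared fixtures: tiny corpora built in code, and an independent
# literal-recursion PPM oracle used to pin the smoothing semantics.

# Independent PPM oracle: recomputes context counts by scanning the raw
# training sequences on every call (no tries, no stored model), applies the
# escape-method-C interpolated recursion literally, and uses the same
# starting-context rule (shortest deterministic matching context under
# PPM*, else longest matching context, capped by the order bound).
oracle_ppm_predict <- function(train, context, n_symbols, order_bound = Inf,
                               ppm_star = TRUE) {
  count_after <- function(ctx) {
    cnt <- numeric(n_symbols)
    k <- length(ctx)
    for (s in train) {
      for (i in seq_along(s)) {
        if (i - 1 >= k && (k == 0 || all(s[(i - k):(i - 1)] == ctx))) {
          cnt[s[i]] <- cnt[s[i]] + 1
        }
      }
    }
    cnt
  }
  kmax <- min(order_bound, length(context))
  matched <- -1L
  det <- -1L
  for (k in 0:kmax) {
    ctx <- if (k == 0) integer(0) else utils::tail(context, k)
    cnt <- count_after(ctx)
    if (sum(cnt) == 0) break
    matched <- k
    if (det < 0 && sum(cnt > 0) == 1) det <- k
  }
  start <- if (ppm_star && det >= 0) det else matched
  p <- rep(1 / n_symbols, n_symbols)
  if (start >= 0) {
    for (k in 0:start) {
      ctx <- if (k == 0) integer(0) else utils::tail(context, k)
      cnt <- count_after(ctx)
      n <- sum(cnt)
      t <- sum(cnt > 0)
      p <- (cnt + t * p) / (n + t)
    }
  }
  p
}

# Downbeat-only rhythms: onsets on every bar line of the given meter.
downbeat_rhythm <- function(meter, n_bars, id = meter) {
  period <- meter_category(meter)$period
  rhythm_sequence(period * (0:(n_bars - 1L)), meter = meter, id = id)
}

# A tiny perfectly separable corpus: downbeat-only 2/4 and 3/4 rhythms.
separable_corpus <- function(n_each = 6, n_bars = 6) {
  rhythm_corpus(c(
    lapply(seq_len(n_each), function(i)
      downbeat_rhythm("2/4", n_bars, sprintf("d24-%d", i))),
    lapply(seq_len(n_each), function(i)
      downbeat_rhythm("3/4", n_bars, sprintf("d34-%d", i)))))
}

# Small three-category training corpus with distinct simple-duple,
# simple-triple and compound profiles, for the bias harness.
three_meter_spec <- function(n, seed) {
  culture_spec(
    categories = c("2/4", "3/4", "6/8"),
    prior = c(1, 1, 1) / 3,
    profiles = list(
      `2/4` = c(0.92, 0.04, 0.20, 0.04, 0.60, 0.04, 0.35, 0.04),
      `3/4` = c(0.92, 0.04, 0.15, 0.04, 0.50, 0.04, 0.15, 0.04,
                0.35, 0.04, 0.15, 0.04),
      `6/8` = c(0.92, 0.04, 0.10, 0.45, 0.04, 0.10, 0.60, 0.04, 0.10,
                0.30, 0.04, 0.10)),
    dependency = 0, n_bars = 4, n = n, seed = seed)
}

# Deterministic small culture for fast experiment tests.
mini_culture <- function(n, seed, n_bars = 4) {
  culture_spec(
    categories = c("2/4", "3/4"),
    prior = c(0.6, 0.4),
    profiles = list(
      `2/4` = c(0.92, 0.04, 0.20, 0.04, 0.60, 0.04, 0.35, 0.04),
      `3/4` = c(0.92, 0.04, 0.15, 0.04, 0.50, 0.04, 0.15, 0.04,
                0.35, 0.04, 0.15, 0.04)),
    dependency = 0, n_bars = n_bars, n = n, seed = seed)
}
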
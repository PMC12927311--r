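# Shared fixtures and independent oracles for the test suite.

# Build an efr_tfr whose coefficients are unit phasors with prescribed
# phases. `phases` is trials x times (recycled over channels/frequencies).
phasor_tfr <- function(phases, n_channels = 1, n_freqs = 1,
                       times = NULL, freqs = NULL) {
  phases <- as.matrix(phases)
  n_tr <- nrow(phases); n_t <- ncol(phases)
  if (is.null(times)) times <- seq_len(n_t)
  if (is.null(freqs)) freqs <- seq_len(n_freqs) + 29
  co <- array(0i, dim = c(n_tr, n_channels, n_freqs, n_t))
  for (ch in seq_len(n_channels)) for (fi in seq_len(n_freqs))
    co[, ch, fi, ] <- exp(1i * phases)
  tfr_from_coeffs(co, freqs = freqs, times = times)
}

# efr_tfr with prescribed coefficient magnitudes (zero phase).
magnitude_tfr <- function(mags, times = NULL) {
  mags <- as.matrix(mags)
  co <- array(complex(real = mags), dim = c(nrow(mags), 1, 1, ncol(mags)))
  tfr_from_coeffs(co, freqs = 40,
                  times = if (is.null(times)) seq_len(ncol(mags)) else times)
}

# Minimal efr_epochs around a raw data array (trials x channels x samples).
epochs_from_array <- function(data, sample_rate = 200, t0 = -1,
                              channels = NULL) {
  d <- dim(data)
  if (is.null(channels)) channels <- paste0("Ch", seq_len(d[2]))
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data,
                 times = t0 + (seq_len(d[3]) - 1) / sample_rate,
                 sample_rate = sample_rate, channels = channels,
                 subject_id = "fixture", group = "A", spec = NULL),
            class = "efr_epochs")
}

# Exhaustive two-sided permutation p value for the rank-sum statistic.
exact_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  E <- n1 * (length(r) + 1) / 2
  combos <- utils::combn(length(r), n1)
  W <- apply(combos, 2, function(ix) sum(r[ix]))
  mean(abs(W - E) >= abs(w_obs - E) - 1e-9)
}

# Exhaustive two-sided sign-flip p value for the signed-rank statistic.
exact_signed_rank_p <- function(x, y) {
  d <- (x - y)[x - y != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  E <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  V <- apply(signs, 1, function(s) sum(r[s]))
  mean(abs(V - E) >= abs(v_obs - E) - 1e-9)
}

# Constant-valued measure map over given channels/freqs/times.
constant_measure <- function(value, channels, freqs, times, measure = "PLI") {
  v <- array(value, dim = c(length(channels), length(freqs), length(times)),
             dimnames = list(channels, NULL, NULL))
  co <- array(0i, dim = c(2, length(channels), length(freqs), length(times)))
  tfr <- tfr_from_coeffs(co, freqs = freqs, times = times,
                         channels = channels)
  m <- structure(list(values = v, freqs = tfr$freqs, times = tfr$times,
                      channels = channels, valid = tfr$valid,
                      measure = measure, n_trials = 2, normalized = FALSE,
                      baseline_window = NULL, sample_rate = NA_real_),
                 class = "efr_measure")
  m
}

# Frequency curve object built directly from values (for stats-level tests).
curve_from_values <- function(values, freqs = 30:60) {
  structure(list(freqs = as.numeric(freqs), values = as.numeric(values),
                 measure = "PLI", roi = "fc9", normalized = TRUE,
                 n_samples = rep(1L, length(freqs))),
            class = "efr_curve")
}

# Midpoint of the segment during which `f` is stimulated in a sweep.
sweep_mid_time <- function(timeline, f, sweep = "up") {
  st <- timeline$stimulus
  row <- st[st$sweep == sweep & abs(st$frequency_hz - f) < 1e-9, ]
  (row$onset_s + row$time_s) / 2
}

# One-channel cohort wrapper used by several simulation tests.
single_channel_cohort <- function(spec, timeline, n_trials, sample_rate = 200,
                                  seed = 3) {
  cohort_spec(list(spec), timeline, n_trials = n_trials,
              sample_rate = sample_rate, channels = c(Cz = 1), seed = seed)
}
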
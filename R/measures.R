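new_measure <- function(values, x, measure, n_trials, normalized = FALSE,
                        baseline_window = NULL) {
  structure(list(values = values, freqs = x$freqs, times = x$times,
                 channels = x$channels, valid = x$valid, measure = measure,
                 n_trials = n_trials, normalized = normalized,
                 baseline_window = baseline_window,
                 sample_rate = x$sample_rate),
            class = "efr_measure")
}

#' Phase-locking index
#'
#' Inter-trial phase coherence: the modulus of the across-trial mean unit
#' phasor of the wavelet phase,
#' `PLI(f, t) = |mean_n exp(i * phi_n(f, t))|`, computed per channel.
#' 0 means random phases across trials, 1 perfect phase locking.
#'
#' @param tfr An `"efr_tfr"` object with at least 2 trials.
#' @return An object of class `"efr_measure"` with `values`
#'   (channel x frequency x time, raw PLI in \[0, 1\]), plus the axes and
#'   validity mask inherited from `tfr`.
#' @export
pli <- function(tfr) {
  stopifnot(inherits(tfr, "efr_tfr"))
  d <- dim(tfr$coeffs)
  if (d[1] < 2) stop("PLI requires at least 2 trials")
  if (any(Mod(tfr$coeffs) == 0))
    stop("zero-magnitude wavelet coefficient: phase undefined")
  phasors <- tfr$coeffs / Mod(tfr$coeffs)
  values <- Mod(colMeans(phasors))           # collapses the trial dimension
  dim(values) <- d[-1]
  dimnames(values) <- list(tfr$channels, NULL, NULL)
  new_measure(values, tfr, "PLI", n_trials = d[1])
}

#' Event-related spectral perturbation
#'
#' Across-trial mean wavelet power,
#' `ERSP(f, t) = mean_n |X_n(f, t)|^2`, computed per channel.
#'
#' @param tfr An `"efr_tfr"` object.
#' @return An `"efr_measure"` object (`values` in squared amplitude units).
#' @export
ersp <- function(tfr) {
  stopifnot(inherits(tfr, "efr_tfr"))
  d <- dim(tfr$coeffs)
  values <- colMeans(Mod(tfr$coeffs)^2)
  dim(values) <- d[-1]
  dimnames(values) <- list(tfr$channels, NULL, NULL)
  new_measure(values, tfr, "ERSP", n_trials = d[1])
}

#' Relative baseline normalization
#'
#' Divides all values by the mean over a pre-stimulus window (default
#' -500 to 0 ms), per channel and, by default, per frequency
#' (`scope = "per-frequency"`). `scope = "global"` divides by a single
#' per-channel scalar instead (mean over the window and all frequencies).
#'
#' @param m An `"efr_measure"` object (raw).
#' @param window Baseline window c(start, end) in s, half-open \[start, end).
#' @param scope `"per-frequency"` (default) or `"global"`.
#' @return The normalized `"efr_measure"`; the mean over the baseline
#'   window equals 1 per channel (and frequency, under the default scope).
#' @export
baseline_normalize <- function(m, window = c(-0.5, 0),
                               scope = c("per-frequency", "global")) {
  stopifnot(inherits(m, "efr_measure"))
  scope <- match.arg(scope)
  if (m$normalized) stop("measure is already baseline-normalized")
  idx <- which(m$times >= window[1] - 1e-12 & m$times < window[2] - 1e-12)
  if (!length(idx)) stop("baseline window contains no samples")
  if (!all(m$valid[, idx]))
    stop("baseline window extends into the epoch-edge region invalidated by the wavelet")
  base <- apply(m$values[, , idx, drop = FALSE], c(1, 2), mean)  # ch x freq
  if (scope == "global") base[] <- rowMeans(base)
  if (any(base <= 1e-12))
    stop("baseline mean is zero or near zero; cannot normalize")
  values <- m$values / as.vector(base)   # recycles over the time dimension
  out <- m
  out$values <- values
  out$normalized <- TRUE
  out$baseline_window <- window
  out
}

#' @export
print.efr_measure <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("%s map (%s): %d channels x %d freqs x %d times, %d trials\n",
              x$measure, if (x$normalized) "baseline-normalized" else "raw",
              d[1], d[2], d[3], x$n_trials))
  invisible(x)
}

#' Compute PLI and ERSP maps for one subject, memory-lean
#'
#' Runs the Morlet decomposition channel by channel and collapses trials
#' immediately, so the full trial-resolved coefficient array is never held
#' for more than one channel at a time. Returns raw and baseline-normalized
#' maps for both measures.
#'
#' @param epochs An `"efr_epochs"` object.
#' @param freqs Analysis frequencies (default 30--60 Hz grid).
#' @param n_cycles Wavelet cycles (default 14).
#' @param channels Channels to analyze (default all in the epochs).
#' @param baseline Baseline window in s (default c(-0.5, 0)).
#' @param scope Baseline scope, see [baseline_normalize()].
#' @return List with elements `pli_raw`, `ersp_raw`, `pli`, `ersp`
#'   (the last two baseline-normalized).
#' @export
compute_measures <- function(epochs, freqs = frequency_grid(),
                             n_cycles = 14, channels = NULL,
                             baseline = c(-0.5, 0),
                             scope = "per-frequency") {
  stopifnot(inherits(epochs, "efr_epochs"))
  if (is.null(channels)) channels <- epochs$channels
  parts <- lapply(channels, function(ch) {
    tfr <- tfr_decompose(epochs, freqs = freqs, n_cycles = n_cycles,
                         channels = ch)
    list(pli = pli(tfr), ersp = ersp(tfr), tfr_meta = tfr[c("freqs", "times",
         "channels", "valid", "sample_rate")])
  })
  bind <- function(field) {
    arr <- array(NA_real_, dim = c(length(channels),
                                   dim(parts[[1]][[field]]$values)[2:3]),
                 dimnames = list(channels, NULL, NULL))
    for (i in seq_along(parts)) arr[i, , ] <- parts[[i]][[field]]$values[1, , ]
    m <- parts[[1]][[field]]
    m$values <- arr
    m$channels <- channels
    m
  }
  pli_raw <- bind("pli")
  ersp_raw <- bind("ersp")
  list(pli_raw = pli_raw, ersp_raw = ersp_raw,
       pli = baseline_normalize(pli_raw, baseline, scope),
       ersp = baseline_normalize(ersp_raw, baseline, scope))
}
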
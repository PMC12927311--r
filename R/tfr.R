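#' Complex Morlet wavelet kernel
#'
#' Complex exponential at frequency `f` under a Gaussian envelope with
#' `sigma_t = n_cycles / (2 * pi * f)`, truncated at +/- 3 sigma_t and
#' L2-normalized (sum of squared magnitudes = 1). The kernel carries a
#' `gain` attribute equal to its response to a unit-amplitude sinusoid at
#' `f` (`0.5 * sum(Mod(kernel))`); [tfr_decompose()] divides by it so that
#' a unit sinusoid yields coefficient magnitude ~1 at every analysis
#' frequency, making amplitude (and hence PLI/ERSP) comparable across the
#' frequency curve.
#'
#' @param f Center frequency in Hz (> 0).
#' @param n_cycles Number of cycles (>= 1); the analysis default is 14.
#' @param sample_rate Sampling rate in Hz.
#' @return Complex vector (odd length) with attributes `sigma_t`, `gain`,
#'   `f`, `sample_rate`.
#' @export
morlet_kernel <- function(f, n_cycles = 14, sample_rate = 1000) {
  stopifnot(f > 0, n_cycles >= 1, sample_rate > 0)
  sigma_t <- n_cycles / (2 * pi * f)
  half <- floor(3 * sigma_t * sample_rate)
  t <- (-half:half) / sample_rate
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w <- w / sqrt(sum(Mod(w)^2))
  structure(w, sigma_t = sigma_t, gain = 0.5 * sum(Mod(w)), f = f,
            sample_rate = sample_rate)
}

#' Morlet wavelet decomposition of epochs
#'
#' Convolves every trial and channel with a complex Morlet kernel at each
#' analysis frequency (FFT-based linear convolution, "same" alignment).
#' Coefficients are kept trial-resolved; samples closer than half a kernel
#' length to either epoch edge are flagged invalid rather than dropped.
#'
#' @param epochs An `"efr_epochs"` object (see [simulate_epochs()]).
#' @param freqs Analysis frequencies in Hz (default the 30--60 Hz grid).
#' @param n_cycles Wavelet cycles (default 14).
#' @param channels Channel labels to decompose (default all).
#' @param tmin,tmax Optional crop of the output time axis in s.
#' @param chunk Trials per FFT batch (memory bound).
#' @return An object of class `"efr_tfr"`: list with `coeffs` (complex
#'   array, trial x channel x frequency x time), `freqs`, `times`,
#'   `channels`, `sample_rate`, `n_cycles`, and `valid` (frequency x time
#'   logical mask relative to the *original* epoch edges).
#' @export
tfr_decompose <- function(epochs, freqs = frequency_grid(), n_cycles = 14,
                          channels = NULL, tmin = NULL, tmax = NULL,
                          chunk = 512L) {
  stopifnot(inherits(epochs, "efr_epochs"))
  freqs <- as.numeric(freqs)
  if (any(!is.finite(epochs$data))) stop("epochs contain non-finite samples")
  if (is.null(channels)) channels <- epochs$channels
  miss <- setdiff(channels, epochs$channels)
  if (length(miss))
    stop("channel(s) not present in epochs: ", paste(miss, collapse = ", "))
  fs <- epochs$sample_rate
  times_all <- epochs$times
  n <- length(times_all)

  kernels <- lapply(freqs, morlet_kernel, n_cycles = n_cycles,
                    sample_rate = fs)
  klen <- vapply(kernels, length, integer(1))
  if (max(klen) > n)
    stop("epoch too short for the lowest-frequency kernel (",
         max(klen), " samples needed, ", n, " available); use longer epochs")

  sel <- seq_len(n)
  if (!is.null(tmin)) sel <- sel[times_all[sel] >= tmin - 1e-12]
  if (!is.null(tmax)) sel <- sel[times_all[sel] <= tmax + 1e-12]
  if (!length(sel)) stop("empty time selection")
  times <- times_all[sel]

  nfft <- 2^ceiling(log2(n + max(klen) - 1))
  kspec <- lapply(kernels, function(k) {
    kk <- complex(length.out = nfft)
    kk[seq_along(k)] <- k / attr(k, "gain")
    stats::fft(kk)
  })

  n_trials <- dim(epochs$data)[1]
  coeffs <- array(complex(real = NA_real_),
                  dim = c(n_trials, length(channels), length(freqs),
                          length(times)),
                  dimnames = list(NULL, channels, NULL, NULL))
  ch_idx <- match(channels, epochs$channels)
  starts <- seq(1L, n_trials, by = chunk)
  for (ci in seq_along(ch_idx)) {
    for (s0 in starts) {
      tr <- s0:min(s0 + chunk - 1L, n_trials)
      x <- t(epochs$data[tr, ch_idx[ci], , drop = FALSE][, 1, ])
      if (length(tr) == 1L) x <- matrix(epochs$data[tr, ch_idx[ci], ], ncol = 1)
      xp <- matrix(0, nfft, length(tr))
      xp[seq_len(n), ] <- x
      xs <- stats::mvfft(xp)
      for (fi in seq_along(freqs)) {
        conv <- stats::mvfft(xs * kspec[[fi]], inverse = TRUE) / nfft
        half <- (klen[fi] - 1L) %/% 2L
        same <- conv[half + sel, , drop = FALSE]
        coeffs[tr, ci, fi, ] <- t(same)
      }
    }
  }
  half_s <- (klen - 1) %/% 2 / fs
  valid <- outer(half_s, times, function(h, tt)
    tt >= times_all[1] + h & tt <= times_all[n] - h)
  structure(list(coeffs = coeffs, freqs = freqs, times = times,
                 channels = channels, sample_rate = fs, n_cycles = n_cycles,
                 valid = valid),
            class = "efr_tfr")
}

#' Construct a TFR object from raw coefficients
#'
#' Low-level constructor, mainly for building small synthetic
#' decompositions (e.g. prescribed phases) to feed [pli()] / [ersp()].
#'
#' @param coeffs Complex array, trial x channel x frequency x time.
#' @param freqs,times Axes matching the array dimensions.
#' @param channels Channel labels (default Ch1..ChK).
#' @param sample_rate Sampling rate in Hz.
#' @param valid Optional frequency x time logical mask (default all TRUE).
#' @return An `"efr_tfr"` object.
#' @export
tfr_from_coeffs <- function(coeffs, freqs, times, channels = NULL,
                            sample_rate = NA_real_, valid = NULL) {
  stopifnot(length(dim(coeffs)) == 4,
            dim(coeffs)[3] == length(freqs), dim(coeffs)[4] == length(times))
  if (is.null(channels)) channels <- paste0("Ch", seq_len(dim(coeffs)[2]))
  if (is.null(valid)) valid <- matrix(TRUE, length(freqs), length(times))
  structure(list(coeffs = coeffs, freqs = as.numeric(freqs),
                 times = as.numeric(times), channels = channels,
                 sample_rate = sample_rate, n_cycles = NA_real_,
                 valid = valid),
            class = "efr_tfr")
}

#' @export
print.efr_tfr <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf(
    "Morlet TFR: %d trials x %d channels x %d freqs (%g-%g Hz) x %d times\n",
    d[1], d[2], d[3], min(x$freqs), max(x$freqs), d[4]))
  invisible(x)
}
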
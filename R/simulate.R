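#' Fronto-central channel sets
#'
#' The nine midline fronto-central electrodes over which envelope-following
#' responses are strongest, and their left/right subsets used for
#' laterality analysis.
#' @format Character vectors of channel labels.
#' @name channel-sets
NULL

#' @rdname channel-sets
#' @export
FC9_CHANNELS <- c("F1", "Fz", "F2", "FC1", "FCz", "FC2", "C1", "Cz", "C2")

#' @rdname channel-sets
#' @export
LEFT_CHANNELS <- c("F1", "FC1", "C1")

#' @rdname channel-sets
#' @export
RIGHT_CHANNELS <- c("F2", "FC2", "C2")

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler. Used for per-trial phase offsets of the
#' simulated evoked oscillation; `kappa = 0` gives uniform phases,
#' `kappa >= 1e6` is treated as perfectly locked (all zero).
#'
#' @param n Number of draws.
#' @param kappa Concentration parameter, >= 0. The expected resultant
#'   length of the sample is `besselI(kappa, 1) / besselI(kappa, 0)`.
#' @param mu Mean direction in radians.
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa >= 1e6) return(rep(mu, n))
  if (kappa < 1e-8) return((stats::runif(n, -pi, pi) + mu + pi) %% (2 * pi) - pi)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(stats::runif(1) - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  (out + mu + pi) %% (2 * pi) - pi
}

#' Per-subject simulation parameters
#'
#' Describes one simulated subject: the resonance frequency of their
#' auditory network (`igf`), how consistently the evoked oscillation is
#' phase-locked across trials (`kappa`), its amplitude at resonance, the
#' Gaussian falloff of the response away from resonance, and the 1/f^alpha
#' background noise.
#'
#' @param subject_id Unique subject label.
#' @param group Group label (e.g. `"F"` / `"M"`).
#' @param igf Resonance frequency in Hz; must lie within the stimulation grid.
#' @param kappa von Mises concentration of the per-trial phase offset (>= 0).
#' @param amplitude Evoked oscillation amplitude at `igf`, in microvolts.
#' @param tuning_bw Gaussian tuning bandwidth in Hz (> 0): the evoked
#'   amplitude at stimulation frequency f is
#'   `amplitude * exp(-(f - igf)^2 / (2 * tuning_bw^2))`.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param noise_scale Background noise standard deviation, in microvolts.
#' @return A list of class `"subject_spec"`.
#' @export
subject_spec <- function(subject_id, group = "A", igf = 40, kappa = 1,
                         amplitude = 1, tuning_bw = 6,
                         noise_exponent = 1, noise_scale = 1) {
  stopifnot(is.character(subject_id), length(subject_id) == 1,
            kappa >= 0, amplitude >= 0, tuning_bw > 0, noise_scale >= 0)
  structure(list(subject_id = subject_id, group = group, igf = igf,
                 kappa = kappa, amplitude = amplitude, tuning_bw = tuning_bw,
                 noise_exponent = noise_exponent, noise_scale = noise_scale),
            class = "subject_spec")
}

#' Cohort-level simulation parameters
#'
#' @param subjects List of [subject_spec()] objects with unique ids.
#' @param timeline A [chirp_timeline()] describing the stimulus.
#' @param n_trials Stimulus repetitions per subject (default 200).
#' @param sample_rate EEG sampling rate in Hz (default 1000).
#' @param epoch_window Epoch limits in s relative to stimulus onset
#'   (default c(-1, 2)); must contain the baseline window and the last
#'   analysis window (stimulus duration + 0.15 s).
#' @param channels Named numeric vector of topographic gains per channel.
#'   Default: the nine fronto-central channels at gain 1 plus `Pz`, `Oz`
#'   at 0.3, emulating the fronto-central response maximum.
#' @param seed Master integer seed. Per-subject streams are derived from it
#'   and the subject id, so adding or removing a subject does not perturb
#'   the others.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(subjects, timeline, n_trials = 200,
                        sample_rate = 1000, epoch_window = c(-1, 2),
                        channels = NULL, seed = 1) {
  if (inherits(subjects, "subject_spec")) subjects <- list(subjects)
  stopifnot(length(subjects) >= 1, inherits(timeline, "chirp_timeline"),
            n_trials >= 2, sample_rate > 0, length(epoch_window) == 2)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject_id in cohort")
  if (is.null(channels)) {
    channels <- c(stats::setNames(rep(1, length(FC9_CHANNELS)), FC9_CHANNELS),
                  Pz = 0.3, Oz = 0.3)
  }
  if (is.null(names(channels)) || anyDuplicated(names(channels)))
    stop("`channels` must be a named vector with unique labels")
  if (epoch_window[1] > -0.5 || epoch_window[2] < timeline$duration + 0.15)
    stop("epoch window too short: must contain [-0.5, duration + 0.15] s")
  structure(list(subjects = subjects, timeline = timeline,
                 n_trials = as.integer(n_trials), sample_rate = sample_rate,
                 epoch_window = epoch_window, channels = channels,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# deterministic 31-bit stream seed from master seed + subject id
subject_seed <- function(master, id) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 1000000007
  as.integer((as.numeric(master) + h) %% 2147483647)
}

# Gaussian noise with power spectral density ~ 1/f^alpha, unit variance,
# one column per trial
one_over_f_noise <- function(n, n_trials, sample_rate, alpha) {
  white <- matrix(stats::rnorm(n * n_trials), n, n_trials)
  if (alpha == 0) return(white)
  spec <- stats::mvfft(white)
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * sample_rate / n
  gain <- c(0, freq[-1]^(-alpha / 2))
  spec <- spec * gain
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Simulate epochs for one subject
#'
#' Each trial is 1/f^alpha Gaussian background noise plus an evoked
#' component active only during the stimulus: an oscillation whose
#' instantaneous frequency follows the chirp timeline (piecewise constant,
#' phase reset at each frequency step), whose per-trial phase offset is
#' von Mises(0, kappa), and whose amplitude follows the subject's Gaussian
#' tuning around `igf`, scaled by the per-channel topographic gain.
#'
#' @param spec A [subject_spec()].
#' @param cohort A [cohort_spec()] (its `subjects` list is not consulted;
#'   trial count, timeline, channels etc. are).
#' @return An object of class `"efr_epochs"`: list with `data`
#'   (trials x channels x samples array, microvolts), `times` (s, 0 =
#'   stimulus onset), `sample_rate`, `channels`, `subject_id`, `group`,
#'   `spec`.
#' @export
simulate_epochs <- function(spec, cohort) {
  stopifnot(inherits(spec, "subject_spec"), inherits(cohort, "cohort_spec"))
  g <- cohort$timeline$grid
  if (spec$igf < min(g) || spec$igf > max(g))
    stop("subject igf lies outside the stimulation grid")
  fs <- cohort$sample_rate
  tw <- cohort$epoch_window
  n <- round((tw[2] - tw[1]) * fs) + 1L
  times <- tw[1] + (seq_len(n) - 1L) / fs
  n_trials <- cohort$n_trials
  ch_gain <- cohort$channels
  n_ch <- length(ch_gain)

  set.seed(subject_seed(cohort$seed, spec$subject_id))
  theta <- rvonmises(n_trials, spec$kappa)

  # evoked template phase/amplitude: shared across trials up to the offset
  st <- cohort$timeline$stimulus
  seg_amp <- spec$amplitude *
    exp(-(st$frequency_hz - spec$igf)^2 / (2 * spec$tuning_bw^2))
  base_phase <- rep(NA_real_, n)  # 2*pi*f*(t - onset) within each segment
  amp_env <- numeric(n)
  for (k in seq_len(nrow(st))) {
    idx <- which(times >= st$onset_s[k] & times < st$time_s[k])
    base_phase[idx] <- 2 * pi * st$frequency_hz[k] * (times[idx] - st$onset_s[k])
    amp_env[idx] <- seg_amp[k]
  }
  active <- !is.na(base_phase)

  data <- array(0, dim = c(n_trials, n_ch, n),
                dimnames = list(NULL, names(ch_gain), NULL))
  evoked <- matrix(0, n_trials, n)
  if (any(active)) {
    evoked[, active] <- outer(theta, base_phase[active], function(th, ph)
      cos(ph + th)) * rep(amp_env[active], each = n_trials)
  }
  for (ch in seq_len(n_ch)) {
    noise <- if (spec$noise_scale > 0)
      t(one_over_f_noise(n, n_trials, fs, spec$noise_exponent)) *
        spec$noise_scale
    else matrix(0, n_trials, n)
    data[, ch, ] <- ch_gain[ch] * evoked + noise
  }
  structure(list(data = data, times = times, sample_rate = fs,
                 channels = names(ch_gain), subject_id = spec$subject_id,
                 group = spec$group, spec = spec),
            class = "efr_epochs")
}

#' @export
print.efr_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "EFR epochs '%s' (group %s): %d trials x %d channels x %d samples @ %g Hz, t in [%.3g, %.3g] s\n",
    x$subject_id, x$group, d[1], d[2], d[3], x$sample_rate,
    x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Simulate a whole cohort
#'
#' @param cohort A [cohort_spec()].
#' @return Named list of [simulate_epochs()] results, one per subject.
#' @export
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  out <- lapply(cohort$subjects, simulate_epochs, cohort = cohort)
  names(out) <- vapply(cohort$subjects, function(s) s$subject_id, character(1))
  out
}
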
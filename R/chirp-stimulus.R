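#' Stimulation frequency grid
#'
#' Builds the ordered vector of stimulation frequencies swept by the
#' chirp-like click train. The default grid covers the low-gamma range
#' 30--60 Hz in 1-Hz steps (31 frequencies).
#'
#' @param f_lo Lowest frequency in Hz.
#' @param f_hi Highest frequency in Hz (inclusive).
#' @param step Grid step in Hz; `(f_hi - f_lo)` must be a multiple of `step`.
#' @return A numeric vector of class `"efr_grid"`, strictly increasing.
#' @examples
#' frequency_grid()          # 30, 31, ..., 60
#' frequency_grid(30, 60, 5)
#' @export
frequency_grid <- function(f_lo = 30, f_hi = 60, step = 1) {
  stopifnot(is.numeric(f_lo), is.numeric(f_hi), is.numeric(step),
            length(f_lo) == 1, length(f_hi) == 1, length(step) == 1)
  if (step <= 0) stop("`step` must be positive")
  if (f_lo <= 0) stop("frequencies must be positive")
  if (f_lo > f_hi) stop("`f_lo` must not exceed `f_hi` (empty range)")
  k <- (f_hi - f_lo) / step
  if (abs(k - round(k)) > 1e-9)
    stop("(f_hi - f_lo) must be divisible by `step`")
  freqs <- f_lo + step * seq(0, round(k))
  structure(freqs, class = "efr_grid")
}

#' Chirp frequency-to-time mapping
#'
#' Assigns a stimulus time to every grid frequency for the descending
#' (chirp-down) and ascending (chirp-up) sweeps. Times are cumulative sums
#' of the per-frequency periods 1/f: the down sweep runs through the grid in
#' descending order, the up sweep continues from the last down time in
#' ascending order. Each frequency thus occupies one period of its own; the
#' cumulative value marks the end of that interval and `onset_s` its start.
#'
#' @param grid A frequency grid from [frequency_grid()] (or a strictly
#'   increasing positive numeric vector).
#' @return An object of class `"chirp_timeline"`: a list with
#'   \describe{
#'     \item{stimulus}{data.frame in chronological order with columns
#'       `sweep` ("down"/"up"), `frequency_hz`, `onset_s`, `time_s`
#'       (`time_s = onset_s + 1/frequency_hz`).}
#'     \item{duration}{total stimulus duration in s (last up time).}
#'     \item{grid}{the input grid.}
#'   }
#' @examples
#' tl <- chirp_timeline(frequency_grid())
#' tl$duration                      # ~1.436 s, i.e. ~1400 ms
#' @export
chirp_timeline <- function(grid) {
  grid <- validate_grid(grid)
  f_down <- rev(grid)                      # sweep starts at the highest rate
  t_down <- cumsum(1 / f_down)
  f_up <- grid
  t_up <- t_down[length(t_down)] + cumsum(1 / f_up)
  stimulus <- data.frame(
    sweep = rep(c("down", "up"), each = length(grid)),
    frequency_hz = c(f_down, f_up),
    time_s = c(t_down, t_up)
  )
  stimulus$onset_s <- stimulus$time_s - 1 / stimulus$frequency_hz
  stimulus <- stimulus[, c("sweep", "frequency_hz", "onset_s", "time_s")]
  structure(list(stimulus = stimulus,
                 duration = t_up[length(t_up)],
                 grid = as.numeric(grid)),
            class = "chirp_timeline")
}

validate_grid <- function(grid) {
  g <- as.numeric(grid)
  if (length(g) < 1 || any(!is.finite(g)) || any(g <= 0))
    stop("grid must be a non-empty vector of positive finite frequencies")
  if (length(g) > 1 && any(diff(g) <= 0))
    stop("grid must be strictly increasing")
  g
}

#' @export
print.chirp_timeline <- function(x, ...) {
  g <- x$grid
  cat(sprintf("Chirp timeline: %d frequencies %g-%g Hz, duration %.4f s\n",
              length(g), min(g), max(g), x$duration))
  invisible(x)
}

#' Window start times for one sweep
#'
#' Internal helper: per grid frequency, the anchor time in the requested
#' sweep. `anchor = "cumsum"` uses the cumulative-sum value (end of the
#' frequency's own period, the literal reading of the mapping procedure);
#' `"onset"` uses the start of that period.
#' @noRd
sweep_times <- function(timeline, sweep, anchor = c("cumsum", "onset")) {
  anchor <- match.arg(anchor)
  st <- timeline$stimulus[timeline$stimulus$sweep == sweep, ]
  st <- st[order(st$frequency_hz), ]
  if (anchor == "cumsum") st$time_s else st$onset_s
}

#' Synthesize the click-train waveform
#'
#' One short white-noise burst at every down- and up-sweep time of the
#' timeline, emulating a click train whose instantaneous rate sweeps across
#' the grid (default clicks: 1.5 ms).
#'
#' @param timeline A [chirp_timeline()].
#' @param click_duration Click length in s (default 0.0015).
#' @param sample_rate Audio sampling rate in Hz (default 44100).
#' @param seed Integer seed; the waveform is deterministic given the seed.
#' @return An object of class `"click_train"`: list with `click_onsets` (s),
#'   `click_duration`, `sample_rate`, and `waveform` (amplitudes in
#'   \[-1, 1\], length `ceiling(duration * sample_rate)`).
#' @export
click_train <- function(timeline, click_duration = 0.0015,
                        sample_rate = 44100, seed = 1) {
  stopifnot(inherits(timeline, "chirp_timeline"))
  if (sample_rate < 2 / click_duration)
    stop("`sample_rate` too low to represent clicks of this duration")
  onsets <- sort(timeline$stimulus$time_s)
  if (any(diff(onsets) < click_duration))
    stop("clicks overlap: `click_duration` exceeds the shortest inter-click interval")
  n <- ceiling(timeline$duration * sample_rate)
  wave <- numeric(n)
  len <- round(click_duration * sample_rate)
  set.seed(as.integer(seed))
  for (t0 in onsets) {
    i0 <- floor(t0 * sample_rate) + 1
    idx <- i0:min(i0 + len - 1, n)
    wave[idx] <- stats::runif(length(idx), -1, 1)
  }
  structure(list(click_onsets = onsets, click_duration = click_duration,
                 sample_rate = sample_rate, waveform = wave),
            class = "click_train")
}

#' Export a chirp timeline as TSV
#'
#' Writes columns `sweep`, `frequency_hz`, `time_s` (and `onset_s`).
#'
#' @param timeline A [chirp_timeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeline_tsv <- function(timeline, path) {
  stopifnot(inherits(timeline, "chirp_timeline"))
  utils::write.table(timeline$stimulus, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
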
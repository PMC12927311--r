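#' Region of interest
#'
#' @param name ROI label.
#' @param channels Non-empty character vector of channel labels.
#' @return A list of class `"efr_roi"`.
#' @seealso [roi_fc9()], [roi_left()], [roi_right()]
#' @export
roi <- function(name, channels) {
  stopifnot(is.character(channels), length(channels) >= 1)
  structure(list(name = name, channels = unique(channels)), class = "efr_roi")
}

#' Standard ROIs
#'
#' `roi_fc9()`: the nine midline fronto-central channels used for the main
#' response curves and IGF extraction. `roi_left()` / `roi_right()`: the
#' mirrored three-channel subsets used for the laterality index.
#' @return An `"efr_roi"` object.
#' @export
roi_fc9 <- function() roi("fc9", FC9_CHANNELS)

#' @rdname roi_fc9
#' @export
roi_left <- function() roi("left", LEFT_CHANNELS)

#' @rdname roi_fc9
#' @export
roi_right <- function() roi("right", RIGHT_CHANNELS)

check_roi <- function(r, channels) {
  miss <- setdiff(r$channels, channels)
  if (length(miss))
    stop("ROI '", r$name, "' references channel(s) absent from the data: ",
         paste(miss, collapse = ", "))
  invisible(r)
}

#' Per-frequency response curve
#'
#' For every stimulation frequency f of the chirp grid, averages the
#' measure map over the ROI channels and over two 150-ms windows anchored
#' at f's time in the down sweep and in the up sweep (300 ms of data per
#' frequency in total; both windows contribute fully even where they
#' overlap in time).
#'
#' @param m An `"efr_measure"` map whose frequency axis contains the grid.
#' @param timeline A [chirp_timeline()].
#' @param roi An `"efr_roi"`; default the nine fronto-central channels.
#' @param window_len Averaging window length in s (default 0.150);
#'   windows are half-open `[t, t + window_len)`.
#' @param anchor `"cumsum"` (default; windows start at the cumulative-sum
#'   time of each frequency) or `"onset"` (start of the frequency's own
#'   period).
#' @return An object of class `"efr_curve"`: list with `freqs`, `values`,
#'   `measure`, `roi`, `n_samples` (pooled samples per frequency).
#' @export
frequency_curve <- function(m, timeline, roi = roi_fc9(),
                            window_len = 0.150,
                            anchor = c("cumsum", "onset")) {
  stopifnot(inherits(m, "efr_measure"), inherits(timeline, "chirp_timeline"),
            inherits(roi, "efr_roi"), window_len > 0)
  anchor <- match.arg(anchor)
  check_roi(roi, m$channels)
  grid <- timeline$grid
  f_idx <- match_freqs(grid, m$freqs)
  ch_idx <- match(roi$channels, m$channels)
  starts_down <- sweep_times(timeline, "down", anchor)
  starts_up <- sweep_times(timeline, "up", anchor)
  values <- numeric(length(grid))
  n_samples <- integer(length(grid))
  for (k in seq_along(grid)) {
    idx <- c(window_index(m$times, starts_down[k], window_len),
             window_index(m$times, starts_up[k], window_len))
    if (!length(idx))
      stop("averaging window contains no samples at ", grid[k], " Hz")
    tmax_needed <- max(starts_down[k], starts_up[k]) + window_len
    dt <- if (length(m$times) > 1) stats::median(diff(m$times)) else 0
    if (m$times[length(m$times)] + dt < tmax_needed - 1e-9)
      stop("averaging window at ", grid[k], " Hz extends past the epoch end")
    if (!all(m$valid[f_idx[k], idx]))
      stop("averaging window at ", grid[k],
           " Hz lies outside the valid (edge-free) region")
    values[k] <- mean(m$values[ch_idx, f_idx[k], idx])
    n_samples[k] <- length(idx)
  }
  structure(list(freqs = as.numeric(grid), values = values,
                 measure = m$measure, roi = roi$name,
                 normalized = m$normalized, n_samples = n_samples),
            class = "efr_curve")
}

match_freqs <- function(grid, freqs) {
  idx <- vapply(grid, function(f) {
    j <- which(abs(freqs - f) < 1e-9)
    if (length(j) != 1) NA_integer_ else j
  }, integer(1))
  if (any(is.na(idx)))
    stop("measure map does not contain grid frequencies: ",
         paste(grid[is.na(idx)], collapse = ", "))
  idx
}

window_index <- function(times, start, len) {
  which(times >= start - 1e-9 & times < start + len - 1e-9)
}

#' @export
print.efr_curve <- function(x, ...) {
  cat(sprintf("%s frequency curve over ROI '%s': %d frequencies %g-%g Hz\n",
              x$measure, x$roi, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' @export
plot.efr_curve <- function(x, ...) {
  graphics::plot(x$freqs, x$values, type = "b", pch = 16,
                 xlab = "Stimulation frequency (Hz)",
                 ylab = paste0(x$measure,
                               if (x$normalized) " (baseline-normalized)"),
                 ...)
  invisible(x)
}

#' Individual gamma frequency
#'
#' The stimulation frequency with the highest curve value. Ties are broken
#' to the lowest frequency. The companion value at 40 Hz is a grid lookup
#' (NA if 40 Hz is not on the grid; never interpolated).
#'
#' @param curve An `"efr_curve"`.
#' @return A list of class `"efr_igf"`: `igf` (Hz), `value_at_igf`,
#'   `value_at_40`.
#' @export
extract_igf <- function(curve) {
  stopifnot(inherits(curve, "efr_curve"), length(curve$freqs) >= 1)
  if (any(!is.finite(curve$values))) stop("curve contains non-finite values")
  k <- which.max(curve$values)            # first maximum = lowest frequency
  j40 <- which(abs(curve$freqs - 40) < 1e-9)
  structure(list(igf = curve$freqs[k], value_at_igf = curve$values[k],
                 value_at_40 = if (length(j40)) curve$values[j40] else
                   NA_real_),
            class = "efr_igf")
}

#' Laterality index
#'
#' `LI = (L - R) / (L + R)` where L and R are the response-curve values at
#' the requested frequency, averaged over the left (F1, FC1, C1) and right
#' (F2, FC2, C2) ROIs. Confined to \[-1, 1\]; negative values indicate
#' right-side, positive left-side dominance.
#'
#' @param m An `"efr_measure"` map containing both ROIs' channels.
#' @param timeline A [chirp_timeline()].
#' @param at Frequency in Hz at which to evaluate (typically the subject's
#'   IGF, or 40).
#' @param left,right ROIs (defaults [roi_left()], [roi_right()]).
#' @param ... Passed on to [frequency_curve()] (e.g. `window_len`, `anchor`).
#' @return A list of class `"efr_li"`: `li`, `at`, `measure`.
#' @export
laterality_index <- function(m, timeline, at, left = roi_left(),
                             right = roi_right(), ...) {
  cl <- frequency_curve(m, timeline, roi = left, ...)
  cr <- frequency_curve(m, timeline, roi = right, ...)
  k <- which(abs(cl$freqs - at) < 1e-9)
  if (length(k) != 1) stop("frequency ", at, " Hz is not on the grid")
  L <- cl$values[k]
  R <- cr$values[k]
  if (L + R <= 0) stop("L + R must be positive to form a laterality index")
  structure(list(li = (L - R) / (L + R), at = at, measure = m$measure),
            class = "efr_li")
}
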
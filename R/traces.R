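#' Uniformly sampled signal traces with stimulus annotations
#'
#' Torque and EMG recordings are represented as uniformly sampled traces:
#' a numeric sample vector, a sampling rate (Hz), a start time (s) and a
#' stimulus-event table.  Each event row has \code{time} (s),
#' \code{kind} (\code{"single"} or \code{"doublet100Hz"}),
#' \code{context} (\code{"superimposed"} or \code{"resting"}) and
#' \code{pulses} (number of pulses in the group).
#'
#' @param samples Numeric vector (Nm for torque, mV for EMG); must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample, s.
#' @param events Stimulus event data.frame (may be empty / NULL).
#' @param channel EMG channel label (e.g. \code{"VL"}, \code{"BF"}).
#' @return A \code{"torque_trace"} / \code{"emg_trace"} object.
#' @export
torque_trace <- function(samples, rate, t0 = 0, events = NULL) {
  new_trace(samples, rate, t0, events, "torque_trace")
}

#' @rdname torque_trace
#' @export
emg_trace <- function(samples, rate, t0 = 0, events = NULL, channel = "VL") {
  tr <- new_trace(samples, rate, t0, events, "emg_trace")
  tr$channel <- channel
  tr
}

new_trace <- function(samples, rate, t0, events, cls) {
  if (!is.numeric(samples) || length(samples) == 0)
    stop("empty input: trace needs at least one sample")
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  if (rate <= 0) stop("trace rate must be > 0")
  if (is.null(events))
    events <- data.frame(time = numeric(0), kind = character(0),
                         context = character(0), pulses = integer(0),
                         stringsAsFactors = FALSE)
  span <- c(t0, t0 + (length(samples) - 1) / rate)
  if (nrow(events) && (any(events$time < span[1]) || any(events$time > span[2])))
    stop("event-placement error: stimulus outside trace span")
  if (nrow(events) > 1 && is.unsorted(events$time, strictly = TRUE))
    stop("stimulus events must be strictly ordered in time")
  structure(list(samples = samples, rate = rate, t0 = t0, events = events),
            class = cls)
}

#' Time axis of a trace
#' @param trace A trace object.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
}

# index range of samples with time in [from, to] (closed)
trace_window_idx <- function(trace, from, to) {
  i0 <- ceiling((from - trace$t0) * trace$rate - 1e-9) + 1
  i1 <- floor((to - trace$t0) * trace$rate + 1e-9) + 1
  i0 <- max(i0, 1L)
  i1 <- min(i1, length(trace$samples))
  if (i0 > i1) stop("empty input: requested window contains no samples")
  seq.int(i0, i1)
}

#' @export
print.torque_trace <- function(x, ...) {
  cat(sprintf("torque trace: %d samples @ %g Hz (%.2f s), %d stimulus event(s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              nrow(x$events)))
  invisible(x)
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("EMG trace [%s]: %d samples @ %g Hz (%.2f s), %d stimulus event(s)\n",
              x$channel, length(x$samples), x$rate,
              length(x$samples) / x$rate, nrow(x$events)))
  invisible(x)
}

#' Shear-wave elastography clip
#'
#' A sequence of 2D shear-wave-speed maps (m/s) with a rectangular region
#' of interest.  The ROI is stored in pixel coordinates as
#' \code{(row0, col0, height, width)}, 0-based, half-open.
#'
#' @param frames List of numeric matrices (m/s), all of the same shape.
#' @param pixel_mm Pixel pitch in mm.
#' @param frame_interval Time between frames, s.
#' @param roi Integer vector \code{(row0, col0, height, width)}.
#' @return An \code{"swe_clip"} object.
#' @export
swe_clip <- function(frames, pixel_mm = 1, frame_interval = 1, roi) {
  if (length(frames) < 1) stop("empty input: clip needs at least one frame")
  dims <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1))))
    stop("all frames must share the same shape")
  if (any(vapply(frames, function(f) any(f < 0), logical(1))))
    stop("invalid-speed error: shear-wave speeds must be >= 0")
  roi <- as.integer(roi)
  if (length(roi) != 4 || any(roi[3:4] < 1) || roi[1] < 0 || roi[2] < 0 ||
      roi[1] + roi[3] > dims[1] || roi[2] + roi[4] > dims[2])
    stop("roi-bounds error: ROI outside the map")
  structure(list(frames = frames, pixel_mm = pixel_mm,
                 frame_interval = frame_interval, roi = roi),
            class = "swe_clip")
}

#' @export
print.swe_clip <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("SWE clip: %d frame(s) of %d x %d px (%g mm/px) @ %g s; ROI %d x %d px\n",
              length(x$frames), d[1], d[2], x$pixel_mm, x$frame_interval,
              x$roi[3], x$roi[4]))
  invisible(x)
}
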
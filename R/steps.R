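# Step detection from the acceleration-vector-change signal.
#
# Each heel strike produces a burst in the AVC (per-sample |dr/dt|)
# signal; steps are counted as peaks of the smoothed detection signal that
# exceed an adaptive threshold and are separated by a refractory period.

#' Step-detection configuration
#'
#' @param smooth_s Moving-average smoothing window in seconds.
#' @param threshold `"adaptive"` (mean + `k` * SD of the smoothed signal)
#'   or a fixed numeric threshold in the detection signal's units.
#' @param k Multiplier for the adaptive threshold.
#' @param refractory_s Minimum interval between two detected steps,
#'   seconds (> 0).
#' @param signal Detection signal: `"avc"` (default) or `"magnitude"`.
#' @param min_height Absolute floor on the detection signal below which no
#'   peak counts as a step, so that quiescent (noise-only) recordings give
#'   zero steps; `NULL` picks 5 m/s^3 for AVC (well above the smoothed
#'   noise-difference level at realistic sensor noise, well below gait
#'   heel-strike bursts) and 0.5 m/s^2 for magnitude.
#' @return List of class `step_config`.
#' @export
step_config <- function(smooth_s = 0.15, threshold = "adaptive", k = 0.5,
                        refractory_s = 0.25, signal = c("avc", "magnitude"),
                        min_height = NULL) {
  if (refractory_s <= 0) abort("`refractory_s` must be > 0.")
  if (smooth_s < 0) abort("`smooth_s` must be >= 0.")
  signal <- match.arg(signal)
  min_height <- min_height %||% if (signal == "avc") 5 else 0.5
  structure(list(smooth_s = smooth_s, threshold = threshold, k = k,
                 refractory_s = refractory_s, signal = signal,
                 min_height = min_height),
            class = "step_config")
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - floor(w / 2), 1L)
  hi <- pmin(i + ceiling(w / 2) - 1L, n)
  cs <- c(0, cumsum(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect steps in a single-sensor recording
#'
#' @param recording Tibble with columns `time_s`, `ax`, `ay`, `az` for one
#'   sensor stream (at least 2 s long).
#' @param cfg A [step_config()].
#' @return List of class `har_steps`: `step_count`, `step_indices`
#'   (strictly increasing sample positions, `>= refractory` apart),
#'   `cadence_hz`, plus the detection signal and threshold for
#'   inspection/plotting.
#' @export
detect_steps <- function(recording, cfg = step_config()) {
  stopifnot(all(c("time_s", "ax", "ay", "az") %in% names(recording)))
  if (length(unique(recording$placement %||% "one")) > 1 ||
      length(unique(recording$subject_id %||% "one")) > 1) {
    abort("`detect_steps()` expects a single (subject, placement) stream.")
  }
  t <- recording$time_s
  n <- nrow(recording)
  fs <- 1 / median(diff(t))
  if (n / fs < 2) abort("Recording must be at least 2 s long.")
  r <- vector_magnitude(recording$ax, recording$ay, recording$az)
  w <- max(1L, round(cfg$smooth_s * fs))
  # differencing at full rate amplifies wideband noise, so the magnitude is
  # lightly low-passed before the AVC is taken; the window stays short so
  # heel-strike transients keep their edge over the smooth gait oscillation
  w_pre <- max(1L, round(min(cfg$smooth_s, 0.05) * fs))
  r_s <- moving_average(r, w_pre)
  sig <- if (cfg$signal == "avc") avc(r_s, fs, M = 1) else r_s - mean(r_s)
  smooth <- moving_average(sig, w)
  thr <- if (identical(cfg$threshold, "adaptive")) {
    max(mean(smooth) + cfg$k * sd(smooth), cfg$min_height)
  } else {
    as.numeric(cfg$threshold)
  }
  # local maxima above threshold
  is_peak <- c(FALSE, diff(smooth) > 0) & c(diff(smooth) <= 0, FALSE) &
    smooth > thr
  cand <- which(is_peak)
  refr <- cfg$refractory_s * fs
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    }
  }
  structure(
    list(step_count = length(keep), step_indices = keep,
         cadence_hz = length(keep) / (n / fs),
         detection_signal = smooth, threshold = thr, fs = fs,
         time_s = t),
    class = "har_steps"
  )
}

#' @export
print.har_steps <- function(x, ...) {
  cat("<har_steps>", x$step_count, "steps over",
      round(length(x$detection_signal) / x$fs, 1), "s (cadence",
      round(x$cadence_hz, 2), "steps/s)\n")
  invisible(x)
}

#' Step-count accuracy against a reference
#'
#' `100 * (1 - |detected - reference| / reference)`.
#'
#' @param detected Detected step count.
#' @param reference True (or reference-device) step count, > 0.
#' @return Percentage.
#' @export
#' @examples
#' step_accuracy(19, 20)
step_accuracy <- function(detected, reference) {
  if (reference <= 0) abort("`reference` must be > 0.")
  100 * (1 - abs(detected - reference) / reference)
}

#' Plot the step-detection signal
#'
#' @param object A [detect_steps()] result.
#' @param ... Unused.
#' @return A ggplot object showing the smoothed detection signal, the
#'   threshold and the detected steps.
#' @method autoplot har_steps
#' @export
autoplot.har_steps <- function(object, ...) {
  df <- tibble::tibble(time_s = object$time_s,
                       signal = object$detection_signal)
  pk <- df[object$step_indices, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$signal)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::geom_point(data = pk, color = "#d7301f", size = 2) +
    ggplot2::labs(x = "Time (s)", y = "Detection signal")
}
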
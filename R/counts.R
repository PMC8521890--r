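# ActiGraph-style activity counts.
#
# The counts measure is proprietary, but a published reconstruction allows
# computing it from any raw accelerometer: convert to g-units, resample to
# 30 Hz, apply a fixed band-pass filter (passband roughly 0.3-2.5 Hz),
# decimate to 10 Hz, rectify, zero below a deadband, clip at saturation,
# quantize, and accumulate per epoch. The filter taps below are the
# published reconstruction's coefficients for 30 Hz input.

counts_filter_coefs <- function() {
  list(
    b = c(0.049109, -0.12284, 0.14356, -0.11269, 0.053804, -0.02023,
          0.0063778, 0.018513, -0.038154, 0.048727, -0.052577, 0.047847,
          -0.046015, 0.036283, -0.012977, -0.0046262, 0.012835, -0.0093762,
          0.0034485, -0.00080972, -0.00019623),
    a = c(1, -4.1637, 7.5712, -7.9805, 5.385, -2.4636, 0.89238, 0.06361,
          -1.3481, 2.4734, -2.9257, 2.9298, -2.7816, 2.4777, -1.6847,
          0.46483, 0.46565, -0.67312, 0.4162, -0.13832, 0.019852)
  )
}

#' Configuration of the activity-counts chain
#'
#' All constants of the counts reconstruction, exposed for transparency.
#' Defaults follow the published reconstruction of the ActiGraph measure:
#' resample to 30 Hz, band-pass with the fixed published taps, decimate to
#' 10 Hz, deadband 0.068 g, saturation 2.13 g, quantization step
#' 2.13/128 g, 1 s epochs.
#'
#' @param resample_hz Intermediate rate the signal is resampled to before
#'   filtering (Hz).
#' @param deadband_g Rectified amplitudes below this (g-units) contribute
#'   nothing.
#' @param saturation_g Rectified amplitudes are clipped here (g-units).
#' @param quant_step_g Quantization step (g-units).
#' @param epoch_s Epoch length in seconds over which counts accumulate.
#' @param downsample_hz Rate of the rectified/quantized stream (Hz);
#'   obtained by keeping every `resample_hz / downsample_hz`-th filtered
#'   sample.
#' @param gravity Conversion constant, m/s^2 per g.
#' @return List of class `counts_config`.
#' @export
counts_config <- function(resample_hz = 30, deadband_g = 0.068,
                          saturation_g = 2.13, quant_step_g = 2.13 / 128,
                          epoch_s = 1, downsample_hz = 10, gravity = 9.81) {
  if (deadband_g <= 0 || deadband_g >= saturation_g) {
    abort("Need 0 < deadband_g < saturation_g.")
  }
  if (quant_step_g <= 0) abort("`quant_step_g` must be > 0.")
  if (resample_hz %% downsample_hz != 0) {
    abort("`resample_hz` must be an integer multiple of `downsample_hz`.")
  }
  if ((epoch_s * downsample_hz) %% 1 != 0) {
    abort("`epoch_s * downsample_hz` must be an integer.")
  }
  cf <- counts_filter_coefs()
  structure(
    list(resample_hz = resample_hz, deadband_g = deadband_g,
         saturation_g = saturation_g, quant_step_g = quant_step_g,
         epoch_s = epoch_s, downsample_hz = downsample_hz, gravity = gravity,
         filter_b = cf$b, filter_a = cf$a,
         resampling = "linear interpolation"),
    class = "counts_config"
  )
}

#' Activity counts per second
#'
#' Runs the counts reconstruction chain on a one-axis (or magnitude)
#' acceleration series sampled at `fs` Hz. The band-pass filter removes DC,
#' so a static sensor yields 0 counts in every epoch regardless of
#' orientation.
#'
#' @param x Acceleration series in m/s^2 (one axis, or the vector
#'   magnitude).
#' @param fs Sampling frequency of `x`, Hz.
#' @param cfg A [counts_config()].
#' @return Tibble with one row per complete epoch: `epoch_start_s`,
#'   `counts` (non-negative integer) and `counts_per_sec`.
#' @export
#' @examples
#' counts_per_sec(rep(9.81, 500), fs = 100)
counts_per_sec <- function(x, fs, cfg = counts_config()) {
  if (fs <= 0) abort("`fs` must be positive.")
  n <- length(x)
  if (n / fs < cfg$epoch_s) {
    abort("Input shorter than one epoch.")
  }
  g <- x / cfg$gravity
  # counts quantify dynamic acceleration only; removing the DC before
  # filtering avoids the band-pass startup transient a constant offset
  # would otherwise inject
  g <- g - mean(g)
  # resample to the filter's design rate
  t_in <- (seq_len(n) - 1) / fs
  n_rs <- floor(t_in[n] * cfg$resample_hz) + 1
  t_rs <- (seq_len(n_rs) - 1) / cfg$resample_hz
  g_rs <- approx(t_in, g, xout = t_rs)$y
  # fixed band-pass
  filt <- signal::filter(cfg$filter_b, cfg$filter_a, g_rs)
  filt <- as.numeric(filt)
  # decimate, rectify, deadband, clip, quantize
  step <- cfg$resample_hz / cfg$downsample_hz
  dec <- filt[seq(1, length(filt), by = step)]
  rect <- abs(dec)
  rect[rect < cfg$deadband_g] <- 0
  rect[rect > cfg$saturation_g] <- cfg$saturation_g
  quant <- floor(rect / cfg$quant_step_g)
  # accumulate per epoch
  per_epoch <- cfg$epoch_s * cfg$downsample_hz
  n_ep <- floor(length(quant) / per_epoch)
  if (n_ep < 1) abort("Input shorter than one epoch after resampling.")
  idx <- rep(seq_len(n_ep), each = per_epoch)
  counts <- as.integer(tapply(quant[seq_len(n_ep * per_epoch)], idx, sum))
  tibble::tibble(
    epoch_start_s = (seq_len(n_ep) - 1) * cfg$epoch_s,
    counts = counts,
    counts_per_sec = counts / cfg$epoch_s
  )
}
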
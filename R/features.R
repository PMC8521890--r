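# Per-sample time-domain features.
#
# 13 metrics, 10 of them per axis, give 33 features per sensor: the raw
# accelerations themselves, tilt angles, AVC, SMA, and windowed mean, SD,
# RMS, MIN, MAX, median, MAD and skewness per axis, plus activity counts
# per second. Windowed statistics use population divisors (1/M) exactly as
# defined; the default windows are M = 1 for AVC and SMA and a centered
# M = 100 window for the order-2+ statistics at fs = 100 Hz.

#' Euclidean magnitude of a tri-axial acceleration signal
#'
#' @param ax,ay,az Numeric vectors of equal length, m/s^2.
#' @return Numeric vector `r = sqrt(ax^2 + ay^2 + az^2)`.
#' @export
#' @examples
#' vector_magnitude(3, 4, 0)
vector_magnitude <- function(ax, ay, az) {
  sqrt(ax^2 + ay^2 + az^2)
}

#' Tilt (inclination) angles of each sensor axis
#'
#' The angle between each body axis and the local gravity direction,
#' `phi_k = arccos(a_k / r)`; for a slowly moving sensor this estimates the
#' sensor inclination. Where the magnitude `r` is zero the tilt is
#' undefined and returned as `NA` (never silently zero).
#'
#' @inheritParams vector_magnitude
#' @return Tibble with columns `tilt_x`, `tilt_y`, `tilt_z` in radians,
#'   each in `[0, pi]`.
#' @export
#' @examples
#' tilt_angles(0, 0, 9.81)
tilt_angles <- function(ax, ay, az) {
  r <- vector_magnitude(ax, ay, az)
  safe_acos <- function(x) acos(pmin(1, pmax(-1, x)))
  bad <- r == 0
  r[bad] <- NA_real_
  tibble::tibble(
    tilt_x = safe_acos(ax / r),
    tilt_y = safe_acos(ay / r),
    tilt_z = safe_acos(az / r)
  )
}

# Centered window bounds for sample i and window length M: [i - floor(M/2),
# i + ceiling(M/2) - 1]; `causal` uses [i - M + 1, i]. Returned unclamped.
window_bounds <- function(i, M, centering = c("centered", "causal")) {
  centering <- match.arg(centering)
  if (centering == "centered") {
    list(lo = i - floor(M / 2), hi = i + ceiling(M / 2) - 1)
  } else {
    list(lo = i - M + 1, hi = i)
  }
}

#' Acceleration vector change (AVC)
#'
#' The windowed mean of the absolute first difference of the acceleration
#' magnitude per unit time: with window `M = 1` (the default used for
#' per-sample features) `AVC_i = |r_[i+1] - r_i| / Ts`. The final sample,
#' which has no forward neighbor, uses the backward difference so that
#' every sample receives a value.
#'
#' @param r Acceleration magnitude series, m/s^2 (length >= 2).
#' @param fs Sampling frequency, Hz.
#' @param M Window length in samples (number of consecutive differences
#'   averaged).
#' @param centering Window placement, `"centered"` (default) or `"causal"`.
#' @return Numeric vector of per-sample AVC values, m/s^3, non-negative.
#' @export
#' @examples
#' avc(c(1, 2), fs = 100)
avc <- function(r, fs, M = 1, centering = "centered") {
  n <- length(r)
  if (n < 2) abort("AVC needs a series of at least 2 samples.")
  d <- abs(diff(r)) * fs  # length n - 1
  b <- window_bounds(seq_len(n), M, centering)
  lo <- pmin(pmax(b$lo, 1L), n - 1L)
  hi <- pmin(pmax(b$hi, 1L), n - 1L)
  cs <- c(0, cumsum(d))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Signal magnitude area (SMA)
#'
#' Windowed mean of the summed absolute axis accelerations; with `M = 1`
#' (the per-sample default) `SMA_i = |ax_i| + |ay_i| + |az_i|`.
#'
#' @inheritParams vector_magnitude
#' @inheritParams avc
#' @return Numeric vector of per-sample SMA values, m/s^2, non-negative.
#' @export
#' @examples
#' sma(1, -1, 0.5)
sma <- function(ax, ay, az, M = 1, centering = "centered") {
  s <- abs(ax) + abs(ay) + abs(az)
  n <- length(s)
  if (n == 0) abort("SMA needs a non-empty series.")
  if (M == 1) return(s)
  b <- window_bounds(seq_len(n), M, centering)
  lo <- pmin(pmax(b$lo, 1L), n)
  hi <- pmin(pmax(b$hi, 1L), n)
  cs <- c(0, cumsum(s))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Rolling one-axis order statistics evaluated at the given centers.
roll_order_stats <- function(x, centers, lo, hi) {
  k <- length(centers)
  mins <- numeric(k); maxs <- numeric(k); meds <- numeric(k); mads <- numeric(k)
  for (j in seq_len(k)) {
    w <- x[lo[j]:hi[j]]
    mins[j] <- min(w)
    maxs[j] <- max(w)
    m <- median(w)
    meds[j] <- m
    mads[j] <- median(abs(w - m))
  }
  list(min = mins, max = maxs, median = meds, mad = mads)
}

#' Windowed per-axis statistics
#'
#' Computes, for every sample of a one-axis series, the windowed mean, SD,
#' RMS, minimum, maximum, median, median absolute deviation and skewness.
#' SD, RMS and skewness use the population divisor `1/M`; the MAD is the
#' median of absolute deviations from the window median; skewness of a
#' zero-variance window is defined as 0. Windows are truncated at the
#' series boundaries (`edge_policy = "shrink"`) or the affected samples
#' dropped (`"drop"`, in which case attribute `"kept"` gives the retained
#' sample indices).
#'
#' @param x Numeric series for one axis.
#' @param M Window length in samples.
#' @param centering `"centered"` (default) or `"causal"`.
#' @param edge_policy `"shrink"` (default) or `"drop"`.
#' @param centers Optional integer vector of sample indices at which to
#'   evaluate (default: every sample).
#' @return Tibble with columns `mean`, `sd`, `rms`, `min`, `max`, `median`,
#'   `mad`, `skew`, one row per evaluated sample.
#' @export
#' @examples
#' axis_stats(c(1, 2, 3, 4, 5), M = 5)[3, ]
axis_stats <- function(x, M = 100, centering = "centered",
                       edge_policy = c("shrink", "drop"), centers = NULL) {
  edge_policy <- match.arg(edge_policy)
  n <- length(x)
  if (n == 0) abort("Empty series.")
  if (M < 1) abort("`M` must be >= 1.")
  centers <- centers %||% seq_len(n)
  b <- window_bounds(centers, M, centering)
  if (edge_policy == "drop") {
    keep <- b$lo >= 1 & b$hi <= n
    if (!any(keep)) {
      abort("Series shorter than the window; nothing left under edge_policy = 'drop'.")
    }
    centers <- centers[keep]
    b$lo <- b$lo[keep]; b$hi <- b$hi[keep]
  }
  lo <- pmin(pmax(b$lo, 1L), n)
  hi <- pmin(pmax(b$hi, 1L), n)
  m <- hi - lo + 1

  cs1 <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  cs3 <- c(0, cumsum(x^3))
  s1 <- cs1[hi + 1] - cs1[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  s3 <- cs3[hi + 1] - cs3[lo]
  mu <- s1 / m
  varp <- pmax(s2 / m - mu^2, 0)
  sdev <- sqrt(varp)
  rms <- sqrt(s2 / m)
  m3 <- s3 / m - 3 * mu * s2 / m + 2 * mu^3
  skew <- ifelse(sdev > 0, m3 / sdev^3, 0)

  os <- roll_order_stats(x, centers, lo, hi)
  out <- tibble::tibble(
    mean = mu, sd = sdev, rms = rms,
    min = os$min, max = os$max, median = os$median, mad = os$mad,
    skew = skew
  )
  attr(out, "kept") <- centers
  out
}

#' Names of the 33 per-sensor features, in canonical column order
#'
#' @return Character vector of length 33.
#' @export
feature_names <- function() {
  per_axis <- function(stem) paste0(stem, "_", c("x", "y", "z"))
  c(per_axis("acc"), per_axis("tilt"), "avc", "sma",
    per_axis("mean"), per_axis("sd"), per_axis("rms"),
    per_axis("min"), per_axis("max"), per_axis("median"),
    per_axis("mad"), per_axis("skew"), "counts_ps")
}

#' Named feature groups used in ablation experiments
#'
#' The groups mirror the rows of the feature-importance tables: each entry
#' maps a display name to the feature columns (per-sensor suffixes) it
#' contains. `"ACC only"` (the raw accelerations) is the ablation baseline
#' and is not part of this list.
#'
#' @return Named list of character vectors of feature suffixes.
#' @export
feature_groups <- function() {
  per_axis <- function(stem) paste0(stem, "_", c("x", "y", "z"))
  list(
    "Tilt Angles" = per_axis("tilt"),
    "AVC" = "avc",
    "SMA" = "sma",
    "Mean + SD" = c(per_axis("mean"), per_axis("sd")),
    "RMS" = per_axis("rms"),
    "MAX + MIN" = c(per_axis("max"), per_axis("min")),
    "Median + MAD" = c(per_axis("median"), per_axis("mad")),
    "Skewness" = per_axis("skew"),
    "Counts/s" = "counts_ps"
  )
}

#' Extract the 33-feature matrix from a recording
#'
#' Computes the full per-sample feature set for every `(subject, placement)`
#' stream in the recording: raw accelerations and tilt angles per sample,
#' AVC and SMA with window `M_inst` (default 1 sample), the eight windowed
#' per-axis statistics with a centered window of `M_stats` samples (default
#' 100 = 1 s at 100 Hz), and ActiGraph-style activity counts per second
#' computed from the acceleration magnitude and held constant within each
#' 1 s epoch.
#'
#' @param recording Tibble as produced by [simulate_recording()] or
#'   [read_recording()].
#' @param M_stats Window length (samples) for the windowed statistics.
#' @param M_inst Window length for AVC and SMA.
#' @param centering Window placement for the windowed statistics.
#' @param edge_policy `"shrink"` (default; windows truncated at the stream
#'   boundaries so every sample keeps a row) or `"drop"`.
#' @param stride Evaluate features every `stride`-th sample (1 = all
#'   samples). Striding thins the heavily overlapping windows without
#'   changing any feature value at the retained samples.
#' @param counts_cfg A [counts_config()] for the counts/s column.
#' @return Tibble with the metadata columns `subject_id`, `placement`,
#'   `time_s`, `label` followed by the 33 feature columns of
#'   [feature_names()].
#' @export
extract_features <- function(recording, M_stats = 100, M_inst = 1,
                             centering = "centered",
                             edge_policy = c("shrink", "drop"), stride = 1L,
                             counts_cfg = counts_config()) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(all(c("time_s", "ax", "ay", "az", "label", "placement",
                  "subject_id") %in% names(recording)))
  fs_of <- function(t) {
    dt <- diff(t)
    1 / median(dt)
  }
  recording |>
    dplyr::group_by(.data$subject_id, .data$placement) |>
    dplyr::group_modify(function(df, key) {
      fs <- fs_of(df$time_s)
      n <- nrow(df)
      if (edge_policy == "drop" && n < M_stats) {
        abort("Recording shorter than the statistics window under edge_policy = 'drop'.")
      }
      centers <- seq(1L, n, by = as.integer(stride))
      r <- vector_magnitude(df$ax, df$ay, df$az)
      av <- avc(r, fs, M = M_inst, centering = centering)
      sm <- sma(df$ax, df$ay, df$az, M = M_inst, centering = centering)
      axes <- list(x = df$ax, y = df$ay, z = df$az)
      stats_by_axis <- purrr::map(axes, axis_stats, M = M_stats,
                                  centering = centering,
                                  edge_policy = edge_policy,
                                  centers = centers)
      kept <- attr(stats_by_axis[[1]], "kept")
      cps <- counts_per_sec(r, fs, counts_cfg)
      epoch_len <- counts_cfg$epoch_s * fs
      epoch_idx <- pmin(floor((kept - 1) / epoch_len) + 1, nrow(cps))
      tilt <- tilt_angles(df$ax[kept], df$ay[kept], df$az[kept])
      out <- tibble::tibble(
        time_s = df$time_s[kept], label = df$label[kept],
        acc_x = df$ax[kept], acc_y = df$ay[kept], acc_z = df$az[kept],
        tilt_x = tilt$tilt_x, tilt_y = tilt$tilt_y, tilt_z = tilt$tilt_z,
        avc = av[kept], sma = sm[kept]
      )
      for (ax_name in c("x", "y", "z")) {
        st <- stats_by_axis[[ax_name]]
        for (stat in c("mean", "sd", "rms", "min", "max", "median", "mad",
                       "skew")) {
          out[[paste0(stat, "_", ax_name)]] <- st[[stat]]
        }
      }
      out$counts_ps <- cps$counts_per_sec[epoch_idx]
      out[, c("time_s", "label", feature_names())]
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("subject_id", "placement", "time_s", "label")
}

#' Concatenate feature matrices across sensors
#'
#' Joins the per-sensor feature rows of a multi-placement feature tibble
#' into one wide matrix whose columns are prefixed with the placement name
#' (`ear_left.acc_x`, ...), 33 columns per sensor. Label streams must agree
#' across sensors at every `(subject, time)`.
#'
#' @param features Feature tibble from [extract_features()] containing one
#'   or more placements.
#' @param placements Placements to include, in prefix order (default: all,
#'   in first-appearance order).
#' @return Wide tibble with columns `subject_id`, `time_s`, `label` and
#'   `33 * length(placements)` feature columns.
#' @export
concat_sensors <- function(features, placements = NULL) {
  placements <- placements %||% unique(features$placement)
  missing_p <- setdiff(placements, unique(features$placement))
  if (length(missing_p) > 0) {
    abort(sprintf("Placement(s) not present in `features`: %s.",
                  paste(missing_p, collapse = ", ")))
  }
  parts <- purrr::map(placements, function(p) {
    df <- dplyr::filter(features, .data$placement == p)
    df <- dplyr::select(df, -"placement")
    nm <- setdiff(names(df), c("subject_id", "time_s", "label"))
    dplyr::rename_with(df, ~ paste0(p, ".", .x), dplyr::all_of(nm))
  })
  ns <- vapply(parts, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    abort("Sensors have mismatched row counts; cannot concatenate.")
  }
  out <- parts[[1]]
  if (length(parts) > 1) {
    for (i in seq(2, length(parts))) {
      p <- parts[[i]]
      if (!identical(paste(out$subject_id, out$time_s),
                     paste(p$subject_id, p$time_s))) {
        abort("Sensors are not sample-aligned; cannot concatenate.")
      }
      if (!identical(as.character(out$label), as.character(p$label))) {
        abort("Label streams differ between sensors; cannot concatenate.")
      }
      out <- dplyr::bind_cols(out, dplyr::select(p, -"subject_id", -"time_s",
                                                 -"label"))
    }
  }
  out
}
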
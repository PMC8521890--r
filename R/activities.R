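#' The nine activity classes
#'
#' Fixed class order used throughout the package: all factors, confusion
#' matrices and summary tables follow this order. The classes cover five
#' resting postures (lying face-down, lying face-up, lying on the side,
#' sitting, standing), three movements (jogging, walking, falling) and a
#' catch-all transitioning class (`TRN`) for inter-activity movement.
#'
#' @return Character vector of the 9 class labels, in canonical order.
#' @export
#' @examples
#' activity_levels()
activity_levels <- function() {
  c("LFD", "LFU", "Falling", "Jogging", "LS",
    "Sitting", "Standing", "TRN", "Walking")
}

#' Coerce labels to the canonical activity factor
#'
#' @param x Character or factor vector of activity labels.
#' @return Factor with levels in the canonical order of [activity_levels()].
#' @export
activity_factor <- function(x) {
  lev <- activity_levels()
  bad <- setdiff(unique(as.character(x)), lev)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown activity label(s): %s. Valid classes are: %s.",
      paste(bad, collapse = ", "), paste(lev, collapse = ", ")
    ))
  }
  factor(as.character(x), levels = lev)
}

# Metadata columns that are never treated as features.
meta_cols <- function() c("subject_id", "placement", "time_s", "label")

# Feature columns of a feature tibble: all non-metadata columns.
feature_cols <- function(df) setdiff(names(df), meta_cols())

# round half away from zero, the convention of printed percentage tables
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
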
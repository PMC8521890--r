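# Reading and writing recordings, feature matrices and confusion
# matrices as delimited text.

#' Write a recording to CSV
#'
#' Long format, one row per sample per sensor: `time_s, ax, ay, az, label,
#' placement, subject_id`. Values round-trip exactly through
#' [read_recording()].
#'
#' @param recording Recording tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  readr::write_csv(recording, path)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Validates the header, the label values, and that each
#' `(subject, placement)` stream has strictly increasing, uniformly spaced
#' time stamps (constant sampling rate within 1e-6 relative).
#'
#' @param path CSV file written by [write_recording()] or following the
#'   same layout.
#' @return Recording tibble with `label` as the canonical activity factor.
#' @export
read_recording <- function(path) {
  req <- c("time_s", "ax", "ay", "az", "label", "placement", "subject_id")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_c <- setdiff(req, names(df))
  if (length(missing_c) > 0) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_c, collapse = ", ")))
  }
  df$label <- activity_factor(df$label)
  check <- df |>
    dplyr::group_by(.data$subject_id, .data$placement) |>
    dplyr::group_walk(function(g, key) {
      dt <- diff(g$time_s)
      if (any(dt <= 0)) {
        abort(sprintf("Non-increasing time in stream (%s, %s) at row %d.",
                      key$subject_id, key$placement, which(dt <= 0)[1] + 1))
      }
      rel <- abs(dt - median(dt)) / median(dt)
      if (any(rel > 1e-6)) {
        abort(sprintf("Non-uniform sampling in stream (%s, %s): first gap at row %d.",
                      key$subject_id, key$placement, which(rel > 1e-6)[1] + 1))
      }
    })
  dplyr::ungroup(check)
  tibble::as_tibble(df[, c(req, setdiff(names(df), req))])
}

#' Write / read a feature matrix as CSV
#'
#' @param features Feature tibble.
#' @param path File path.
#' @return `path` invisibly (write); feature tibble (read).
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(df)) df$label <- activity_factor(df$label)
  df
}

#' Write / read a confusion matrix as CSV
#'
#' The CSV has a `truth` column followed by one column per predicted
#' class; [read_confusion()] restores the `har_confusion` matrix.
#'
#' @param cm A [confusion()] matrix.
#' @param path File path.
#' @export
write_confusion <- function(cm, path) {
  df <- tibble::as_tibble(unclass(cm), rownames = "truth")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  names(dimnames(m)) <- c("truth", "predicted")
  as_har_confusion(m)
}

#' Plot a recording
#'
#' Axis traces over time, faceted by placement, with the activity label
#' shown as a colored band.
#'
#' @param recording Recording tibble.
#' @param max_points Thin the traces to at most this many rows per
#'   placement (plotting only).
#' @return A ggplot object.
#' @export
plot_recording <- function(recording, max_points = 20000) {
  df <- recording |>
    dplyr::group_by(.data$placement) |>
    dplyr::slice(seq(1, dplyr::n(),
                     by = max(1, floor(dplyr::n() / max_points)))) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(c("ax", "ay", "az"), names_to = "axis",
                        values_to = "accel")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$accel,
                                   color = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_rug(ggplot2::aes(color = NULL), sides = "b",
                      data = df[!duplicated(df[c("placement", "label")]), ],
                      alpha = 0) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$placement)) +
    ggplot2::labs(x = "Time (s)", y = expression(Acceleration ~ (m/s^2)),
                  color = "Axis")
}
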
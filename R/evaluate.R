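# Confusion matrices, per-class correct/not-correct percentages, the
# feature-ablation harness and the sensor-combination harness.

#' Build a confusion matrix
#'
#' @param truth,predicted Vectors of activity labels of equal length.
#' @param class_order Class order for rows and columns (default the
#'   canonical order of [activity_levels()]).
#' @return Integer matrix of class `har_confusion`: rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(truth, predicted, class_order = activity_levels()) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  t_f <- factor(as.character(truth), levels = class_order)
  p_f <- factor(as.character(predicted), levels = class_order)
  if (anyNA(t_f) || anyNA(p_f)) {
    abort(sprintf("Labels outside the class set; valid classes are: %s.",
                  paste(class_order, collapse = ", ")))
  }
  m <- table(truth = t_f, predicted = p_f)
  m <- matrix(as.integer(m), nrow = length(class_order),
              dimnames = list(truth = class_order, predicted = class_order))
  structure(m, class = c("har_confusion", "matrix"))
}

as_har_confusion <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  structure(matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m)),
            class = c("har_confusion", "matrix"))
}

#' @export
print.har_confusion <- function(x, ...) {
  cat("<har_confusion>", sum(x), "samples\n")
  print(unclass(x))
  invisible(x)
}

#' @method tidy har_confusion
#' @export
tidy.har_confusion <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), n = "n") |>
    dplyr::rename(truth = 1, predicted = 2)
}

#' Per-class recall (row-wise correct percentage)
#'
#' `100 * diagonal / row sum`, reported to 2 decimals (half away from
#' zero), the convention of printed confusion tables. Classes with an
#' empty row are `NA`, never 0.
#'
#' @param cm A [confusion()] matrix.
#' @param class Class name (row label).
#' @return Percentage, 2 decimals.
#' @export
class_recall <- function(cm, class) {
  rs <- sum(cm[class, ])
  if (rs == 0) return(NA_real_)
  round_half_away(100 * cm[class, class] / rs)
}

#' Per-class precision (column-wise correct percentage)
#'
#' `100 * diagonal / column sum`, 2 decimals; `NA` for an empty column.
#'
#' @inheritParams class_recall
#' @export
class_precision <- function(cm, class) {
  cs <- sum(cm[, class])
  if (cs == 0) return(NA_real_)
  round_half_away(100 * cm[class, class] / cs)
}

#' Overall accuracy of a confusion matrix
#'
#' `100 * trace / n`.
#'
#' @param cm A [confusion()] matrix.
#' @param digits Decimals to round to (half away from zero); `NULL` for
#'   unrounded.
#' @return Percentage.
#' @export
overall_accuracy <- function(cm, digits = 2) {
  n <- sum(cm)
  if (n == 0) abort("Empty confusion matrix.")
  acc <- 100 * sum(diag(cm)) / n
  if (is.null(digits)) acc else round_half_away(acc, digits)
}

#' Per-class summary of a confusion matrix
#'
#' Recall (row-wise C), miss rate (row-wise NC), precision (column-wise C)
#' and column-wise NC per class, plus the overall accuracy as an
#' attribute. `C + NC = 100` for every non-empty class.
#'
#' @param cm A [confusion()] matrix.
#' @return Tibble with columns `class`, `n_true`, `recall_pct`,
#'   `miss_pct`, `precision_pct`, `col_miss_pct`; attribute
#'   `overall_accuracy_pct`.
#' @export
class_summary <- function(cm) {
  classes <- rownames(cm)
  rec <- unname(vapply(classes, class_recall, numeric(1), cm = cm))
  prec <- unname(vapply(classes, class_precision, numeric(1), cm = cm))
  out <- tibble::tibble(
    class = classes,
    n_true = as.integer(rowSums(cm)),
    recall_pct = rec,
    miss_pct = round_half_away(100 - rec),
    precision_pct = prec,
    col_miss_pct = round_half_away(100 - prec)
  )
  attr(out, "overall_accuracy_pct") <- overall_accuracy(cm)
  out
}

# fit + evaluate one feature subset; returns the confusion matrix
fit_eval <- function(train, test, cols, n_trees, seed, max_depth = 30) {
  keep <- c(intersect(meta_cols(), names(train)), cols)
  model <- train_ensemble(train[, keep, drop = FALSE], n_trees = n_trees,
                          seed = seed, max_depth = max_depth)
  pred <- predict(model, test[, keep, drop = FALSE])
  confusion(test$label, pred)
}

# Map feature-group suffixes to the (possibly placement-prefixed) columns
# of a feature tibble.
match_suffix_cols <- function(features, suffixes) {
  nm <- feature_cols(features)
  nm[sub("^.*\\.", "", nm) %in% suffixes]
}

#' Feature-ablation experiment
#'
#' Quantifies what each feature group adds on top of the raw-acceleration
#' baseline ("ACC only"): for the baseline and for each group the same
#' seeded split is classified with bagged trees trained on baseline-plus-
#' group columns, and overall plus per-activity accuracy (per-class
#' recall) are reported together with the delta against the baseline row.
#'
#' @param features Feature tibble (single- or multi-sensor, see
#'   [concat_sensors()]).
#' @param groups Named list of feature-column suffixes (default
#'   [feature_groups()]).
#' @param n_trees,seed,split_unit,train_fraction Training and split
#'   settings; one split is shared by all rows of the table.
#' @return Tibble of class `har_ablation`, long format: `feature_set`,
#'   `activity` (`"OA"` = overall accuracy first), `accuracy_pct`,
#'   `delta_pct`.
#' @export
ablation_run <- function(features, groups = feature_groups(), n_trees = 100,
                         seed = 1L, split_unit = "subject",
                         train_fraction = 0.7) {
  if (anyDuplicated(names(groups))) abort("Duplicate group names.")
  base_cols <- match_suffix_cols(features, paste0("acc_", c("x", "y", "z")))
  if (length(base_cols) == 0) abort("No raw acceleration columns found.")
  all_suffix <- unique(unlist(feature_groups()))
  for (g in names(groups)) {
    unknown <- setdiff(groups[[g]], all_suffix)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown feature name(s) in group '%s': %s.", g,
                    paste(unknown, collapse = ", ")))
    }
  }
  sp <- split_dataset(features, train_fraction = train_fraction,
                      unit = split_unit, seed = seed)
  sets <- c(list("ACC only" = character(0)), groups)
  rows <- purrr::imap(sets, function(suffixes, set_name) {
    cols <- c(base_cols, match_suffix_cols(features, suffixes))
    cm <- fit_eval(sp$train, sp$test, cols, n_trees, seed)
    tibble::tibble(
      feature_set = set_name,
      activity = c("OA", rownames(cm)),
      accuracy_pct = c(overall_accuracy(cm),
                       vapply(rownames(cm), class_recall, numeric(1), cm = cm))
    )
  })
  out <- dplyr::bind_rows(rows)
  base <- dplyr::filter(out, .data$feature_set == "ACC only")
  out <- out |>
    dplyr::left_join(dplyr::select(base, "activity", base_pct = "accuracy_pct"),
                     by = "activity") |>
    dplyr::mutate(delta_pct = round_half_away(.data$accuracy_pct - .data$base_pct)) |>
    dplyr::select(-"base_pct")
  class(out) <- c("har_ablation", class(out))
  out
}

#' Sensor-combination experiment
#'
#' Trains and evaluates the same seeded split for several sensor subsets
#' (e.g. left ear; right ear; both ears; waist; all three) so their
#' accuracies are directly comparable. Feature counts are 33 per sensor.
#'
#' @param features Per-sensor feature tibble from [extract_features()]
#'   (long, with a `placement` column).
#' @param combos Named list of placement vectors.
#' @param n_trees,seed,split_unit,train_fraction As in [ablation_run()].
#' @return Tibble: `combo`, `n_sensors`, `n_features`, `accuracy_pct`.
#' @export
sensor_combination_run <- function(features,
                                   combos = list(
                                     L = "ear_left", R = "ear_right",
                                     `L & R` = c("ear_left", "ear_right"),
                                     W = "waist",
                                     `L, R & W` = c("ear_left", "ear_right", "waist")
                                   ),
                                   n_trees = 100, seed = 1L,
                                   split_unit = "subject",
                                   train_fraction = 0.7) {
  if (anyDuplicated(names(combos))) abort("Duplicate combo names.")
  have <- unique(features$placement)
  purrr::imap_dfr(combos, function(placements, combo_name) {
    missing_p <- setdiff(placements, have)
    if (length(missing_p) > 0) {
      abort(sprintf("Placement(s) missing for combo '%s': %s.", combo_name,
                    paste(missing_p, collapse = ", ")))
    }
    wide <- concat_sensors(features, placements)
    sp <- split_dataset(wide, train_fraction = train_fraction,
                        unit = split_unit, seed = seed)
    cm <- fit_eval(sp$train, sp$test, feature_cols(wide), n_trees, seed)
    tibble::tibble(
      combo = combo_name,
      n_sensors = length(placements),
      n_features = length(feature_cols(wide)),
      accuracy_pct = overall_accuracy(cm)
    )
  })
}

#' Bundled reference confusion matrices
#'
#' Integer confusion-matrix counts from a published study of ear- and
#' waist-level accelerometer activity tracking (two ear sensors; waist
#' sensor; ears plus waist), shipped as plain-text fixtures. They are used
#' to verify the summary arithmetic (per-class C/NC percentages and
#' overall accuracy) against an independently printed source.
#'
#' @param which `"ear"`, `"waist"` or `"ear_waist"`.
#' @return A `har_confusion` matrix.
#' @export
benchmark_confusion <- function(which = c("ear", "waist", "ear_waist")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("confusion_", which, ".csv"),
                      package = "earmotion")
  read_confusion(path)
}

#' Plot a confusion matrix as a heatmap
#'
#' @param object A [confusion()] matrix.
#' @param normalize Show row-normalized percentages instead of counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot har_confusion
#' @export
autoplot.har_confusion <- function(object, normalize = FALSE, ...) {
  df <- tidy(object)
  if (normalize) {
    df <- df |>
      dplyr::group_by(.data$truth) |>
      dplyr::mutate(n = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$n, 1)), size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 name = if (normalize) "%" else "n") +
    ggplot2::labs(x = "Predicted", y = "True")
}
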
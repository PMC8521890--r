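# Supervised activity classification.
#
# The primary classifier is bootstrap-aggregated (bagged) decision trees:
# each tree is fitted on a bootstrap resample of the training rows (same
# size, with replacement) and prediction is by majority vote with ties
# broken by the fixed class order. Trees are grown essentially to full
# depth by default. KNN, LDA and an AdaBoost-style boosting variant are
# available as alternates.

#' Split a feature matrix into training and test parts
#'
#' Random 70/30 partition (by default), either by subject -- every row of a
#' subject goes to the same side, which prevents leakage between the
#' heavily overlapping windows of one subject -- or by sample. Both parts
#' are guaranteed to contain every activity class present in the input
#' (best-effort: the split is re-drawn up to `max_tries` times, then moved
#' rows for unit = "sample"); an error is raised if a class cannot appear
#' on both sides. The train side receives `round(train_fraction * n)`
#' units (half away from zero).
#'
#' @param features Feature tibble with at least `label` and (for
#'   `unit = "subject"`) `subject_id` columns.
#' @param train_fraction Fraction of units assigned to training.
#' @param unit `"subject"` (default) or `"sample"`.
#' @param seed Integer seed; the same seed reproduces the partition.
#' @param stratified Ensure all classes appear in both parts.
#' @param max_tries Redraw attempts for stratification.
#' @return List with elements `train` and `test` (disjoint row subsets).
#' @export
split_dataset <- function(features, train_fraction = 0.7,
                          unit = c("subject", "sample"), seed = 1L,
                          stratified = TRUE, max_tries = 100L) {
  unit <- match.arg(unit)
  lab <- activity_factor(features$label)
  classes <- unique(as.character(lab))
  withr::with_seed(as.integer(seed), {
    if (unit == "subject") {
      subjects <- unique(features$subject_id)
      if (length(subjects) < 2) abort("Need >= 2 subjects for a subject-wise split.")
      n_train <- max(1, min(length(subjects) - 1,
                            round_half_away(train_fraction * length(subjects), 0)))
      for (try in seq_len(max_tries)) {
        tr_subj <- sample(subjects, n_train)
        tr <- features$subject_id %in% tr_subj
        ok <- all(classes %in% as.character(lab[tr])) &&
          all(classes %in% as.character(lab[!tr]))
        if (ok) break
      }
      if (!ok) {
        abort("Could not produce a subject-wise split with every class in both parts.")
      }
    } else {
      n <- nrow(features)
      if (any(table(lab) < 2)) {
        abort("Every class needs >= 2 samples for a sample-wise split.")
      }
      n_train <- round_half_away(train_fraction * n, 0)
      tr <- rep(FALSE, n)
      tr[sample.int(n, n_train)] <- TRUE
      if (stratified) {
        for (cl in classes) {
          rows <- which(as.character(lab) == cl)
          if (!any(tr[rows])) tr[rows[1]] <- TRUE
          if (all(tr[rows])) tr[rows[1]] <- FALSE
        }
      }
    }
  })
  list(train = features[tr, , drop = FALSE],
       test = features[!tr, , drop = FALSE])
}

prepare_xy <- function(features) {
  x <- features[, feature_cols(features), drop = FALSE]
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  y <- activity_factor(features$label)
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    message(sum(!complete), " row(s) with undefined features dropped.")
    x <- x[complete, , drop = FALSE]
    y <- y[complete]
  }
  list(x = as.data.frame(x), y = y)
}

#' Train an activity classifier
#'
#' Fits the configured ensemble on a feature tibble. The default -- and the
#' configuration all evaluation harnesses use -- is bagging over
#' full-depth CART trees. Boosting (multi-class AdaBoost with a shrinkage
#' `learn_rate`), single-tree, KNN and LDA alternates are available via
#' `method`/`base`.
#'
#' @param features Feature tibble: metadata columns plus numeric feature
#'   columns (see [extract_features()] / [concat_sensors()]).
#' @param n_trees Ensemble size.
#' @param method `"bagging"` (default) or `"boosting"`; ignored for
#'   `base != "tree"`.
#' @param base `"tree"` (default), `"knn"` or `"lda"`.
#' @param max_depth Maximum tree depth (default 30, rpart's limit --
#'   effectively unconstrained growth).
#' @param seed Integer seed: same data + seed give an identical model and
#'   identical predictions.
#' @param learn_rate Shrinkage for boosting only (a bagging "learning
#'   rate" is not meaningful and is ignored).
#' @param k Neighborhood size for `base = "knn"`.
#' @return An object of class `har_model`.
#' @export
train_ensemble <- function(features, n_trees = 100, method = c("bagging", "boosting"),
                           base = c("tree", "knn", "lda"), max_depth = 30,
                           seed = 1L, learn_rate = 0.1, k = 5) {
  method <- match.arg(method)
  base <- match.arg(base)
  if (n_trees < 1) abort("`n_trees` must be >= 1.")
  d <- prepare_xy(features)
  if (nlevels(droplevels(d$y)) < 2) abort("Training data contain a single class.")
  if (nrow(d$x) != length(d$y)) abort("Feature/label length mismatch.")
  classes <- activity_levels()
  fit <- NULL
  ctrl <- rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                               maxdepth = max_depth, xval = 0,
                               maxcompete = 0, maxsurrogate = 0)
  df <- d$x
  df$.label <- d$y
  if (base == "tree" && method == "bagging") {
    n <- nrow(df)
    fit <- withr::with_seed(as.integer(seed), {
      purrr::map(seq_len(n_trees), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        rpart::rpart(.label ~ ., data = df[idx, , drop = FALSE],
                     method = "class", control = ctrl)
      })
    })
  } else if (base == "tree" && method == "boosting") {
    # SAMME multi-class AdaBoost over depth-limited trees
    n <- nrow(df)
    K <- nlevels(d$y)
    w <- rep(1 / n, n)
    ctrl_b <- rpart::rpart.control(minsplit = 10, cp = 0, maxdepth = min(8, max_depth),
                                   xval = 0, maxcompete = 0, maxsurrogate = 0)
    fit <- withr::with_seed(as.integer(seed), {
      out <- list()
      for (i in seq_len(n_trees)) {
        tr <- rpart::rpart(.label ~ ., data = df, weights = w,
                           method = "class", control = ctrl_b)
        pred <- predict(tr, df, type = "class")
        err <- sum(w * (pred != d$y)) / sum(w)
        if (err >= 1 - 1 / K) break
        err <- max(err, 1e-10)
        alpha <- learn_rate * (log((1 - err) / err) + log(K - 1))
        w <- w * exp(alpha * (pred != d$y))
        w <- w / sum(w)
        out[[i]] <- list(tree = tr, alpha = alpha)
        if (err < 1e-10) break
      }
      out
    })
  } else if (base == "knn") {
    fit <- list(train_x = as.matrix(d$x), train_y = d$y, k = k)
  } else if (base == "lda") {
    fit <- MASS::lda(d$x, grouping = droplevels(d$y))
  }
  structure(
    list(fit = fit, method = method, base = base,
         feature_names = names(d$x), classes = classes,
         p = ncol(d$x), n_train = nrow(d$x),
         n_trees = if (base == "tree") n_trees else NA_integer_,
         seed = as.integer(seed)),
    class = "har_model"
  )
}

#' @export
print.har_model <- function(x, ...) {
  cat("<har_model>", x$method, "of", x$base,
      if (x$base == "tree") paste0("(", length(x$fit), " trees)") else "",
      "on", x$p, "features,", x$n_train, "training rows\n")
  invisible(x)
}

vote_matrix <- function(model, newdata) {
  classes <- model$classes
  votes <- matrix(0, nrow(newdata), length(classes),
                  dimnames = list(NULL, classes))
  if (model$method == "bagging") {
    for (tr in model$fit) {
      p <- as.character(predict(tr, newdata, type = "class"))
      votes[cbind(seq_len(nrow(newdata)), match(p, classes))] <-
        votes[cbind(seq_len(nrow(newdata)), match(p, classes))] + 1
    }
  } else {
    for (st in model$fit) {
      p <- as.character(predict(st$tree, newdata, type = "class"))
      votes[cbind(seq_len(nrow(newdata)), match(p, classes))] <-
        votes[cbind(seq_len(nrow(newdata)), match(p, classes))] + st$alpha
    }
  }
  votes
}

#' Predict activity labels
#'
#' @param object A [train_ensemble()] model.
#' @param newdata Feature tibble whose feature columns match the model's
#'   `feature_names` exactly.
#' @param ... Unused.
#' @return Factor of predicted labels over [activity_levels()], one per
#'   row. Majority-vote ties are broken by the fixed class order.
#' @export
predict.har_model <- function(object, newdata, ...) {
  nd_cols <- intersect(names(newdata), feature_cols(newdata))
  nd_cols <- nd_cols[vapply(newdata[nd_cols], is.numeric, logical(1))]
  if (!identical(sort(nd_cols), sort(object$feature_names))) {
    abort(sprintf(
      "Feature columns do not match the model (expected %d: %s...).",
      length(object$feature_names),
      paste(head(object$feature_names, 3), collapse = ", ")
    ))
  }
  if (nrow(newdata) == 0) abort("Empty prediction input.")
  x <- as.data.frame(newdata[, object$feature_names, drop = FALSE])
  if (object$base == "tree") {
    votes <- vote_matrix(object, x)
    win <- max.col(votes, ties.method = "first")
    factor(object$classes[win], levels = object$classes)
  } else if (object$base == "knn") {
    p <- class::knn(object$fit$train_x, as.matrix(x), object$fit$train_y,
                    k = object$fit$k)
    factor(as.character(p), levels = object$classes)
  } else {
    p <- predict(object$fit, x)$class
    factor(as.character(p), levels = object$classes)
  }
}

#' @method glance har_model
#' @export
glance.har_model <- function(x, ...) {
  tibble::tibble(
    method = x$method, base = x$base,
    n_trees = if (x$base == "tree") length(x$fit) else NA_integer_,
    p = x$p, n_train = x$n_train, seed = x$seed
  )
}

#' @method tidy har_model
#' @export
tidy.har_model <- function(x, ...) {
  if (x$base != "tree") {
    return(tibble::tibble(term = x$feature_names, importance = NA_real_))
  }
  imp <- numeric(0)
  members <- if (x$method == "bagging") x$fit else purrr::map(x$fit, "tree")
  for (tr in members) {
    vi <- tr$variable.importance
    if (!is.null(vi)) {
      imp <- c(imp, vi)
    }
  }
  agg <- tapply(imp, names(imp), sum)
  tibble::tibble(term = names(agg),
                 importance = as.numeric(agg) / length(members)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
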
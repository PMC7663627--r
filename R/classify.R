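#' Classifier specification
#'
#' Two model families are supported, mirroring the two analysis routes used
#' for TFR datasets:
#' \describe{
#'   \item{`logistic_regression`}{Features are standardized and reduced by
#'     PCA (both fitted on training data only), then a ridge-penalized
#'     multinomial logistic regression is fit. Hyperparameters:
#'     `n_components` (PCA dimensions) and `C` (inverse regularization
#'     strength; the ridge penalty is `1/C`).}
#'   \item{`random_forest`}{A random forest on the raw features, without
#'     dimensionality reduction. Hyperparameter: `n_estimators` (trees).}
#' }
#'
#' @param family `"logistic_regression"` or `"random_forest"`.
#' @param grid Named list of hyperparameter candidate vectors; defaults to
#'   `n_components` in \{5, 10, 20, 40\} and `C` in \{0.01, 0.1, 1, 10, 100\}
#'   for logistic regression, `n_estimators` in \{100, 300, 1000\} for random
#'   forests.
#' @return An object of class `tfr_model_spec`.
#' @export
model_spec <- function(family = c("logistic_regression", "random_forest"),
                       grid = NULL) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      logistic_regression = list(n_components = c(5, 10, 20, 40),
                                 C = c(0.01, 0.1, 1, 10, 100)),
      random_forest = list(n_estimators = c(100, 300, 1000)))
  }
  if (length(grid) == 0L || any(lengths(grid) == 0L))
    stop("hyperparameter grid must be non-empty")
  preprocessing <- switch(family,
    logistic_regression = c("standardize", "pca"),
    random_forest = character(0))
  structure(list(family = family, preprocessing = preprocessing,
                 grid = grid),
            class = "tfr_model_spec")
}

# Grid rows in declared order: first listed hyperparameter varies fastest.
grid_rows <- function(grid) {
  g <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# Small deterministic seed derivation; stays well below 2^31.
derive_seed <- function(seed, ...) {
  v <- c(seed %% 1000000L, ...)
  as.integer((sum(v * (1009L^(seq_along(v) - 1L) %% 104729L))) %% 2147483647L)
}

# Stratified fold assignment drawn from the current RNG state.
make_stratified_folds <- function(labels, k) {
  counts <- table(labels)
  if (any(counts < k))
    stop("stratification error: class '",
         names(counts)[which(counts < k)[1L]], "' has ",
         min(counts), " members but ", k, " folds were requested")
  folds <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Fit standardization + PCA on training rows only; returns a transformer.
fit_reduction <- function(x_train, n_components) {
  center <- colMeans(x_train)
  scl <- apply(x_train, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x_train, center = center, scale = scl)
  rank_max <- min(nrow(xs) - 1L, ncol(xs), n_components)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE, rank. = rank_max)
  list(center = center, scale = scl, loadings = pc$rotation,
       transform = function(x, k = rank_max) {
         xs <- scale(x, center = center, scale = scl)
         (xs %*% pc$rotation)[, seq_len(min(k, ncol(pc$rotation))),
                              drop = FALSE]
       })
}

fit_logistic <- function(scores, y, C) {
  n <- nrow(scores)
  lambda <- 1 / (n * C)
  # glmnet warns about classes with < 8 members on small folds; harmless for
  # a ridge fit and expected at nested-CV fold sizes
  fit <- withCallingHandlers(
    glmnet::glmnet(scores, y, family = "multinomial", alpha = 0,
                   lambda = lambda, standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(fit = fit, lambda = lambda)
}

predict_logistic <- function(m, scores) {
  as.character(stats::predict(m$fit, scores, s = m$lambda, type = "class"))
}

fit_rf <- function(x, y, n_estimators, seed) {
  ranger::ranger(x = x, y = factor(y), num.trees = n_estimators,
                 seed = seed, num.threads = 1L)
}

# Fit one pipeline (preprocessing + model) on training data.
# Returns list(predict = function(x_new) labels, stats = preprocessing stats).
fit_pipeline <- function(family, x_train, y_train, hp, seed) {
  if (family == "logistic_regression") {
    red <- fit_reduction(x_train, hp$n_components)
    m <- fit_logistic(red$transform(x_train, hp$n_components), y_train, hp$C)
    list(predict = function(x) predict_logistic(m, red$transform(x, hp$n_components)),
         stats = list(center = red$center, scale = red$scale,
                      loadings = red$loadings))
  } else {
    fit <- fit_rf(x_train, y_train, hp$n_estimators, seed)
    list(predict = function(x)
           as.character(stats::predict(fit, data = x,
                                       num.threads = 1L)$predictions),
         stats = NULL)
  }
}

# Inner grid search on one outer-training portion. Candidates are scored by
# mean inner-validation accuracy; ties resolve to the earliest grid row.
inner_grid_search <- function(family, x, y, grid, k_inner, seed, fold) {
  cands <- grid_rows(grid)
  set.seed(derive_seed(seed, fold, 7L))
  inner <- make_stratified_folds(y, k_inner)
  acc <- matrix(NA_real_, length(cands), k_inner)
  for (i in seq_len(k_inner)) {
    tr <- inner != i
    if (family == "logistic_regression") {
      # standardize+PCA depend only on the split: fit once at max rank,
      # then truncate per candidate
      red <- fit_reduction(x[tr, , drop = FALSE],
                           max(unlist(grid$n_components)))
      for (ci in seq_along(cands)) {
        hp <- cands[[ci]]
        m <- fit_logistic(red$transform(x[tr, , drop = FALSE],
                                        hp$n_components), y[tr], hp$C)
        pred <- predict_logistic(m, red$transform(x[!tr, , drop = FALSE],
                                                  hp$n_components))
        acc[ci, i] <- mean(pred == y[!tr])
      }
    } else {
      for (ci in seq_along(cands)) {
        hp <- cands[[ci]]
        fit <- fit_rf(x[tr, , drop = FALSE], y[tr], hp$n_estimators,
                      derive_seed(seed, fold, ci, i))
        pred <- as.character(stats::predict(fit, data = x[!tr, , drop = FALSE],
                                            num.threads = 1L)$predictions)
        acc[ci, i] <- mean(pred == y[!tr])
      }
    }
  }
  mean_acc <- rowMeans(acc)
  cands[[which.max(mean_acc)]]  # which.max takes the first maximum
}

#' Nested cross-validated evaluation
#'
#' Evaluates a classifier family by k-outer by k-inner nested
#' cross-validation (default 5 x 5): data are split into stratified outer
#' folds; within each outer-training portion an inner grid search selects the
#' hyperparameters by mean inner-validation accuracy (ties resolve to the
#' first candidate in grid order); the selected model is refit on the full
#' outer-training portion and scored on the held-out fold. All fitted
#' preprocessing (standardization statistics, PCA loadings) is estimated on
#' training portions only, so no information leaks from test folds. Identical
#' seed, dataset and spec give a bit-identical report.
#'
#' @param ds A [feature_dataset()].
#' @param spec A [model_spec()].
#' @param k_outer,k_inner Fold counts (default 5 each).
#' @param seed Integer seed governing fold assignment and forest randomness.
#' @param outer_folds Optional precomputed outer fold assignment (integer
#'   vector in `1..k_outer`), used to share splits across band/model cells.
#' @return An object of class `tfr_cv_report`: list with
#'   `outer_fold_accuracies`, `mean_accuracy`, `std_accuracy`,
#'   `selected_hyperparameters` (one named list per fold), `outer_folds`,
#'   `preprocessing_stats` (per fold; `NULL` entries for random forests),
#'   `family`, `seed`.
#' @export
nested_cv <- function(ds, spec, k_outer = 5L, k_inner = 5L, seed = 1L,
                      outer_folds = NULL) {
  stopifnot(inherits(ds, "tfr_dataset"), inherits(spec, "tfr_model_spec"))
  x <- ds$matrix
  y <- ds$labels
  if (length(unique(y)) < 2L)
    stop("nested_cv needs at least 2 classes")
  if (is.null(outer_folds)) {
    set.seed(as.integer(seed))
    outer_folds <- make_stratified_folds(y, k_outer)
  }
  accs <- numeric(k_outer)
  selected <- vector("list", k_outer)
  prep <- vector("list", k_outer)
  for (fold in seq_len(k_outer)) {
    tr <- outer_folds != fold
    hp <- inner_grid_search(spec$family, x[tr, , drop = FALSE], y[tr],
                            spec$grid, k_inner, seed, fold)
    fit <- fit_pipeline(spec$family, x[tr, , drop = FALSE], y[tr], hp,
                        derive_seed(seed, fold))
    pred <- fit$predict(x[!tr, , drop = FALSE])
    accs[fold] <- mean(pred == y[!tr])
    selected[[fold]] <- hp
    prep[[fold]] <- fit$stats
  }
  structure(
    list(outer_fold_accuracies = accs,
         mean_accuracy = mean(accs),
         std_accuracy = stats::sd(accs),
         selected_hyperparameters = selected,
         outer_folds = outer_folds,
         preprocessing_stats = prep,
         family = spec$family,
         seed = as.integer(seed)),
    class = "tfr_cv_report")
}

#' @rdname nested_cv
#' @param x A `tfr_cv_report`.
#' @param ... Ignored.
#' @export
print.tfr_cv_report <- function(x, ...) {
  cat(sprintf("<tfr_cv_report> %s: accuracy %.3f +/- %.3f (folds: %s)\n",
              x$family, x$mean_accuracy, x$std_accuracy,
              paste(sprintf("%.2f", x$outer_fold_accuracies),
                    collapse = ", ")))
  invisible(x)
}

#' Fit a deployable classifier
#'
#' Fits the full pipeline (preprocessing + model) with fixed hyperparameters
#' on the whole dataset. The returned predictor remembers the feature
#' descriptors and refuses inputs whose columns do not match; it can be
#' serialized with `saveRDS()` and reloaded with identical predictions.
#'
#' @param ds A [feature_dataset()].
#' @param spec A [model_spec()].
#' @param hyperparameters Named list, e.g. `list(n_components = 20, C = 1)`.
#' @param seed Integer seed (random forests only).
#' @return An object of class `tfr_predictor`.
#' @export
fit_final_model <- function(ds, spec, hyperparameters, seed = 1L) {
  stopifnot(inherits(ds, "tfr_dataset"), inherits(spec, "tfr_model_spec"))
  for (nm in names(spec$grid)) {
    if (!nm %in% names(hyperparameters))
      stop("missing hyperparameter: ", nm)
    if (!hyperparameters[[nm]] %in% spec$grid[[nm]])
      stop("hyperparameter ", nm, " = ", hyperparameters[[nm]],
           " is outside the grid domain")
  }
  fit <- fit_pipeline(spec$family, ds$matrix, ds$labels, hyperparameters,
                      as.integer(seed))
  structure(
    list(family = spec$family, hyperparameters = hyperparameters,
         pipeline = fit, descriptors = ds$descriptors,
         classes = sort(unique(ds$labels))),
    class = "tfr_predictor")
}

#' @rdname fit_final_model
#' @param object A `tfr_predictor`.
#' @param newdata A numeric matrix, [feature_dataset()], or single feature
#'   vector whose columns match the training descriptors.
#' @param ... Ignored.
#' @export
predict.tfr_predictor <- function(object, newdata, ...) {
  desc <- NULL
  if (inherits(newdata, "tfr_dataset")) {
    desc <- newdata$descriptors
    newdata <- newdata$matrix
  } else if (inherits(newdata, "tfr_feature_vector")) {
    desc <- newdata$descriptors
    newdata <- matrix(newdata$values, nrow = 1L)
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) == 1L && nrow(newdata) == nrow(object$descriptors))
      newdata <- t(newdata)
  }
  if (ncol(newdata) != nrow(object$descriptors))
    stop("contract error: predictor was trained on ",
         nrow(object$descriptors), " features but received ",
         ncol(newdata))
  if (!is.null(desc)) {
    same <- desc$pair == object$descriptors$pair &
      desc$kind == object$descriptors$kind &
      abs(desc$frequency - object$descriptors$frequency) < 1e-9
    if (!all(same))
      stop("contract error: feature descriptor mismatch at column ",
           which(!same)[1L], " (", desc$pair[which(!same)[1L]], " ",
           desc$kind[which(!same)[1L]], " @ ",
           desc$frequency[which(!same)[1L]], " Hz)")
  }
  object$pipeline$predict(newdata)
}

#' Accuracy per frequency band and model family
#'
#' Runs [nested_cv()] for every (band, spec) combination on the band-selected
#' dataset. Outer splits are computed once from the seed and shared across
#' all cells, so accuracies are comparable across bands and families.
#'
#' @param ds A [feature_dataset()].
#' @param bands Named list of [band()] objects.
#' @param specs List of [model_spec()] objects.
#' @param seed Integer seed.
#' @param k_outer,k_inner Fold counts.
#' @return Data frame with columns `band`, `family`, `mean_accuracy`,
#'   `std_accuracy`, `n_features`.
#' @export
band_accuracy_scan <- function(ds, bands, specs, seed = 1L, k_outer = 5L,
                               k_inner = 5L) {
  stopifnot(inherits(ds, "tfr_dataset"))
  if (inherits(bands, "tfr_band")) bands <- list(bands)
  if (inherits(specs, "tfr_model_spec")) specs <- list(specs)
  nm <- names(bands)
  if (is.null(nm)) nm <- rep("", length(bands))
  set.seed(as.integer(seed))
  outer_folds <- make_stratified_folds(ds$labels, k_outer)
  out <- list()
  for (i in seq_along(bands)) {
    sub <- select_band(ds, bands[[i]])
    for (s in specs) {
      rep_ <- nested_cv(sub, s, k_outer, k_inner, seed,
                        outer_folds = outer_folds)
      out[[length(out) + 1L]] <- data.frame(
        band = if (nzchar(nm[i])) nm[i]
               else sprintf("%g-%g Hz", bands[[i]]$f_lo, bands[[i]]$f_hi),
        family = s$family,
        mean_accuracy = rep_$mean_accuracy,
        std_accuracy = rep_$std_accuracy,
        n_features = ncol(sub$matrix),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
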
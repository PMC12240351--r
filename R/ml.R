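#' Standardize a descriptor table for machine learning
#'
#' Centers every numeric column to mean 0 and scales it to unit variance.
#' Zero-variance columns carry no information and are dropped with a warning.
#'
#' @param table a tibble with numeric feature columns (non-numeric columns,
#'   e.g. `compound`, pass through untouched).
#' @return a tibble of the same shape minus any dropped columns.
#' @export
ml_preprocess <- function(table) {
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  if (length(num) == 0 || nrow(table) == 0) {
    stop("no numeric feature columns to standardize", call. = FALSE)
  }
  sds <- vapply(table[num], stats::sd, 0)
  const <- num[sds == 0 | is.na(sds)]
  if (length(const) == length(num)) {
    stop("all feature columns have zero variance", call. = FALSE)
  }
  if (length(const)) {
    warning("dropping zero-variance column(s): ", paste(const, collapse = ", "),
            call. = FALSE)
    table <- dplyr::select(table, -dplyr::all_of(const))
    num <- setdiff(num, const)
  }
  dplyr::mutate(table, dplyr::across(dplyr::all_of(num),
                                     ~ as.numeric(scale(.x))))
}

#' Feature selection for the descriptor table
#'
#' Two standard reductions: recursive feature elimination (`"rfe"`) ranks
#' features by iteratively refitting a random forest and discarding the least
#' important feature, and `"pca"` projects onto the first `k` principal
#' components.  Both are deterministic given `seed`.
#'
#' @param data tibble holding feature columns and the target column.
#' @param target name of the target column.
#' @param method `"rfe"` or `"pca"`.
#' @param k number of features to keep / components to return.
#' @param seed integer seed.
#' @return for `"rfe"`, a tibble `feature`, `rank` (rank 1 = retained
#'   longest) restricted to the top `k`, with the full ranking in the
#'   `"ranking"` attribute; for `"pca"`, a list with `scores` (n x k tibble),
#'   `loadings` and `var_explained`.
#' @export
select_features <- function(data, target, method = c("rfe", "pca"), k,
                            seed = 1) {
  method <- match.arg(method)
  stopifnot(target %in% names(data))
  feats <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], target)
  if (length(feats) == 0) stop("no numeric features", call. = FALSE)
  if (k < 1 || k > length(feats)) {
    stop("k must be between 1 and the feature count (", length(feats), ")",
         call. = FALSE)
  }
  y <- data[[target]]
  if (method == "pca") {
    pc <- stats::prcomp(as.matrix(data[feats]), center = TRUE, scale. = TRUE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    return(list(
      scores = tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE]),
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      var_explained = ve[seq_len(k)]
    ))
  }
  remaining <- feats
  eliminated <- character(0)
  with_rng(seed, {
    while (length(remaining) > 1) {
      rf <- randomForest::randomForest(
        x = as.data.frame(data[remaining]), y = y, ntree = 200)
      imp <- randomForest::importance(rf)[, 1]
      worst <- names(which.min(imp))
      eliminated <- c(eliminated, worst)
      remaining <- setdiff(remaining, worst)
    }
  })
  ranking <- c(remaining, rev(eliminated))   # rank 1 = survived longest
  out <- tibble::tibble(feature = ranking[seq_len(k)], rank = seq_len(k))
  attr(out, "ranking") <- ranking
  out
}

fit_ml <- function(kind, xtr, ytr, seed) {
  switch(kind,
    rf = randomForest::randomForest(x = xtr, y = ytr, ntree = 500),
    svm = e1071::svm(x = xtr, y = ytr),
    gbm = xgboost::xgb.train(
      params = list(max_depth = 3, eta = 0.1, objective = "reg:squarederror",
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(as.matrix(xtr), label = ytr, nthread = 1),
      nrounds = 200
    ),
    stop("unknown model kind '", kind, "'", call. = FALSE)
  )
}

predict_ml <- function(kind, model, xte) {
  if (kind == "gbm") {
    stats::predict(model, xgboost::xgb.DMatrix(as.matrix(xte), nthread = 1))
  } else stats::predict(model, xte)
}

#' Cross-validated evaluation of an ML regressor
#'
#' Deterministic k-fold cross-validation of a random forest (`"rf"`),
#' epsilon-support-vector regression (`"svm"`) or gradient-boosted trees
#' (`"gbm"`) predicting a target from descriptor features.  Per-fold metrics
#' are MSE, RMSE (\eqn{\sqrt{MSE}}) and \eqn{R^2 = 1 - SSE/SST} on the held
#' -out fold; aggregate metrics are fold means.
#'
#' @param data tibble with numeric feature columns and the target.
#' @param target name of the target column.
#' @param kind `"rf"`, `"svm"` or `"gbm"`.
#' @param folds number of folds (`2 <= folds <= n`).
#' @param seed integer seed driving the fold assignment and the learners.
#' @param features optional character vector restricting the feature set.
#' @return an object of class `ml_eval`: list with `kind`, `folds`, `seed`,
#'   `features`, `metrics` (per-fold tibble) and `aggregate` (one-row
#'   tibble `mse`, `rmse`, `r2`).
#' @export
cv_evaluate <- function(data, target, kind = c("rf", "svm", "gbm"), folds = 5,
                        seed = 1, features = NULL) {
  kind <- match.arg(kind)
  stopifnot(target %in% names(data))
  feats <- features %||%
    setdiff(names(data)[vapply(data, is.numeric, TRUE)], target)
  stopifnot(all(feats %in% names(data)))
  n <- nrow(data)
  if (folds < 2 || folds > n) {
    stop("folds must be between 2 and n = ", n, call. = FALSE)
  }
  y <- data[[target]]
  X <- as.data.frame(data[feats])
  assign_fold <- with_rng(seed, sample(rep(seq_len(folds), length.out = n)))
  metrics <- purrr::map(seq_len(folds), function(f) {
    tr <- assign_fold != f
    model <- with_rng(seed + f, fit_ml(kind, X[tr, , drop = FALSE], y[tr], seed))
    pred <- predict_ml(kind, model, X[!tr, , drop = FALSE])
    obs <- y[!tr]
    mse <- mean((obs - pred)^2)
    tibble::tibble(fold = f, mse = mse, rmse = sqrt(mse),
                   r2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  }) |> dplyr::bind_rows()
  structure(list(
    kind = kind, folds = folds, seed = seed, features = feats,
    metrics = metrics,
    aggregate = dplyr::summarise(metrics, mse = mean(.data$mse),
                                 rmse = mean(.data$rmse), r2 = mean(.data$r2))
  ), class = "ml_eval")
}

#' @export
print.ml_eval <- function(x, ...) {
  cat("<ml_eval> ", x$kind, ", ", x$folds, "-fold CV, seed ", x$seed, "\n", sep = "")
  cat(sprintf("  aggregate: MSE = %.4g, RMSE = %.4g, R2 = %.4f\n",
              x$aggregate$mse, x$aggregate$rmse, x$aggregate$r2))
  invisible(x)
}
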
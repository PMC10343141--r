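# Two-step hierarchical cross-validation: the kernel is chosen by nested
# CV (inner folds pick the penalty per outer fold, outer folds score the
# kernel), then the penalty for the winning kernel is re-selected on the
# full data.

#' Cross-validation configuration
#'
#' @param n_outer Number of outer folds (default 10).
#' @param n_inner Number of inner folds (default 5).
#' @param lambda_grid Positive penalty grid; default 10 values log-spaced
#'   from `1e-6` to `1e3`.
#' @param scoring `"neg-rmse"` (regression) or `"balanced-accuracy"`
#'   (classification). Both are oriented so larger is better.
#' @param stratified Stratify folds by class (classification only).
#' @param seed Integer seed controlling all fold randomness.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_outer = 10L, n_inner = 5L,
                      lambda_grid = 10^seq(-6, 3, length.out = 10),
                      scoring = c("neg-rmse", "balanced-accuracy"),
                      stratified = FALSE, seed = 1L) {
  scoring <- match.arg(scoring)
  if (n_outer < 2 || n_inner < 2) {
    stop_ck("invalid_input", "need n_outer >= 2 and n_inner >= 2")
  }
  if (!length(lambda_grid) || any(lambda_grid <= 0)) {
    stop_ck("invalid_input", "lambda_grid must be positive and non-empty")
  }
  structure(list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 lambda_grid = sort(as.numeric(lambda_grid)),
                 scoring = scoring, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# Deterministic fold assignment. Returns an integer vector of fold ids.
make_folds <- function(n, k, seed, stratify = NULL) {
  if (k > n) stop_ck("invalid_input", "more folds (%d) than samples (%d)", k, n)
  with_seed(seed, {
    if (is.null(stratify)) {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    } else {
      fold <- integer(n)
      offset <- 0L
      for (cl in split(seq_len(n), stratify)) {
        cl <- cl[sample.int(length(cl))]
        fold[cl] <- ((offset + seq_along(cl) - 1L) %% k) + 1L
        offset <- offset + length(cl)
      }
    }
    fold
  })
}

#' Cross-validation score
#'
#' `"neg-rmse"` returns the negative root-mean-squared error;
#' `"balanced-accuracy"` the mean of per-class recalls. Both are oriented
#' so that larger values are better.
#'
#' @param y_true,y_pred Vectors of equal length; for balanced accuracy
#'   these are class labels.
#' @param scoring Metric name.
#' @return Scalar score.
#' @export
cv_score <- function(y_true, y_pred, scoring = c("neg-rmse", "balanced-accuracy")) {
  scoring <- match.arg(scoring)
  if (length(y_true) != length(y_pred)) {
    stop_ck("invalid_input", "y_true and y_pred differ in length")
  }
  if (scoring == "neg-rmse") {
    return(-sqrt(mean((y_true - y_pred)^2)))
  }
  classes <- sort(unique(y_true))
  if (length(classes) < 2) {
    stop_ck("undefined_metric",
            "balanced accuracy undefined: a class is absent from y_true")
  }
  recalls <- vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
  mean(recalls)
}

task_of <- function(scoring) {
  if (scoring == "neg-rmse") "regression" else "classification"
}

# Score predictions of a fitted dual system on held-out data.
score_predictions <- function(f, y_true, scoring, levels = NULL) {
  if (scoring == "neg-rmse") return(cv_score(y_true, f, scoring))
  pred <- ifelse(f >= 0, 1, -1)
  cv_score(y_true, pred, "balanced-accuracy")
}

# Inner CV of the penalty on a (training) Gram matrix. Uses a single
# eigendecomposition per inner training fold, so all penalties in the grid
# are scored at negligible extra cost; each (fold, lambda) pair still
# counts as one model fit in the audit counter. Ties are broken towards
# the larger penalty (stronger regularization).
inner_lambda_cv <- function(K, y, folds, lambda_grid, scoring) {
  H <- length(lambda_grid)
  scores <- matrix(NA_real_, nrow = max(folds), ncol = H)
  for (fo in seq_len(max(folds))) {
    tr <- which(folds != fo)
    va <- which(folds == fo)
    ntr <- length(tr)
    e <- eigen((K[tr, tr] + t(K[tr, tr])) / 2, symmetric = TRUE)
    Qty <- crossprod(e$vectors, y[tr] - if (scoring == "neg-rmse") mean(y[tr]) else 0)
    icpt <- if (scoring == "neg-rmse") mean(y[tr]) else 0
    Kva <- K[va, tr, drop = FALSE]
    for (hh in seq_len(H)) {
      fit_counter_add()
      alpha <- e$vectors %*% (Qty / (e$values + ntr * lambda_grid[hh]))
      fva <- drop(Kva %*% alpha) + icpt
      scores[fo, hh] <- score_predictions(fva, y[va], scoring)
    }
  }
  mean_scores <- colMeans(scores)
  best <- max(which(mean_scores == max(mean_scores)))  # tie -> larger lambda
  list(lambda = lambda_grid[best], scores = mean_scores)
}

#' Select a kernel by hierarchical cross-validation
#'
#' For every kernel in the grid, each outer fold is scored by a model
#' whose penalty was chosen by inner cross-validation on the remaining
#' folds; the kernel with the best mean outer score wins (ties broken by
#' grid order). The total number of inner model fits equals
#' `K * H * n_inner * n_outer` and is reported as `fit_count`.
#'
#' @param X Composition table.
#' @param y Response vector.
#' @param kernel_grid List of [kernel_spec()] objects (default:
#'   [default_kernel_grid()]).
#' @param config A [cv_config()].
#' @return A `selection_result` with elements `best_spec`, `best_lambda`,
#'   `best_model`, `cv_table` and `fit_count`.
#' @export
select_kernel <- function(X, y, kernel_grid = NULL, config = cv_config()) {
  X <- as_comp_matrix(X)
  n <- nrow(X)
  if (is.null(kernel_grid)) kernel_grid <- default_kernel_grid(X)
  if (!length(kernel_grid)) stop_ck("invalid_input", "empty kernel grid")
  scoring <- config$scoring
  yenc <- if (scoring == "balanced-accuracy") encode_labels(y)$y else as.numeric(y)
  strat <- if (config$stratified && scoring == "balanced-accuracy") yenc else NULL
  outer_folds <- make_folds(n, config$n_outer, config$seed, strat)
  # inner folds depend only on the seed and outer fold, not on the kernel,
  # so every kernel is scored on identical splits
  inner_fold_list <- lapply(seq_len(config$n_outer), function(fo) {
    tr <- which(outer_folds != fo)
    make_folds(length(tr), config$n_inner, config$seed + 1000L * fo,
               if (!is.null(strat)) strat[tr] else NULL)
  })
  fit_counter_reset()
  K_cnt <- length(kernel_grid)
  outer_scores <- matrix(NA_real_, nrow = K_cnt, ncol = config$n_outer)
  failures <- character(0)
  for (kk in seq_len(K_cnt)) {
    spec <- kernel_grid[[kk]]
    res <- tryCatch({
      K <- withCallingHandlers(
        gram_matrix(spec, X),
        warning = function(w) invokeRestart("muffleWarning")
      )
      for (fo in seq_len(config$n_outer)) {
        tr <- which(outer_folds != fo)
        va <- which(outer_folds == fo)
        sel <- inner_lambda_cv(K[tr, tr], yenc[tr], inner_fold_list[[fo]],
                               config$lambda_grid, scoring)
        ntr <- length(tr)
        icpt <- if (scoring == "neg-rmse") mean(yenc[tr]) else 0
        alpha <- krr_solve(K[tr, tr], yenc[tr] - icpt, ntr * sel$lambda)
        fva <- drop(K[va, tr, drop = FALSE] %*% alpha) + icpt
        outer_scores[kk, fo] <- score_predictions(fva, yenc[va], scoring)
      }
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(res)) {
      failures <- c(failures, sprintf("%s: %s", kernel_id(spec), res))
      outer_scores[kk, ] <- NA_real_
    }
  }
  mean_sc <- rowMeans(outer_scores)
  if (all(is.na(mean_sc))) {
    stop_ck("selection_failure", "all kernels failed:\n%s",
            paste(failures, collapse = "\n"))
  }
  best_k <- which.max(mean_sc)  # ties -> first in grid order
  fit_count <- fit_counter_value()
  refit <- refit_lambda(X, y, kernel_grid[[best_k]], config)
  structure(
    list(
      best_spec = kernel_grid[[best_k]],
      best_lambda = refit$lambda,
      best_model = refit$model,
      cv_table = data.frame(
        kernel = vapply(kernel_grid, kernel_id, character(1)),
        mean_score = mean_sc,
        sd_score = apply(outer_scores, 1, stats::sd),
        stringsAsFactors = FALSE
      ),
      fit_count = fit_count,
      failures = failures,
      config = config
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("hierarchical CV over", nrow(x$cv_table), "kernels,",
      x$fit_count, "inner model fits\n")
  cat("selected:", kernel_id(x$best_spec), "with lambda =", x$best_lambda, "\n")
  invisible(x)
}

#' Select the penalty for a fixed kernel and refit on all data
#'
#' Runs `n_inner`-fold cross-validation of the penalty grid on the full
#' data for the given kernel and returns the chosen penalty together with
#' the final model fit on all samples.
#'
#' @inheritParams select_kernel
#' @param spec The kernel to use.
#' @return List with elements `lambda` and `model`.
#' @export
refit_lambda <- function(X, y, spec, config = cv_config()) {
  X <- as_comp_matrix(X)
  scoring <- config$scoring
  task <- task_of(scoring)
  yenc <- if (task == "classification") encode_labels(y)$y else as.numeric(y)
  strat <- if (config$stratified && task == "classification") yenc else NULL
  folds <- make_folds(nrow(X), config$n_inner, config$seed + 99991L, strat)
  K <- withCallingHandlers(
    gram_matrix(spec, X),
    warning = function(w) invokeRestart("muffleWarning")
  )
  sel <- inner_lambda_cv(K, yenc, folds, config$lambda_grid, scoring)
  model <- krr_fit(X, if (task == "classification") yenc else y,
                   spec, sel$lambda, task = task)
  list(lambda = sel$lambda, model = model, scores = sel$scores)
}
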
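# Kernel ridge regression / classification in dual form, prediction, and
# the path derivative along the multiplicative perturbation that the CFI
# is built from.

# Counter used to audit the number of model fits performed by the
# cross-validation layer (see select_kernel()).
.fit_env <- new.env(parent = emptyenv())
.fit_env$count <- 0L

fit_counter_reset <- function() .fit_env$count <- 0L
fit_counter_add <- function(k = 1L) .fit_env$count <- .fit_env$count + as.integer(k)
fit_counter_value <- function() .fit_env$count

#' Fit kernel ridge regression on compositional covariates
#'
#' Solves the dual ridge system `(K + n * lambda * I) alpha = y_centered`
#' where `K` is the kernel Gram matrix of the training compositions. The
#' penalty multiplies `n` so that `lambda` grids transfer across sample
#' sizes. For regression the response is centered and the mean added back
#' as intercept; for classification labels are mapped to -1/+1, fit by
#' ridge regression, and thresholded at zero for class prediction.
#'
#' @param X Composition table of training samples.
#' @param y Numeric response (regression) or two-level response
#'   (classification).
#' @param spec A [kernel_spec()].
#' @param lambda Positive regularization parameter.
#' @param task `"regression"` or `"classification"`.
#' @return An object of class `"krr_model"`.
#' @export
krr_fit <- function(X, y, spec, lambda, task = c("regression", "classification")) {
  task <- match.arg(task)
  X <- as_comp_matrix(X)
  n <- nrow(X)
  if (n < 2) stop_ck("invalid_input", "need at least two training samples")
  if (length(y) != n) stop_ck("invalid_input", "length(y) != nrow(X)")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    stop_ck("invalid_input", "lambda must be a positive scalar")
  }
  levels <- NULL
  if (task == "classification") {
    enc <- encode_labels(y)
    y <- enc$y
    levels <- enc$levels
  } else {
    if (!is.numeric(y) || anyNA(y) || any(!is.finite(y))) {
      stop_ck("invalid_input", "regression response must be finite numeric")
    }
  }
  intercept <- if (task == "regression") mean(y) else 0
  yc <- y - intercept
  K <- gram_matrix(spec, X)
  alpha <- krr_solve(K, yc, n * lambda)
  structure(
    list(spec = spec, train_X = X, alpha = alpha, intercept = intercept,
         lambda = lambda, task = task, levels = levels),
    class = "krr_model"
  )
}

encode_labels <- function(y) {
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    return(list(y = as.numeric(y), levels = c(-1, 1)))
  }
  f <- factor(y)
  if (nlevels(f) != 2) {
    stop_ck("invalid_input", "classification requires exactly two classes")
  }
  list(y = ifelse(as.integer(f) == 2, 1, -1), levels = levels(f))
}

krr_solve <- function(K, yc, ridge) {
  A <- K + diag(ridge, nrow(K))
  alpha <- tryCatch(
    solve(A, yc),
    error = function(e) {
      stop_ck("numerical_error",
              "ridge system is numerically singular (%s); increase lambda",
              conditionMessage(e))
    }
  )
  unname(drop(alpha))
}

#' @export
print.krr_model <- function(x, ...) {
  cat(sprintf("kernel ridge %s: n = %d, p = %d, %s, lambda = %g\n",
              x$task, nrow(x$train_X), ncol(x$train_X),
              kernel_id(x$spec), x$lambda))
  invisible(x)
}

#' Predict from a fitted kernel ridge model
#'
#' Evaluates `f(x) = sum_i alpha_i k(X_i, x) + intercept` at new
#' compositions. Component labels must match the training table exactly;
#' no silent reordering is performed.
#'
#' @param object A `krr_model`.
#' @param newdata Composition table with the same components as training.
#' @param type `"response"` for the real-valued prediction, `"class"` for
#'   thresholded class labels (classification only).
#' @param ... Unused.
#' @return Numeric vector (or class labels).
#' @export
predict.krr_model <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  Xn <- as_comp_matrix(newdata)
  if (ncol(Xn) != ncol(object$train_X)) {
    stop_ck("schema_error", "new data has %d components, model expects %d",
            ncol(Xn), ncol(object$train_X))
  }
  trl <- colnames(object$train_X)
  nwl <- colnames(Xn)
  if (!is.null(trl) && !is.null(nwl) && !identical(trl, nwl) &&
      !all(grepl("^C[0-9]+$", nwl))) {
    stop_ck("schema_error",
            "component labels differ from training; align columns explicitly")
  }
  Kc <- gram_core(object$spec, object$train_X, Xn)  # n_train x n_new
  f <- drop(crossprod(Kc, object$alpha)) + object$intercept
  if (type == "class") {
    if (object$task != "classification") {
      stop_ck("invalid_input", "type = 'class' requires a classification model")
    }
    lv <- object$levels
    return(ifelse(f >= 0, lv[2], lv[1]))
  }
  unname(f)
}

# Vectorized predictor: matrix of compositions in, numeric vector out.
# Accepts a fitted model or a user function (assumed row-vectorized; if it
# returns the wrong length it is applied row by row).
as_predictor <- function(f) {
  if (inherits(f, "krr_model")) {
    return(function(X) predict(f, X))
  }
  if (!is.function(f)) stop_ck("invalid_input", "need a krr_model or a function")
  function(X) {
    X <- as_comp_matrix(X)
    out <- tryCatch(f(X), error = function(e) NULL)
    if (is.numeric(out) && length(out) == nrow(X)) return(as.numeric(out))
    apply(X, 1, f)
  }
}

#' Derivative of a prediction along the multiplicative perturbation
#'
#' Central finite difference of `c -> f(psi_j(x, c))` at `c = 1`:
#' `[f(psi_j(x, 1+h)) - f(psi_j(x, 1-h))] / (2h)`. For differentiable `f`
#' this estimates `x_j * (d_j f(x) - sum_l x_l d_l f(x))`, the per-sample
#' contribution to the compositional feature influence.
#'
#' @param f A `krr_model` or a function mapping a composition matrix to a
#'   numeric vector of predictions.
#' @param x A single composition.
#' @param j Component index or label.
#' @param h Step size in `(0, 1)`; default `1e-4`.
#' @return Scalar derivative estimate.
#' @export
path_derivative <- function(f, x, j, h = 1e-4) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0 || h >= 1) {
    stop_ck("invalid_input", "step h must lie in (0, 1)")
  }
  pred <- as_predictor(f)
  X <- as_comp_matrix(x)
  up <- psi_perturb(X, j, 1 + h)
  dn <- psi_perturb(X, j, 1 - h)
  drop(pred(up) - pred(dn)) / (2 * h)
}

#' Serialize / restore a fitted model as JSON
#'
#' Writes a versioned JSON container holding the kernel specification,
#' component labels, dual coefficients, intercept and penalty, sufficient
#' to reproduce predictions exactly.
#'
#' @param model A `krr_model`.
#' @param path Output file path.
#' @return `read_model()` returns the restored `krr_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "krr_model"))
  spec <- model$spec
  obj <- list(
    format = "compkernel-model",
    version = 1L,
    task = model$task,
    kernel = list(family = spec$family, g = spec$g, c = spec$c, t = spec$t,
                  scale = spec$scale, anchor = spec$anchor,
                  W = if (!is.null(spec$W)) unclass(spec$W)),
    component_labels = colnames(model$train_X),
    sample_ids = rownames(model$train_X),
    train_X = unclass(model$train_X),
    alpha = model$alpha,
    intercept = model$intercept,
    lambda = model$lambda,
    levels = model$levels
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "compkernel-model")) {
    stop_ck("schema_error", "'%s' is not a compkernel model file", path)
  }
  k <- obj$kernel
  spec <- kernel_spec(k$family, g = k$g, c = k$c, t = k$t,
                      scale = k$scale %||% 1, anchor = k$anchor)
  if (!is.null(k$W)) spec <- apply_weights(spec, as.matrix(k$W))
  X <- composition_table(as.matrix(obj$train_X),
                         component_labels = obj$component_labels,
                         sample_ids = obj$sample_ids)
  structure(
    list(spec = spec, train_X = unclass(X), alpha = as.numeric(obj$alpha),
         intercept = obj$intercept, lambda = obj$lambda, task = obj$task,
         levels = obj$levels),
    class = "krr_model"
  )
}
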
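# Compositional feature influence (CFI) and compositional perturbation
# dependence (CPD): simplex-aware analogues of relative influence and
# partial-dependence plots. Both are Monte-Carlo plug-ins that replace
# population expectations by empirical means over the supplied samples.

#' Compositional feature influence
#'
#' For each component `j`, the CFI is the expected derivative of the
#' prediction along the multiplicative perturbation at `c = 1`,
#' `I_j = E[ d/dc f(psi_j(X, c)) |_{c=1} ]`, estimated by averaging a
#' central finite difference over the rows of `X`. For a log-contrast
#' model `f(x) = sum_j beta_j log(x_j)` with coefficients summing to zero
#' the CFI equals `beta` exactly (up to `O(h^2)`). The CFI values of any
#' differentiable function sum to zero across components.
#'
#' @param f A fitted `krr_model` or a function mapping a composition
#'   matrix to a vector of predictions.
#' @param X Composition table at which to average.
#' @param h Finite-difference step (default `1e-4`).
#' @return An `influence_result` with fields `cfi` (named numeric vector),
#'   `component_labels`, `h` and `n_used`.
#' @export
cfi <- function(f, X, h = 1e-4) {
  pred <- as_predictor(f)
  X <- as_comp_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 1) stop_ck("invalid_input", "X must be non-empty")
  vals <- numeric(p)
  n_used <- integer(p)
  for (j in seq_len(p)) {
    # psi_j(x, 1 +/- h) is defined for every x in the simplex when h < 1
    up <- psi_perturb(X, j, 1 + h)
    dn <- psi_perturb(X, j, 1 - h)
    d <- (pred(up) - pred(dn)) / (2 * h)
    ok <- is.finite(d)
    if (!all(ok)) {
      warning(sprintf("component %d: dropped %d samples with non-finite derivative",
                      j, sum(!ok)), call. = FALSE)
    }
    vals[j] <- mean(d[ok])
    n_used[j] <- sum(ok)
  }
  names(vals) <- colnames(X)
  structure(
    list(cfi = vals, component_labels = colnames(X), h = h, n_used = n_used),
    class = "influence_result"
  )
}

#' @export
print.influence_result <- function(x, ...) {
  cat("compositional feature influence (h =", x$h, ")\n")
  print(round(x$cfi, 6))
  invisible(x)
}

#' Compositional perturbation dependence curve
#'
#' For a component `j` and grid values `z` in `[0, 1]`, the CPD is
#' `S_j(z) = E[f(phi_j(X, z))] - E[f(X)]`: the average prediction after
#' fixing component `j` to `z` (rescaling the rest proportionally), minus
#' the baseline average prediction. For a log-contrast model the curve is
#' `beta_j * log(z / (1 - z))` plus a constant, and identically zero when
#' `beta_j = 0`. Values of `z` outside the observed support of `X_j`
#' require the fitted model to extrapolate and should be read with
#' caution; the default grid therefore spans the 5%-95% quantile range of
#' the observed component.
#'
#' @inheritParams cfi
#' @param j Component index or label.
#' @param grid Numeric grid in `[0, 1]`; default 25 points across the
#'   5%-95% quantile range of `X[, j]`.
#' @return A `cpd_curve` with fields `component`, `grid`, `values`,
#'   `baseline` and `n_used`.
#' @export
cpd <- function(f, X, j, grid = NULL) {
  pred <- as_predictor(f)
  X <- as_comp_matrix(X)
  j <- resolve_component(j, X)
  if (is.null(grid)) {
    q <- stats::quantile(X[, j], c(0.05, 0.95), names = FALSE)
    if (q[2] <= q[1]) q <- c(max(0, q[1] - 1e-3), min(1, q[2] + 1e-3))
    grid <- seq(q[1], q[2], length.out = 25)
  }
  grid <- sort(unique(as.numeric(grid)))
  if (any(grid < 0 | grid > 1)) stop_ck("invalid_input", "grid must lie in [0, 1]")
  degenerate <- X[, j] >= 1 - SIMPLEX_TOL
  if (any(degenerate) && any(grid < 1)) {
    warning(sprintf("dropping %d samples with x_j = 1 (degenerate phi perturbation)",
                    sum(degenerate)), call. = FALSE)
  }
  Xu <- X[!degenerate, , drop = FALSE]
  if (!nrow(Xu)) stop_ck("degenerate_perturbation", "no usable samples for CPD")
  baseline <- mean(pred(Xu))
  values <- vapply(grid, function(z) {
    mean(pred(phi_perturb(Xu, j, z))) - baseline
  }, numeric(1))
  structure(
    list(component = colnames(X)[j] %||% j, grid = grid, values = values,
         baseline = baseline, n_used = nrow(Xu)),
    class = "cpd_curve"
  )
}

#' @export
print.cpd_curve <- function(x, ...) {
  cat("CPD curve for component", x$component, "on", length(x$grid), "grid points\n")
  print(utils::head(data.frame(z = x$grid, S = x$values), 10))
  invisible(x)
}

#' Write CFI values or a CPD curve as delimited text
#'
#' @param x An `influence_result` or `cpd_curve`.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_influence <- function(x, path, sep = "\t") {
  df <- if (inherits(x, "influence_result")) {
    data.frame(component = x$component_labels %||% seq_along(x$cfi),
               cfi = unname(x$cfi), n_used = x$n_used)
  } else if (inherits(x, "cpd_curve")) {
    data.frame(component = x$component, z = x$grid, value = x$values)
  } else {
    stop_ck("invalid_input", "expected an influence_result or cpd_curve")
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
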
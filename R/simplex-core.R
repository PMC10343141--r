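# Compositions, closure, the centered log-ratio transform and the two
# simplex-preserving coordinate perturbations that all model interpretation
# in this package rests on.

SIMPLEX_TOL <- 1e-9   # strict tolerance on row sums
RECLOSE_TOL <- 1e-6   # rows off by up to this much are re-closed with a warning

#' Close a non-negative vector onto the simplex
#'
#' Divides a non-negative vector by its sum so that it lies on the unit
#' simplex. Idempotent on vectors that already sum to one.
#'
#' @param v Numeric vector with at least two entries, all non-negative,
#'   at least one positive.
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' closure(c(1, 1, 2))
#' @export
closure <- function(v) {
  if (!is.numeric(v) || length(v) < 2) {
    stop_ck("invalid_input", "closure() needs a numeric vector of length >= 2")
  }
  if (anyNA(v) || any(v < 0)) {
    stop_ck("invalid_input", "closure() requires non-negative, non-missing entries")
  }
  s <- sum(v)
  if (s <= 0) stop_ck("invalid_input", "closure() of an all-zero vector is undefined")
  v / s
}

#' Construct a composition table
#'
#' A composition table is the covariate object used throughout the package:
#' an `n x p` matrix whose rows are compositions (non-negative, summing to
#' one). Rows whose sums deviate by at most `1e-6` are re-closed with a
#' warning; larger deviations are rejected.
#'
#' @param x Numeric matrix (or data.frame) of non-negative values; rows are
#'   samples, columns are components.
#' @param component_labels Optional character vector of unique column labels.
#' @param sample_ids Optional character vector of row identifiers.
#' @return A numeric matrix of class `"composition_table"` with unit row sums.
#' @export
composition_table <- function(x, component_labels = NULL, sample_ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) < 2) stop_ck("invalid_input", "compositions need p >= 2 components")
  if (anyNA(x) || any(x < 0)) {
    stop_ck("invalid_input", "composition table entries must be non-negative and non-missing")
  }
  rs <- rowSums(x)
  if (any(rs <= 0)) stop_ck("invalid_input", "all-zero rows cannot be closed")
  off <- abs(rs - 1)
  if (any(off > RECLOSE_TOL)) {
    stop_ck("invalid_input",
            "row sums deviate from 1 by more than %g (max deviation %g); close counts first",
            RECLOSE_TOL, max(off))
  }
  if (any(off > SIMPLEX_TOL)) {
    warning("re-closing rows whose sums deviate from 1 by up to ",
            format(max(off)), call. = FALSE)
  }
  x <- x / rs
  if (!is.null(component_labels)) colnames(x) <- component_labels
  if (is.null(colnames(x))) colnames(x) <- paste0("C", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) {
    stop_ck("invalid_input", "component labels must be unique")
  }
  if (!is.null(sample_ids)) rownames(x) <- sample_ids
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  class(x) <- c("composition_table", "matrix", "array")
  x
}

# Coerce a single composition (vector) or table to a validated matrix.
as_comp_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (inherits(x, "composition_table")) return(unclass(x))
  unclass(composition_table(x))
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("composition table: %d samples x %d components\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Multiplicative simplex perturbation
#'
#' Multiplies component `j` by `c` and re-closes the vector onto the
#' simplex: the j-th coordinate becomes `c*x_j / (1 + (c-1)*x_j)` and every
#' other coordinate is divided by the same denominator. `c = 1` is the
#' identity. This is the perturbation underlying the compositional feature
#' influence ([cfi()]).
#'
#' @param x Composition (numeric vector on the simplex) or composition table
#'   (perturbed row-wise).
#' @param j Component index (or label for tables).
#' @param c Non-negative multiplier.
#' @return Perturbed composition(s) of the same shape as `x`.
#' @export
psi_perturb <- function(x, j, c) {
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c < 0) {
    stop_ck("invalid_input", "psi_perturb() needs a single multiplier c >= 0")
  }
  X <- as_comp_matrix(x)
  j <- resolve_component(j, X)
  xj <- X[, j]
  denom <- 1 + (c - 1) * xj
  if (any(denom <= SIMPLEX_TOL)) {
    stop_ck("degenerate_perturbation",
            "psi_perturb() undefined: c = %g removes all mass (x_j = 1)", c)
  }
  out <- X / denom
  out[, j] <- c * xj / denom
  if (is.null(dim(x))) unname(drop(out)) else restore_table(out, x)
}

#' Fix-and-rescale simplex perturbation
#'
#' Fixes component `j` to the value `z` and rescales the remaining
#' coordinates proportionally so the result stays on the simplex:
#' the other coordinates become `x_l * (1-z) / (1-x_j)`. `z = x_j` is the
#' identity. This is the perturbation underlying the compositional
#' perturbation dependence ([cpd()]).
#'
#' @inheritParams psi_perturb
#' @param z Target value in `[0, 1]` for component `j`.
#' @export
phi_perturb <- function(x, j, z) {
  if (!is.numeric(z) || length(z) != 1 || is.na(z) || z < 0 || z > 1) {
    stop_ck("invalid_input", "phi_perturb() needs z in [0, 1]")
  }
  X <- as_comp_matrix(x)
  j <- resolve_component(j, X)
  xj <- X[, j]
  rest <- 1 - xj
  if (z < 1 && any(rest <= SIMPLEX_TOL)) {
    stop_ck("degenerate_perturbation",
            "phi_perturb() undefined: x_j = 1 leaves no mass to rescale for z < 1")
  }
  scale <- ifelse(rest > SIMPLEX_TOL, (1 - z) / rest, 0)
  out <- X * scale
  out[, j] <- z
  if (is.null(dim(x))) unname(drop(out)) else restore_table(out, x)
}

#' Centered log-ratio transform with zero shift
#'
#' Applies a pseudo-count shift `c` to every component, re-closes, and
#' returns the centered log-ratio: `log(xs) - mean(log(xs))` where
#' `xs = (x + c) / sum(x + c)`. The shift makes the transform well defined
#' in the presence of zeros and is treated throughout as a tunable kernel
#' hyperparameter rather than a fixed preprocessing constant.
#'
#' @param x Composition vector or composition table (transformed row-wise).
#' @param c Non-negative shift; `c = 0` requires strictly positive entries.
#' @return Vector (or matrix) of clr coordinates; each row sums to zero.
#' @export
clr_shift <- function(x, c = 0) {
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c < 0) {
    stop_ck("invalid_input", "clr_shift() needs a single shift c >= 0")
  }
  X <- as_comp_matrix(x)
  if (c == 0 && any(X == 0)) {
    stop_ck("zero_handling",
            "clr_shift() with c = 0 on data containing zeros; supply a positive shift")
  }
  Xs <- (X + c) / (1 + ncol(X) * c)  # rows of X sum to 1
  L <- log(Xs)
  out <- L - rowMeans(L)
  if (is.null(dim(x))) unname(drop(out)) else out
}

# Map a component reference (position or label) to a column index.
resolve_component <- function(j, X) {
  if (is.character(j)) {
    idx <- match(j, colnames(X))
    if (is.na(idx)) stop_ck("schema_error", "unknown component label '%s'", j)
    return(idx)
  }
  j <- as.integer(j)
  if (length(j) != 1 || is.na(j) || j < 1 || j > ncol(X)) {
    stop_ck("invalid_input", "component index out of range")
  }
  j
}

restore_table <- function(out, template) {
  dimnames(out) <- dimnames(template)
  class(out) <- class(template)
  out
}
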
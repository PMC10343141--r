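# Kernels on the simplex, Gram-matrix computation, induced distances,
# and the data-adaptive default kernel grid.
#
# Four groups of kernels are provided:
#   * Euclidean restrictions:  linear, rbf
#   * Aitchison geometry:      aitchison, aitchison-rbf (clr with zero shift)
#   * Probability distances:   prob-js, prob-hellinger, prob-tv, prob-chisq,
#     realized through the anchored construction
#       k(x, y) = 1/2 * [ d(x, u0) + d(y, u0) - d(x, y) ],
#     where d is the family's conditionally negative definite squared
#     distance and u0 an anchor point (barycenter by default). This yields
#     a componentwise-sum structure compatible with prior-knowledge
#     weighting.
#   * Riemannian manifold:     heat-diffusion, the Gaussian of the
#     spherical geodesic d_g(x, y) = 2*acos(sum_j sqrt(x_j y_j)); only
#     approximately PSD, so square Gram matrices are spectrally repaired.

KERNEL_FAMILIES <- c("linear", "rbf", "aitchison", "aitchison-rbf",
                     "prob-js", "prob-hellinger", "prob-tv", "prob-chisq",
                     "heat-diffusion")
PROB_FAMILIES <- c("prob-js", "prob-hellinger", "prob-tv", "prob-chisq")

#' Specify a kernel on the simplex
#'
#' @param family One of `"linear"`, `"rbf"`, `"aitchison"`,
#'   `"aitchison-rbf"`, `"prob-js"`, `"prob-hellinger"`, `"prob-tv"`,
#'   `"prob-chisq"`, `"heat-diffusion"`.
#' @param g Bandwidth (> 0) for the RBF families (`rbf`, `aitchison-rbf`).
#' @param c Non-negative zero shift for the Aitchison families.
#' @param t Diffusion time (> 0) for `heat-diffusion`.
#' @param scale Positive multiplier applied to the squared distance of the
#'   probability families before anchoring (default 1).
#' @param anchor Optional anchor composition for the probability families;
#'   defaults to the barycenter `(1/p, ..., 1/p)`.
#' @param W Optional weight matrix (see [apply_weights()]).
#' @return An object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(family, g = NULL, c = NULL, t = NULL, scale = 1,
                        anchor = NULL, W = NULL) {
  family <- match.arg(family, KERNEL_FAMILIES)
  chk_pos <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop_ck("invalid_input", "kernel '%s' needs a single positive '%s'", family, nm)
    }
  }
  if (family %in% c("rbf", "aitchison-rbf")) chk_pos(g, "g")
  if (family %in% c("aitchison", "aitchison-rbf")) {
    if (!is.numeric(c) || length(c) != 1 || is.na(c) || c < 0) {
      stop_ck("invalid_input", "kernel '%s' needs a single shift c >= 0", family)
    }
  }
  if (family == "heat-diffusion") chk_pos(t, "t")
  if (family %in% PROB_FAMILIES) chk_pos(scale, "scale")
  spec <- structure(
    list(family = family, g = g, c = c, t = t, scale = scale,
         anchor = anchor, W = W),
    class = "kernel_spec"
  )
  spec
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("kernel:", kernel_id(x), if (!is.null(x$W)) "(weighted)", "\n")
  invisible(x)
}

#' Short human-readable identifier for a kernel spec
#' @param spec A `kernel_spec`.
#' @return A single string such as `"aitchison(c=0.005)"`.
#' @export
kernel_id <- function(spec) {
  par <- c(
    if (!is.null(spec$g)) sprintf("g=%.4g", spec$g),
    if (!is.null(spec$c)) sprintf("c=%.4g", spec$c),
    if (!is.null(spec$t)) sprintf("t=%.4g", spec$t),
    if (spec$family %in% PROB_FAMILIES && !identical(spec$scale, 1))
      sprintf("s=%.4g", spec$scale),
    if (spec$family %in% PROB_FAMILIES && !is.null(spec$anchor)) "anchor=data",
    if (!is.null(spec$W)) "W"
  )
  paste0(spec$family, "(", paste(par, collapse = ","), ")")
}

# ---- squared-distance matrices for the probability families ----------------
# All are conditionally negative definite on the simplex, which makes the
# anchored construction below positive semi-definite.

prob_sqdist <- function(family, A, B) {
  switch(family,
    "prob-hellinger" = row_sqdist(sqrt(A), sqrt(B)),
    "prob-tv" = cross_rowwise(A, B, function(a, b) 0.5 * sum(abs(a - b))),
    "prob-chisq" = cross_rowwise(A, B, function(a, b) {
      s <- a + b
      ok <- s > 0
      sum((a[ok] - b[ok])^2 / s[ok])
    }),
    "prob-js" = cross_rowwise(A, B, function(a, b) {
      m <- (a + b) / 2
      xlog <- function(u, v) {
        out <- numeric(length(u))
        pos <- u > 0
        out[pos] <- u[pos] * log(u[pos] / v[pos])
        out
      }
      0.5 * sum(xlog(a, m)) + 0.5 * sum(xlog(b, m))
    }),
    stop_ck("invalid_input", "no squared distance for family '%s'", family)
  )
}

cross_rowwise <- function(A, B, f) {
  out <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(nrow(B))) {
    b <- B[j, ]
    out[, j] <- vapply(seq_len(nrow(A)), function(i) f(A[i, ], b), numeric(1))
  }
  out
}

# Componentwise scalar squared distances d0(a, b) used by Eq-4 weighting;
# prob_sqdist(x, y) = sum_j d0(x_j, y_j).
prob_sqdist0 <- function(family, a, b) {
  switch(family,
    "prob-hellinger" = (sqrt(a) - sqrt(b))^2,
    "prob-tv" = 0.5 * abs(a - b),
    "prob-chisq" = {
      s <- a + b
      ifelse(s > 0, (a - b)^2 / s, 0)
    },
    "prob-js" = {
      m <- (a + b) / 2
      xlog <- function(u) ifelse(u > 0, u * log(u / m), 0)
      0.5 * xlog(a) + 0.5 * xlog(b)
    }
  )
}

heat_geodesic <- function(A, B) {
  cosang <- tcrossprod(sqrt(A), sqrt(B))
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  2 * acos(cosang)
}

# ---- Gram computation ------------------------------------------------------

gram_core <- function(spec, A, B) {
  fam <- spec$family
  if (!is.null(spec$W)) return(gram_weighted(spec, A, B))
  switch(fam,
    "linear" = tcrossprod(A, B),
    "rbf" = exp(-spec$g * row_sqdist(A, B)),
    "aitchison" = tcrossprod(clr_shift(A, spec$c), clr_shift(B, spec$c)),
    "aitchison-rbf" = exp(-spec$g * row_sqdist(clr_shift(A, spec$c),
                                               clr_shift(B, spec$c))),
    "heat-diffusion" = exp(-heat_geodesic(A, B)^2 / (4 * spec$t)),
    {
      u0 <- matrix(spec$anchor %||% rep(1 / ncol(A), ncol(A)), nrow = 1)
      dA <- prob_sqdist(fam, A, u0)
      dB <- prob_sqdist(fam, B, u0)
      dAB <- prob_sqdist(fam, A, B)
      spec$scale * 0.5 * (outer(drop(dA), drop(dB), `+`) - dAB)
    }
  )
}

# Eq-4 style weighted kernels. Linear and the probability families use the
# componentwise double sum sum_{ij} W_ij k0(x_i, y_j); the Aitchison kernel
# uses the W-quadratic form in clr coordinates; the exponential families use
# the W-quadratic form of their underlying difference vector.
gram_weighted <- function(spec, A, B) {
  W <- spec$W
  if (!is.matrix(W) || nrow(W) != ncol(A)) {
    stop_ck("invalid_input", "weight matrix dimension does not match p = %d", ncol(A))
  }
  fam <- spec$family
  switch(fam,
    "linear" = A %*% W %*% t(B),
    "aitchison" = clr_shift(A, spec$c) %*% W %*% t(clr_shift(B, spec$c)),
    "rbf" = exp(-spec$g * w_sqdist(A, B, W)),
    "aitchison-rbf" = exp(-spec$g * w_sqdist(clr_shift(A, spec$c),
                                             clr_shift(B, spec$c), W)),
    # chordal (small-angle) version of the geodesic: d^2 ~ 4*||sqrt(x)-sqrt(y)||^2
    "heat-diffusion" = exp(-4 * w_sqdist(sqrt(A), sqrt(B), W) / (4 * spec$t)),
    gram_weighted_prob(spec, A, B)
  )
}

w_sqdist <- function(A, B, W) {
  qa <- rowSums((A %*% W) * A)
  qb <- rowSums((B %*% W) * B)
  d <- outer(qa, qb, `+`) - 2 * A %*% W %*% t(B)
  d[d < 0] <- 0
  d
}

gram_weighted_prob <- function(spec, A, B) {
  fam <- spec$family
  p <- ncol(A)
  u0 <- spec$anchor %||% rep(1 / p, p)
  W <- spec$W
  rw <- rowSums(W)
  cw <- colSums(W)
  hA <- t(apply(A, 1, function(a) prob_sqdist0(fam, a, u0)))
  hB <- t(apply(B, 1, function(b) prob_sqdist0(fam, b, u0)))
  base <- outer(drop(hA %*% rw), drop(hB %*% cw), `+`)
  cross <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      D0 <- outer(A[i, ], B[j, ], function(a, b) prob_sqdist0(fam, a, b))
      cross[i, j] <- sum(W * D0)
    }
  }
  spec$scale * 0.5 * (base - cross)
}

#' Evaluate a kernel on two compositions
#'
#' @param spec A [kernel_spec()].
#' @param x,y Compositions (numeric vectors on the simplex) of equal length.
#' @return The scalar kernel value `k(x, y)`.
#' @export
kernel_eval <- function(spec, x, y) {
  X <- as_comp_matrix(x)
  Y <- as_comp_matrix(y)
  if (ncol(X) != ncol(Y)) stop_ck("invalid_input", "compositions differ in p")
  drop(gram_core(spec, X, Y))
}

#' Gram matrix of a kernel on one or two composition tables
#'
#' With a single table the result is the symmetric `n x n` kernel matrix;
#' with two tables the `n x m` cross matrix. Square heat-diffusion Gram
#' matrices are spectrally repaired (negative eigenvalues clipped to zero)
#' because the geodesic Gaussian is only approximately positive
#' semi-definite.
#'
#' @param spec A [kernel_spec()].
#' @param A Composition table (rows on the simplex).
#' @param B Optional second table with the same components.
#' @return Numeric matrix of kernel evaluations with attribute `"spec"`.
#' @export
gram_matrix <- function(spec, A, B = NULL) {
  A <- as_comp_matrix(A)
  square <- is.null(B)
  B <- if (square) A else as_comp_matrix(B)
  if (ncol(A) != ncol(B)) stop_ck("invalid_input", "tables differ in p")
  K <- gram_core(spec, A, B)
  if (square) {
    K <- (K + t(K)) / 2
    if (spec$family == "heat-diffusion") K <- psd_repair(K)
  }
  attr(K, "spec") <- spec
  K
}

# Clip negative eigenvalues to zero. Used for the heat-diffusion family and
# for weight-matrix validation.
psd_repair <- function(K, warn = TRUE) {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-12 * max(abs(e$values))) {
    if (warn) {
      warning("Gram matrix not PSD (min eigenvalue ", format(min(e$values)),
              "); clipping negative eigenvalues to 0", call. = FALSE)
    }
    v <- pmax(e$values, 0)
    K <- e$vectors %*% (v * t(e$vectors))
    K <- (K + t(K)) / 2
  }
  K
}

#' Kernel-induced distance between two compositions
#'
#' Every kernel induces a semi-metric
#' `d_k(x, y) = sqrt(k(x,x) - 2 k(x,y) + k(y,y))`.
#'
#' @inheritParams kernel_eval
#' @return Non-negative scalar distance.
#' @export
induced_distance <- function(spec, x, y) {
  kxx <- kernel_eval(spec, x, x)
  kyy <- kernel_eval(spec, y, y)
  kxy <- kernel_eval(spec, x, y)
  sqrt(max(0, kxx - 2 * kxy + kyy))
}

# Pairwise induced-distance matrix from a square Gram matrix.
gram_to_dist <- function(K) {
  d2 <- outer(diag(K), diag(K), `+`) - 2 * K
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Default data-adaptive kernel grid
#'
#' Returns the default grid of 55 kernel specifications spanning all
#' families, with data-adaptive parameters: RBF bandwidths around the
#' median heuristic, Aitchison shifts centered at half the minimum
#' non-zero relative abundance, probability kernels with barycenter and
#' data-mean anchors at three distance scalings, and log-spaced diffusion
#' times. Deterministic given `X`.
#'
#' @param X Composition table.
#' @param families Optional character vector restricting the grid to a
#'   subset of kernel families.
#' @return A list of [kernel_spec()] objects.
#' @export
default_kernel_grid <- function(X, families = NULL) {
  X <- as_comp_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  # median heuristic on Euclidean squared distances (subsample for big n)
  idx <- if (n > 200) round(seq(1, n, length.out = 200)) else seq_len(n)
  d2 <- row_sqdist(X[idx, , drop = FALSE], X[idx, , drop = FALSE])
  med2 <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(med2) || med2 <= 0) med2 <- 1 / p
  g0 <- 1 / med2
  pos <- X[X > 0]
  cmin <- if (length(pos)) min(pos) / 2 else 1 / (2 * p)
  shifts <- cmin * 10^seq(-2, 2)
  clr_g <- function(cc) {
    Z <- clr_shift(X[idx, , drop = FALSE], cc)
    dz <- row_sqdist(Z, Z)
    m <- stats::median(dz[upper.tri(dz)])
    if (!is.finite(m) || m <= 0) 1 else 1 / m
  }
  grid <- c(
    list(kernel_spec("linear")),
    lapply(c(0.1, 1, 10, 100), function(s) kernel_spec("rbf", g = g0 * s)),
    lapply(shifts, function(cc) kernel_spec("aitchison", c = cc)),
    unlist(lapply(shifts, function(cc) {
      ga <- clr_g(cc)
      list(kernel_spec("aitchison-rbf", g = ga, c = cc),
           kernel_spec("aitchison-rbf", g = 10 * ga, c = cc))
    }), recursive = FALSE),
    unlist(lapply(PROB_FAMILIES, function(fam) {
      anchors <- list(NULL, closure(colMeans(X)))
      unlist(lapply(anchors, function(a) {
        lapply(c(0.5, 1, 2), function(s) kernel_spec(fam, scale = s, anchor = a))
      }), recursive = FALSE)
    }), recursive = FALSE),
    lapply(10^seq(-2, 1, length.out = 11), function(tt) {
      kernel_spec("heat-diffusion", t = tt)
    })
  )
  if (!is.null(families)) {
    families <- match.arg(families, KERNEL_FAMILIES, several.ok = TRUE)
    grid <- Filter(function(s) s$family %in% families, grid)
    if (!length(grid)) stop_ck("invalid_input", "no kernels left after filtering")
  }
  grid
}
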
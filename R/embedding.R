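# Kernel PCA with compositionally adjusted component influence, and
# kernel-distance scalar summaries: closeness to a reference point,
# geometric median, and a data-adaptive alpha-diversity.

#' Kernel principal component analysis
#'
#' Double-centers the kernel Gram matrix, eigendecomposes it, and returns
#' the top `m` sample scores scaled by the square root of the eigenvalue.
#' Signs are fixed so that the largest-magnitude entry of each eigenvector
#' is positive. With the linear kernel the scores coincide with classical
#' PCA scores of the composition matrix.
#'
#' @param spec A [kernel_spec()].
#' @param X Composition table.
#' @param m Number of components, at most `n - 1`.
#' @return An `embedding_result` with `coordinates` (n x m), `eigenvalues`,
#'   the centering statistics needed for out-of-sample projection, and
#'   `spec`.
#' @export
kpca <- function(spec, X, m = 2L) {
  X <- as_comp_matrix(X)
  n <- nrow(X)
  m <- as.integer(m)
  if (m < 1 || m > n - 1) {
    stop_ck("invalid_input", "m must lie in [1, n - 1] = [1, %d]", n - 1)
  }
  K <- gram_matrix(spec, X)
  rowm <- rowMeans(K)
  allm <- mean(K)
  Kc <- K - outer(rowm, rep(1, n)) - outer(rep(1, n), rowm) + allm
  e <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  vals <- pmax(e$values[seq_len(m)], 0)
  vecs <- e$vectors[, seq_len(m), drop = FALSE]
  for (k in seq_len(m)) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  coords <- sweep(vecs, 2, sqrt(vals), `*`)
  dimnames(coords) <- list(rownames(X), paste0("PC", seq_len(m)))
  structure(
    list(coordinates = coords, eigenvalues = vals, vectors = vecs,
         train_X = X, row_means = rowm, grand_mean = allm, spec = spec),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("kernel PCA: %d samples, %d components, %s\n",
              nrow(x$coordinates), ncol(x$coordinates), kernel_id(x$spec)))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

# Out-of-sample kernel PCA score functions using the training centering
# statistics. Returns an n_new x m matrix.
kpca_project <- function(embedding, Xnew) {
  Xn <- as_comp_matrix(Xnew)
  Kx <- gram_core(embedding$spec, embedding$train_X, Xn)  # n_train x n_new
  n <- nrow(embedding$train_X)
  # center against training distribution
  Kc <- Kx - embedding$row_means - rep(colMeans(Kx), each = n) +
    embedding$grand_mean
  vals <- embedding$eigenvalues
  sc <- crossprod(Kc, embedding$vectors)  # n_new x m
  sweep(sc, 2, ifelse(vals > 0, sqrt(vals), Inf), `/`)
}

#' Component influence on kernel principal components
#'
#' Computes, for every component and every principal component, the CFI of
#' the out-of-sample PC score function: how much multiplicatively
#' perturbing a single component (and re-closing) moves a sample along
#' that principal axis. Each column sums to zero, like every CFI.
#'
#' @param embedding An `embedding_result` from [kpca()].
#' @param X Composition table to average over (defaults to the embedding's
#'   training table).
#' @param h Finite-difference step.
#' @return A `p x m` matrix of influences.
#' @export
pc_influence <- function(embedding, X = NULL, h = 1e-4) {
  stopifnot(inherits(embedding, "embedding_result"))
  X <- if (is.null(X)) embedding$train_X else as_comp_matrix(X)
  m <- ncol(embedding$coordinates)
  out <- sapply(seq_len(m), function(k) {
    g <- function(Z) kpca_project(embedding, Z)[, k]
    cfi(g, X, h = h)$cfi
  })
  out <- matrix(out, nrow = ncol(X), ncol = m,
                dimnames = list(colnames(X), colnames(embedding$coordinates)))
  out
}

#' Closeness of samples to a reference composition
#'
#' `D(x) = -d_k(x, u)^2`, the negative squared kernel-induced distance to
#' a reference point `u`. Values are non-positive and zero exactly when
#' the induced distance vanishes. With `u` the geometric median of a
#' healthy subgroup this acts as a simple kernel health score.
#'
#' @param spec A [kernel_spec()].
#' @param X Composition table.
#' @param u Reference composition.
#' @return A `summary_stat` with fields `values`, `reference`, `spec`.
#' @export
closeness_score <- function(spec, X, u) {
  X <- as_comp_matrix(X)
  u <- drop(as_comp_matrix(u))
  if (length(u) != ncol(X)) stop_ck("invalid_input", "reference has wrong p")
  U <- matrix(u, nrow = 1)
  kxx <- diag(gram_core(spec, X, X))
  kuu <- drop(gram_core(spec, U, U))
  kxu <- drop(gram_core(spec, X, U))
  vals <- -(pmax(0, kxx - 2 * kxu + kuu))
  names(vals) <- rownames(X)
  structure(list(values = vals, reference = u, spec = spec),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat("kernel closeness scores (", kernel_id(x$spec), ")\n", sep = "")
  print(utils::head(round(x$values, 6)))
  invisible(x)
}

#' Kernel geometric median of a sample set
#'
#' Returns the index of the observation with the smallest total
#' kernel-induced distance to all other observations in the subset; ties
#' are broken towards the lowest index.
#'
#' @param spec A [kernel_spec()].
#' @param X Composition table.
#' @param subset Optional logical mask or integer indices restricting the
#'   candidate (and reference) samples.
#' @return Integer index into the rows of `X`.
#' @export
geometric_median <- function(spec, X, subset = NULL) {
  X <- as_comp_matrix(X)
  idx <- if (is.null(subset)) seq_len(nrow(X)) else {
    if (is.logical(subset)) which(subset) else as.integer(subset)
  }
  if (!length(idx)) stop_ck("invalid_input", "empty subset")
  Xs <- X[idx, , drop = FALSE]
  D <- gram_to_dist(gram_matrix(spec, Xs))
  tot <- rowSums(D)
  idx[which.min(tot)]  # which.min takes the first minimum -> lowest index
}

#' Data-adaptive alpha-diversity
#'
#' The closeness score with the barycenter `(1/p, ..., 1/p)` — the most
#' diverse point of the simplex — as reference. For the linear kernel this
#' equals the Gini-Simpson diversity `1 - sum(x^2)` shifted by the constant
#' `(p - 1) / p`, so the two induce the same ordering of samples.
#'
#' @param spec A [kernel_spec()].
#' @param X Composition table.
#' @return A `summary_stat`.
#' @export
alpha_diversity <- function(spec, X) {
  X <- as_comp_matrix(X)
  closeness_score(spec, X, rep(1 / ncol(X), ncol(X)))
}
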
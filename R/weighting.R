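# Prior-knowledge weight matrices: construction from partitions (e.g.
# taxonomic ranks) or phylogenetic trees, validation, and attachment to
# kernel specifications.

#' Validate a weight matrix
#'
#' A valid weight matrix is symmetric, entrywise non-negative, and positive
#' semi-definite. Eigenvalues in `[-1e-8 * lambda_max, 0)` are clipped to
#' zero; more negative eigenvalues are a hard error.
#'
#' @param W Square numeric matrix.
#' @param component_labels Optional labels attached as dimnames.
#' @return The validated (possibly clipped) matrix of class `"weight_matrix"`.
#' @export
weight_matrix <- function(W, component_labels = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop_ck("invalid_input", "weight matrix must be square")
  if (anyNA(W) || any(W < 0)) {
    stop_ck("invalid_input", "weight matrix entries must be non-negative")
  }
  if (max(abs(W - t(W))) > 1e-8 * max(1, max(abs(W)))) {
    stop_ck("invalid_input", "weight matrix must be symmetric")
  }
  W <- (W + t(W)) / 2
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(abs(ev))
  if (min(ev) < -1e-8 * lmax) {
    stop_ck("invalid_input",
            "weight matrix is not positive semi-definite (min eigenvalue %g)",
            min(ev))
  }
  if (min(ev) < 0) W <- psd_repair(W, warn = FALSE)
  if (!is.null(component_labels)) dimnames(W) <- list(component_labels, component_labels)
  class(W) <- c("weight_matrix", "matrix", "array")
  W
}

# Normalize a partition given as a list of index vectors, or as a factor /
# character / integer vector of block memberships of length p.
as_partition <- function(partition, p) {
  if (!is.list(partition)) {
    if (length(partition) != p) {
      stop_ck("invalid_partition", "membership vector must have length p = %d", p)
    }
    partition <- split(seq_len(p), factor(partition))
  }
  idx <- unlist(partition, use.names = FALSE)
  if (any(vapply(partition, length, 1L) == 0)) {
    stop_ck("invalid_partition", "empty block in partition")
  }
  if (anyDuplicated(idx)) stop_ck("invalid_partition", "overlapping blocks")
  if (!setequal(idx, seq_len(p))) {
    stop_ck("invalid_partition", "blocks must cover 1..p exactly")
  }
  lapply(partition, as.integer)
}

#' Block weight matrix from a partition
#'
#' Builds the block-diagonal weight matrix with entries `1/|P_l|` inside
#' block `l` and 0 elsewhere. Each block contributes a rank-one projector,
#' so the eigenvalues are 0 and 1. Using this matrix with the weighted
#' Aitchison kernel restricts the model to log-contrast functions whose
#' coefficients are constant within blocks.
#'
#' @param partition List of disjoint index vectors covering `1..p`, or a
#'   membership vector (factor/character/integer) of length `p`.
#' @param p Number of components.
#' @param component_labels Optional labels.
#' @return A `weight_matrix`.
#' @export
partition_weights <- function(partition, p, component_labels = NULL) {
  blocks <- as_partition(partition, p)
  W <- matrix(0, p, p)
  for (b in blocks) W[b, b] <- 1 / length(b)
  weight_matrix(W, component_labels)
}

#' Weight matrix from a phylogenetic tree
#'
#' Computes pairwise patristic (branch-length) distances between the leaves
#' named in `labels`, converts them to similarities `exp(-D / bandwidth)`,
#' clips negative eigenvalues to zero, and rescales the diagonal to one.
#' This is a pragmatic phylogeny-derived weighting in the spirit of
#' UniFrac-based constructions; a user-supplied weight matrix can always be
#' used instead.
#'
#' @param tree A Newick string, a path to a Newick file, or an
#'   [ape::phylo] object with branch lengths.
#' @param labels Component labels; each must be a leaf of the tree.
#' @param bandwidth Positive length scale of the similarity; `Inf` gives
#'   the all-ones (rank one) matrix.
#' @return A `weight_matrix` ordered as `labels`.
#' @export
tree_weights <- function(tree, labels, bandwidth) {
  if (is.character(tree)) {
    tree <- if (length(tree) == 1 && file.exists(tree)) {
      ape::read.tree(tree)
    } else {
      ape::read.tree(text = tree)
    }
  }
  if (!inherits(tree, "phylo")) stop_ck("invalid_tree", "cannot parse tree input")
  if (is.null(tree$edge.length)) {
    stop_ck("invalid_tree", "tree has no branch lengths")
  }
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing)) {
    stop_ck("label_mismatch", "labels not found in tree: %s",
            paste(missing, collapse = ", "))
  }
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0) {
    stop_ck("invalid_input", "bandwidth must be a positive scalar")
  }
  D <- ape::cophenetic.phylo(tree)[labels, labels]
  W <- exp(-D / bandwidth)
  W <- psd_repair((W + t(W)) / 2, warn = FALSE)
  d <- diag(W)
  if (any(d <= 0)) stop_ck("invalid_tree", "degenerate similarity matrix")
  W <- W / sqrt(outer(d, d))
  weight_matrix(W, labels)
}

#' Attach a weight matrix to a kernel specification
#'
#' Returns a weighted version of `spec`. The linear and probability
#' families use the componentwise double sum
#' `k_W(x, y) = sum_ij W_ij k0(x_i, y_j)`; the Aitchison kernel becomes
#' the `W`-quadratic form in clr coordinates (so block weights from
#' [partition_weights()] restrict it to block-constant log-contrast
#' functions); the RBF-type families exponentiate the corresponding
#' `W`-quadratic-form squared distance.
#'
#' @param spec A [kernel_spec()].
#' @param W A `weight_matrix` (or matrix coercible to one) of dimension `p`.
#' @return A weighted `kernel_spec`.
#' @export
apply_weights <- function(spec, W) {
  stopifnot(inherits(spec, "kernel_spec"))
  W <- weight_matrix(W)
  spec$W <- unclass(W)
  spec
}

#' Read / write a labeled weight matrix as delimited text
#'
#' @param path File path.
#' @param W Weight matrix with dimnames.
#' @param sep Field separator (default tab).
#' @return `read_weight_matrix()` returns a `weight_matrix`.
#' @export
read_weight_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  weight_matrix(as.matrix(df), component_labels = rownames(df))
}

#' @rdname read_weight_matrix
#' @export
write_weight_matrix <- function(W, path, sep = "\t") {
  utils::write.table(as.data.frame(unclass(W)), path, sep = sep,
                     quote = FALSE, col.names = NA)
  invisible(path)
}
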
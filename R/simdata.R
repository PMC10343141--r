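# Seeded synthetic generators: compositional log-normal covariates,
# multinomial zero-inflation mimicking finite sequencing depth, and
# log-contrast responses including block-structured coefficient designs
# for studying prior-knowledge weighting.

#' Log-contrast model specification
#'
#' @param beta Coefficient vector; must sum to zero (tolerance `1e-9`).
#' @param noise_sd Non-negative response noise standard deviation.
#' @return A `log_contrast_model` list.
#' @export
log_contrast_model <- function(beta, noise_sd = 0) {
  beta <- as.numeric(beta)
  if (abs(sum(beta)) > 1e-9) {
    stop_ck("invalid_input", "log-contrast coefficients must sum to 0 (got %g)",
            sum(beta))
  }
  if (noise_sd < 0) stop_ck("invalid_input", "noise_sd must be >= 0")
  structure(list(beta = beta, noise_sd = noise_sd),
            class = "log_contrast_model")
}

#' Vectorized log-contrast function
#'
#' Returns `f(x) = sum_j beta_j log(x_j)` as a function that maps a
#' composition matrix to a vector of values, suitable for [cfi()] and
#' [cpd()].
#'
#' @param beta Coefficients summing to zero.
#' @return A function `matrix -> numeric`.
#' @export
log_contrast_fn <- function(beta) {
  beta <- log_contrast_model(beta)$beta
  function(X) {
    X <- as_comp_matrix(X)
    if (ncol(X) != length(beta)) stop_ck("invalid_input", "wrong p for beta")
    unname(drop(log(X) %*% beta))
  }
}

#' Sample compositional log-normal covariates
#'
#' Draws `Z ~ N(mu, sigma)` and returns `closure(exp(Z))` row-wise; the
#' classical logistic-normal distribution on the simplex. Strictly
#' positive; combine with [zero_inflate()] for realistic sparsity.
#'
#' @param n Number of samples.
#' @param p Number of components.
#' @param mu Mean vector (default 0).
#' @param sigma Covariance matrix (default identity).
#' @param seed Integer seed.
#' @return A `composition_table`.
#' @export
sample_logistic_normal <- function(n, p, mu = rep(0, p), sigma = diag(p),
                                   seed = 1L) {
  if (length(mu) != p) stop_ck("invalid_input", "mu must have length p")
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == p)) stop_ck("invalid_input", "sigma must be p x p")
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    stop_ck("invalid_input", "sigma is not positive semi-definite")
  }
  A <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  Z <- with_seed(seed, matrix(stats::rnorm(n * p), n, p)) %*% A
  Z <- sweep(Z, 2, mu, `+`)
  X <- exp(Z)
  composition_table(X / rowSums(X))
}

#' Multinomial zero inflation at finite sequencing depth
#'
#' Resamples each composition as `multinomial(depth, x) / depth`,
#' emulating the sparsity of count data at a given sequencing depth: rare
#' components drop to exact zeros with probability `(1 - x_j)^depth`.
#'
#' @param X Composition table.
#' @param depth Sequencing depth (counts per sample), `>= 1`.
#' @param seed Integer seed.
#' @return A `composition_table` with zeros.
#' @export
zero_inflate <- function(X, depth, seed = 1L) {
  X <- as_comp_matrix(X)
  depth <- as.integer(depth)
  if (depth < 1) stop_ck("invalid_input", "depth must be >= 1")
  counts <- with_seed(seed, {
    t(vapply(seq_len(nrow(X)),
             function(i) as.numeric(stats::rmultinom(1, depth, X[i, ])),
             numeric(ncol(X))))
  })
  composition_table(counts / depth, component_labels = colnames(X),
                    sample_ids = rownames(X))
}

#' Log-contrast responses with Gaussian noise
#'
#' `y_i = sum_j beta_j log(X_ij) + eps_i`, `eps ~ N(0, noise_sd^2)`.
#' Requires strictly positive compositions (generate responses before
#' zero-inflating, or shift).
#'
#' @param X Strictly positive composition table.
#' @param model A [log_contrast_model()].
#' @param seed Integer seed for the noise.
#' @return Numeric response vector.
#' @export
logcontrast_response <- function(X, model, seed = 1L) {
  stopifnot(inherits(model, "log_contrast_model"))
  X <- as_comp_matrix(X)
  if (any(X == 0)) {
    stop_ck("zero_handling",
            "log-contrast response undefined on zeros; generate before zero_inflate()")
  }
  f <- unname(drop(log(X) %*% model$beta))
  eps <- if (model$noise_sd > 0) {
    with_seed(seed, stats::rnorm(nrow(X), 0, model$noise_sd))
  } else {
    0
  }
  f + eps
}

#' Block-structured log-contrast data generating processes
#'
#' Builds a log-contrast response on top of given covariates with
#' coefficients organized in blocks of a partition (e.g. phyla). Two
#' designated blocks carry signal; all other components start at zero.
#' Under `"dgp1"` every member of a designated block shares the block
#' coefficient (`beta_B`, `beta_P`), so block-structured prior weights are
#' informative. Under `"dgp2"` the first half of each designated block
#' gets the negated coefficient and the second half the positive one, so
#' the same weights are adversarial. Coefficients are re-centered to sum
#' to zero within the designated blocks.
#'
#' @param X Strictly positive composition table.
#' @param partition Partition of the components (list of index vectors or
#'   membership vector); the first two blocks are the designated ones.
#' @param beta_B,beta_P Block coefficients (defaults 2 and -1).
#' @param variant `"dgp1"` or `"dgp2"`.
#' @param noise_sd Response noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return A `synthetic_dataset` list: `X`, `y`, `truth`
#'   (a [log_contrast_model()]), `partition`, `dgp_tag`.
#' @export
block_dgp <- function(X, partition, beta_B = 2, beta_P = -1,
                      variant = c("dgp1", "dgp2"), noise_sd = 1, seed = 1L) {
  variant <- match.arg(variant)
  X <- as_comp_matrix(X)
  p <- ncol(X)
  blocks <- as_partition(partition, p)
  if (length(blocks) < 2) stop_ck("invalid_input", "need at least two blocks")
  des <- blocks[1:2]
  coefs <- c(beta_B, beta_P)
  beta <- numeric(p)
  for (b in 1:2) {
    idx <- des[[b]]
    if (variant == "dgp1") {
      beta[idx] <- coefs[b]
    } else {
      if (length(idx) < 2) {
        stop_ck("invalid_input", "dgp2 needs designated blocks of size >= 2")
      }
      half <- floor(length(idx) / 2)
      beta[idx[seq_len(half)]] <- -coefs[b]
      beta[idx[-seq_len(half)]] <- coefs[b]
    }
  }
  # re-center to sum zero using only the designated components, so the
  # zero coefficients of the remaining components stay exactly zero
  didx <- unlist(des)
  beta[didx] <- beta[didx] - sum(beta) / length(didx)
  truth <- log_contrast_model(beta, noise_sd)
  y <- logcontrast_response(X, truth, seed = seed)
  structure(
    list(X = X, y = y, truth = truth, partition = blocks, dgp_tag = variant),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset (%s): n = %d, p = %d, noise_sd = %g\n",
              x$dgp_tag, nrow(x$X), ncol(x$X), x$truth$noise_sd))
  invisible(x)
}
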
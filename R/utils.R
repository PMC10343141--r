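# Internal helpers shared across modules.

# Run `expr` with a temporary RNG state seeded at `seed`; restores the
# caller's .Random.seed so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stop_ck <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "compkernel_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pairwise squared Euclidean distances between rows of A and rows of B.
row_sqdist <- function(A, B) {
  d <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}
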
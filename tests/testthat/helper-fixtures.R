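# Shared fixtures: all test data is generated in code, seeded.

with_seed <- compkernel:::with_seed

# n sparse compositions on the p-simplex (zeros from multinomial resampling)
rand_sparse_simplex <- function(n, p, seed = 1L, depth = 50L) {
  X <- sample_logistic_normal(n, p, seed = seed)
  zero_inflate(X, depth = depth, seed = seed + 1L)
}

rand_dense_simplex <- function(n, p, seed = 1L) {
  sample_logistic_normal(n, p, seed = seed)
}

# every kernel family with small fixed parameters, for property loops
all_family_specs <- function(c_shift = 1e-3) {
  list(
    kernel_spec("linear"),
    kernel_spec("rbf", g = 1),
    kernel_spec("aitchison", c = c_shift),
    kernel_spec("aitchison-rbf", g = 0.5, c = c_shift),
    kernel_spec("prob-js"),
    kernel_spec("prob-hellinger"),
    kernel_spec("prob-tv"),
    kernel_spec("prob-chisq"),
    kernel_spec("heat-diffusion", t = 0.5)
  )
}

expect_simplex_rows <- function(X, tol = 1e-9) {
  X <- unclass(X)
  expect_true(all(X >= -tol))
  expect_true(all(abs(rowSums(X) - 1) < 1e-8))
}
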
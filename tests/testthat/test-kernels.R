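test_that("kernel_eval reproduces hand-computed values", {
  expect_equal(kernel_eval(kernel_spec("linear"), c(1, 0), c(0, 1)), 0)
  x <- closure(c(1, 2, 3))
  expect_equal(kernel_eval(kernel_spec("rbf", g = 3), x, x), 1)
  expect_equal(kernel_eval(kernel_spec("heat-diffusion", t = 1), x, x), 1)
  p <- 3
  bary <- rep(1 / p, p)
  expect_equal(kernel_eval(kernel_spec("aitchison", c = 0), bary, bary), 0)
  # p = 2 anchored Hellinger at opposite vertices: k = 1 - sqrt(2)
  expect_equal(kernel_eval(kernel_spec("prob-hellinger"), c(1, 0), c(0, 1)),
               1 - sqrt(2))
  expect_error(kernel_eval(kernel_spec("linear"), c(0.5, 0.5), c(1, 0, 0) / 1),
               class = "invalid_input")
  expect_error(kernel_eval(kernel_spec("aitchison", c = 0), c(0, 1), c(0.5, 0.5)),
               class = "zero_handling")
})

test_that("kernel_spec validates family parameters", {
  expect_error(kernel_spec("rbf"), class = "invalid_input")
  expect_error(kernel_spec("rbf", g = -1), class = "invalid_input")
  expect_error(kernel_spec("heat-diffusion"), class = "invalid_input")
  expect_error(kernel_spec("aitchison"), class = "invalid_input")
  expect_silent(kernel_spec("aitchison", c = 0))
})

test_that("gram_matrix is symmetric, consistent with kernel_eval, transposes", {
  A <- rand_sparse_simplex(8, 5, seed = 2)
  B <- rand_sparse_simplex(3, 5, seed = 3)
  for (spec in all_family_specs()) {
    K <- suppressWarnings(gram_matrix(spec, A))
    expect_equal(K, t(K))
    KAB <- gram_matrix(spec, A, B)
    KBA <- gram_matrix(spec, B, A)
    expect_equal(unname(KAB), unname(t(KBA)), tolerance = 1e-12)
    # spot value agrees with scalar evaluation (skip repaired heat gram)
    if (spec$family != "heat-diffusion") {
      expect_equal(K[2, 5], kernel_eval(spec, unclass(A)[2, ], unclass(A)[5, ]))
    }
    # Cauchy-Schwarz on the cross matrix
    dA <- diag(suppressWarnings(gram_matrix(spec, A)))
    dB <- diag(suppressWarnings(gram_matrix(spec, B)))
    expect_true(all(KAB^2 <= outer(dA, dB) + 1e-10))
  }
  one <- composition_table(matrix(c(0.4, 0.6), 1))
  expect_equal(dim(gram_matrix(kernel_spec("linear"), one)), c(1L, 1L))
})

test_that("PSD suite: all families except heat-diffusion on sparse data", {
  for (p in c(3, 10, 50)) {
    X <- rand_sparse_simplex(200, p, seed = 40 + p, depth = 30L)
    for (spec in all_family_specs(c_shift = 1e-3)) {
      if (spec$family == "heat-diffusion") next
      K <- gram_matrix(spec, X)
      ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * max(abs(ev)))
    }
  }
})

test_that("heat-diffusion square Gram is repaired to PSD", {
  X <- rand_sparse_simplex(60, 10, seed = 77, depth = 25L)
  K <- suppressWarnings(gram_matrix(kernel_spec("heat-diffusion", t = 0.05), X))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(abs(ev)))
})

test_that("induced_distance satisfies semi-metric axioms and known forms", {
  X <- rand_dense_simplex(10, 4, seed = 5)
  Xm <- unclass(X)
  for (spec in all_family_specs()) {
    for (i in c(1, 4)) {
      expect_equal(induced_distance(spec, Xm[i, ], Xm[i, ]), 0, tolerance = 1e-7)
      d12 <- induced_distance(spec, Xm[i, ], Xm[i + 1, ])
      d21 <- induced_distance(spec, Xm[i + 1, ], Xm[i, ])
      expect_gte(d12, 0)
      expect_equal(d12, d21)
    }
  }
  # linear kernel -> Euclidean, aitchison -> Euclidean in clr coordinates
  expect_equal(induced_distance(kernel_spec("linear"), Xm[1, ], Xm[2, ]),
               sqrt(sum((Xm[1, ] - Xm[2, ])^2)))
  expect_equal(
    induced_distance(kernel_spec("aitchison", c = 0), Xm[1, ], Xm[2, ]),
    sqrt(sum((clr_shift(Xm[1, ]) - clr_shift(Xm[2, ]))^2))
  )
  # triangle inequality for linear / aitchison / hellinger
  for (spec in list(kernel_spec("linear"), kernel_spec("aitchison", c = 1e-3),
                    kernel_spec("prob-hellinger"))) {
    for (tri in list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))) {
      d <- function(i, j) induced_distance(spec, Xm[i, ], Xm[j, ])
      expect_lte(d(tri[1], tri[3]), d(tri[1], tri[2]) + d(tri[2], tri[3]) + 1e-10)
    }
  }
})

test_that("default kernel grid has 55 valid, deterministic members", {
  X <- rand_sparse_simplex(40, 8, seed = 9)
  g1 <- default_kernel_grid(X)
  g2 <- default_kernel_grid(X)
  expect_length(g1, 55L)
  expect_identical(g1, g2)
  fams <- vapply(g1, function(s) s$family, character(1))
  expect_setequal(unique(fams), c("linear", "rbf", "aitchison", "aitchison-rbf",
                                  "prob-js", "prob-hellinger", "prob-tv",
                                  "prob-chisq", "heat-diffusion"))
  for (s in g1) expect_s3_class(s, "kernel_spec")
  # family filter used by the CLI
  expect_length(default_kernel_grid(X, families = "aitchison"), 5L)
  expect_error(default_kernel_grid(X, families = "cosine"))
})

test_that("aitchison kernel ridge equals ridge on clr features", {
  X <- rand_dense_simplex(30, 6, seed = 21)
  f <- log_contrast_fn(c(1, -2, 0.5, 0.5, 0, 0))
  set.seed(99)
  y <- f(X) + stats::rnorm(30, 0, 0.1)
  lambda <- 0.05
  m <- krr_fit(X, y, kernel_spec("aitchison", c = 0), lambda)
  Z <- clr_shift(X, 0)
  w <- solve(crossprod(Z) + diag(30 * lambda, 6), crossprod(Z, y - mean(y)))
  expect_equal(predict(m, X), unname(drop(Z %*% w)) + mean(y), tolerance = 1e-6)
  Xn <- rand_dense_simplex(7, 6, seed = 22)
  expect_equal(predict(m, Xn), unname(drop(clr_shift(Xn, 0) %*% w)) + mean(y),
               tolerance = 1e-6)
})
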
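test_that("linear-kernel kPCA equals classical PCA up to sign", {
  X <- rand_dense_simplex(25, 6, seed = 121)
  emb <- kpca(kernel_spec("linear"), X, m = 3)
  pc <- prcomp(unclass(X), center = TRUE, scale. = FALSE)
  for (k in 1:3) {
    expect_equal(abs(unname(emb$coordinates[, k])), abs(unname(pc$x[, k])),
                 tolerance = 1e-8)
  }
  expect_equal(emb$eigenvalues,
               (pc$sdev[1:3]^2) * (nrow(X) - 1), tolerance = 1e-8)
})

test_that("kPCA eigenvalues match a dense eigensolver oracle", {
  X <- rand_sparse_simplex(30, 8, seed = 122)
  spec <- kernel_spec("prob-hellinger")
  emb <- kpca(spec, X, m = 5)
  K <- gram_matrix(spec, X)
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  ev <- eigen(H %*% K %*% H, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(emb$eigenvalues, ev[1:5], tolerance = 1e-8)
  # coordinates orthogonal across components
  G <- crossprod(emb$coordinates)
  expect_equal(G, diag(diag(G)), tolerance = 1e-6, ignore_attr = TRUE)
  # eigenvalues non-increasing
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
})

test_that("kPCA reconstruction and out-of-sample projection are consistent", {
  X <- rand_dense_simplex(18, 5, seed = 123)
  spec <- kernel_spec("aitchison", c = 1e-3)
  emb <- kpca(spec, X, m = 17)
  K <- gram_matrix(spec, X)
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  expect_equal(tcrossprod(emb$coordinates), Kc, tolerance = 1e-6,
               ignore_attr = TRUE)
  # projecting the training points recovers the training coordinates
  proj <- compkernel:::kpca_project(emb, X)
  expect_equal(unname(proj[, 1:5]), unname(emb$coordinates[, 1:5]),
               tolerance = 1e-6)
  # duplicated sample gets an identical embedding row
  Xd <- composition_table(rbind(unclass(X), unclass(X)[1, ]))
  embd <- kpca(spec, Xd, m = 2)
  expect_equal(unname(embd$coordinates[19, ]), unname(embd$coordinates[1, ]),
               tolerance = 1e-8)
  expect_error(kpca(spec, X, m = 18), class = "invalid_input")
})

test_that("pc_influence columns sum to zero and respect structure", {
  X <- rand_dense_simplex(20, 5, seed = 124)
  emb <- kpca(kernel_spec("aitchison", c = 1e-3), X, m = 2)
  infl <- pc_influence(emb)
  expect_equal(dim(infl), c(5L, 2L))
  expect_equal(unname(colSums(infl)), c(0, 0), tolerance = 1e-6)
  # permutation equivariance
  perm <- c(4, 2, 5, 1, 3)
  Xp <- composition_table(unclass(X)[, perm])
  infp <- pc_influence(kpca(kernel_spec("aitchison", c = 1e-3), Xp, m = 2))
  expect_equal(abs(unname(infp)), abs(unname(infl[perm, ])), tolerance = 1e-6)
})

test_that("closeness_score is the negative squared induced distance", {
  X <- rand_dense_simplex(12, 4, seed = 125)
  u <- closure(c(1, 2, 3, 4))
  for (spec in list(kernel_spec("linear"), kernel_spec("prob-js"))) {
    sc <- closeness_score(spec, X, u)
    expect_true(all(sc$values <= 1e-12))
    d <- vapply(seq_len(12), function(i) {
      induced_distance(spec, unclass(X)[i, ], u)
    }, numeric(1))
    expect_equal(unname(sc$values), unname(-d^2), tolerance = 1e-10)
  }
  # at the reference itself the score is exactly zero
  Xu <- composition_table(rbind(u, unclass(X)))
  expect_equal(unname(closeness_score(kernel_spec("linear"), Xu, u)$values[1]), 0)
  # linear kernel: -||x - u||^2
  sc <- closeness_score(kernel_spec("linear"), X, u)
  expect_equal(unname(sc$values),
               unname(-rowSums(sweep(unclass(X), 2, u)^2)), tolerance = 1e-12)
})

test_that("geometric_median picks the central observation", {
  # three collinear points under the linear kernel: middle one wins
  X <- composition_table(rbind(c(0.1, 0.9), c(0.5, 0.5), c(0.8, 0.2)))
  expect_equal(geometric_median(kernel_spec("linear"), X), 2L)
  # single sample
  expect_equal(geometric_median(kernel_spec("linear"), X, subset = 3), 3L)
  # duplicated winner: lowest index
  Xd <- composition_table(rbind(c(0.5, 0.5), c(0.1, 0.9), c(0.5, 0.5)))
  expect_equal(geometric_median(kernel_spec("linear"), Xd), 1L)
  expect_error(geometric_median(kernel_spec("linear"), X, subset = integer(0)),
               class = "invalid_input")
})

test_that("alpha diversity is shifted Gini-Simpson under the linear kernel", {
  X <- rand_sparse_simplex(40, 6, seed = 126)
  p <- 6
  ad <- alpha_diversity(kernel_spec("linear"), X)
  gini <- 1 - rowSums(unclass(X)^2)
  # derived constant (p-1)/p: D(x) = GS(x) - (p-1)/p
  expect_equal(unname(ad$values), unname(gini - (p - 1) / p), tolerance = 1e-12)
  # hence identical sample ordering
  expect_equal(order(ad$values), order(gini))
  # verified at p = 2, x = (1, 0): D = -1/2, GS = 0
  X2 <- composition_table(rbind(c(1, 0), c(0.5, 0.5)))
  ad2 <- alpha_diversity(kernel_spec("linear"), X2)
  expect_equal(unname(ad2$values), c(-0.5, 0))
  # permutation invariance
  adp <- alpha_diversity(kernel_spec("linear"),
                         composition_table(unclass(X)[, c(3, 1, 2, 6, 5, 4)]))
  expect_equal(unname(adp$values), unname(ad$values), tolerance = 1e-12)
  # maximized exactly at the barycenter
  Xb <- composition_table(rbind(rep(1 / p, p), unclass(X)))
  adb <- alpha_diversity(kernel_spec("prob-js"), Xb)
  expect_equal(unname(adb$values[1]), 0)
  expect_true(all(adb$values[-1] <= 1e-12))
})
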
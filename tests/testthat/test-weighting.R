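test_that("partition_weights builds block projectors", {
  # singleton blocks give the identity
  W <- partition_weights(as.list(1:4), 4)
  expect_equal(unclass(W), diag(4))
  # one block at p = 2: all entries 1/2
  W2 <- partition_weights(list(1:2), 2)
  expect_equal(unclass(W2), matrix(0.5, 2, 2))
  # arbitrary partition: eigenvalues in {0, 1} (sum of rank-1 projectors)
  W3 <- partition_weights(list(c(1, 3), c(2, 5), 4), 5)
  ev <- eigen(unclass(W3), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(abs(ev) < 1e-12 | abs(ev - 1) < 1e-12))
  # membership-vector interface
  W4 <- partition_weights(c("a", "b", "a", "c", "b"), 5)
  expect_equal(unclass(W4), unclass(W3))
  expect_error(partition_weights(list(1:2, 2:3), 3), class = "invalid_partition")
  expect_error(partition_weights(list(1:2), 3), class = "invalid_partition")
})

test_that("tree_weights derives PSD similarities from patristic distances", {
  # star tree, equal branch length b = 0.5: all patristic distances are 1
  star <- "(a:0.5,b:0.5,c:0.5,d:0.5);"
  W <- tree_weights(star, c("a", "b", "c", "d"), bandwidth = 2)
  off <- unclass(W)[upper.tri(W)]
  expect_equal(off, rep(exp(-1 / 2), 6), tolerance = 1e-8)
  expect_equal(diag(unclass(W)), rep(1, 4), ignore_attr = TRUE)
  # bandwidth -> Inf gives the all-ones matrix
  Winf <- tree_weights(star, c("a", "b", "c", "d"), bandwidth = Inf)
  expect_equal(unclass(Winf), matrix(1, 4, 4), ignore_attr = TRUE)
  # two-leaf tree is a valid 2x2 weight matrix
  W2 <- tree_weights("(x:1,y:2);", c("x", "y"), bandwidth = 1)
  expect_s3_class(W2, "weight_matrix")
  expect_equal(dim(W2), c(2L, 2L))
  expect_error(tree_weights(star, c("a", "z"), bandwidth = 1),
               class = "label_mismatch")
  expect_error(tree_weights("(a,b);", c("a", "b"), bandwidth = 1),
               class = "invalid_tree")
})

test_that("weight_matrix validation clips tiny negatives, rejects bad W", {
  expect_error(weight_matrix(matrix(c(1, -0.1, -0.1, 1), 2)),
               class = "invalid_input")
  expect_error(weight_matrix(matrix(c(1, 0.2, 0.4, 1), 2)),
               class = "invalid_input")  # asymmetric
  expect_error(weight_matrix(matrix(c(0, 1, 1, 0), 2)),
               class = "invalid_input")  # indefinite
})

test_that("identity weights reduce to the unweighted kernel", {
  X <- rand_sparse_simplex(10, 5, seed = 31)
  for (fam in c("linear", "prob-js", "prob-hellinger", "prob-tv", "prob-chisq")) {
    spec <- if (fam == "linear") kernel_spec(fam) else kernel_spec(fam)
    wspec <- apply_weights(spec, diag(5))
    expect_equal(gram_matrix(wspec, X), gram_matrix(spec, X),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # aitchison with identity W also reduces (clr' I clr)
  sa <- kernel_spec("aitchison", c = 1e-3)
  expect_equal(gram_matrix(apply_weights(sa, diag(5)), X), gram_matrix(sa, X),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("weighted linear kernel is the W-bilinear form", {
  W <- matrix(0.5, 2, 2)
  spec <- apply_weights(kernel_spec("linear"), W)
  expect_equal(kernel_eval(spec, c(1, 0), c(0, 1)), 0.5)
  expect_error(
    kernel_eval(apply_weights(kernel_spec("linear"), diag(3)), c(1, 0), c(0, 1)),
    class = "invalid_input"
  )
})

test_that("weighted Gram matrices stay PSD for PSD non-negative W", {
  X <- rand_sparse_simplex(40, 6, seed = 33)
  W <- partition_weights(list(1:2, 3:4, 5:6), 6)
  Wt <- tree_weights("((a:1,b:1):1,(c:1,d:1):1,(e:2,f:2):0.5);",
                     letters[1:6], bandwidth = 1.5)
  for (W0 in list(W, Wt)) {
    for (spec in all_family_specs(c_shift = 1e-3)) {
      K <- suppressWarnings(gram_matrix(apply_weights(spec, W0), X))
      ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * max(abs(ev)))
    }
  }
})

test_that("weighted-Aitchison span is block-constant log contrasts", {
  # KRR with partition weights must produce predictions expressible as
  # beta' log(x) with beta constant within blocks and summing to zero
  X <- rand_dense_simplex(40, 6, seed = 35)
  blocks <- list(1:3, 4:5, 6)
  W <- partition_weights(blocks, 6)
  f <- log_contrast_fn(c(1, 1, 1, -1.5, -1.5, 0))
  set.seed(36)
  y <- f(X) + rnorm(40, 0, 0.05)
  m <- krr_fit(X, y, apply_weights(kernel_spec("aitchison", c = 0), W), 1e-4)
  # implied coefficient vector: f(x) - intercept = beta' clr(x) with
  # beta = t(clr(X)) W alpha; check block-constant and zero-sum
  beta <- drop(unclass(W) %*% t(clr_shift(m$train_X, 0)) %*% m$alpha)
  expect_equal(sum(beta), 0, tolerance = 1e-8)
  for (b in blocks) expect_lt(max(beta[b]) - min(beta[b]), 1e-8)
  # predictions coincide with the explicit log-contrast form
  Xn <- rand_dense_simplex(8, 6, seed = 37)
  expect_equal(predict(m, Xn),
               unname(drop(log(unclass(Xn)) %*% beta)) + m$intercept,
               tolerance = 1e-6)
})

test_that("weight matrices round-trip through delimited text", {
  W <- partition_weights(list(1:2, 3:5), 5, component_labels = paste0("sp", 1:5))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_weight_matrix(W, path)
  W2 <- read_weight_matrix(path)
  expect_equal(unclass(W2), unclass(W), tolerance = 1e-12)
})
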
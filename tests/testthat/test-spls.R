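test_that("soft-thresholding follows its definition", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(-0.5, 0.2), -0.3)
  expect_equal(soft_threshold(0.1, 0.2), 0)
  expect_equal(soft_threshold(c(-1, 0, 2), 0.5), c(-0.5, 0, 1.5))
})

test_that("unpenalised one-component fit equals the leading singular vectors", {
  set.seed(61)
  for (i in 1:10) {
    X <- matrix(rnorm(20 * 15), 20, 15,
                dimnames = list(NULL, paste0("x", 1:15)))
    Y <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(NULL, paste0("y", 1:10)))
    fit <- spls_fit(X, Y, spls_config(ncomp = 1))
    sv <- svd(crossprod(scale(X), scale(Y)), nu = 1, nv = 1)
    u <- sv$u[, 1]; if (u[which.max(abs(u))] < 0) u <- -u
    v <- sv$v[, 1]; if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(fit$x_loadings[, 1]), u, tolerance = 1e-8)
    expect_equal(unname(fit$y_loadings[, 1]), v, tolerance = 1e-8)
  }
})

test_that("fitting a block against itself is symmetric", {
  set.seed(62)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("x", 1:8)))
  fit <- spls_fit(X, X, spls_config(ncomp = 1))
  expect_setequal(fit$selected_x[[1]], fit$selected_y[[1]])
  expect_equal(fit$x_scores[, 1], fit$y_scores[, 1], tolerance = 1e-6)
})

test_that("sparsity keeps at most the requested number of loadings", {
  set.seed(63)
  for (i in 1:10) {
    p <- sample(5:15, 1); q <- sample(4:12, 1)
    kx <- sample(seq_len(p), 1); ky <- sample(seq_len(q), 1)
    X <- matrix(rnorm(25 * p), 25, p, dimnames = list(NULL, paste0("x", 1:p)))
    Y <- matrix(rnorm(25 * q), 25, q, dimnames = list(NULL, paste0("y", 1:q)))
    fit <- spls_fit(X, Y, spls_config(ncomp = 2, keep_x = kx, keep_y = ky))
    for (h in 1:2) {
      expect_lte(sum(fit$x_loadings[, h] != 0), kx)
      expect_lte(sum(fit$y_loadings[, h] != 0), ky)
      # unit norm (or degenerate all-zero)
      nu <- sum(fit$x_loadings[, h]^2)
      expect_true(abs(nu - 1) < 1e-8 || nu == 0)
      # sign convention: largest-magnitude entry positive
      expect_gte(fit$x_loadings[which.max(abs(fit$x_loadings[, h])), h], 0)
    }
  }
})

test_that("x scores are mutually orthogonal in regression mode", {
  set.seed(64)
  X <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("x", 1:10)))
  Y <- matrix(rnorm(30 * 9), 30, 9, dimnames = list(NULL, paste0("y", 1:9)))
  fit <- spls_fit(X, Y, spls_config(ncomp = 3, keep_x = 4, keep_y = 4))
  g <- crossprod(fit$x_scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-6 * max(diag(g)))
})

test_that("fit rejects non-conformable or degenerate inputs", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("x1", "x2")))
  Y <- matrix(rnorm(18), 9, 2, dimnames = list(NULL, c("y1", "y2")))
  expect_error(spls_fit(X, Y), "identical ordered sample set")
  Y2 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("y1", "y2")))
  expect_error(spls_fit(X, Y2, spls_config(ncomp = 5)), "ncomp")
  Xc <- X; Xc[, 2] <- 1
  expect_error(spls_fit(Xc, Y2, spls_config(ncomp = 1)), "constant column")
})

test_that("dependency pairs combine selections per component", {
  fit <- fake_spls_fit(c("x1", "x2"), c("y1", "y2"),
                       selected_x = list("x1"), selected_y = list("y2"))
  dep <- dependency_pairs(fit)
  expect_identical(which(dep), which(matrix(c(FALSE, FALSE, TRUE, FALSE), 2)))

  # disjoint components do not create cross terms
  fit <- fake_spls_fit(c("x1", "x2"), c("y1", "y2"),
                       selected_x = list("x1", "x2"),
                       selected_y = list("y1", "y2"))
  dep <- dependency_pairs(fit)
  expect_true(dep["x1", "y1"] && dep["x2", "y2"])
  expect_false(dep["x1", "y2"] || dep["x2", "y1"])

  # full keep on every component marks every pair
  fit <- fake_spls_fit(c("x1", "x2"), c("y1", "y2"),
                       selected_x = list(c("x1", "x2")),
                       selected_y = list(c("y1", "y2")))
  expect_true(all(dependency_pairs(fit)))
})

test_that("association matrix is the dependency-masked Pearson correlation", {
  x <- c(1, 2, 3)
  X <- cbind(x1 = x, x2 = c(5, 1, 4))
  Y <- cbind(y1 = c(6, 4, 2), y2 = x)
  dep <- matrix(TRUE, 2, 2, dimnames = list(colnames(X), colnames(Y)))
  ma <- association_ma(X, Y, dep)
  expect_equal(ma["x1", "y1"], -1)
  expect_equal(ma["x1", "y2"], 1)
  expect_true(all(ma >= -1 & ma <= 1))

  dep["x1", "y2"] <- FALSE
  ma <- association_ma(X, Y, dep)
  expect_identical(ma["x1", "y2"], 0) # exactly zero despite r = 1

  Xz <- cbind(x1 = x, x2 = c(2, 2, 2))
  expect_error(association_ma(Xz, Y, dep), "zero-variance.*x2")

  # zero pattern exactly complements the dependency set
  set.seed(65)
  Xr <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("x", 1:4)))
  Yr <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("y", 1:3)))
  depr <- matrix(runif(12) < 0.5, 4, 3,
                 dimnames = list(colnames(Xr), colnames(Yr)))
  mar <- association_ma(Xr, Yr, depr)
  expect_identical(unname(mar == 0), unname(!depr))
})

test_that("a strongly correlated planted pair is selected under sparsity", {
  set.seed(66)
  hits <- replicate(20, {
    n <- 50
    u <- rnorm(n)
    X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("x", 1:20)))
    Y <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, paste0("y", 1:15)))
    lam <- sqrt(0.9 / (1 - 0.9)) # r = 0.9 against unit noise
    X[, 1] <- lam * u + rnorm(n)
    Y[, 1] <- lam * u + rnorm(n)
    fit <- spls_fit(X, Y, spls_config(ncomp = 1, keep_x = 5, keep_y = 5))
    ("x1" %in% fit$selected_x[[1]]) && ("y1" %in% fit$selected_y[[1]])
  })
  expect_gte(mean(hits), 0.95)
})

test_that("loadings agree with the reference sPLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(67)
  X <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(paste0("s", 1:20), paste0("x", 1:8)))
  Y <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(paste0("s", 1:20), paste0("y", 1:6)))
  mine <- spls_fit(X, Y, spls_config(ncomp = 2, keep_x = 3, keep_y = 4,
                                     tol = 1e-12, max_iter = 10000))
  ref <- mixOmics::spls(X, Y, ncomp = 2, keepX = c(3, 3), keepY = c(4, 4),
                        mode = "regression", scale = TRUE,
                        tol = 1e-12, max.iter = 10000)
  for (h in 1:2) {
    a <- mine$x_loadings[, h]; b <- ref$loadings$X[, h]
    if (sum(a * b) < 0) b <- -b
    expect_equal(unname(a), unname(b), tolerance = 1e-4)
    av <- mine$y_loadings[, h]; bv <- ref$loadings$Y[, h]
    if (sum(av * bv) < 0) bv <- -bv
    expect_equal(unname(av), unname(bv), tolerance = 1e-4)
  }
})
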
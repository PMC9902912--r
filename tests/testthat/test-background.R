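test_that("sample covariance matches a hand computation on 4 listed vectors", {
  x <- rbind(c(1, 2), c(3, 0), c(5, 4), c(7, 2))
  # hand calculation: means (4, 2); deviations (-3,0),(-1,-2),(1,2),(3,0)
  # Sxx = 20, Sxy = 4, Syy = 8; divide by n - 1 = 3
  bg <- background_model_from_voxels(x)
  expect_equal(bg$mu, c(4, 2), ignore_attr = TRUE)
  expect_equal(unname(bg$cm), matrix(c(20, 4, 4, 8), 2) / 3,
               tolerance = 1e-12)
  # eigen-decomposition reconstructs the covariance
  rec <- bg$eigenvectors %*% diag(bg$eigenvalues) %*% t(bg$eigenvectors)
  expect_lt(norm(rec - unname(bg$cm), "F") / norm(bg$cm, "F"), 1e-10)
})

test_that("too few voxels or a degenerate background is handled", {
  expect_error(background_model_from_voxels(matrix(1:6, 2, 3)),
               "fewer background voxels")
  same <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  bg <- background_model_from_voxels(same)
  expect_equal(unname(bg$cm), matrix(0, 3, 3))
  expect_error(scr(c(2, 2, 2), bg), "singular")
  expect_error(pc_filtered_inverse(bg, 1L), "eigenvalue")
})

test_that("covariance of many Gaussian draws approaches the truth", {
  set.seed(31)
  b <- 5
  sigma <- random_spd(b)
  z <- matrix(rnorm(1e4 * b), ncol = b) %*% chol(sigma)
  bg <- background_model_from_voxels(z)
  expect_lt(norm(bg$cm - sigma, "F") / norm(sigma, "F"), 0.05)
})

test_that("pc_filtered_inverse matches the dense inverse with nothing removed", {
  set.seed(5)
  for (rep in 1:5) {
    sigma <- random_spd(6)
    bg <- background_model_from_voxels(
      matrix(rnorm(600), ncol = 6) %*% chol(sigma))
    expect_lt(max(abs(pc_filtered_inverse(bg, 0L) - solve(bg$cm))), 1e-10)
  }
})

test_that("pc_filtered_inverse equals the spectral oracle with components removed", {
  set.seed(6)
  for (k_rm in 0:4) {
    sigma <- random_spd(6)
    bg <- background_model_from_voxels(
      matrix(rnorm(900), ncol = 6) %*% chol(sigma))
    # oracle via SVD (symmetric PSD: singular pairs = eigenpairs)
    sv <- svd(bg$cm)
    keep <- seq_len(6 - k_rm)
    oracle <- sv$u[, keep, drop = FALSE] %*%
      diag(1 / sv$d[keep], length(keep)) %*% t(sv$u[, keep, drop = FALSE])
    expect_lt(max(abs(pc_filtered_inverse(bg, k_rm) - oracle)), 1e-8)
  }
  bg <- background_model_from_voxels(matrix(rnorm(40), ncol = 2))
  expect_error(pc_filtered_inverse(bg, 2L), "at least one")
})

test_that("diagonal toy case: removing the small component leaves 1/4 e1 e1^T", {
  bg <- structure(list(mu = c(0, 0), cm = diag(c(4, 1)),
                       eigenvalues = c(4, 1), eigenvectors = diag(2),
                       n_voxels = 100, band_names = c("a", "b")),
                  class = "background_model")
  expect_equal(pc_filtered_inverse(bg, 1L),
               matrix(c(0.25, 0, 0, 0), 2), tolerance = 1e-14)
})

test_that("regularization closed forms and trace preservation hold", {
  set.seed(8)
  for (rep in 1:20) {
    cm <- random_spd(5)
    expect_equal(regularize(cm, "standard", 0), cm, tolerance = 1e-14)
    expect_equal(regularize(cm, "modified", 0), cm, tolerance = 1e-14)
    expect_equal(regularize(cm, "standard", 1),
                 diag(sum(diag(cm)) / 5, 5), tolerance = 1e-12)
    expect_equal(regularize(cm, "modified", 1), diag(diag(cm), 5),
                 tolerance = 1e-12)
    for (g in c(0.15, 0.5, 0.85)) {
      expect_equal(sum(diag(regularize(cm, "standard", g))),
                   sum(diag(cm)), tolerance = 1e-10)
      expect_equal(sum(diag(regularize(cm, "modified", g))),
                   sum(diag(cm)), tolerance = 1e-10)
    }
  }
  expect_error(regularize(random_spd(3), "standard", 1.2), "gamma")
})

test_that("scr matches direct linear algebra in every inverse mode", {
  set.seed(9)
  b <- 5
  sigma <- random_spd(b)
  x <- matrix(rnorm(400 * b), ncol = b) %*% chol(sigma)
  bg <- background_model_from_voxels(x)
  s <- bg$mu + rnorm(b)
  d <- s - bg$mu
  modes <- list(
    inverse_spec("full"),
    inverse_spec("pc_filtered", k_removed = 2L),
    inverse_spec("regularized", gamma = 0.3),
    inverse_spec("modified_regularized", gamma = 0.3))
  oracles <- list(
    solve(bg$cm),
    {
      eg <- eigen(bg$cm, symmetric = TRUE)
      eg$vectors[, 1:3] %*% diag(1 / eg$values[1:3]) %*% t(eg$vectors[, 1:3])
    },
    solve(0.7 * bg$cm + 0.3 * diag(mean(diag(bg$cm)), b)),
    solve(0.7 * bg$cm + 0.3 * diag(diag(bg$cm), b)))
  for (i in seq_along(modes)) {
    expect_equal(scr(s, bg, modes[[i]]),
                 sqrt(drop(t(d) %*% oracles[[i]] %*% d)), tolerance = 1e-10)
  }
  # identity-covariance Euclidean case and the zero case
  bg_id <- structure(list(mu = rep(0, 4), cm = diag(4),
                          eigenvalues = rep(1, 4), eigenvectors = diag(4),
                          n_voxels = 100, band_names = paste0("b", 1:4)),
                     class = "background_model")
  expect_equal(scr(c(3, 4, 0, 0), bg_id), 5, tolerance = 1e-12)
  expect_equal(scr(rep(0, 4), bg_id), 0)
  expect_equal(scr(c(3, 4, 0, 0), bg_id, squared = TRUE), 25,
               tolerance = 1e-12)
})

test_that("scr is non-increasing as more principal components are removed", {
  set.seed(10)
  for (rep in 1:25) {
    b <- sample(4:7, 1)
    sigma <- random_spd(b)
    x <- matrix(rnorm((20 * b) * b), ncol = b) %*% chol(sigma)
    bg <- background_model_from_voxels(x)
    s <- bg$mu + rnorm(b, sd = 2)
    vals <- vapply(0:(b - 1), function(k)
      scr(s, bg, inverse_spec("pc_filtered", k_removed = k)), numeric(1))
    expect_true(all(diff(vals) <= 1e-10))
  }
})

test_that("standard shrinkage endpoints and continuity in gamma", {
  set.seed(12)
  sigma <- random_spd(6)
  x <- matrix(rnorm(1200), ncol = 6) %*% chol(sigma)
  bg <- background_model_from_voxels(x)
  s <- bg$mu + rnorm(6)
  d <- s - bg$mu
  expect_equal(scr(s, bg, inverse_spec("regularized", gamma = 1)),
               sqrt(sum(d^2)) * sqrt(6 / sum(diag(bg$cm))),
               tolerance = 1e-10)
  gs <- seq(0, 1, by = 0.02)
  vals <- vapply(gs, function(g)
    scr(s, bg, inverse_spec("regularized", gamma = g)), numeric(1))
  expect_true(all(abs(diff(vals)) < 0.25 * max(vals)))  # no jumps
})

test_that("whitening identity: full-inverse SCR^2 equals whitened norm", {
  set.seed(13)
  sigma <- random_spd(5)
  x <- matrix(rnorm(1000), ncol = 5) %*% chol(sigma)
  bg <- background_model_from_voxels(x)
  s <- bg$mu + rnorm(5)
  w <- backsolve(chol(bg$cm), s - bg$mu, transpose = TRUE)
  expect_equal(scr(s, bg, squared = TRUE), sum(w^2), tolerance = 1e-10)
})

test_that("background Mahalanobis distances follow chi-square under the true CM", {
  set.seed(14)
  b <- 6
  sigma <- random_spd(b)
  x <- matrix(rnorm(1e4 * b), ncol = b) %*% chol(sigma)
  ch <- chol(sigma)
  d2 <- colSums(backsolve(ch, t(x), transpose = TRUE)^2)
  expect_gt(stats::ks.test(d2, "pchisq", df = b)$p.value, 0.01)
})

test_that("gamma selection favors tiny shrinkage for a clean Gaussian background", {
  set.seed(15)
  b <- 5
  sigma <- random_spd(b)
  x <- matrix(rnorm(2e4 * b), ncol = b) %*% chol(sigma)
  bg <- background_model_from_voxels(x)
  sel <- select_gamma(bg, x, "standard")
  expect_lte(sel$gamma, 0.05)
  # reproducible: same inputs give the same gamma
  sel2 <- select_gamma(bg, x, "standard")
  expect_identical(sel$gamma, sel2$gamma)
})

test_that("a rank-deficient covariance forces positive shrinkage", {
  set.seed(16)
  b <- 7
  sigma <- random_spd(b, jitter = 0.01)
  x <- matrix(rnorm(80 * b), ncol = b) %*% chol(sigma)
  x[, b] <- x[, 1]   # exact collinearity: CM singular at gamma = 0
  bg <- background_model_from_voxels(x)
  expect_message(sel <- select_gamma(bg, x, "modified"), "skipped")
  expect_gt(sel$gamma, 0)
  expect_true(is.na(sel$path$ks[1]))
})
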
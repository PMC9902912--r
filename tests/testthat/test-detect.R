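# small helper: build a cube+mask whose masked voxels are the given matrix
cube_from_voxels <- function(x) {
  n <- nrow(x); b <- ncol(x)
  dims <- c(n, 1, 1)
  vals <- array(0, c(dims, b))
  for (j in seq_len(b)) vals[, 1, 1, j] <- x[, j]
  list(cube = hypercube(vals, c(1, 1, 6), paste0("b", seq_len(b))),
       mask = prostate_mask(array(1L, dims)))
}

test_that("ACE scores match the dense quadratic-form oracle", {
  set.seed(21)
  for (rep in 1:10) {
    b <- sample(4:7, 1)
    sigma <- random_spd(b)
    xbg <- matrix(rnorm(300 * b), ncol = b) %*% chol(sigma)
    bg <- background_model_from_voxels(xbg)
    s <- bg$mu + rnorm(b)
    x <- matrix(rnorm(50 * b, sd = 2), ncol = b)
    cm <- cube_from_voxels(sweep(x, 2, bg$mu, `+`))
    am <- ace_map(cm$cube, cm$mask, s, bg)
    ginv <- solve(bg$cm)
    for (i in seq_len(50)) {
      expect_equal(am$scores[i, 1, 1],
                   ace_formula(x[i, ] + bg$mu, s, bg$mu, ginv),
                   tolerance = 1e-12)
    }
    expect_true(all(am$scores >= 0 & am$scores <= 1))
  }
})

test_that("whitened-collinear voxels score 1 and orthogonal voxels score 0", {
  set.seed(22)
  b <- 5
  sigma <- random_spd(b)
  bg <- background_model_from_voxels(
    matrix(rnorm(500 * b), ncol = b) %*% chol(sigma))
  s <- bg$mu + rnorm(b)
  ds <- s - bg$mu
  # collinear: x = mu + c * (s - mu), any c != 0
  xc <- rbind(bg$mu + 2.7 * ds, bg$mu - 0.4 * ds)
  # whitened-orthogonal: pick v with ds' CM^-1 v = 0
  g <- solve(bg$cm)
  v <- rnorm(b)
  v <- v - ds * drop(t(ds) %*% g %*% v) / drop(t(ds) %*% g %*% ds)
  cm <- cube_from_voxels(rbind(xc, bg$mu + v))
  am <- ace_map(cm$cube, cm$mask, s, bg)
  expect_equal(am$scores[1, 1, 1], 1, tolerance = 1e-10)
  expect_equal(am$scores[2, 1, 1], 1, tolerance = 1e-10)
  expect_equal(am$scores[3, 1, 1], 0, tolerance = 1e-10)
})

test_that("ACE is invariant to invertible linear band re-mixing", {
  set.seed(23)
  b <- 5
  sigma <- random_spd(b)
  xbg <- matrix(rnorm(400 * b), ncol = b) %*% chol(sigma)
  x <- matrix(rnorm(30 * b, sd = 1.5), ncol = b)
  s <- rnorm(b, sd = 2)
  for (rep in 1:5) {
    a <- matrix(rnorm(b * b), b) + diag(b)  # invertible w.h.p.
    bg1 <- background_model_from_voxels(xbg)
    bg2 <- background_model_from_voxels(xbg %*% t(a))
    c1 <- cube_from_voxels(x)
    c2 <- cube_from_voxels(x %*% t(a))
    a1 <- ace_map(c1$cube, c1$mask, s, bg1)
    a2 <- ace_map(c2$cube, c2$mask, drop(a %*% s), bg2)
    expect_equal(a2$scores, a1$scores, tolerance = 1e-8)
  }
})

test_that("thresholding semantics: corner contact merges only at 26-connectivity", {
  sc <- array(0, c(4, 4, 2))
  sc[1, 1, 1] <- 0.9
  sc[2, 2, 2] <- 0.9   # touches the first only at a corner
  am <- structure(list(scores = sc, spacing_mm = c(1, 1, 6)),
                  class = "ace_map")
  expect_equal(nrow(threshold_blobs(am, 0.5, 26L)$blobs), 1L)
  expect_equal(nrow(threshold_blobs(am, 0.5, 6L)$blobs), 2L)
  # everything below the threshold: empty detection is allowed
  expect_equal(nrow(threshold_blobs(am, 0.95, 26L)$blobs), 0L)
  expect_error(threshold_blobs(am, 1.2), "tau")
})

test_that("component counts agree with a brute-force flood fill", {
  set.seed(24)
  for (rep in 1:6) {
    bin <- array(runif(20 * 20 * 5) < 0.25, c(20, 20, 5))
    am <- structure(list(scores = bin * 0.9, spacing_mm = c(1, 1, 6)),
                    class = "ace_map")
    for (conn in c(6L, 26L)) {
      bs <- threshold_blobs(am, 0.5, conn)
      expect_equal(nrow(bs$blobs), flood_fill_count(bin, conn))
      expect_equal(sum(bs$blobs$n_voxels), sum(bin))
    }
  }
})

test_that("blob-voxel total is non-increasing in the threshold", {
  set.seed(25)
  sc <- array(runif(15 * 15 * 4), c(15, 15, 4))
  am <- structure(list(scores = sc, spacing_mm = c(1, 1, 6)),
                  class = "ace_map")
  tot <- vapply(seq(0.1, 0.9, by = 0.1), function(tau)
    sum(threshold_blobs(am, tau)$blobs$n_voxels), numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("volume conversion is voxel count times voxel size", {
  sc <- array(0, c(10, 10, 4))
  sc[1:5, 1:10, 1:2] <- 0.9   # 100 voxels
  am <- structure(list(scores = sc, spacing_mm = c(1, 1, 6)),
                  class = "ace_map")
  bs <- threshold_blobs(am, 0.5)
  expect_equal(total_volume_cc(bs), 0.6, tolerance = 1e-12)
  empty <- threshold_blobs(am, 0.95)
  expect_equal(total_volume_cc(empty), 0)
})

test_that("digital ball volume approaches the analytic sphere volume", {
  ball <- digital_ball(12)
  vol_mm3 <- nrow(ball$vox) * 1      # 1 mm isotropic voxels
  expect_lt(abs(vol_mm3 - 4 / 3 * pi * 12^3) / (4 / 3 * pi * 12^3), 0.02)
})

test_that("eccentricity endpoints: ball -> 0, axis-aligned segment -> 1", {
  ball <- digital_ball(6)
  e_ball <- eccentricity(ball$vox, c(1, 1, 1))
  expect_equal(e_ball$e, 0, tolerance = 1e-10)
  seg <- cbind(1:20, rep(1, 20), rep(1, 20))
  e_seg <- eccentricity(seg, c(1, 1, 1))
  expect_equal(e_seg$e, 1, tolerance = 1e-12)
  expect_equal(e_seg$s, 0, tolerance = 1e-12)
  # single voxel: 0 by convention; empty blob errors
  expect_equal(eccentricity(cbind(3, 3, 3), c(1, 1, 6))$e, 0)
  expect_error(eccentricity(matrix(0, 0, 3), c(1, 1, 1)), "empty")
})

test_that("filled in-plane ellipse matches the analytic eccentricity", {
  g <- expand.grid(x = -15:15, y = -15:15)
  inside <- (g$x / 10)^2 + (g$y / 5)^2 <= 1
  vox <- cbind(g$x[inside] + 16, g$y[inside] + 16, 1)
  e <- eccentricity(vox, c(1, 1, 1))
  expect_equal(e$e, sqrt(1 - 25 / 100), tolerance = 0.02)
})

test_that("eccentricity is rotation-invariant in-plane and scale-invariant", {
  g <- expand.grid(x = seq(-12, 12, by = 0.5), y = seq(-12, 12, by = 0.5))
  base <- function(th) {
    xr <- g$x * cos(th) + g$y * sin(th)
    yr <- -g$x * sin(th) + g$y * cos(th)
    inside <- (xr / 9)^2 + (yr / 4)^2 <= 1
    cbind(g$x[inside], g$y[inside], 0)
  }
  e0 <- eccentricity(base(0), c(1, 1, 1))$e
  for (th in c(pi / 7, pi / 3, 1.2)) {
    expect_equal(eccentricity(base(th), c(1, 1, 1))$e, e0, tolerance = 0.03)
  }
  # uniform scaling leaves eccentricity exactly unchanged
  v <- base(0.4)
  expect_equal(eccentricity(v * 3, c(1, 1, 1))$e,
               eccentricity(v, c(1, 1, 1))$e, tolerance = 1e-12)
  expect_equal(eccentricity(v, c(2, 2, 2))$e,
               eccentricity(v, c(1, 1, 1))$e, tolerance = 1e-12)
})

test_that("largest blob picks maximum voxel count with stable tie-breaking", {
  sc <- array(0, c(12, 6, 2))
  sc[1:2, 1:5, 1] <- 0.9       # 10 voxels, scan-order first
  sc[6:10, 1:5, 1] <- 0.9      # 25 voxels
  am <- structure(list(scores = sc, spacing_mm = c(1, 1, 6)),
                  class = "ace_map")
  bs <- threshold_blobs(am, 0.5)
  expect_equal(largest_blob(bs)$n_voxels, 25L)
  # tie: equal sizes -> lowest label
  sc2 <- array(0, c(12, 6, 2))
  sc2[1:2, 1:5, 1] <- 0.9
  sc2[6:7, 1:5, 1] <- 0.9
  bs2 <- threshold_blobs(structure(list(scores = sc2,
                                        spacing_mm = c(1, 1, 6)),
                                   class = "ace_map"), 0.5)
  expect_equal(largest_blob(bs2)$label, 1L)
  empty <- threshold_blobs(am, 0.95)
  expect_error(largest_blob(empty), "no detection")
})
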
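#' Synthetic cohort parameters
#'
#' Describes a cohort of synthetic patients carrying the statistical
#' structure the downstream analysis assumes: a multivariate-normal
#' normal-prostate background with correlated band statistics on a
#' 1 x 1 mm in-plane / 6 mm slice grid, an ellipsoidal tumor of
#' controllable volume, axis ratio (hence eccentricity) and spectral
#' contrast, a DCE washout rate, and a clinically-significant-cancer label
#' drawn from a logistic model on the true (generator-side) features.
#'
#' The default band list carries seven components: T1 pre-contrast, T1 at
#' maximum contrast, T2, ADC, high-b diffusion, the DCE washout rate kep,
#' plus a spare channel (acquisitions routinely carry an extra derived
#' channel; six modalities are named, the seventh is generic).
#'
#' @param n_patients number of patients (>= 1).
#' @param bands character vector of band names (default 7 bands).
#' @param spacing_mm voxel spacing, default `c(1, 1, 6)` mm.
#' @param prostate_semi_axes_mm semi-axes of the prostate ellipsoid.
#' @param background_mean,background_cov background band means and a
#'   symmetric positive-definite covariance (defaults: plausible
#'   intensities with AR(1)-correlated bands).
#' @param tumor_signature_offset spectral contrast added inside the tumor
#'   (band units); per patient it is scaled by a random factor in
#'   `contrast_scale_range`, which spreads the true SCR across the cohort.
#' @param contrast_scale_range interval for the per-patient contrast
#'   multiplier.
#' @param tumor_volume_range_cc interval of true tumor volumes.
#' @param tumor_axis_ratio_range interval of major:transverse axis ratios
#'   `q` (prolate tumor, so true eccentricity is `sqrt(1 - 1/q^2)`).
#' @param dce_time_grid_s DCE sampling grid (seconds).
#' @param kep_range_per_min interval of tumor washout rates (per minute);
#'   normal tissue uses `kep_background_per_min`.
#' @param kep_background_per_min washout rate of normal tissue.
#' @param label_coefficients named vector `(b0, b_ecc, b_scr, b_vol)` of
#'   the logistic label model on the true features; defaults give a
#'   generating-probability AUC near 0.9 at moderate prevalence.
#' @param background_df degrees of freedom for a heavier-tailed
#'   (multivariate-t) background; `Inf` (default) is Gaussian.
#' @param seed cohort seed; per-patient seeds are derived from it by a
#'   fixed counter so each patient is independently reproducible.
#' @return Object of class `"cohort_params"`.
#' @export
cohort_params <- function(n_patients = 25,
                          bands = c("t1_pre", "t1_max", "t2", "adc",
                                    "dwi_b1000", "kep", "spare"),
                          spacing_mm = c(1, 1, 6),
                          prostate_semi_axes_mm = c(22, 17, 15),
                          background_mean = NULL,
                          background_cov = NULL,
                          tumor_signature_offset = NULL,
                          contrast_scale_range = c(0.6, 1.8),
                          tumor_volume_range_cc = c(0.5, 3),
                          tumor_axis_ratio_range = c(1.15, 3.5),
                          dce_time_grid_s = seq(0, 300, by = 15),
                          kep_range_per_min = c(0.3, 1.5),
                          kep_background_per_min = 0.35,
                          label_coefficients = NULL,
                          background_df = Inf,
                          seed = 1L) {
  b <- length(bands)
  if (is.null(background_mean)) {
    background_mean <- default_band_stats(b)$mean
  }
  if (is.null(background_cov)) {
    background_cov <- default_band_stats(b)$cov
  }
  if (is.null(tumor_signature_offset)) {
    tumor_signature_offset <- default_band_stats(b)$offset
  }
  if (is.null(label_coefficients)) {
    # calibrated once so the oracle AUC (from true generating
    # probabilities) sits near 0.9 with prevalence near one half
    label_coefficients <- c(b0 = -19.5, b_ecc = 9.0, b_scr = 1.7,
                            b_vol = 2.5)
  }
  stopifnot(length(background_mean) == b,
            all(dim(background_cov) == c(b, b)),
            length(tumor_signature_offset) == b)
  if (max(abs(background_cov - t(background_cov))) > 1e-10) {
    stop("background_cov must be symmetric", call. = FALSE)
  }
  if (min(eigen(background_cov, symmetric = TRUE,
                only.values = TRUE)$values) <= 0) {
    stop("background_cov must be positive-definite", call. = FALSE)
  }
  if (any(spacing_mm <= 0)) stop("spacing must be positive", call. = FALSE)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  structure(
    list(n_patients = as.integer(n_patients), bands = bands,
         spacing_mm = spacing_mm,
         prostate_semi_axes_mm = prostate_semi_axes_mm,
         background_mean = background_mean,
         background_cov = background_cov,
         tumor_signature_offset = tumor_signature_offset,
         contrast_scale_range = contrast_scale_range,
         tumor_volume_range_cc = tumor_volume_range_cc,
         tumor_axis_ratio_range = tumor_axis_ratio_range,
         dce_time_grid_s = dce_time_grid_s,
         kep_range_per_min = kep_range_per_min,
         kep_background_per_min = kep_background_per_min,
         label_coefficients = label_coefficients,
         background_df = background_df,
         seed = as.integer(seed)),
    class = "cohort_params")
}

default_band_stats <- function(b) {
  mean7 <- c(5, 9, 7, 12, 6, 0.6, 1)
  sd7 <- c(0.8, 1.2, 1.0, 1.5, 0.9, 0.12, 0.3)
  # tumors: mild T1 enhancement, darker T2, restricted diffusion (low ADC,
  # high DWI), faster washout; the spare channel carries no contrast
  off7 <- c(0.5, 1.5, -1.2, -2.0, 1.4, 0.25, 0)
  mu <- rep_len(mean7, b); sd <- rep_len(sd7, b); off <- rep_len(off7, b)
  if (b == 7) off[7] <- 0
  rho <- 0.4 ^ abs(outer(seq_len(b), seq_len(b), `-`))
  list(mean = mu, cov = diag(sd) %*% rho %*% diag(sd), offset = off)
}

patient_seed_for <- function(cohort_seed, i) {
  as.integer((as.numeric(cohort_seed) + 104729 * i) %% 2147483629)
}

# draws the per-patient tumor truth (geometry, contrast, washout) from the
# current RNG stream; shared by the image-level and feature-level generators
draw_tumor_truth <- function(params) {
  pa <- params$prostate_semi_axes_mm
  vol_cc <- stats::runif(1, params$tumor_volume_range_cc[1],
                         params$tumor_volume_range_cc[2])
  q <- stats::runif(1, params$tumor_axis_ratio_range[1],
                    params$tumor_axis_ratio_range[2])
  # feasibility: the major semi-axis a = q^(2/3) * (3V/4pi)^(1/3) must fit
  # inside the organ; large tumors are capped to a rounder shape, and a
  # volume too large for even a sphere is an error
  c0 <- (3 * vol_cc * 1000 / (4 * pi))^(1 / 3)
  a_max <- min(pa) - 1
  if (c0 >= a_max) stop("tumor exceeds organ", call. = FALSE)
  q_max <- (a_max / c0)^(3 / 2)
  q <- max(min(q, 0.99 * q_max), 1)
  bax <- (3 * vol_cc * 1000 / (4 * pi * q))^(1 / 3)
  semi <- c(q * bax, bax, bax)
  contrast <- stats::runif(1, params$contrast_scale_range[1],
                           params$contrast_scale_range[2])
  offset <- contrast * params$tumor_signature_offset
  kep_t <- stats::runif(1, params$kep_range_per_min[1],
                        params$kep_range_per_min[2])
  sig_inv <- solve(params$background_cov)
  list(vol_cc = 4 / 3 * pi * prod(semi) / 1000, semi = semi,
       ecc = sqrt(1 - (semi[2] / semi[1])^2),
       contrast = contrast, offset = offset, kep = kep_t,
       scr = sqrt(drop(t(offset) %*% sig_inv %*% offset)))
}

#' Simulate one synthetic patient
#'
#' Draws a registered hypercube and truth mask: background voxels inside
#' the prostate ellipsoid are multivariate-normal draws with the
#' configured mean and covariance (or multivariate-t when
#' `background_df < Inf`); a solid tumor ellipsoid, rasterized at the grid
#' spacing, additionally carries the (scaled) signature offset; voxels
#' outside the organ are zero. Deterministic given `(params, patient_seed)`.
#'
#' @param params A [cohort_params()].
#' @param patient_seed integer seed for this patient.
#' @return A list with elements `cube` ([hypercube()]), `mask`
#'   ([prostate_mask()]) and `truth` (tibble row: center voxel, semi-axes,
#'   true volume/eccentricity/kep, contrast scale, true SCR under the
#'   generating covariance).
#' @export
simulate_patient <- function(params, patient_seed) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(patient_seed)
  sp <- params$spacing_mm
  pa <- params$prostate_semi_axes_mm
  margin <- 4
  dims <- c(ceiling(2 * (pa[1] + margin) / sp[1]),
            ceiling(2 * (pa[2] + margin) / sp[2]),
            ceiling(2 * (pa[3] + margin) / sp[3]))
  center <- (dims - 1) / 2 * sp
  w1 <- ((seq_len(dims[1]) - 1) * sp[1] - center[1]) / pa[1]
  w2 <- ((seq_len(dims[2]) - 1) * sp[2] - center[2]) / pa[2]
  w3 <- ((seq_len(dims[3]) - 1) * sp[3] - center[3]) / pa[3]
  r2 <- outer(outer(w1^2, w2^2, `+`), w3^2, `+`)
  labels <- array(0L, dims)
  labels[r2 <= 1] <- 1L

  # tumor geometry: prolate ellipsoid, axis ratio q = major / transverse
  tt <- draw_tumor_truth(params)
  semi <- tt$semi
  if (max(semi) >= min(pa)) stop("tumor exceeds organ", call. = FALSE)
  # place the center so the tumor's bounding sphere stays inside the organ
  for (try in 1:200) {
    u <- stats::runif(3, -0.5, 0.5)
    ctr <- center + u * pa
    lim <- 1 - max(semi) / min(pa)
    if (sqrt(sum((u)^2)) <= lim) break
    if (try == 200) ctr <- center
  }
  # random orientation of the major axis within the axial plane (keeps the
  # rasterization well-sampled at 6 mm slices)
  th <- stats::runif(1, 0, pi)
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  wx <- (seq_len(dims[1]) - 1) * sp[1]
  wy <- (seq_len(dims[2]) - 1) * sp[2]
  wz <- (seq_len(dims[3]) - 1) * sp[3]
  grid <- expand.grid(x = wx, y = wy, z = wz)
  rel <- t(rot) %*% rbind(grid$x - ctr[1], grid$y - ctr[2], grid$z - ctr[3])
  inside_t <- (rel[1, ] / semi[1])^2 + (rel[2, ] / semi[2])^2 +
    (rel[3, ] / semi[3])^2 <= 1
  tum <- array(inside_t, dims) & labels == 1L
  labels[tum] <- 2L

  b <- length(params$bands)
  offset <- tt$offset

  inmask <- labels > 0L
  n_in <- sum(inmask)
  ch <- chol(params$background_cov)
  z <- matrix(stats::rnorm(n_in * b), n_in, b)
  if (is.finite(params$background_df)) {
    g <- stats::rchisq(n_in, df = params$background_df) / params$background_df
    z <- z / sqrt(g)
  }
  vox <- z %*% ch
  vox <- sweep(vox, 2, params$background_mean, `+`)
  vox[labels[inmask] == 2L, ] <-
    sweep(vox[labels[inmask] == 2L, , drop = FALSE], 2, offset, `+`)
  values <- array(0, c(dims, b))
  flat <- matrix(values, ncol = b)
  flat[as.vector(inmask), ] <- vox
  values <- array(flat, c(dims, b))

  cube <- hypercube(values, sp, params$bands)
  mask <- prostate_mask(labels)
  truth <- tibble::tibble(
    center_voxel_x = ctr[1] / sp[1] + 1, center_voxel_y = ctr[2] / sp[2] + 1,
    center_voxel_z = ctr[3] / sp[3] + 1,
    semi_a_mm = semi[1], semi_b_mm = semi[2], semi_c_mm = semi[3],
    true_volume_cc = tt$vol_cc,
    true_eccentricity = tt$ecc,
    contrast_scale = tt$contrast,
    true_scr = tt$scr,
    true_kep_per_min = tt$kep,
    n_tumor_voxels = sum(labels == 2L),
    n_background_voxels = sum(labels == 1L))
  if (truth$n_tumor_voxels == 0L) stop("tumor rasterized to zero voxels",
                                       call. = FALSE)
  list(cube = cube, mask = mask, truth = truth)
}

#' Simulate a full cohort with clinically-significant-cancer labels
#'
#' Generates `n_patients` independent patients (per-patient seeds derived
#' from the cohort seed by a fixed counter) and draws each CsPCa label
#' Bernoulli with probability `plogis(b0 + b_ecc * Ecc + b_scr * SCR +
#' b_vol * Vol)` evaluated on the TRUE generator-side features — so
#' measurement error in the pipeline attenuates, never inflates, the
#' recovered discrimination. Optionally writes per-patient 4-D NIfTI
#' hypercubes, 3-D truth masks, a cohort truth table CSV and a JSON
#' parameter sidecar.
#'
#' @param params A [cohort_params()].
#' @param dir optional output directory; when `NULL` everything stays
#'   in memory.
#' @param keep_images keep the per-patient cube/mask objects in the
#'   returned bundle (default `TRUE`; set `FALSE` for large cohorts when
#'   only features are needed downstream — images are regenerated on
#'   demand from the per-patient seed).
#' @return A list of class `"cohort_bundle"`: `truth` (tibble with one row
#'   per patient incl. `p_cspca` and `cspca`), `patients` (list, possibly
#'   `NULL` elements when `keep_images = FALSE`), `params`.
#' @export
simulate_cohort <- function(params, dir = NULL, keep_images = TRUE) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_patients
  patients <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- patient_seed_for(params$seed, i)
    p <- simulate_patient(params, ps)
    rows[[i]] <- dplyr::mutate(p$truth, patient_id = i,
                               patient_seed = ps, .before = 1)
    if (keep_images) patients[[i]] <- p
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_hypercube(p$cube,
                      file.path(dir, sprintf("patient%03d_cube.nii.gz", i)))
      write_mask(p$mask,
                 file.path(dir, sprintf("patient%03d_mask.nii.gz", i)))
    }
  }
  truth <- attach_labels(dplyr::bind_rows(rows), params)
  if (!is.null(dir)) {
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(bands = params$bands, spacing_mm = params$spacing_mm,
           seed = params$seed,
           label_coefficients = as.list(params$label_coefficients)),
      file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(truth = truth, patients = patients, params = params),
            class = "cohort_bundle")
}

# CsPCa labels: Bernoulli draws from the logistic model on true features,
# using a dedicated label RNG stream (counter 0) so labels do not perturb
# the per-patient image streams
attach_labels <- function(truth, params) {
  co <- params$label_coefficients
  set.seed(patient_seed_for(params$seed, 0L))
  eta <- co[1] + co[2] * truth$true_eccentricity +
    co[3] * truth$true_scr + co[4] * truth$true_volume_cc
  truth$p_cspca <- stats::plogis(eta)
  truth$cspca <- as.integer(stats::runif(nrow(truth)) < truth$p_cspca)
  truth
}

#' Feature-level view of the cohort generator
#'
#' Draws the TRUE per-patient features (volume, eccentricity, spectral
#' contrast, SCR under the generating covariance, washout rate) and the
#' CsPCa labels without rasterizing any images. Uses the same per-patient
#' seeds and the same truth draws as [simulate_cohort()], so the returned
#' rows match that function's truth table exactly; it exists for
#' large-sample experiments on the label model where voxel data is not
#' needed.
#'
#' @param params A [cohort_params()].
#' @return Tibble with one row per patient: `patient_id`, `patient_seed`,
#'   true features, `p_cspca`, `cspca`.
#' @export
simulate_truth_table <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  rows <- lapply(seq_len(params$n_patients), function(i) {
    ps <- patient_seed_for(params$seed, i)
    set.seed(ps)
    tt <- draw_tumor_truth(params)
    tibble::tibble(patient_id = i, patient_seed = ps,
                   true_volume_cc = tt$vol_cc,
                   true_eccentricity = tt$ecc,
                   contrast_scale = tt$contrast,
                   true_scr = tt$scr,
                   true_kep_per_min = tt$kep)
  })
  attach_labels(dplyr::bind_rows(rows), params)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d patients, prevalence %.2f\n",
              nrow(x$truth), mean(x$truth$cspca)))
  invisible(x)
}
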
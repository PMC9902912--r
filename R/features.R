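#' Clinically significant prostate cancer from the Gleason pattern pair
#'
#' A tumor is clinically significant (CsPCa = 1) when its Gleason pattern
#' pair is at least 4+3 in the primary-then-sum ordering; 3+4 and below are
#' clinically insignificant. The asymmetry between 3+4 and 4+3 (equal sums)
#' is intentional: a dominant pattern-4 component carries higher risk.
#'
#' @param gleason_primary,gleason_secondary integer pattern grades in
#'   `{3, 4, 5}` (vectorized).
#' @return Integer vector of 0/1 labels.
#' @export
label_cspca <- function(gleason_primary, gleason_secondary) {
  p <- as.integer(gleason_primary); s <- as.integer(gleason_secondary)
  if (any(!(p %in% 3:5)) || any(!(s %in% 3:5))) {
    stop("Gleason pattern grades must lie in {3, 4, 5}", call. = FALSE)
  }
  as.integer(p > 4L | (p == 4L & p + s >= 7L))
}

#' Measure the reporting features of one patient
#'
#' Runs detection end-to-end on one patient's hypercube: background
#' statistics from the normal-prostate voxels, tumor signature from the
#' requested voxel set, ACE maps, then the per-patient feature set used by
#' the clinical models — eccentricity of the largest blob at the shape
#' threshold (0.45), total detected volume at the volume threshold (0.65),
#' and the four SCR variants (3 and 4 principal components removed,
#' standard and modified shrinkage).
#'
#' @param cube A [hypercube()].
#' @param mask A [prostate_mask()] (label 1 = background; label 2 used for
#'   the default signature voxel set).
#' @param sig optional tumor signature vector; defaults to the mean vector
#'   over label-2 voxels via [signature_from_mask()].
#' @param tau_ecc ACE threshold for the shape measurement (default 0.45).
#' @param tau_vol ACE threshold for the volume measurement (default 0.65).
#' @param detection_inv [inverse_spec()] used inside ACE (default: the
#'   full inverse; pass a filtered or regularized spec when the background
#'   covariance is noisy or near-singular).
#' @param connectivity blob connectivity (default 26).
#' @return One-row tibble: `ecc_045`, `vol_065`, `scr_3pc`, `scr_4pc`,
#'   `scr_reg`, `scr_modreg`, `gamma_reg`, `gamma_modreg`, `n_blobs_045`,
#'   `missing` (TRUE when nothing was detected at the shape threshold).
#' @export
measure_patient <- function(cube, mask, sig = NULL,
                            tau_ecc = 0.45, tau_vol = 0.65,
                            detection_inv = inverse_spec("full"),
                            connectivity = 26L) {
  bg <- estimate_background(cube, mask)
  if (is.null(sig)) sig <- signature_from_mask(cube, mask, 2L)
  x_bg <- masked_voxels(cube, mask, 1L)
  sv <- scr_variants(sig, bg, x_bg)
  am <- ace_map(cube, mask, sig, bg, detection_inv)
  blobs_e <- threshold_blobs(am, tau_ecc, connectivity)
  blobs_v <- threshold_blobs(am, tau_vol, connectivity)
  if (nrow(blobs_e$blobs) == 0L) {
    return(dplyr::bind_cols(
      tibble::tibble(ecc_045 = NA_real_, vol_065 = NA_real_), sv,
      tibble::tibble(n_blobs_045 = 0L, missing = TRUE)))
  }
  lb <- largest_blob(blobs_e)
  dplyr::bind_cols(
    tibble::tibble(ecc_045 = lb$eccentricity,
                   vol_065 = total_volume_cc(blobs_v)),
    sv,
    tibble::tibble(n_blobs_045 = nrow(blobs_e$blobs), missing = FALSE))
}

#' Assemble the per-patient feature table
#'
#' Binds per-patient measurement rows into the modeling table, joining the
#' outcome labels by `patient_id`. Patients flagged missing (no uptake, no
#' detection) are excluded listwise with a message, mirroring how a
#' patient without contrast uptake drops out of a real cohort.
#'
#' @param measurements tibble with `patient_id` plus the columns of
#'   [measure_patient()] (a `missing` logical column is honored).
#' @param labels tibble with `patient_id` and `cspca` (0/1).
#' @return A `feature_table` tibble, one row per retained patient.
#' @export
assemble_features <- function(measurements, labels) {
  if (anyDuplicated(measurements$patient_id)) {
    stop("duplicate patient_id in measurements", call. = FALSE)
  }
  if (anyDuplicated(labels$patient_id)) {
    stop("duplicate patient_id in labels", call. = FALSE)
  }
  tab <- dplyr::inner_join(measurements, labels, by = "patient_id")
  if (!"missing" %in% names(tab)) tab$missing <- FALSE
  tab$missing <- tab$missing | !is.finite(tab$ecc_045)
  n_drop <- sum(tab$missing)
  if (n_drop > 0) {
    message(sprintf("excluding %d patient(s) with missing features: %s",
                    n_drop,
                    paste(tab$patient_id[tab$missing], collapse = ", ")))
    tab <- tab[!tab$missing, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("empty feature table", call. = FALSE)
  if (!all(tab$cspca %in% c(0L, 1L))) {
    stop("cspca labels must be 0/1", call. = FALSE)
  }
  class(tab) <- c("feature_table", class(tab))
  tab
}

#' Even/odd enrollment split into training and test sets
#'
#' Training patients are the even enrollment numbers, test patients the
#' odd (1-based enrollment numbering); on a 26-patient cohort with one
#' excluded odd-numbered patient this yields 13 training and 12 test
#' patients.
#'
#' @param table A feature table with a numeric `patient_id` column
#'   carrying the enrollment number.
#' @return List with tibbles `train` (even ids) and `test` (odd ids).
#' @export
split_train_test <- function(table) {
  even <- table$patient_id %% 2 == 0
  out <- list(train = table[even, , drop = FALSE],
              test = table[!even, , drop = FALSE])
  if (nrow(out$train) == 0L || nrow(out$test) == 0L) {
    warning("one side of the even/odd split is empty")
  }
  out
}
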
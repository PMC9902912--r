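#' Multi-band voxel hypercube
#'
#' A spatially registered hypercube holds one spectral vector per voxel:
#' several co-registered MRI modalities (T1 pre/post contrast, T2, ADC,
#' high-b diffusion, DCE washout rate, ...) resampled onto a common grid so
#' that each voxel can be treated as a vector rather than a scalar.
#'
#' @param values 4-D numeric array `(rows, cols, slices, bands)`.
#' @param spacing_mm numeric length-3: physical voxel spacing
#'   `(row, col, slice)` in mm.
#' @param band_names character vector naming the spectral bands; its length
#'   must equal `dim(values)[4]`.
#' @param origin_offset_mm numeric length-3 world-coordinate offset of voxel
#'   `(1, 1, 1)` (default zero). World coordinate of 0-based index `i` along
#'   an axis is `i * spacing + origin`.
#'
#' @return An object of class `"hypercube"`.
#' @export
hypercube <- function(values, spacing_mm, band_names,
                      origin_offset_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) == 3L) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 4L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("spacing_mm must be three strictly positive numbers", call. = FALSE)
  }
  band_names <- as.character(band_names)
  if (length(band_names) != dim(values)[4]) {
    stop("band_names length must equal the number of bands", call. = FALSE)
  }
  structure(
    list(values = values, spacing_mm = spacing_mm, band_names = band_names,
         origin_offset_mm = as.numeric(origin_offset_mm)),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<hypercube> %d x %d x %d voxels, %d bands @ %g x %g x %g mm\n",
    d[1], d[2], d[3], d[4],
    x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat("bands:", paste(x$band_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

n_bands <- function(cube) dim(cube$values)[4]

#' Prostate label mask
#'
#' Integer label volume aligned to a hypercube grid: 0 = outside the organ,
#' 1 = normal prostate (the statistical background), 2 = tumor truth (used
#' by the synthetic generator; real masks may carry only 0/1).
#'
#' @param labels 3-D integer array with values in `{0, 1, 2}`.
#' @return Object of class `"prostate_mask"`.
#' @export
prostate_mask <- function(labels) {
  labels <- as.array(labels)
  stopifnot(length(dim(labels)) == 3L)
  if (!all(labels %in% c(0L, 1L, 2L))) {
    stop("mask labels must be 0 (outside), 1 (normal prostate) or 2 (tumor)",
         call. = FALSE)
  }
  structure(list(labels = array(as.integer(labels), dim(labels))),
            class = "prostate_mask")
}

#' @export
dim.prostate_mask <- function(x) dim(x$labels)

check_aligned <- function(cube, mask) {
  if (!all(dim(cube$values)[1:3] == dim(mask$labels))) {
    stop("mask grid does not match hypercube grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Extract masked voxel vectors as a matrix
#'
#' @param cube A [hypercube()].
#' @param mask A [prostate_mask()] aligned to `cube`.
#' @param label Which mask labels to extract (default `1`, the normal
#'   background; use `c(1, 2)` for the whole organ).
#' @return Numeric matrix, one row per voxel, one column per band.
#' @export
masked_voxels <- function(cube, mask, label = 1L) {
  check_aligned(cube, mask)
  keep <- mask$labels %in% label
  b <- n_bands(cube)
  flat <- matrix(cube$values, ncol = b)
  m <- flat[as.vector(keep), , drop = FALSE]
  colnames(m) <- cube$band_names
  m
}

#' Resample a single-modality volume onto the registration grid
#'
#' Brings a natively sampled 3-D image onto the common reporting grid
#' (1 x 1 mm in-plane, 6 mm slice spacing by convention) using linear
#' interpolation in-plane and nearest-slice reslicing along the slice axis
#' (slices are aligned by table position, so no through-plane blending).
#' Only a rigid translation is applied; registration between scans of the
#' same session needs no deformable component.
#'
#' @param image 3-D numeric array at its native spacing.
#' @param native_spacing_mm length-3 positive spacing of `image`.
#' @param target_spacing_mm length-3 spacing of the output grid
#'   (default `c(1, 1, 6)`).
#' @param translation_mm rigid world-space shift applied to the image
#'   (default zero).
#' @param target_dim optional output grid size; defaults to the native
#'   field of view divided by the target spacing.
#' @return 3-D numeric array on the target grid.
#' @export
resample_to_grid <- function(image, native_spacing_mm,
                             target_spacing_mm = c(1, 1, 6),
                             translation_mm = c(0, 0, 0),
                             target_dim = NULL) {
  image <- as.array(image)
  stopifnot(length(dim(image)) == 3L)
  ns <- as.numeric(native_spacing_mm)
  ts <- as.numeric(target_spacing_mm)
  if (any(ns <= 0) || any(ts <= 0)) {
    stop("spacings must be strictly positive", call. = FALSE)
  }
  d <- dim(image)
  if (is.null(target_dim)) {
    target_dim <- pmax(1L, as.integer(floor((d - 1) * ns / ts)) + 1L)
  }
  # world coordinate of target voxel (0-based index i): i * ts; map into
  # native continuous index space (0-based): (i * ts - translation) / ns
  wx <- ((seq_len(target_dim[1]) - 1) * ts[1] - translation_mm[1]) / ns[1]
  wy <- ((seq_len(target_dim[2]) - 1) * ts[2] - translation_mm[2]) / ns[2]
  wz <- ((seq_len(target_dim[3]) - 1) * ts[3] - translation_mm[3]) / ns[3]
  if (max(wx) < 0 || min(wx) > d[1] - 1 ||
      max(wy) < 0 || min(wy) > d[2] - 1 ||
      max(wz) < 0 || min(wz) > d[3] - 1) {
    stop("grids do not overlap after translation", call. = FALSE)
  }
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  wx <- clamp(wx, d[1] - 1); wy <- clamp(wy, d[2] - 1)
  # nearest-slice reslice along axis 3
  kz <- as.integer(round(clamp(wz, d[3] - 1))) + 1L
  x0 <- pmin(floor(wx), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(wy), d[2] - 2); y0 <- pmax(y0, 0)
  if (d[1] == 1L) x0 <- rep(0, length(wx))
  if (d[2] == 1L) y0 <- rep(0, length(wy))
  fx <- wx - x0; fy <- wy - y0
  out <- array(0, target_dim)
  for (k in seq_len(target_dim[3])) {
    sl <- image[, , kz[k], drop = FALSE]
    dim(sl) <- d[1:2]
    i0 <- x0 + 1L; i1 <- pmin(i0 + 1L, d[1])
    j0 <- y0 + 1L; j1 <- pmin(j0 + 1L, d[2])
    a00 <- sl[i0, j0, drop = FALSE]; a10 <- sl[i1, j0, drop = FALSE]
    a01 <- sl[i0, j1, drop = FALSE]; a11 <- sl[i1, j1, drop = FALSE]
    fxm <- matrix(fx, target_dim[1], target_dim[2])
    fym <- matrix(fy, target_dim[1], target_dim[2], byrow = TRUE)
    out[, , k] <- a00 * (1 - fxm) * (1 - fym) + a10 * fxm * (1 - fym) +
      a01 * (1 - fxm) * fym + a11 * fxm * fym
  }
  out
}

#' Stitch registered multi-band cubes along the slice axis
#'
#' Registered per-station cubes sharing band count and in-plane spacing are
#' concatenated slice-wise into one narrow hypercube covering the scan; a
#' provenance table records which input each output slice came from. All
#' downstream statistics are voxel-set based, so they are invariant to the
#' stitching layout.
#'
#' @param cubes list of [hypercube()] objects with identical in-plane
#'   dimensions, spacing and band names.
#' @return A [hypercube()] with attribute `"provenance"`: a tibble with
#'   columns `slice`, `source_cube`, `source_slice`.
#' @export
stack_and_stitch <- function(cubes) {
  stopifnot(length(cubes) >= 1L)
  ref <- cubes[[1]]
  for (cb in cubes) {
    if (!identical(cb$band_names, ref$band_names)) {
      stop("band mismatch between cubes", call. = FALSE)
    }
    if (!all(dim(cb$values)[c(1, 2, 4)] == dim(ref$values)[c(1, 2, 4)])) {
      stop("in-plane dimensions or band count differ between cubes",
           call. = FALSE)
    }
    if (!all(cb$spacing_mm[1:2] == ref$spacing_mm[1:2])) {
      stop("in-plane spacing differs between cubes", call. = FALSE)
    }
  }
  nz <- vapply(cubes, function(cb) dim(cb$values)[3], integer(1))
  d <- dim(ref$values)
  values <- array(0, c(d[1], d[2], sum(nz), d[4]))
  prov <- vector("list", length(cubes))
  at <- 0L
  for (i in seq_along(cubes)) {
    values[, , at + seq_len(nz[i]), ] <- cubes[[i]]$values
    prov[[i]] <- tibble::tibble(
      slice = at + seq_len(nz[i]),
      source_cube = i,
      source_slice = seq_len(nz[i]))
    at <- at + nz[i]
  }
  out <- hypercube(values, ref$spacing_mm, ref$band_names,
                   ref$origin_offset_mm)
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}

#' Read / write hypercubes and masks as NIfTI
#'
#' The hypercube is stored as 4-D NIfTI (x, y, slice, band) with band names
#' in a JSON sidecar (`<file>.json`); masks and scalar maps as 3-D NIfTI.
#'
#' @param cube A [hypercube()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_hypercube()` returns `path` invisibly; `read_hypercube()`
#'   returns a [hypercube()].
#' @export
write_hypercube <- function(cube, path) {
  img <- RNifti::asNifti(cube$values,
                         pixdim = c(cube$spacing_mm, 1))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(band_names = cube$band_names,
         spacing_mm = cube$spacing_mm,
         origin_offset_mm = cube$origin_offset_mm),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_hypercube
#' @export
read_hypercube <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    hypercube(as.array(img), meta$spacing_mm, meta$band_names,
              meta$origin_offset_mm)
  } else {
    vals <- as.array(img)
    if (length(dim(vals)) == 3L) dim(vals) <- c(dim(vals), 1L)
    pd <- RNifti::pixdim(img)
    hypercube(vals, pd[1:3], paste0("band", seq_len(dim(vals)[4])))
  }
}

#' @rdname write_hypercube
#' @param mask A [prostate_mask()].
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$labels + 0)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_hypercube
#' @export
read_mask <- function(path) {
  prostate_mask(round(as.array(RNifti::readNifti(path))))
}
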
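#' Adaptive cosine estimator (ACE) score map
#'
#' Supervised target detection: for each masked voxel vector `x`,
#' \deqn{ACE(x) = \frac{[(s-\mu)^T G (x-\mu)]^2}
#'   {[(s-\mu)^T G (s-\mu)]\,[(x-\mu)^T G (x-\mu)]}}
#' with `G` the (possibly filtered or regularized) inverse of the
#' background covariance. This is the squared cosine between signature and
#' voxel in covariance-whitened coordinates, so scores lie in `[0, 1]`:
#' 1 when the whitened voxel is collinear with the whitened signature,
#' 0 when orthogonal. Voxels outside the mask get score 0; a voxel exactly
#' at the background mean scores 0 by convention.
#'
#' @param cube A [hypercube()].
#' @param mask A [prostate_mask()]; scores are computed where labels are in
#'   `score_labels`.
#' @param sig tumor signature vector (length = bands).
#' @param bg A `background_model` from [estimate_background()].
#' @param inv An [inverse_spec()]; the full inverse errors on a numerically
#'   singular covariance (the message reports the condition number) —
#'   choose a filtered or regularized inverse instead.
#' @param score_labels mask labels treated as prostate tissue
#'   (default `c(1, 2)`).
#' @return Object of class `"ace_map"`: list with `scores` (3-D array
#'   aligned to the grid) and `spacing_mm`.
#' @export
ace_map <- function(cube, mask, sig, bg, inv = inverse_spec("full"),
                    score_labels = c(1L, 2L)) {
  check_aligned(cube, mask)
  g <- inverse_operator(bg, inv)
  d_s <- as.numeric(sig) - bg$mu
  gs <- drop(g %*% d_s)
  ss <- sum(d_s * gs)
  if (ss <= 0) stop("signature coincides with the background mean",
                    call. = FALSE)
  keep <- mask$labels %in% score_labels
  flat <- matrix(cube$values, ncol = n_bands(cube))
  xm <- sweep(flat[as.vector(keep), , drop = FALSE], 2, bg$mu)
  num <- drop(xm %*% gs)^2
  xx <- rowSums((xm %*% g) * xm)
  sc <- ifelse(xx > 0, num / (ss * xx), 0)
  sc <- pmin(pmax(sc, 0), 1)
  scores <- array(0, dim(mask$labels))
  scores[keep] <- sc
  structure(list(scores = scores, spacing_mm = cube$spacing_mm),
            class = "ace_map")
}

# 3-D connected-component labeling (26- or 6-connectivity) by
# breadth-first search over the supra-threshold voxel set; labels are
# assigned in scan (column-major linear index) order of each component's
# first-encountered voxel, so labeling is deterministic.
label_components <- function(binary, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  d <- dim(binary)
  idx <- which(binary)
  labels <- array(0L, d)
  if (length(idx) == 0L) return(labels)
  inset <- array(FALSE, d); inset[idx] <- TRUE
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  coord <- arrayInd(idx, d)
  rownames(coord) <- NULL
  lin <- function(m) (m[, 3] - 1L) * (d[1] * d[2]) + (m[, 2] - 1L) * d[1] + m[, 1]
  cur <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      q <- arrayInd(queue, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
        sweep(q, 2, -offs[k, ])
      }))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      nl <- unique(lin(nb))
      nl <- nl[inset[nl] & labels[nl] == 0L]
      labels[nl] <- cur
      queue <- nl
    }
  }
  labels
}

#' Threshold an ACE map into labeled blobs
#'
#' Voxels with score strictly above `tau` are assigned to tumor and grouped
#' into connected components (default 26-connectivity, so corner-touching
#' voxels merge — conservative at coarse slice spacing). Components are
#' labeled deterministically in scan order. An empty result is allowed.
#'
#' @param ace An `ace_map` from [ace_map()].
#' @param tau detection threshold in `(0, 1)`; the reporting convention
#'   uses 0.45 for eccentricity and 0.65 for volume.
#' @param connectivity 26 (default) or 6.
#' @return Object of class `"blob_set"`: list with `labels` (3-D integer
#'   array), `spacing_mm`, `tau`, `connectivity`, and `blobs`, a tibble
#'   with one row per component: `label`, `n_voxels`, `volume_cc`, `l_k`,
#'   `s_k`, `eccentricity`.
#' @export
threshold_blobs <- function(ace, tau, connectivity = 26L) {
  stopifnot(inherits(ace, "ace_map"))
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)", call. = FALSE)
  labels <- label_components(ace$scores > tau, connectivity)
  k <- max(labels)
  rows <- lapply(seq_len(k), function(lb) {
    vox <- arrayInd(which(labels == lb), dim(labels))
    mom <- blob_moments(vox, ace$spacing_mm)
    tibble::tibble(label = lb, n_voxels = nrow(vox),
                   volume_cc = nrow(vox) * prod(ace$spacing_mm) / 1000,
                   l_k = mom$l, s_k = mom$s, eccentricity = mom$e)
  })
  structure(
    list(labels = labels, spacing_mm = ace$spacing_mm, tau = tau,
         connectivity = as.integer(connectivity),
         blobs = if (k) dplyr::bind_rows(rows) else tibble::tibble(
           label = integer(), n_voxels = integer(), volume_cc = numeric(),
           l_k = numeric(), s_k = numeric(), eccentricity = numeric())),
    class = "blob_set")
}

#' @export
print.blob_set <- function(x, ...) {
  cat(sprintf("<blob_set> tau = %g, %d-connectivity, %d blob(s)\n",
              x$tau, x$connectivity, nrow(x$blobs)))
  print(x$blobs)
  invisible(x)
}

# second-central-moment (scatter) matrix of voxel world coordinates in mm;
# its largest eigenvalue tracks the major axis (scatter eigenvalues scale
# with squared semi-axes), matching the l >= s assignment.
blob_moments <- function(vox, spacing_mm, method = c("sqrt", "ratio")) {
  method <- match.arg(method)
  w <- sweep(vox - 1, 2, spacing_mm, `*`)
  if (nrow(w) == 1L) return(list(l = 0, s = 0, e = 0))
  cc <- sweep(w, 2, colMeans(w))
  scatter <- crossprod(cc) / nrow(w)
  ev <- sort(eigen(scatter, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  l <- max(ev[1], 0); s <- max(ev[2], 0)
  e <- if (l <= 0) 0 else switch(method,
    sqrt = sqrt(max(0, 1 - s / l)),
    ratio = (l - s) / (l + s))
  list(l = l, s = s, e = e)
}

#' Blob eccentricity from image moments
#'
#' Shape of a detected blob, from the second-central-moment matrix of its
#' voxel world coordinates (mm, so 6 mm slices weigh in physically). With
#' eigenvalues sorted descending, the largest `l_k` tracks the major axis
#' and the second `s_k` the transverse moment; eccentricity is
#' `E = sqrt(1 - s_k / l_k)`, ranging 0 (sphere) to 1 (line). A
#' single-voxel blob has eccentricity 0 by convention. The alternative
#' normalized difference `(l - s)/(l + s)` is available via
#' `method = "ratio"`.
#'
#' @param vox integer matrix of voxel indices (rows = voxels, 3 columns),
#'   or a `blob_set` plus `label`.
#' @param spacing_mm voxel spacing in mm.
#' @param method `"sqrt"` (default) or `"ratio"`.
#' @return A list with `l` and `s` (mm^2) and `e` (unitless).
#' @export
eccentricity <- function(vox, spacing_mm, method = c("sqrt", "ratio")) {
  if (inherits(vox, "blob_set")) {
    stop("pass voxel indices; blob_set objects already carry per-blob ",
         "eccentricity in $blobs", call. = FALSE)
  }
  vox <- as.matrix(vox)
  if (nrow(vox) == 0L) stop("blob is empty", call. = FALSE)
  blob_moments(vox, spacing_mm, method)
}

#' Largest blob of a detection
#'
#' The blob with the maximum voxel count; ties break to the smallest label
#' (scan order), so the choice is stable across runs.
#'
#' @param blobs A `blob_set`.
#' @return One-row tibble (the winning row of `blobs$blobs`).
#' @export
largest_blob <- function(blobs) {
  stopifnot(inherits(blobs, "blob_set"))
  if (nrow(blobs$blobs) == 0L) stop("no detection", call. = FALSE)
  ord <- order(-blobs$blobs$n_voxels, blobs$blobs$label)
  blobs$blobs[ord[1], ]
}

#' Total detected volume
#'
#' Voxel count converted to volume by the grid spacing:
#' `volume_cc = n_voxels * row_mm * col_mm * slice_mm / 1000`.
#'
#' @param blobs A `blob_set`.
#' @return Scalar total volume in cc (0 for an empty detection).
#' @export
total_volume_cc <- function(blobs) {
  stopifnot(inherits(blobs, "blob_set"))
  sum(blobs$blobs$volume_cc)
}

#' Mean signature over a voxel set
#'
#' The tumor signature is the band-wise mean spectral vector over a chosen
#' voxel set (e.g. voxels identified on the colorized registered
#' hypercube, or the truth label 2 of a synthetic patient).
#'
#' @param cube A [hypercube()].
#' @param mask A [prostate_mask()].
#' @param label mask label defining the voxel set (default 2).
#' @return Numeric vector of length bands.
#' @export
signature_from_mask <- function(cube, mask, label = 2L) {
  x <- masked_voxels(cube, mask, label = label)
  if (nrow(x) == 0L) stop("no voxels with the requested label", call. = FALSE)
  colMeans(x)
}
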
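#' Dynamic contrast-enhanced (DCE) voxel time-series
#'
#' Per-voxel tracer concentration curves sampled on a common time grid.
#' After bolus injection the tissue concentration rises to a peak and then
#' empties through the tumor vasculature; for times well past the peak the
#' decay is exponential with washout rate `kep` (per minute).
#'
#' @param values numeric matrix, one row per voxel, one column per time
#'   point.
#' @param times_s strictly increasing numeric vector of sample times in
#'   seconds; length must equal `ncol(values)`.
#' @return Object of class `"dce_series"`.
#' @export
dce_series <- function(values, times_s) {
  values <- as.matrix(values)
  times_s <- as.numeric(times_s)
  if (length(times_s) == 0L) stop("empty time grid", call. = FALSE)
  if (any(diff(times_s) <= 0)) {
    stop("times_s must be strictly increasing", call. = FALSE)
  }
  stopifnot(ncol(values) == length(times_s))
  structure(list(values = values, times_s = times_s), class = "dce_series")
}

#' Simulate DCE concentration curves with an exponential washout
#'
#' Builds per-voxel curves that rise to a peak along a gamma-variate bump
#' (the rise exists only to give [fit_washout()] a realistic peak to find;
#' only the decay segment is contractual) and then decay as
#' `A * exp(-kep * (t - t_peak))`, with optional additive Gaussian noise.
#'
#' @param kep_per_min washout rates, one per voxel (per minute).
#' @param times_s sampling grid in seconds; must extend beyond `t_peak_s`.
#' @param amplitude peak concentration `A` per voxel (recycled).
#' @param t_peak_s time of peak uptake in seconds (recycled).
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   concentration units (0 = noiseless).
#' @return A [dce_series()] with one row per element of `kep_per_min`.
#' @export
simulate_dce_series <- function(kep_per_min, times_s, amplitude = 1,
                                t_peak_s = 60, noise_sd = 0) {
  times_s <- as.numeric(times_s)
  if (length(times_s) == 0L) stop("empty time grid", call. = FALSE)
  n <- length(kep_per_min)
  amplitude <- rep_len(amplitude, n)
  t_peak_s <- rep_len(t_peak_s, n)
  if (any(max(times_s) <= t_peak_s)) {
    stop("time grid must span beyond the uptake peak", call. = FALSE)
  }
  vals <- matrix(0, n, length(times_s))
  for (i in seq_len(n)) {
    t <- times_s
    tp <- t_peak_s[i]
    rise <- (t / tp)^2 * exp(2 * (1 - t / tp))   # gamma-variate, =1 at t=tp
    decay <- exp(-kep_per_min[i] * (t - tp) / 60)
    vals[i, ] <- amplitude[i] * ifelse(t <= tp, rise, decay)
  }
  if (noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sd),
                          nrow = n)
  }
  dce_series(vals, times_s)
}

#' Fit the washout rate kep from post-peak DCE samples
#'
#' For each voxel, the peak time is the argmax of the curve; samples later
#' than `t_peak + post_peak_delay_s` are fitted with an exponential decay
#' `A * exp(-kep * (t - t_peak))`. The fit is log-linear least squares
#' (exact for the noiseless model and deterministic); voxels with a
#' non-positive concentration in the fit window fall back to bounded
#' nonlinear least squares on `kep` in `[0, 10]` per minute, initialized
#' from the log-linear fit on the positive samples. Voxels with fewer than
#' `min_samples` usable post-peak samples are flagged with `kep = NA`.
#'
#' @param series A [dce_series()].
#' @param post_peak_delay_s seconds past the peak before the decay fit
#'   window opens (default 50).
#' @param min_samples minimum post-peak samples required (default 3).
#' @return A tibble with one row per voxel: `voxel`, `kep_per_min`
#'   (`>= 0`, `NA` when flagged), `amplitude`, `t_peak_s`, `n_fit`,
#'   `flagged`.
#' @export
fit_washout <- function(series, post_peak_delay_s = 50, min_samples = 3) {
  stopifnot(inherits(series, "dce_series"))
  t <- series$times_s
  fit1 <- function(y) {
    ip <- which.max(y)
    tp <- t[ip]
    win <- which(t > tp + post_peak_delay_s)
    if (length(win) < min_samples) {
      return(c(NA_real_, NA_real_, tp, length(win), 1))
    }
    tw <- (t[win] - tp) / 60          # minutes past peak
    yw <- y[win]
    if (all(yw > 0)) {
      co <- unname(stats::lm.fit(cbind(1, tw), log(yw))$coefficients)
      kep <- max(0, -co[2])
      A <- exp(co[1])
      return(c(kep, A, tp, length(win), 0))
    }
    # nonlinear fallback when the window contains non-positive values
    pos <- yw > 0
    if (sum(pos) >= 2) {
      co <- unname(stats::lm.fit(cbind(1, tw[pos]), log(yw[pos]))$coefficients)
      k0 <- min(10, max(0, -co[2])); A0 <- exp(co[1])
    } else {
      k0 <- 1; A0 <- max(yw, 1e-6)
    }
    obj <- function(p) sum((yw - p[2] * exp(-p[1] * tw))^2)
    op <- stats::optim(c(k0, A0), obj, method = "L-BFGS-B",
                       lower = c(0, 0), upper = c(10, Inf))
    c(op$par[1], op$par[2], tp, length(win), 0)
  }
  res <- t(apply(series$values, 1, fit1))
  tibble::tibble(
    voxel = seq_len(nrow(res)),
    kep_per_min = res[, 1],
    amplitude = res[, 2],
    t_peak_s = res[, 3],
    n_fit = as.integer(res[, 4]),
    flagged = res[, 5] == 1)
}
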
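#' Points-based nomogram from a logistic fit
#'
#' Renders a fitted logistic model as the familiar paper nomogram: each
#' variable gets a points axis; a patient's points are summed and the
#' total projected onto the risk scale. The construction is exact: with
#' reference value `ref_i` chosen as the end of the observed range that
#' minimizes `beta_i * x` (so points are non-negative), scale
#' `M = max_i |beta_i| * range_i`, per-variable points
#' `points_i(x) = 100 * beta_i * (x - ref_i) / M`, and risk
#' `risk(T) = plogis(eta_min + M * T / 100)` where
#' `eta_min = beta0 + sum_i beta_i * ref_i`, the round trip
#' `risk(sum_i points_i)` reproduces the model probability exactly (up to
#' floating point), so the tabulated axes are the only approximation.
#'
#' @param fit A `cspca_fit`.
#' @param ranges optional named list of `c(lo, hi)` observed ranges per
#'   variable; defaults to the ranges seen by the fit.
#' @param n_ticks ticks per axis in the tick tables (default 11).
#' @return Object of class `"nomogram_spec"`: `axes` (tibble: variable,
#'   ref, beta, max_points and a nested tick table), `scale_m`,
#'   `eta_min`, `risk_table` (total points vs risk), plus the fit.
#' @export
build_nomogram <- function(fit, ranges = NULL, n_ticks = 11) {
  stopifnot(inherits(fit, "cspca_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  vars <- fit$variables
  beta <- fit$coefficients[vars]
  b0 <- fit$coefficients[1]
  mf <- fit$glm$model
  if (is.null(ranges)) {
    ranges <- lapply(vars, function(v) range(mf[[v]]))
    names(ranges) <- vars
  }
  span <- vapply(vars, function(v) diff(ranges[[v]]), numeric(1))
  if (any(span <= 0)) {
    stop("zero-range variable: ",
         paste(vars[span <= 0], collapse = ", "), call. = FALSE)
  }
  m <- max(abs(beta) * span)
  ref <- vapply(vars, function(v) {
    r <- ranges[[v]]
    if (beta[v] >= 0) r[1] else r[2]   # minimizes beta * x
  }, numeric(1))
  eta_min <- unname(b0 + sum(beta * ref))
  axes <- lapply(vars, function(v) {
    xs <- seq(ranges[[v]][1], ranges[[v]][2], length.out = n_ticks)
    tibble::tibble(value = xs,
                   points = 100 * beta[v] * (xs - ref[v]) / m)
  })
  names(axes) <- vars
  max_total <- sum(vapply(axes, function(a) max(a$points), numeric(1)))
  tot <- seq(0, max_total, length.out = 101)
  risk_table <- tibble::tibble(
    total_points = tot,
    risk = stats::plogis(eta_min + m * tot / 100))
  structure(
    list(axes = tibble::tibble(
           variable = vars, beta = unname(beta), ref = unname(ref),
           range_lo = vapply(ranges, `[`, numeric(1), 1)[vars],
           range_hi = vapply(ranges, `[`, numeric(1), 2)[vars],
           max_points = vapply(axes, function(a) max(a$points), numeric(1)),
           ticks = unname(axes)),
         scale_m = m, eta_min = eta_min, risk_table = risk_table,
         fit = fit),
    class = "nomogram_spec")
}

#' Score patients through the nomogram
#'
#' @param nom A `nomogram_spec`.
#' @param newdata data frame with the nomogram's variables.
#' @return Tibble with per-variable points, `total_points` and `risk`.
#' @export
nomogram_points <- function(nom, newdata) {
  vars <- nom$axes$variable
  pts <- vapply(seq_along(vars), function(i) {
    v <- vars[i]
    100 * nom$axes$beta[i] * (newdata[[v]] - nom$axes$ref[i]) / nom$scale_m
  }, numeric(nrow(as.data.frame(newdata))))
  pts <- matrix(pts, ncol = length(vars))
  colnames(pts) <- paste0("points_", vars)
  total <- rowSums(pts)
  dplyr::bind_cols(
    tibble::as_tibble(pts),
    tibble::tibble(total_points = total,
                   risk = stats::plogis(nom$eta_min +
                                          nom$scale_m * total / 100)))
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat("<nomogram_spec>", paste(x$axes$variable, collapse = " + "), "\n")
  cat(sprintf("  scale M = %.4f, eta_min = %.4f\n", x$scale_m, x$eta_min))
  print(x$axes[, c("variable", "beta", "ref", "max_points")])
  invisible(x)
}

#' @rdname build_nomogram
#' @param object A `nomogram_spec`.
#' @param ... unused.
#' @export
autoplot.nomogram_spec <- function(object, ...) {
  ax <- object$axes
  dat <- dplyr::bind_rows(lapply(seq_len(nrow(ax)), function(i) {
    dplyr::mutate(ax$ticks[[i]], variable = ax$variable[i])
  }))
  risk <- dplyr::mutate(object$risk_table, variable = "Risk of CsPCa")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$points, y = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)),
                       vjust = -0.9, size = 2.6, check_overlap = TRUE) +
    ggplot2::geom_line(data = risk,
                       ggplot2::aes(x = .data$total_points *
                                      100 / max(risk$total_points),
                                    y = .data$variable)) +
    ggplot2::labs(x = "Points", y = NULL, title = "Nomogram") +
    ggplot2::theme_minimal()
}
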
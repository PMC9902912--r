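#' Decision-curve analysis
#'
#' For each threshold probability `pt` on the grid, a patient is called
#' positive when the model's predicted probability is at least `pt`; the
#' net benefit of that policy is
#' `NB(pt) = TP/N - (FP/N) * pt / (1 - pt)` — true positives credited at
#' face value, false positives debited at the odds of the threshold, which
#' encodes how a decision maker at threshold `pt` trades a missed cancer
#' against an unnecessary intervention. Reference strategies: treat-all
#' (`NB = pi - (1 - pi) * pt / (1 - pt)` with prevalence `pi`) and
#' treat-none (`NB = 0`). Univariate companion curves come from
#' single-feature logistic fits, so every model's benefit can be compared
#' to acting on one feature alone.
#'
#' @param fits named list of `cspca_fit` objects (e.g. the full model plus
#'   each univariate model).
#' @param table the feature table the fits were built on (supplies labels
#'   and covariates).
#' @param pt_grid threshold probabilities in `(0, 1)`; default
#'   `seq(0.01, 0.99, by = 0.01)`.
#' @return Object of class `"dca_curve"`: tibble `curves` with columns
#'   `strategy`, `pt`, `net_benefit`, `tp`, `fp`, plus `n` and
#'   `prevalence`.
#' @export
decision_curve <- function(fits, table,
                           pt_grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(pt_grid) == 0L) stop("empty threshold grid", call. = FALSE)
  if (any(pt_grid <= 0 | pt_grid >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (inherits(fits, "cspca_fit")) fits <- list(model = fits)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f)
      paste(f$variables, collapse = "+"), character(1))
  }
  y <- table$cspca
  n <- length(y)
  pi_hat <- mean(y)
  one <- function(name, p_hat) {
    tp <- vapply(pt_grid, function(pt) sum(p_hat >= pt & y == 1), numeric(1))
    fp <- vapply(pt_grid, function(pt) sum(p_hat >= pt & y == 0), numeric(1))
    tibble::tibble(strategy = name, pt = pt_grid,
                   net_benefit = tp / n - (fp / n) * pt_grid / (1 - pt_grid),
                   tp = tp, fp = fp)
  }
  curves <- dplyr::bind_rows(
    lapply(names(fits), function(nm) {
      one(nm, predict(fits[[nm]], newdata = table))
    }))
  treat_all <- tibble::tibble(
    strategy = "treat_all", pt = pt_grid,
    net_benefit = pi_hat - (1 - pi_hat) * pt_grid / (1 - pt_grid),
    tp = sum(y == 1), fp = sum(y == 0))
  treat_none <- tibble::tibble(strategy = "treat_none", pt = pt_grid,
                               net_benefit = 0, tp = 0, fp = 0)
  structure(
    list(curves = dplyr::bind_rows(curves, treat_all, treat_none),
         n = n, prevalence = pi_hat),
    class = "dca_curve")
}

#' @export
print.dca_curve <- function(x, ...) {
  cat(sprintf("<dca_curve> n = %d, prevalence = %.3f, strategies: %s\n",
              x$n, x$prevalence,
              paste(unique(x$curves$strategy), collapse = ", ")))
  invisible(x)
}

#' @rdname decision_curve
#' @param x A `dca_curve`.
#' @param ... unused.
#' @export
tidy.dca_curve <- function(x, ...) x$curves

#' @rdname decision_curve
#' @param object A `dca_curve`.
#' @export
autoplot.dca_curve <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$pt, y = .data$net_benefit,
                               color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(
      ylim = c(-0.05, max(object$prevalence * 1.2, 0.1))) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  color = NULL, title = "Decision curve analysis") +
    ggplot2::theme_minimal()
}
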
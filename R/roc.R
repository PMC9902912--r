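#' Empirical ROC curve and AUC with confidence interval
#'
#' Sweeps all score thresholds to trace sensitivity against
#' 1 - specificity; the area under the curve is the trapezoid integral,
#' which equals the Mann-Whitney U statistic divided by `n1 * n0` with
#' tied pairs counted one half. The 95% confidence interval uses the
#' DeLong variance estimate (primary) or a seeded stratified bootstrap.
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param labels 0/1 outcome; both classes must be present.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n bootstrap replicates (default 2000).
#' @param boot_seed seed for the bootstrap resampling.
#' @return Object of class `"roc_result"`: `auc`, `ci` (length 2),
#'   `curve` (tibble `threshold`, `sensitivity`, `specificity`), and the
#'   underlying `pROC::roc` object.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    boot_n = 2000, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- if (ci_method == "delong") {
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
  } else {
    set.seed(boot_seed)
    suppressWarnings(as.numeric(
      pROC::ci.auc(r, method = "bootstrap", boot.n = boot_n,
                   boot.stratified = TRUE))[c(1, 3)])
  }
  curve <- tibble::tibble(threshold = r$thresholds,
                          sensitivity = r$sensitivities,
                          specificity = r$specificities)
  structure(list(auc = auc, ci = ci, curve = curve, roc = r,
                 n1 = sum(labels == 1), n0 = sum(labels == 0)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f [%.3f, %.3f] (n1 = %d, n0 = %d)\n",
              x$auc, x$ci[1], x$ci[2], x$n1, x$n0))
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `roc_result`.
#' @param ... unused.
#' @return `tidy()`: the ROC curve tibble; `glance()`: one row with `auc`,
#'   `ci_low`, `ci_high`, `n1`, `n0`.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_auc
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci[1], ci_high = x$ci[2],
                 n1 = x$n1, n0 = x$n0)
}

#' @rdname roc_auc
#' @param object A `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  dat <- object$curve
  ggplot2::ggplot(dat, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.9) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f [%.3f, %.3f]",
                                  object$auc, object$ci[1], object$ci[2])) +
    ggplot2::theme_minimal()
}
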
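#' Logistic regression of CsPCa on imaging features
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' tolerance 1e-8, up to 100 iterations) of the binary
#' clinically-significant-cancer label on a subset of the imaging
#' features. The headline fit statistics follow the reporting style of
#' multivariable regression summaries: the primary R-squared is the
#' squared correlation between the outcome and the fitted probability, and
#' the F statistic is the linear-probability companion
#' `F = (R2/k) / ((1 - R2)/(n - k - 1))` with its F-distribution p-value.
#' McFadden and Nagelkerke pseudo-R-squared and the likelihood-ratio
#' chi-square p-value are reported alongside, all labeled, so either
#' convention can be compared.
#'
#' @param table a feature table (see [assemble_features()]) with a `cspca`
#'   column.
#' @param variables character vector of covariate column names.
#' @param outcome outcome column name (default `"cspca"`).
#' @return Object of class `"cspca_fit"`: the `glm` fit plus the labeled
#'   statistics; see [glance.cspca_fit()] and [tidy.cspca_fit()].
#' @export
fit_cspca_logistic <- function(table, variables, outcome = "cspca") {
  stopifnot(all(variables %in% names(table)), outcome %in% names(table))
  y <- table[[outcome]]
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 events and 2 non-events", call. = FALSE)
  }
  x <- as.data.frame(table)[, variables, drop = FALSE]
  const <- vapply(x, function(v) stats::var(v) == 0, logical(1))
  if (any(const)) {
    stop("constant covariate: ", paste(variables[const], collapse = ", "),
         call. = FALSE)
  }
  sep <- vapply(variables, function(v) {
    max(x[[v]][y == 0]) < min(x[[v]][y == 1]) ||
      max(x[[v]][y == 1]) < min(x[[v]][y == 0])
  }, logical(1))
  dat <- cbind(x, .y = y)
  fml <- stats::as.formula(paste(".y ~", paste(variables, collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (any(sep) ||
      (!fit$converged || max(abs(stats::coef(fit)[-1])) > 50)) {
    if (any(sep)) {
      stop("complete separation on variable(s): ",
           paste(variables[sep], collapse = ", "),
           "; the likelihood has no finite maximum", call. = FALSE)
    }
  }
  p_hat <- stats::fitted(fit)
  n <- length(y); k <- length(variables)
  r2 <- if (stats::sd(p_hat) == 0) 0 else stats::cor(y, p_hat)^2
  f_val <- (r2 / k) / ((1 - r2) / (n - k - 1))
  f_p <- stats::pf(f_val, k, n - k - 1, lower.tail = FALSE)
  null_dev <- fit$null.deviance
  lrt <- null_dev - fit$deviance
  lrt_p <- stats::pchisq(lrt, df = k, lower.tail = FALSE)
  mcfadden <- 1 - fit$deviance / null_dev
  nagelkerke <- (1 - exp((fit$deviance - null_dev) / n)) /
    (1 - exp(-null_dev / n))
  structure(
    list(glm = fit, variables = variables, outcome = outcome,
         coefficients = stats::coef(fit), fitted = p_hat, y = y,
         n = n, k = k,
         r2 = r2, f_value = f_val, p_value = f_p,
         lrt_chisq = lrt, lrt_p = lrt_p,
         r2_mcfadden = mcfadden, r2_nagelkerke = nagelkerke,
         converged = fit$converged),
    class = "cspca_fit")
}

#' @export
print.cspca_fit <- function(x, ...) {
  cat("<cspca_fit>", paste(x$variables, collapse = " + "), "\n")
  cat(sprintf("  n = %d, F = %.3f, p = %.4g, R2 = %.3f (McFadden %.3f)\n",
              x$n, x$f_value, x$p_value, x$r2, x$r2_mcfadden))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict CsPCa probability for new patients
#'
#' @param object A `cspca_fit`.
#' @param newdata data frame with the fit's covariate columns; omit for
#'   fitted values.
#' @param ... unused.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict.cspca_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  stats::predict(object$glm, newdata = as.data.frame(newdata),
                 type = "response")
}

#' Tidy a CsPCa logistic fit
#'
#' @param x A `cspca_fit`.
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.cspca_fit <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' One-row fit summary
#'
#' @param x A `cspca_fit`.
#' @param ... unused.
#' @return Tibble with the headline and pseudo statistics.
#' @export
glance.cspca_fit <- function(x, ...) {
  tibble::tibble(
    variables = paste(x$variables, collapse = "+"),
    n = x$n, k = x$k,
    f_value = x$f_value, p_value = x$p_value, r2 = x$r2,
    r2_mcfadden = x$r2_mcfadden, r2_nagelkerke = x$r2_nagelkerke,
    lrt_chisq = x$lrt_chisq, lrt_p = x$lrt_p,
    converged = x$converged)
}
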
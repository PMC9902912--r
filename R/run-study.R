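#' Default variable subsets for the study report
#'
#' The seven reported combinations of eccentricity, SCR variants and
#' volume for the all-patients analysis, and the three combinations
#' carried through the train/test protocol.
#'
#' @return Named list of character vectors of feature-table column names.
#' @export
study_subsets <- function() {
  list(
    "3PC+Vol"              = c("scr_3pc", "vol_065"),
    "Ecc+3PC"              = c("ecc_045", "scr_3pc"),
    "Ecc+ModReg+3PC"       = c("ecc_045", "scr_modreg", "scr_3pc"),
    "Ecc+Reg+3PC"          = c("ecc_045", "scr_reg", "scr_3pc"),
    "Ecc+3PC+Vol"          = c("ecc_045", "scr_3pc", "vol_065"),
    "Ecc+Reg+3PC+Vol"      = c("ecc_045", "scr_reg", "scr_3pc", "vol_065"),
    "Ecc+ModReg+3PC+Vol"   = c("ecc_045", "scr_modreg", "scr_3pc",
                               "vol_065"))
}

#' @rdname study_subsets
#' @export
train_test_subsets <- function() {
  study_subsets()[c("3PC+Vol", "Ecc+Reg+3PC", "Ecc+Reg+3PC+Vol")]
}

#' Measure every patient of a cohort bundle
#'
#' Runs [measure_patient()] over a synthetic cohort, regenerating images
#' from the stored per-patient seeds when the bundle was built with
#' `keep_images = FALSE`.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param ... passed to [measure_patient()].
#' @return Tibble of per-patient measurements keyed by `patient_id`.
#' @export
measure_cohort <- function(bundle, ...) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  rows <- lapply(seq_len(nrow(bundle$truth)), function(i) {
    p <- bundle$patients[[i]]
    if (is.null(p)) {
      p <- simulate_patient(bundle$params, bundle$truth$patient_seed[i])
    }
    dplyr::mutate(measure_patient(p$cube, p$mask, ...),
                  patient_id = bundle$truth$patient_id[i], .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Run the full study on a feature table
#'
#' For each configured variable subset: the logistic fit with its F,
#' p-value and R-squared, and the ROC AUC with 95% confidence interval on
#' all patients; then the train/test protocol (fit on even-numbered
#' patients, score odd-numbered patients with frozen coefficients); and a
#' nomogram plus decision curves for a chosen subset.
#'
#' @param table a feature table (see [assemble_features()]).
#' @param subsets named list of variable subsets (default
#'   [study_subsets()]).
#' @param tt_subsets subsets carried through the train/test protocol
#'   (default [train_test_subsets()]).
#' @param nomogram_subset name of the subset rendered as nomogram + DCA
#'   (default `"Ecc+Reg+3PC"`).
#' @param pt_grid DCA threshold grid.
#' @return Object of class `"study_report"`: `all_patients` (one row per
#'   subset: k, F, p, R2, AUC, CI), `train_test` (train AUC, frozen-
#'   coefficient test AUC + CI), `nomogram`, `dca`, `fits`, `table`.
#' @export
run_study <- function(table, subsets = study_subsets(),
                      tt_subsets = train_test_subsets(),
                      nomogram_subset = "Ecc+Reg+3PC",
                      pt_grid = seq(0.01, 0.99, by = 0.01)) {
  fits <- lapply(subsets, function(v) fit_cspca_logistic(table, v))
  all_rows <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    r <- roc_auc(predict(f), table$cspca)
    tibble::tibble(subset = nm, k = f$k, f_value = f$f_value,
                   p_value = f$p_value, r2 = f$r2,
                   auc = r$auc, ci_low = r$ci[1], ci_high = r$ci[2])
  }))
  sp <- split_train_test(table)
  tt_rows <- dplyr::bind_rows(lapply(names(tt_subsets), function(nm) {
    v <- tt_subsets[[nm]]
    ft <- fit_cspca_logistic(sp$train, v)
    beta_before <- ft$coefficients
    auc_train <- roc_auc(predict(ft), sp$train$cspca)$auc
    p_test <- predict(ft, newdata = sp$test)
    r_test <- roc_auc(p_test, sp$test$cspca)
    stopifnot(identical(beta_before, ft$coefficients))  # no refit leakage
    tibble::tibble(subset = nm, k = ft$k, f_value = ft$f_value,
                   p_value = ft$p_value, r2 = ft$r2,
                   auc_train = auc_train, auc_test = r_test$auc,
                   ci_low = r_test$ci[1], ci_high = r_test$ci[2],
                   n_train = nrow(sp$train), n_test = nrow(sp$test))
  }))
  nom_fit <- fits[[nomogram_subset]]
  nom <- build_nomogram(nom_fit)
  uni <- lapply(subsets[[nomogram_subset]], function(v)
    fit_cspca_logistic(table, v))
  names(uni) <- subsets[[nomogram_subset]]
  dca <- decision_curve(c(list(model = nom_fit), uni), table,
                        pt_grid = pt_grid)
  structure(
    list(all_patients = all_rows, train_test = tt_rows,
         nomogram = nom, dca = dca, fits = fits, table = table),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> all-patients fits:\n")
  print(x$all_patients)
  cat("train/test protocol:\n")
  print(x$train_test)
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the all-patients and train/test tables as CSV, the nomogram tick
#' tables and DCA/ROC curves as CSV, and a machine-readable JSON summary.
#'
#' @param report A `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$all_patients,
                   file.path(dir, "all_patients.csv"), row.names = FALSE)
  utils::write.csv(report$train_test,
                   file.path(dir, "train_test.csv"), row.names = FALSE)
  utils::write.csv(tidy(report$dca), file.path(dir, "dca_curves.csv"),
                   row.names = FALSE)
  ax <- report$nomogram$axes
  ticks <- dplyr::bind_rows(lapply(seq_len(nrow(ax)), function(i) {
    dplyr::mutate(ax$ticks[[i]], variable = ax$variable[i], .before = 1)
  }))
  utils::write.csv(ticks, file.path(dir, "nomogram_ticks.csv"),
                   row.names = FALSE)
  utils::write.csv(report$nomogram$risk_table,
                   file.path(dir, "nomogram_risk.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(all_patients = report$all_patients,
         train_test = report$train_test),
    file.path(dir, "report.json"), dataframe = "rows", digits = NA)
  invisible(dir)
}
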
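#' Describe one regression design
#'
#' A plan names the response, the predictors under test, the always-included
#' base covariates (intercept and land coverage by default), the predictors
#' to drop one at a time for likelihood-ratio tests, and an optional
#' subsampling regime applied before fitting.
#'
#' @param predictors character vector of predictor column names (may include
#'   factor columns such as `biome`).
#' @param response response column (default `"diversity"`).
#' @param drop predictors to test by drop-one LR (default all of
#'   `predictors`).
#' @param base always-included covariates (default land coverage).
#' @param log_response take the natural log of the response column
#'   (default `TRUE`; set `FALSE` when the column already is a log scale,
#'   e.g. the generator's `log_diversity`).
#' @param step,row_offset,col_offset subsampling regime (see
#'   [subsample_cells()]).
#' @param name label used in printed reports.
#' @return a list of class `analysis_plan`.
#' @export
analysis_plan <- function(predictors, response = "diversity",
                          drop = predictors, base = "land_fraction",
                          log_response = TRUE,
                          step = 1L, row_offset = 0L, col_offset = 0L,
                          name = "model") {
  structure(list(predictors = predictors, response = response, drop = drop,
                 base = base, log_response = log_response, step = as.integer(step),
                 row_offset = as.integer(row_offset),
                 col_offset = as.integer(col_offset), name = name),
            class = "analysis_plan")
}

.subset_matrix <- function(M, ids) {
  if (is.null(M)) return(NULL)
  if (!is.null(dimnames(M)[[1]])) M[ids, ids] else M
}

# assemble response + design data for a plan on (already subsampled) cells
.plan_data <- function(cells, plan) {
  vars <- unique(c(plan$response, plan$base, plan$predictors))
  missing <- setdiff(vars, names(cells))
  if (length(missing))
    stop("cells lack columns named in the plan: ", paste(missing, collapse = ", "))
  dat <- as.data.frame(cells[vars], stringsAsFactors = FALSE)
  dat$.y <- if (plan$log_response) log(cells[[plan$response]]) else cells[[plan$response]]
  dat
}

#' Run a regression design with drop-one likelihood-ratio tests
#'
#' Subsamples the cells per the plan, computes the PhyloSor and distance
#' matrices, fits the full GLS model, and refits with each listed predictor
#' dropped to obtain likelihood-ratio tests of its contribution beyond
#' covariation with the others.  Rows are formatted `"t (p) LR"` in the
#' style of published regression tables; factor predictors (several
#' coefficients) report only the LR.
#'
#' @param cells cell table with occupancy and covariates.
#' @param tree language tree (used for PhyloSor); ignored when `P` given.
#' @param plan an [analysis_plan()].
#' @param control [lsgls_control()] passed to the fits.
#' @param P,D optional precomputed matrices for the *unsubsampled* cells
#'   (subset by `cell_id` when the plan subsamples).
#' @param ols fit by ordinary least squares instead of GLS.
#' @return list of class `lsgls_report`: `name`, `fit` (full model),
#'   `drops` (one row per dropped predictor), `n`.
#' @export
run_plan <- function(cells, tree, plan, control = lsgls_control(),
                     P = NULL, D = NULL, ols = FALSE) {
  stopifnot(inherits(plan, "analysis_plan"))
  if (plan$step > 1L)
    cells <- subsample_cells(cells, plan$step, plan$row_offset, plan$col_offset)
  dat <- .plan_data(cells, plan)
  if (!ols) {
    P <- if (is.null(P)) suppressWarnings(phylosor_matrix(tree, cells))
         else .subset_matrix(P, cells$cell_id)
    D <- if (is.null(D)) greatcircle_matrix(cells)
         else .subset_matrix(D, cells$cell_id)
  }
  rhs <- unique(c(plan$base, plan$predictors))
  form <- stats::reformulate(rhs, response = ".y")
  fit <- if (ols) lsgls(form, dat, correlation = "none", control = control)
         else lsgls(form, dat, P = P, D = D, control = control)

  drops <- lapply(plan$drop, function(pred) {
    rhs_red <- setdiff(rhs, pred)
    form_red <- if (length(rhs_red)) stats::reformulate(rhs_red, response = ".y")
                else stats::as.formula(".y ~ 1")
    red <- if (ols) lsgls(form_red, dat, correlation = "none", control = control)
           else lsgls(form_red, dat, P = P, D = D, control = control)
    lr <- lr_test(fit, red)
    tv <- if (pred %in% names(fit$coefficients)) fit$tval[pred] else NA_real_
    pv <- if (pred %in% names(fit$coefficients)) fit$pval[pred] else NA_real_
    data.frame(predictor = pred, t = unname(tv), p = unname(pv),
               LR = lr$statistic, df = lr$df, p_LR = lr$p.value,
               cell = if (is.na(tv)) sprintf("LR %.2f (df %d)", lr$statistic, lr$df)
                      else sprintf("%.2f (%.3f) %.2f", tv, pv, lr$statistic),
               stringsAsFactors = FALSE)
  })
  drops <- do.call(rbind, drops)
  rownames(drops) <- NULL
  structure(list(name = plan$name, fit = fit, drops = drops, n = fit$n),
            class = "lsgls_report")
}

#' @export
print.lsgls_report <- function(x, ...) {
  cat("Analysis:", x$name, " (n =", x$n, "cells)\n")
  if (x$fit$correlation != "none")
    cat(sprintf("alpha = %.3f, beta = %.3f, gamma = %.1f km\n",
                x$fit$params[1], x$fit$params[2], x$fit$params[3]))
  cat("\nDrop-one tests [t (p) LR]:\n")
  print(x$drops[c("predictor", "cell", "p_LR")], row.names = FALSE)
  invisible(x)
}

#' Latitudinal gradient in language diversity
#'
#' Fits a GLS of log diversity on absolute latitude (plus land coverage);
#' with `climate` given, additionally tests whether absolute latitude adds
#' explanatory power beyond the climatic variables (LR of the augmented
#' model against the climate-only model).
#'
#' @param cells cell table with `lat` centroids (spherical grids).
#' @param tree language tree; ignored when `P` given.
#' @param climate optional character vector of climate column names.
#' @param response response column, log-transformed unless
#'   `log_response = FALSE`.
#' @inheritParams run_plan
#' @return list with `fit` (diversity ~ |lat| + land coverage) and, when
#'   `climate` is given, `augmentation` (an `lsgls_lr`).
#' @export
latitude_gradient <- function(cells, tree, climate = NULL,
                              response = "diversity", log_response = TRUE,
                              control = lsgls_control(), P = NULL, D = NULL) {
  if (all(is.na(cells$lat)))
    stop("cells have no latitude (planar grid); latitude gradient needs a spherical grid")
  cells$abs_lat <- abs(cells$lat)
  if (max(cells$abs_lat) - min(cells$abs_lat) < 1e-12)
    stop("absolute latitude is constant across cells (degenerate design)")
  if (is.null(P)) P <- suppressWarnings(phylosor_matrix(tree, cells))
  if (is.null(D)) D <- greatcircle_matrix(cells)
  dat <- as.data.frame(cells[unique(c("abs_lat", "land_fraction", climate))])
  dat$.y <- if (log_response) log(cells[[response]]) else cells[[response]]
  fit <- lsgls(stats::reformulate(c("abs_lat", "land_fraction"), response = ".y"),
               dat, P = P, D = D, control = control)
  out <- list(fit = fit)
  if (!is.null(climate)) {
    full <- lsgls(stats::reformulate(c(climate, "abs_lat", "land_fraction"),
                                     response = ".y"),
                  dat, P = P, D = D, control = control)
    red <- lsgls(stats::reformulate(c(climate, "land_fraction"), response = ".y"),
                 dat, P = P, D = D, control = control)
    out$augmentation <- lr_test(full, red)
  }
  out
}

#' Residual hotspots and the family-count regression
#'
#' Maps standardized residuals of a fitted diversity model onto the grid,
#' flags cells beyond `threshold` (default |1.96|: more, or fewer,
#' languages than climate and landscape predict), and regresses the
#' residuals on the number of language families per cell with the same GLS
#' correlation structure -- a qualitative probe of whether deeper
#' within-cell divergence accompanies unexplained diversity.
#'
#' @param fit an `lsgls` fit of the diversity model.
#' @param cells the cell table the model was fitted to (same row order).
#' @param threshold flag threshold (default 1.96).
#' @param control [lsgls_control()] for the family-count regression.
#' @return list with `table` (cell_id, row, col, lon, lat, residual, flag),
#'   `family_fit` (GLS of residuals on `n_families`), `shapiro_p`.
#' @export
residual_hotspots <- function(fit, cells, threshold = 1.96,
                              control = lsgls_control()) {
  stopifnot(inherits(fit, "lsgls"), nrow(cells) == fit$n)
  sr <- standardized_residuals(fit, threshold)
  tab <- data.frame(cell_id = cells$cell_id, row = cells$row, col = cells$col,
                    lon = cells$lon, lat = cells$lat,
                    residual = sr$standardized, flag = sr$flag,
                    stringsAsFactors = FALSE)
  dat <- data.frame(resid = sr$standardized, n_families = cells$n_families)
  family_fit <- if (fit$correlation == "none")
    lsgls(resid ~ n_families, dat, correlation = "none", control = control)
  else
    lsgls(resid ~ n_families, dat, P = fit$P, D = fit$D, control = control)
  list(table = tab, family_fit = family_fit, shapiro_p = sr$shapiro_p)
}

#' Variance partitioning between climate, landscape and autocorrelation
#'
#' Computes the leave-one-out predicted R-squared of the full
#' (climate + landscape) GLS model, the share contributed by the climatic
#' variables alone, and the GLS-minus-OLS difference in predicted
#' R-squared, which quantifies how much explanatory power rides on spatial
#' autocorrelation and phylogenetic non-independence.
#'
#' @param cells cell table.
#' @param tree language tree; ignored when `P` given.
#' @param climate,landscape character vectors of predictor columns.
#' @param response response column (log-transformed unless
#'   `log_response = FALSE`).
#' @inheritParams run_plan
#' @return list with `pr2_full`, `pr2_climate`, `climate_share`,
#'   `pr2_ols`, `gls_minus_ols`, and the three fits.
#' @export
variance_partition <- function(cells, tree, climate, landscape = character(0),
                               response = "diversity", log_response = TRUE,
                               control = lsgls_control(), P = NULL, D = NULL) {
  if (is.null(P)) P <- suppressWarnings(phylosor_matrix(tree, cells))
  if (is.null(D)) D <- greatcircle_matrix(cells)
  rhs_full <- unique(c("land_fraction", climate, landscape))
  rhs_climate <- unique(c("land_fraction", climate))
  dat <- as.data.frame(cells[rhs_full])
  dat$.y <- if (log_response) log(cells[[response]]) else cells[[response]]
  f_full <- stats::reformulate(rhs_full, response = ".y")
  f_climate <- stats::reformulate(rhs_climate, response = ".y")
  fit_full <- lsgls(f_full, dat, P = P, D = D, control = control)
  fit_climate <- lsgls(f_climate, dat, P = P, D = D, control = control)
  fit_ols <- lsgls(f_full, dat, correlation = "none", control = control)
  pr2_full <- predicted_r2(fit_full)
  pr2_climate <- predicted_r2(fit_climate)
  pr2_ols <- predicted_r2(fit_ols)
  list(pr2_full = pr2_full, pr2_climate = pr2_climate,
       climate_share = pr2_climate / pr2_full,
       pr2_ols = pr2_ols, gls_minus_ols = pr2_full - pr2_ols,
       fit_full = fit_full, fit_climate = fit_climate, fit_ols = fit_ols)
}

#' Run a plan under every subsampling regime at a step
#'
#' Repeats [run_plan()] for all `step^2` offset regimes and summarizes the
#' sign agreement of each predictor's coefficient across regimes -- the
#' consistency check that subsampling does not drive the conclusions.
#'
#' @inheritParams run_plan
#' @param step subsampling period (3 gives the nine regimes).
#' @return list with `reports` (per regime) and `consistency` (data frame
#'   of sign agreement per coefficient).
#' @export
run_subsample_regimes <- function(cells, tree, plan, step = 3L,
                                  control = lsgls_control(), P = NULL, D = NULL) {
  offs <- expand.grid(row_offset = 0:(step - 1L), col_offset = 0:(step - 1L))
  reports <- list()
  for (i in seq_len(nrow(offs))) {
    p_i <- plan
    p_i$step <- as.integer(step)
    p_i$row_offset <- offs$row_offset[i]
    p_i$col_offset <- offs$col_offset[i]
    p_i$name <- sprintf("%s [offset %d,%d]", plan$name,
                        offs$row_offset[i], offs$col_offset[i])
    reports[[i]] <- tryCatch(
      run_plan(cells, tree, p_i, control = control, P = P, D = D),
      error = function(e) e)
  }
  ok <- vapply(reports, inherits, TRUE, "lsgls_report")
  if (!any(ok)) stop("no subsampling regime could be fitted")
  coefs <- vapply(reports[ok], function(r) coef(r$fit), coef(reports[ok][[1]]$fit))
  coefs <- matrix(coefs, ncol = sum(ok),
                  dimnames = list(names(coef(reports[ok][[1]]$fit)), NULL))
  consistency <- data.frame(
    coefficient = rownames(coefs),
    n_regimes = sum(ok),
    n_positive = rowSums(coefs > 0),
    n_negative = rowSums(coefs < 0),
    sign_agreement = apply(coefs, 1, function(v) max(mean(v > 0), mean(v < 0))),
    row.names = NULL)
  list(reports = reports[ok], consistency = consistency, n_failed = sum(!ok))
}
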
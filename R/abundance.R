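# Conditional (presence-only) abundance modelling on the natural-log
# scale, with regression-of-observed-on-estimated (ROE) recalibration,
# Duan's smearing retransformation, and per-iteration calibration ratios
# for the model-based population estimator.

#' Ordinary least-squares recalibration of log predictions
#'
#' Regresses observed on predicted log densities; the fitted line
#' `a + b * predicted` replaces the raw predictions, pulling
#' over-predicted low values up and under-predicted high values down
#' toward the observed scale.
#'
#' @param observed,predicted Log-scale observed and predicted densities
#'   (>= 3 pairs).
#' @return List with intercept `a`, slope `b` and `corrected` predictions.
#'   Constant predictions give `a = mean(observed)`, `b = 0` with a
#'   warning.
#' @export
roe_correct <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("need >= 3 pairs")
  if (stats::sd(predicted) == 0) {
    warning("constant predictions; ROE slope set to 0")
    return(list(a = mean(observed), b = 0,
                corrected = rep(mean(observed), length(observed))))
  }
  fit <- stats::lm(observed ~ predicted)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  list(a = a, b = b, corrected = a + b * predicted)
}

#' Duan's smearing estimate
#'
#' The nonparametric retransformation factor `D = mean(exp(residual))` for
#' predictions back-transformed from the natural-log scale; under Normal
#' residuals `D -> exp(sigma^2 / 2)`.
#'
#' @param residuals Log-scale residuals (observed - corrected prediction).
#' @return The smearing factor `D > 0`.
#' @export
duan_smearing <- function(residuals) {
  if (length(residuals) == 0) stop("empty residuals")
  if (any(!is.finite(residuals))) stop("non-finite residuals")
  mean(exp(residuals))
}

#' Back-transform corrected log predictions to densities and counts
#'
#' `density = exp(a + b * raw) * D`; `count = density * cell_area`.
#'
#' @param raw_log Raw model predictions on the natural-log density scale.
#' @param a,b ROE intercept and slope.
#' @param D Duan smearing factor.
#' @param cell_area Cell area in m^2 (default 100, i.e. 10 x 10 m cells).
#' @return data.frame with `density` (ind m^-2) and `count` (individuals
#'   per cell).  Non-finite inputs yield `NA` with a warning.
#' @export
predict_density <- function(raw_log, a = 0, b = 1, D = 1, cell_area = 100) {
  bad <- !is.finite(raw_log)
  if (any(bad)) warning(sum(bad), " non-finite prediction(s) masked")
  d <- exp(a + b * raw_log) * D
  d[bad] <- NA_real_
  data.frame(density = d, count = d * cell_area)
}

#' Calibration ratio of predicted to observed individuals
#'
#' `rho = sum(predicted counts) / sum(observed counts)` over a set of
#' omitted sites; divides the mapped total in the model-based population
#' estimator to correct consistent prediction bias.
#'
#' @param predicted,observed Site-level predicted and observed counts.
#' @return The ratio, or `NA` with a warning when the observed sum is 0.
#' @export
calibration_ratio <- function(predicted, observed) {
  so <- sum(observed)
  if (so <= 0) {
    warning("observed sum is 0; calibration ratio undefined")
    return(NA_real_)
  }
  sum(predicted) / so
}

#' Abundance-model configuration
#'
#' @param params Boosted-tree hyperparameters.
#' @param tune `"once"` (repeated-CV tuning of the log-scale RMSE on the
#'   full presence set) or `"none"`.
#' @param grid,cv_k,cv_repeats Tuning grid and repeated-CV specification.
#' @export
abund_config <- function(params = gbt_params(), tune = c("none", "once"),
                         grid = default_occ_grid(), cv_k = 10,
                         cv_repeats = 10) {
  tune <- match.arg(tune)
  list(params = params, tune = tune, grid = grid, cv_k = cv_k,
       cv_repeats = cv_repeats)
}

#' Fit the conditional density regressor on presence sites
#'
#' Boosted-tree regression of `log(density)` on the covariates (plus the
#' modelled occurrence probability where supplied).  Sites with zero
#' density are rejected: the model's domain is presence sites only.
#'
#' @param data Presence-site data with a positive `density` column.
#' @param density_col Name of the density column (ind m^-2).
#' @param covariates Covariate column names.
#' @param params Boosted-tree hyperparameters.
#' @param min_sites Minimum number of presence sites (default 20).
#' @return A `fit_gbt`-style list predicting natural-log density.
#' @export
fit_abundance <- function(data, density_col, covariates,
                          params = gbt_params(), min_sites = 20) {
  d <- data[[density_col]]
  if (is.null(d)) stop("no column ", density_col)
  if (any(d <= 0)) stop("zero or negative densities: presence-only contract")
  if (nrow(data) < min_sites)
    stop("need >= ", min_sites, " presence sites, got ", nrow(data))
  data$.logdens <- log(d)
  fit_gbt(data, ".logdens", covariates, params,
          objective = "reg:squarederror")
}

# repeated-CV RMSE tuning for the regressor (log scale)
tune_abundance <- function(data, density_col, covariates, grid, k, repeats,
                           seed, max_depth = 3) {
  set.seed(seed)
  y <- log(data[[density_col]])
  n <- nrow(data)
  cv_rmse <- matrix(NA_real_, nrow(grid), k * repeats)
  col <- 0L
  for (r in seq_len(repeats)) {
    folds <- sample(rep_len(seq_len(k), n))
    for (f in seq_len(k)) {
      col <- col + 1L
      test <- folds == f
      if (sum(!test) < 10) next
      for (g in seq_len(nrow(grid))) {
        p <- gbt_params(eta = grid$eta[g], nrounds = grid$nrounds[g],
                        max_depth = max_depth,
                        min_child_weight = grid$min_child_weight[g])
        fit <- fit_abundance(data[!test, , drop = FALSE], density_col,
                             covariates, p, min_sites = 10)
        pr <- fit$predict(data[test, , drop = FALSE])
        cv_rmse[g, col] <- sqrt(mean((y[test] - pr)^2))
      }
    }
  }
  mean_rmse <- rowMeans(cv_rmse, na.rm = TRUE)
  g <- which.min(mean_rmse)
  list(best = gbt_params(eta = grid$eta[g], nrounds = grid$nrounds[g],
                         max_depth = max_depth,
                         min_child_weight = grid$min_child_weight[g]),
       cv = data.frame(grid, mean_cv_rmse = mean_rmse))
}

#' Abundance pipeline for one species
#'
#' Bootstraps the whole survey; each iteration fits the log-density
#' regressor on the in-bag presence sites (covariates plus the `P_presence`
#' probability from the occurrence stage), applies the ROE correction and
#' Duan smearing fitted on the in-bag pairs, scores Spearman rho, Pearson
#' r, R^2 and RMSE on the out-of-bag presence sites at the untransformed
#' scale, and computes the iteration's calibration ratio `rho_b` over all
#' out-of-bag sites (predicted counts thresholded at the paired occurrence
#' threshold `t_b`).  Final map corrections use the iteration averages of
#' `(a, b, D)`.
#'
#' @param survey Survey table with `count_<species>` and
#'   `density_<species>` columns.
#' @param species Species name.
#' @param covariates Covariate column names (without `P_presence`; it is
#'   appended automatically).
#' @param occurrence An `occurrence_fit` for the same species and survey
#'   (provides `P_presence` per site and the thresholds `t_b`).
#' @param B Bootstrap iterations; must equal the occurrence fit's B.
#' @param seed Integer seed.
#' @param config An [abund_config()].
#' @return Object of class `abundance_fit` with the full-data model,
#'   averaged corrections `a`, `b`, `D`, per-iteration `a_b`, `b_b`,
#'   `D_b`, `rho_b`, the performance report, and the `boot_result`.
#' @export
abundance_pipeline <- function(survey, species, covariates, occurrence,
                               B = 100, seed = 1, config = abund_config()) {
  ycol <- paste0("count_", species)
  dcol <- paste0("density_", species)
  if (is.null(survey[[ycol]]) || is.null(survey[[dcol]]))
    stop("survey lacks count/density columns for ", species)
  if (!is.null(occurrence) && length(occurrence$thresholds) != B)
    stop("occurrence fit has ", length(occurrence$thresholds),
         " thresholds but B = ", B)

  survey$P_presence <- if (!is.null(occurrence)) occurrence$p_presence else 0
  # a site can (rarely) be in-bag in every iteration; fall back to the mean
  bad_pp <- !is.finite(survey$P_presence)
  if (any(bad_pp))
    survey$P_presence[bad_pp] <- mean(survey$P_presence[!bad_pp])
  covs <- unique(c(covariates,
                   if (!is.null(occurrence)) "P_presence"))
  thresholds <- if (!is.null(occurrence)) occurrence$thresholds else
    rep(-Inf, B)

  params <- config$params
  tuning <- NULL
  if (config$tune == "once") {
    pres_all <- survey[survey[[ycol]] > 0, , drop = FALSE]
    tuning <- tune_abundance(pres_all, dcol, covs, config$grid,
                             config$cv_k, config$cv_repeats, seed)
    params <- tuning$best
  }

  b_counter <- new.env(); b_counter$i <- 0L

  fitter <- function(train) {
    pres <- train[train[[ycol]] > 0, , drop = FALSE]
    fit <- fit_abundance(pres, dcol, covs, params, min_sites = 10)
    raw_train <- fit$predict(pres)
    roe <- roe_correct(log(pres[[dcol]]), raw_train)
    D <- duan_smearing(log(pres[[dcol]]) - roe$corrected)
    predict_corrected <- function(newdata) {
      raw <- fit$predict(newdata)
      predict_density(raw, roe$a, roe$b, D, cell_area = 1)$density
    }
    list(predict = predict_corrected,
         aux = list(a = roe$a, b = roe$b, D = D), model = fit)
  }

  oob_stat <- function(fit_b, oob_data, train_data) {
    b_counter$i <- b_counter$i + 1L
    t_b <- thresholds[min(b_counter$i, length(thresholds))]
    dens <- fit_b$predict(oob_data)
    open <- oob_data$P_presence >= t_b
    pred_counts <- dens * oob_data$area * open
    obs_counts <- oob_data[[ycol]]
    suppressWarnings(
      c(rho = calibration_ratio(pred_counts, obs_counts)))
  }

  metrics <- list(presence_only(metric_spearman(), ycol),
                  presence_only(metric_pearson(), ycol),
                  presence_only(metric_r2(), ycol),
                  presence_only(metric_rmse(), ycol))
  boot <- bootstrap_fit(survey, fitter, dcol, metrics, B = B, seed = seed,
                        oob_stat = oob_stat)

  a_b <- aux_values(boot, "a"); b_b <- aux_values(boot, "b")
  D_b <- aux_values(boot, "D")
  rho_b <- if (!is.null(boot$iter_stats)) boot$iter_stats$rho else
    rep(NA_real_, B)

  # full-data raw model (uncorrected); map predictions apply the averaged
  # iteration corrections
  pres_full <- survey[survey[[ycol]] > 0, , drop = FALSE]
  full_fit <- fit_abundance(pres_full, dcol, covs, params, min_sites = 10)

  structure(list(
    species = species, covariates = covs, params = params, tuning = tuning,
    model = full_fit,
    a = mean(a_b), b = mean(b_b), D = mean(D_b),
    a_b = a_b, b_b = b_b, D_b = D_b, rho_b = rho_b,
    n_rho_excluded = sum(is.na(rho_b)),
    boot = boot, report = boot$report),
    class = "abundance_fit")
}

#' Predict density and per-cell counts over new cells
#'
#' Applies the full-data regressor with the averaged ROE and smearing
#' corrections.  `newdata` needs the model covariates including
#' `P_presence` (for cells, the occurrence-model probability map).
#'
#' @param object An `abundance_fit`.
#' @param newdata Cell table.
#' @param cell_area Cell area in m^2 (default 100).
#' @param ... Unused.
#' @return data.frame with `density` and `count`.
#' @export
predict.abundance_fit <- function(object, newdata, cell_area = 100, ...) {
  raw <- object$model$predict(newdata)
  predict_density(raw, object$a, object$b, object$D, cell_area)
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat("abundance model for", x$species, "- B =", x$boot$B, "iterations\n")
  cat(sprintf("ROE a = %.3f, b = %.3f; smearing D = %.3f; mean rho = %.3f\n",
              x$a, x$b, x$D, mean(x$rho_b, na.rm = TRUE)))
  print(x$report[, c("metric", "apparent", "mean_oob", "best")],
        digits = 3, row.names = FALSE)
  invisible(x)
}
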
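# Presence-absence modelling with prevalence-matched cut-off thresholds.
#
# Boosted-tree classifiers are tuned by repeated cross-validation on AUC;
# predicted probabilities are translated into presences with a cut-off
# chosen so that modelled prevalence matches the observed prevalence of
# the training data (stratified random sampling makes the observed
# prevalence an estimate of the true prevalence).  The whole stage runs
# under the bootstrap 0.632+ engine, which also collects the per-iteration
# thresholds and the per-site averaged out-of-bag occurrence probability.

#' Prevalence-matched classification threshold
#'
#' Returns the cut-off `t` such that the fraction of `scores >= t` matches
#' the target prevalence `p` as closely as the empirical score distribution
#' allows: the midpoint between the `ceiling(n p)`-th and the next largest
#' score (sentinels 1 above and 0 below at the extremes).
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param p Target prevalence in (0, 1\].  `p = 0` returns a threshold
#'   above the maximum score with a warning (everything absent).
#' @return The threshold `t`.
#' @export
prevalence_threshold <- function(scores, p) {
  n <- length(scores)
  if (n < 1) stop("empty scores")
  if (p < 0 || p > 1) stop("prevalence must be in [0, 1]")
  s <- sort(scores, decreasing = TRUE)
  if (p == 0) {
    warning("prevalence 0: threshold set above the maximum score")
    return(s[1] + 1e-9)
  }
  m <- ceiling(n * p)
  hi <- if (m >= 1) s[m] else 1
  lo <- if (m + 1 <= n) s[m + 1] else 0
  min(1, max(0, (hi + lo) / 2))
}

#' Binary classification of scores at a threshold
#'
#' Presence iff `score >= t`.
#'
#' @param scores Numeric scores.
#' @param t Finite threshold.
#' @return Integer 0/1 vector.
#' @export
classify <- function(scores, t) {
  if (!is.finite(t)) stop("threshold must be finite")
  as.integer(scores >= t)
}

#' Default tuning grid for the occurrence classifier
#'
#' A small desk-scale grid (shrinkage x trees x minimum node size); the
#' full-study grid is whatever data.frame the caller supplies.
#'
#' @export
default_occ_grid <- function() {
  expand.grid(eta = c(0.05, 0.1, 0.3), nrounds = c(40, 100, 200),
              min_child_weight = c(2, 10))
}

#' Tune and fit a boosted-tree classifier by repeated cross-validation
#'
#' Evaluates every grid point with `repeats` independent `k`-fold
#' cross-validations, selects the point with the highest mean AUC (first
#' row on ties), and refits on all training rows at that point.  Folds
#' lacking one of the classes are skipped and counted.
#'
#' @param data Training data.
#' @param response Name of the binary response column.
#' @param covariates Covariate column names.
#' @param grid data.frame with columns `eta`, `nrounds`,
#'   `min_child_weight`.
#' @param k,repeats Cross-validation folds and repeats (study protocol:
#'   k = 10, repeats = 10).
#' @param seed Integer seed.
#' @param max_depth Tree depth (fixed, not tuned).
#' @return List with the fitted `model` (see `fit_gbt`), `best` (chosen
#'   grid row), `cv` (per-point mean AUC and skipped-fold count).
#' @export
tune_and_fit_classifier <- function(data, response, covariates,
                                    grid = default_occ_grid(),
                                    k = 10, repeats = 10, seed = 1,
                                    max_depth = 3) {
  if (nrow(grid) < 1) stop("empty tuning grid")
  y <- as.numeric(data[[response]])
  if (length(unique(y)) < 2) stop("both classes required for tuning")
  set.seed(seed)
  n <- nrow(data)
  cv_auc <- matrix(NA_real_, nrow(grid), k * repeats)
  skipped <- 0L
  col <- 0L
  for (r in seq_len(repeats)) {
    folds <- sample(rep_len(seq_len(k), n))
    for (f in seq_len(k)) {
      col <- col + 1L
      test <- folds == f
      if (length(unique(y[test])) < 2 || length(unique(y[!test])) < 2) {
        skipped <- skipped + 1L
        next
      }
      for (g in seq_len(nrow(grid))) {
        p <- gbt_params(eta = grid$eta[g], nrounds = grid$nrounds[g],
                        max_depth = max_depth,
                        min_child_weight = grid$min_child_weight[g])
        fit <- fit_gbt(data[!test, , drop = FALSE], response, covariates, p)
        cv_auc[g, col] <- auc(y[test], fit$predict(data[test, , drop = FALSE]))
      }
    }
  }
  mean_auc <- rowMeans(cv_auc, na.rm = TRUE)
  g <- which.max(mean_auc)              # first row on ties
  best <- gbt_params(eta = grid$eta[g], nrounds = grid$nrounds[g],
                     max_depth = max_depth,
                     min_child_weight = grid$min_child_weight[g])
  model <- fit_gbt(data, response, covariates, best)
  list(model = model, best = cbind(grid[g, , drop = FALSE],
                                   mean_cv_auc = mean_auc[g]),
       cv = data.frame(grid, mean_cv_auc = mean_auc),
       skipped_folds = skipped)
}

#' Occurrence-model configuration
#'
#' @param params Boosted-tree hyperparameters used when `tune = "none"`,
#'   and as the fixed tree depth when tuning.
#' @param tune `"once"` (repeated-CV tuning on the full data, tuned
#'   hyperparameters reused in every bootstrap iteration) or `"none"`.
#' @param grid,cv_k,cv_repeats Tuning grid and repeated-CV specification.
#' @export
occ_config <- function(params = gbt_params(), tune = c("none", "once"),
                       grid = default_occ_grid(), cv_k = 10,
                       cv_repeats = 10) {
  tune <- match.arg(tune)
  list(params = params, tune = tune, grid = grid, cv_k = cv_k,
       cv_repeats = cv_repeats)
}

#' Presence-absence pipeline for one species
#'
#' Fits the classifier under the bootstrap 0.632+ engine.  Each iteration
#' refits the model on its bootstrap sample, computes the iteration's
#' prevalence-matched threshold `t_b` from the sample's own scores and
#' prevalence, and scores AUC, sensitivity, specificity, accuracy and TSS
#' (threshold metrics at `t_b`).  The final threshold is the mean of the
#' `t_b`; the per-site averaged out-of-bag probability is retained as the
#' `P_presence` covariate for the abundance stage.
#'
#' @param survey A survey table with a `count_<species>` column.
#' @param species Species name (suffix of the count column).
#' @param covariates Covariate column names.
#' @param B Bootstrap iterations (study protocol: 100).
#' @param seed Integer seed.
#' @param config An [occ_config()].
#' @return Object of class `occurrence_fit`: full-data `model`, tuning
#'   record, `thresholds` (t_b), `threshold` (mean), `p_presence`,
#'   `boot` (`boot_result`) and `report`.
#' @export
occurrence_pipeline <- function(survey, species, covariates, B = 100,
                                seed = 1, config = occ_config()) {
  ycol <- paste0("count_", species)
  if (is.null(survey[[ycol]])) stop("no count column for species ", species)
  survey$.presence <- as.integer(survey[[ycol]] > 0)
  if (length(unique(survey$.presence)) < 2)
    stop("species ", species, " has a single class")

  tuning <- NULL
  params <- config$params
  if (config$tune == "once") {
    tuning <- tune_and_fit_classifier(survey, ".presence", covariates,
                                      grid = config$grid, k = config$cv_k,
                                      repeats = config$cv_repeats,
                                      seed = seed,
                                      max_depth = config$params$max_depth)
    params <- gbt_params(eta = tuning$best$eta,
                         nrounds = tuning$best$nrounds,
                         max_depth = config$params$max_depth,
                         min_child_weight = tuning$best$min_child_weight)
  }

  fitter <- function(train) {
    y <- train$.presence
    if (length(unique(y)) < 2) {
      fit <- fit_constant(mean(y), covariates)
    } else {
      fit <- fit_gbt(train, ".presence", covariates, params)
    }
    scores <- fit$predict(train)
    t_b <- prevalence_threshold(scores, mean(y))
    list(predict = fit$predict, aux = list(threshold = t_b), model = fit)
  }

  metrics <- list(metric_auc(), metric_sensitivity(), metric_specificity(),
                  metric_accuracy(), metric_tss())
  boot <- bootstrap_fit(survey, fitter, ".presence", metrics, B = B,
                        seed = seed)

  structure(list(
    species = species, covariates = covariates,
    model = boot$full_fit$model, tuning = tuning, params = params,
    thresholds = aux_values(boot, "threshold"),
    threshold = mean(aux_values(boot, "threshold")),
    p_presence = oob_mean_prediction(boot),
    boot = boot, report = boot$report),
    class = "occurrence_fit")
}

#' Predict occurrence probability and presence over new cells
#'
#' @param object An `occurrence_fit`.
#' @param newdata Cell table (e.g. [seascape_cells()]).
#' @param ... Unused.
#' @return data.frame with `score` (probability) and `presence` (binary at
#'   the mean prevalence-matched threshold).
#' @export
predict.occurrence_fit <- function(object, newdata, ...) {
  s <- object$model$predict(newdata)
  data.frame(score = s, presence = classify(s, object$threshold))
}

#' @export
print.occurrence_fit <- function(x, ...) {
  cat("occurrence model for", x$species, "- B =", x$boot$B,
      "bootstrap iterations\n")
  cat("mean prevalence-matched threshold:", signif(x$threshold, 3), "\n")
  print(x$report[, c("metric", "apparent", "mean_oob", "best")],
        digits = 3, row.names = FALSE)
  invisible(x)
}
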
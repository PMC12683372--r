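# Zero-one-inflated models of proportional substrate cover.
#
# Observed covers live on [0, 1] with point masses at exactly 0 and 1; the
# model is a three-part hurdle decomposition: a classifier for no cover, a
# classifier for full cover among covered sites, and a boosted regression
# for the logit-transformed interior covers.  Expected cover is the
# mixture mean p1 + (1 - p0 - p1) * mu.

#' Substrate-model configuration
#'
#' @param learning_rate Boosting learning rate (study value 0.05).
#' @param max_iter Iteration cap for the boosted components.
#' @param nfold Internal cross-validation folds used to choose the
#'   stopping iteration.
#' @param early_stopping Rounds without improvement before stopping.
#' @param max_depth,min_child_weight Tree complexity controls.
#' @export
substrate_config <- function(learning_rate = 0.05, max_iter = 300,
                             nfold = 4, early_stopping = 10,
                             max_depth = 3, min_child_weight = 5) {
  list(learning_rate = learning_rate, max_iter = max_iter, nfold = nfold,
       early_stopping = early_stopping, max_depth = max_depth,
       min_child_weight = min_child_weight)
}

# one boosted component with the stopping iteration chosen by internal CV
fit_substrate_component <- function(data, y, covariates, config, objective) {
  if (length(y) == 0) return(fit_constant(0, covariates))
  if (length(unique(y)) < 2 || length(covariates) == 0) {
    # degenerate class or intercept-only contract: empirical constant
    return(fit_constant(mean(y), covariates))
  }
  X <- xgb_matrix(data, covariates)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
  par <- list(objective = objective, eta = config$learning_rate,
              max_depth = config$max_depth,
              min_child_weight = config$min_child_weight, nthread = 1)
  m_stop <- config$max_iter
  cv <- tryCatch(
    xgboost::xgb.cv(params = par, data = dtrain, nrounds = config$max_iter,
                    nfold = config$nfold,
                    early_stopping_rounds = config$early_stopping,
                    verbose = 0),
    error = function(e) NULL)
  if (!is.null(cv) && !is.null(cv$best_iteration))
    m_stop <- cv$best_iteration
  booster <- xgboost::xgb.train(params = par, data = dtrain,
                                nrounds = m_stop, verbose = 0)
  list(booster = booster, covariates = covariates, m_stop = m_stop,
       predict = function(newdata)
         stats::predict(booster, xgb_matrix(newdata, covariates)))
}

#' Fit a zero-one-inflated substrate cover model
#'
#' Three components: P(cover = 0), P(cover = 1 | cover > 0), and the
#' interior mean on the logit scale.  The stopping iteration of each
#' boosted component is chosen by internal cross-validation; with an empty
#' covariate list the components reduce to the empirical point-mass
#' probabilities and interior mean.
#'
#' @param data Sites with observed covers.
#' @param cover_col Name of the observed cover column (values in \[0, 1\]).
#' @param covariates Physical covariate columns (may be empty).
#' @param config A [substrate_config()].
#' @param min_sites Minimum observations (default 30).
#' @return Object of class `zoib_fit` with components `m0`, `m1`, `mu`,
#'   training ranges (for extrapolation flags) and the config.
#' @export
fit_substrate <- function(data, cover_col, covariates = character(),
                          config = substrate_config(), min_sites = 30) {
  v <- data[[cover_col]]
  if (is.null(v)) stop("no column ", cover_col)
  if (any(v < 0 | v > 1)) stop("covers must be in [0, 1]")
  if (nrow(data) < min_sites)
    stop("need >= ", min_sites, " sites with cover observations")
  is0 <- v == 0; is1 <- v == 1
  interior <- !is0 & !is1

  m0 <- fit_substrate_component(data, as.numeric(is0), covariates, config,
                                "binary:logistic")
  pos <- data[!is0, , drop = FALSE]
  m1 <- fit_substrate_component(pos, as.numeric(v[!is0] == 1), covariates,
                                config, "binary:logistic")
  mu <- NULL
  if (any(interior)) {
    di <- data[interior, , drop = FALSE]
    di$.logit_cover <- stats::qlogis(pmin(1 - 1e-6, pmax(1e-6, v[interior])))
    if (length(covariates) == 0) {
      mu <- fit_constant(mean(di$.logit_cover), covariates)
    } else {
      mu <- fit_substrate_component(di, di$.logit_cover, covariates, config,
                                    "reg:squarederror")
    }
  } else {
    warning("no interior covers; interior mean undefined, ",
            "predictions fall back to the point masses")
  }
  ranges <- if (length(covariates) > 0)
    lapply(data[, covariates, drop = FALSE], range) else list()
  structure(list(m0 = m0, m1 = m1, mu = mu, covariates = covariates,
                 ranges = ranges, config = config,
                 empirical = c(p0 = mean(is0),
                               p1 = if (any(!is0)) mean(v[!is0] == 1) else 0,
                               mu = if (any(interior)) mean(v[interior])
                               else NA_real_)),
            class = "zoib_fit")
}

#' Predict expected substrate cover and component probabilities
#'
#' `p1` is the unconditional full-cover probability
#' `(1 - p0) * P(cover = 1 | cover > 0)`, so `p0 + p1 + P(interior) = 1`
#' at every cell; expected cover is `p1 + (1 - p0 - p1) * mu`.  Cells with
#' any covariate outside the training range are flagged as extrapolation
#' (and still predicted).
#'
#' @param object A `zoib_fit`.
#' @param newdata Cell or site table with the model covariates.
#' @param ... Unused.
#' @return data.frame with `p0`, `p1`, `mu`, `expected`, `extrapolated`.
#' @export
predict.zoib_fit <- function(object, newdata, ...) {
  n <- nrow(newdata)
  p0 <- object$m0$predict(newdata)
  p1c <- object$m1$predict(newdata)
  p1 <- (1 - p0) * p1c
  if (!is.null(object$mu)) {
    mu <- stats::plogis(object$mu$predict(newdata))
    expected <- p1 + (1 - p0 - p1) * mu
  } else {
    # no interior mass observed: renormalise over the point masses
    mu <- rep(NA_real_, n)
    expected <- ifelse(p0 + p1 > 0, p1 / (p0 + p1), 0.5)
  }
  extrap <- rep(FALSE, n)
  for (v in names(object$ranges)) {
    r <- object$ranges[[v]]
    extrap <- extrap | newdata[[v]] < r[1] | newdata[[v]] > r[2]
  }
  data.frame(p0 = p0, p1 = p1, mu = mu, expected = expected,
             extrapolated = extrap)
}

#' Substrate model evaluation metrics
#'
#' `R^2` is the squared Pearson correlation between predicted expected and
#' observed cover; `zero_acc` / `one_acc` are the accuracies of predicting
#' exactly 0% / 100% cover with the component probabilities at a 0.5
#' threshold.  An accuracy whose class is absent in the evaluation set is
#' still defined (it is an accuracy over all sites); `R^2` is `NA` for
#' constant inputs.
#'
#' @param fit A `zoib_fit`.
#' @param data Evaluation sites.
#' @param cover_col Observed cover column.
#' @return List with `r2`, `zero_acc`, `one_acc`.
#' @export
substrate_metrics <- function(fit, data, cover_col) {
  v <- data[[cover_col]]
  pr <- predict(fit, data)
  r2 <- if (stats::sd(v) == 0 || stats::sd(pr$expected) == 0) NA_real_
  else stats::cor(v, pr$expected)^2
  list(r2 = r2,
       zero_acc = mean((pr$p0 >= 0.5) == (v == 0)),
       one_acc = mean((pr$p1 >= 0.5) == (v == 1)))
}

#' Substrate pipeline: fit, validate and map one cover response
#'
#' Runs the zero-one-inflated fit under the bootstrap 0.632+ engine
#' (metrics: R^2 and the 0/1-cover accuracies) and predicts expected cover
#' over the supplied cells.
#'
#' @param survey Sites with the observed cover column.
#' @param cover_col Observed cover column, e.g. `"P_HARD_obs"`.
#' @param covariates Physical covariates.
#' @param cells Cell table to map over (optional).
#' @param B Bootstrap iterations.
#' @param seed Integer seed.
#' @param config A [substrate_config()].
#' @return List of class `substrate_fit`: `fit` (full-data `zoib_fit`),
#'   `boot`, `report`, and `map` (predictions for `cells`).
#' @export
substrate_pipeline <- function(survey, cover_col, covariates, cells = NULL,
                               B = 100, seed = 1,
                               config = substrate_config()) {
  fitter <- function(train) {
    f <- fit_substrate(train, cover_col, covariates, config,
                       min_sites = 10)
    list(predict = function(nd) {
      p <- predict(f, nd)
      data.frame(score = p$expected, p0 = p$p0, p1 = p$p1)
    }, aux = list(), model = f)
  }
  m_r2 <- metric_r2()
  m_zero <- perf_metric("zero_acc", "gain",
    compute = function(obs, pred, aux, data)
      mean((pred$p0 >= 0.5) == (obs == 0)),
    noinfo = function(obs, pred, aux = NULL) {
      p <- mean(obs == 0); q <- mean(pred$p0 >= 0.5)
      p * q + (1 - p) * (1 - q)
    })
  m_one <- perf_metric("one_acc", "gain",
    compute = function(obs, pred, aux, data)
      mean((pred$p1 >= 0.5) == (obs == 1)),
    noinfo = function(obs, pred, aux = NULL) {
      p <- mean(obs == 1); q <- mean(pred$p1 >= 0.5)
      p * q + (1 - p) * (1 - q)
    })
  boot <- bootstrap_fit(survey, fitter, cover_col,
                        list(m_r2, m_zero, m_one), B = B, seed = seed)
  map <- if (!is.null(cells)) predict(boot$full_fit$model, cells) else NULL
  structure(list(cover_col = cover_col, fit = boot$full_fit$model,
                 boot = boot, report = boot$report, map = map),
            class = "substrate_fit")
}
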
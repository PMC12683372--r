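# Thin wrappers around the gradient-boosted tree learner (xgboost).
# All models in the pipeline go through these two functions so that the
# modelling modules stay independent of the engine.

xgb_matrix <- function(data, covariates) {
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0)
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Boosted-tree hyperparameters
#'
#' @param eta Learning rate (shrinkage).
#' @param nrounds Number of trees.
#' @param max_depth Maximum tree depth.
#' @param min_child_weight Minimum observations (hessian weight) per node.
#' @return Named list.
#' @export
gbt_params <- function(eta = 0.1, nrounds = 80, max_depth = 3,
                       min_child_weight = 5) {
  list(eta = eta, nrounds = nrounds, max_depth = max_depth,
       min_child_weight = min_child_weight)
}

# Fit a boosted-tree model; objective "binary:logistic" or
# "reg:squarederror".  Returns a list with a matrix-free predict().
fit_gbt <- function(data, response, covariates, params = gbt_params(),
                    objective = "binary:logistic") {
  X <- xgb_matrix(data, covariates)
  y <- as.numeric(data[[response]])
  # xgboost draws from the RNG; keep the caller's seed stream intact
  booster <- xgboost::xgb.train(
    params = list(objective = objective, eta = params$eta,
                  max_depth = params$max_depth,
                  min_child_weight = params$min_child_weight,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = params$nrounds, verbose = 0)
  list(booster = booster, covariates = covariates,
       predict = function(newdata)
         stats::predict(booster, xgb_matrix(newdata, covariates)))
}

# Constant-prediction fallback for degenerate training sets
fit_constant <- function(value, covariates = character()) {
  list(booster = NULL, covariates = covariates,
       predict = function(newdata) rep(value, nrow(newdata)))
}
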
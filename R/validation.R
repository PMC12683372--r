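# Performance metrics and the bootstrap 0.632+ validation engine.
#
# Any model stage is validated by fitting on B bootstrap samples of the
# data and scoring both the sample itself ("apparent") and the omitted
# sites ("out-of-bag"); the 0.632+ estimator combines the full-data
# apparent value with the mean out-of-bag value, weighted by the relative
# overfitting rate against a no-information rate.

#' Confusion-matrix metrics for binary predictions
#'
#' @param observed,predicted Binary (0/1 or logical) vectors of equal
#'   length.
#' @return List with `sensitivity` (TP/(TP+FN)), `specificity`
#'   (TN/(TN+FP)), `accuracy` and `tss` (sensitivity + specificity - 1).
#'   Metrics whose class is absent are `NA`.
#' @export
confusion_metrics <- function(observed, predicted) {
  o <- as.integer(as.logical(observed)); p <- as.integer(as.logical(predicted))
  if (length(o) != length(p) || length(o) < 1) stop("length mismatch")
  tp <- sum(o == 1 & p == 1); fn <- sum(o == 1 & p == 0)
  tn <- sum(o == 0 & p == 0); fp <- sum(o == 0 & p == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(o),
       tss = sens + spec - 1)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Fraction of (positive, negative) pairs in which the positive scores
#' higher, ties counted 0.5; computed from average ranks.
#'
#' @param observed Binary vector.
#' @param scores Numeric scores, larger = more positive.
#' @return AUC in \[0, 1\]; `NA` if only one class is present.
#' @export
auc <- function(observed, scores) {
  o <- as.logical(observed)
  n1 <- sum(o); n0 <- sum(!o)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)                     # average ranks handle ties as 0.5
  (sum(r[o]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Regression performance metrics
#'
#' @param observed,predicted Numeric vectors (length >= 3; observed
#'   non-constant).
#' @return List with Pearson `r`, Spearman `rho` (average ranks on ties),
#'   `r2` (squared Pearson r) and `rmse`.  Correlations are `NA` when
#'   predictions are constant; RMSE is always returned.
#' @export
regression_metrics <- function(observed, predicted) {
  if (length(observed) < 3) stop("need length >= 3")
  rmse <- sqrt(mean((observed - predicted)^2))
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    return(list(r = NA_real_, rho = NA_real_, r2 = NA_real_, rmse = rmse))
  r <- stats::cor(observed, predicted)
  rho <- stats::cor(observed, predicted, method = "spearman")
  list(r = r, rho = rho, r2 = r^2, rmse = rmse)
}

# ---- metric definitions -------------------------------------------------

#' Define a performance metric for the bootstrap engine
#'
#' @param name Metric name.
#' @param orientation `"gain"` (larger is better) or `"loss"`.
#' @param compute `function(obs, pred, aux, data)` returning a scalar;
#'   `pred` is whatever the fitter's `predict` returns, `aux` the fitter's
#'   auxiliary parameters and `data` the evaluated rows.
#' @param noinfo `function(obs, pred, aux)` returning the no-information rate
#'   gamma on the metric's own scale.
#' @return A list of class `perf_metric`.
#' @export
perf_metric <- function(name, orientation = c("gain", "loss"),
                        compute, noinfo) {
  orientation <- match.arg(orientation)
  structure(list(name = name, orientation = orientation,
                 compute = compute, noinfo = noinfo),
            class = "perf_metric")
}

as_score <- function(pred) {
  if (is.data.frame(pred)) {
    if (!is.null(pred$score)) pred$score else pred[[1]]
  } else as.numeric(pred)
}

bin_rates <- function(obs, pred_bin) {
  c(p = mean(as.logical(obs)), q = mean(as.logical(pred_bin)))
}

#' Standard metric set constructors
#'
#' `metric_auc()` scores probabilities; the confusion metrics binarise the
#' score with the fitter's `aux$threshold`; the regression metrics treat
#' the score as a numeric prediction.  No-information rates: AUC 0.5
#' (analytic); accuracy `p*q + (1-p)*(1-q)`; sensitivity `q`; specificity
#' `1-q`; TSS 0; correlations 0; RMSE the all-pairings value.
#'
#' @return A `perf_metric`.
#' @name standard_metrics
NULL

#' @rdname standard_metrics
#' @export
metric_auc <- function() perf_metric(
  "auc", "gain",
  compute = function(obs, pred, aux, data) auc(obs, as_score(pred)),
  noinfo = function(obs, pred, aux = NULL) 0.5)

pred_rate <- function(pred, aux) {
  t <- if (!is.null(aux$threshold)) aux$threshold else 0.5
  mean(as_score(pred) >= t)
}

conf_metric <- function(name, pick, noinfo) perf_metric(
  name, "gain",
  compute = function(obs, pred, aux, data) {
    if (is.null(aux$threshold)) stop("metric ", name, " needs aux$threshold")
    confusion_metrics(obs, classify(as_score(pred), aux$threshold))[[pick]]
  },
  noinfo = noinfo)

#' @rdname standard_metrics
#' @export
metric_accuracy <- function() conf_metric(
  "accuracy", "accuracy",
  function(obs, pred, aux = NULL) {
    p <- mean(as.logical(obs)); q <- pred_rate(pred, aux)
    p * q + (1 - p) * (1 - q)
  })

#' @rdname standard_metrics
#' @export
metric_sensitivity <- function() conf_metric(
  "sensitivity", "sensitivity",
  function(obs, pred, aux = NULL) pred_rate(pred, aux))

#' @rdname standard_metrics
#' @export
metric_specificity <- function() conf_metric(
  "specificity", "specificity",
  function(obs, pred, aux = NULL) 1 - pred_rate(pred, aux))

#' @rdname standard_metrics
#' @export
metric_tss <- function() conf_metric(
  "tss", "tss", function(obs, pred, aux = NULL) 0)

#' @rdname standard_metrics
#' @export
metric_rmse <- function() perf_metric(
  "rmse", "loss",
  compute = function(obs, pred, aux, data)
    sqrt(mean((obs - as_score(pred))^2)),
  noinfo = function(obs, pred, aux = NULL) {
    s <- as_score(pred)
    sqrt(mean(outer(obs, s, `-`)^2))
  })

cor_metric <- function(name, method) perf_metric(
  name, "gain",
  compute = function(obs, pred, aux, data) {
    s <- as_score(pred)
    if (stats::sd(s) == 0 || stats::sd(obs) == 0) return(NA_real_)
    v <- stats::cor(obs, s, method = method)
    if (name == "r2") v^2 else v
  },
  noinfo = function(obs, pred, aux = NULL) 0)

#' @rdname standard_metrics
#' @export
metric_pearson <- function() cor_metric("pearson_r", "pearson")

#' @rdname standard_metrics
#' @export
metric_spearman <- function() cor_metric("spearman_rho", "spearman")

#' @rdname standard_metrics
#' @export
metric_r2 <- function() cor_metric("r2", "pearson")

#' Restrict a metric to presence sites
#'
#' Wraps a metric so it is computed only on rows where `data[[presence_col]]`
#' is positive (used for conditional abundance models, whose domain is
#' presence sites).
#'
#' @param metric A `perf_metric`.
#' @param presence_col Column of `data` defining presences (`> 0`).
#' @export
presence_only <- function(metric, presence_col) {
  compute_inner <- metric$compute
  metric$compute <- function(obs, pred, aux, data) {
    keep <- data[[presence_col]] > 0
    if (sum(keep) < 3) return(NA_real_)
    s <- as_score(pred)
    compute_inner(obs[keep], s[keep], aux, data[keep, , drop = FALSE])
  }
  metric
}

#' No-information rate of a metric
#'
#' The expected metric value when predictions carry no information about
#' the observations: for binary misclassification `p(1-q) + (1-p)q`, for
#' AUC the analytic 0.5, for continuous losses the mean over all
#' observation-prediction pairings.
#'
#' @param observed Observed responses.
#' @param predictions Model predictions for the same rows.
#' @param metric A `perf_metric`.
#' @return gamma on the metric's own scale.
#' @export
no_information <- function(observed, predictions, metric) {
  metric$noinfo(observed, predictions, NULL)
}

#' Misclassification no-information rate
#'
#' `gamma = p(1-q) + (1-p)q` with `p` the observed and `q` the predicted
#' positive rate.
#'
#' @param observed,predicted Binary vectors.
#' @export
noinfo_misclassification <- function(observed, predicted) {
  p <- mean(as.logical(observed)); q <- mean(as.logical(predicted))
  p * (1 - q) + (1 - p) * q
}

# ---- the 0.632+ estimator ----------------------------------------------

#' Bootstrap 0.632+ best estimate
#'
#' On the loss scale: `oob' = min(oob, gamma)`;
#' `R = (oob' - apparent) / (gamma - apparent)` clipped to \[0, 1\] (R = 0
#' when `gamma <= apparent`; R = 1 when `gamma == apparent` but
#' `oob > apparent`); `w = 0.632 / (1 - 0.368 R)`; estimate =
#' `(1 - w) apparent + w oob'`.  Gain metrics are converted to losses as
#' `1 - value` and converted back.
#'
#' @param apparent Full-data apparent metric value.
#' @param oob Mean out-of-bag metric value.
#' @param gamma No-information rate on the metric's own scale.
#' @param orientation `"loss"` or `"gain"`.
#' @return The 0.632+ best estimate on the metric's own scale.
#' @export
err632plus <- function(apparent, oob, gamma,
                       orientation = c("loss", "gain")) {
  orientation <- match.arg(orientation)
  if (any(!is.finite(c(apparent, oob, gamma)))) return(NA_real_)
  a <- apparent; o <- oob; g <- gamma
  if (orientation == "gain") { a <- 1 - a; o <- 1 - o; g <- 1 - g }
  op <- min(o, g)
  if (g <= a) {
    R <- if (g == a && o > a) 1 else 0
  } else {
    R <- (op - a) / (g - a)
    R <- min(1, max(0, R))
  }
  w <- 0.632 / (1 - 0.368 * R)
  est <- (1 - w) * a + w * op
  if (orientation == "gain") 1 - est else est
}

# ---- engine -------------------------------------------------------------

#' Fit and validate a model with the bootstrap 0.632+ engine
#'
#' Draws `B` bootstrap samples of the rows of `data` (simple resampling
#' with replacement), applies `fitter` to each, and scores every metric on
#' the sample itself (apparent) and on the omitted rows (out-of-bag).  The
#' full-data fit provides the apparent value and the no-information rate
#' entering the 0.632+ estimate.
#'
#' @param data A data.frame of sites.
#' @param fitter `function(train_data)` returning a list with `predict`
#'   (`function(newdata)` -> numeric scores or a data.frame with a `score`
#'   column) and optionally `aux` (named list of fitted auxiliary
#'   parameters, e.g. a classification threshold).
#' @param response Name of the observed response column.
#' @param metrics List of [perf_metric()] objects.
#' @param B Number of bootstrap iterations (>= 1; the study protocol uses
#'   100).
#' @param seed Integer seed.
#' @param oob_stat Optional `function(fit, oob_data, train_data)` returning
#'   a named numeric vector of per-iteration statistics computed on the
#'   out-of-bag rows (e.g. a calibration ratio).
#' @return Object of class `boot_result`: `report` (per metric: apparent,
#'   mean OOB, gamma, 0.632+ best estimate, spread), per-iteration metric
#'   matrices, auxiliary parameters, an `n x B` matrix of out-of-bag
#'   predictions (`NA` where in-bag), out-of-bag set sizes, `iter_stats`,
#'   and the full-data fit.
#' @export
bootstrap_fit <- function(data, fitter, response, metrics, B = 100,
                          seed = 1, oob_stat = NULL) {
  stopifnot(B >= 1)
  set.seed(seed)
  n <- nrow(data)
  obs <- data[[response]]
  if (is.null(obs)) stop("response column not found: ", response)
  mnames <- vapply(metrics, `[[`, "", "name")

  full <- fitter(data)
  pred_full <- full$predict(data)
  apparent_full <- vapply(seq_along(metrics), function(m)
    metrics[[m]]$compute(obs, pred_full, full$aux, data), numeric(1))
  gamma <- vapply(seq_along(metrics), function(m)
    metrics[[m]]$noinfo(obs, pred_full, full$aux), numeric(1))

  app_iter <- matrix(NA_real_, B, length(metrics),
                     dimnames = list(NULL, mnames))
  oob_iter <- app_iter
  oob_pred <- matrix(NA_real_, n, B)
  oob_sizes <- integer(B)
  aux_list <- vector("list", B)
  stat_list <- vector("list", B)

  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    out_idx <- setdiff(seq_len(n), idx)
    oob_sizes[b] <- length(out_idx)
    fit_b <- fitter(data[idx, , drop = FALSE])
    aux_list[[b]] <- fit_b$aux
    p_in <- fit_b$predict(data[idx, , drop = FALSE])
    app_iter[b, ] <- vapply(seq_along(metrics), function(m)
      tryCatch(metrics[[m]]$compute(obs[idx], p_in, fit_b$aux,
                                    data[idx, , drop = FALSE]),
               error = function(e) NA_real_), numeric(1))
    if (length(out_idx) > 0) {
      p_out <- fit_b$predict(data[out_idx, , drop = FALSE])
      oob_pred[out_idx, b] <- as_score(p_out)
      oob_iter[b, ] <- vapply(seq_along(metrics), function(m)
        tryCatch(metrics[[m]]$compute(obs[out_idx], p_out, fit_b$aux,
                                      data[out_idx, , drop = FALSE]),
                 error = function(e) NA_real_), numeric(1))
      if (!is.null(oob_stat))
        stat_list[[b]] <- oob_stat(fit_b, data[out_idx, , drop = FALSE],
                                   data[idx, , drop = FALSE])
    }
  }

  mean_oob <- colMeans(oob_iter, na.rm = TRUE)
  n_excl <- colSums(is.na(oob_iter))
  best <- vapply(seq_along(metrics), function(m)
    err632plus(apparent_full[m], mean_oob[m], gamma[m],
               metrics[[m]]$orientation), numeric(1))
  qs <- apply(oob_iter, 2, stats::quantile,
              probs = c(0.025, 0.975), na.rm = TRUE)
  report <- data.frame(
    metric = mnames,
    orientation = vapply(metrics, `[[`, "", "orientation"),
    apparent = apparent_full,
    mean_oob = mean_oob,
    gamma = gamma,
    best = best,
    sd_oob = apply(oob_iter, 2, stats::sd, na.rm = TRUE),
    q025 = qs[1, ], q975 = qs[2, ],
    n_oob_excluded = n_excl,
    row.names = NULL)

  iter_stats <- if (any(!vapply(stat_list, is.null, logical(1)))) {
    as.data.frame(do.call(rbind, lapply(stat_list, function(s)
      if (is.null(s)) NA else s)))
  } else NULL

  structure(list(report = report, apparent_full = stats::setNames(
    apparent_full, mnames), apparent_iter = app_iter,
    oob_iter = oob_iter, gamma = stats::setNames(gamma, mnames),
    aux = aux_list, oob_pred = oob_pred, oob_sizes = oob_sizes,
    iter_stats = iter_stats, B = B, seed = seed, full_fit = full),
    class = "boot_result")
}

#' Extract one auxiliary parameter across bootstrap iterations
#'
#' @param boot A `boot_result`.
#' @param name Name of the auxiliary parameter.
#' @return Numeric vector of length `B` (`NA` where absent).
#' @export
aux_values <- function(boot, name) {
  vapply(boot$aux, function(a)
    if (is.null(a[[name]])) NA_real_ else as.numeric(a[[name]]), numeric(1))
}

#' Per-site averaged out-of-bag prediction
#'
#' For each site, the mean of its out-of-bag predictions over the
#' iterations in which it was omitted (the `P_presence` covariate of the
#' abundance stage when applied to an occurrence model).
#'
#' @param boot A `boot_result`.
#' @return Numeric vector of length `nrow(data)`.
#' @export
oob_mean_prediction <- function(boot) {
  rowMeans(boot$oob_pred, na.rm = TRUE)
}

#' @export
print.boot_result <- function(x, ...) {
  cat("bootstrap 0.632+ validation,", x$B, "iterations\n")
  print(x$report[, c("metric", "apparent", "mean_oob", "gamma", "best")],
        digits = 3, row.names = FALSE)
  invisible(x)
}
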
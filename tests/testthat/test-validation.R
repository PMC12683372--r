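# Metric suite and the bootstrap 0.632+ engine.

test_that("confusion metrics count correctly", {
  o <- c(rep(1, 10), rep(0, 10))
  p <- c(rep(1, 8), rep(0, 2), rep(1, 3), rep(0, 7))
  m <- confusion_metrics(o, p)       # TP=8 FN=2 TN=7 FP=3
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$tss, 0.5)
  perf <- confusion_metrics(c(1, 1, 0), c(1, 1, 0))
  expect_equal(perf$tss, 1)
  expect_true(is.na(confusion_metrics(c(1, 1), c(1, 0))$specificity))
})

test_that("AUC follows the Mann-Whitney pair count", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(auc(c(1, 0), c(5, 1)), 1)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)   # all ties
  expect_true(is.na(auc(c(1, 1), c(0.2, 0.4))))
  # invariance under strictly monotone transforms of the scores
  set.seed(1)
  o <- rbinom(50, 1, 0.4); s <- runif(50)
  expect_equal(auc(o, s), auc(o, qlogis(s)))
  expect_equal(auc(o, s), auc(o, s^3))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  o <- rbinom(200, 1, 0.3); s <- plogis(rnorm(200) + o)
  ref <- as.numeric(pROC::auc(pROC::roc(o, s, quiet = TRUE)))
  expect_equal(auc(o, s), ref, tolerance = 1e-12)
})

test_that("regression metrics match hand sums", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3))
  perf <- regression_metrics(1:5, 1:5)
  expect_equal(perf$r, 1); expect_equal(perf$rho, 1)
  expect_equal(perf$rmse, 0)
  anti <- regression_metrics(1:5, -(1:5))
  expect_equal(anti$r, -1); expect_equal(anti$rho, -1)
  const <- regression_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_true(is.na(const$r)); expect_equal(const$rmse, sqrt(2 / 3))
})

test_that("no-information rates follow their stated rules", {
  # balanced classes, all-negative predictions -> 0.5 misclassification
  expect_equal(noinfo_misclassification(c(1, 1, 0, 0), c(0, 0, 0, 0)), 0.5)
  # AUC: analytic 0.5 regardless of data
  expect_equal(no_information(c(1, 0), c(9, 1), metric_auc()), 0.5)
  # squared-error loss over all pairings: obs {0,2} x preds {0,2}
  g <- no_information(c(0, 2), c(0, 2), metric_rmse())
  expect_equal(g^2, (0 + 4 + 4 + 0) / 4)
})

test_that("the 0.632+ estimator reproduces hand-computed values", {
  # direct evaluation of the stated formulas as an independent oracle:
  # R = (0.20-0.05)/(0.50-0.05) = 1/3; w = 0.632/(1-0.368/3)
  w <- 0.632 / (1 - 0.368 / 3)
  oracle <- (1 - w) * 0.05 + w * 0.20
  expect_equal(err632plus(0.05, 0.20, 0.5, "loss"), oracle)
  expect_equal(oracle, 0.1581, tolerance = 1e-3)
  # R = 0 limit: apparent == oob -> estimate is the apparent value exactly
  expect_equal(err632plus(0.1, 0.1, 0.5, "loss"), 0.1)
  # R = 1 limit: oob worse than chance -> gamma-capped oob exactly
  expect_equal(err632plus(0.05, 0.7, 0.5, "loss"), 0.5)
  # gamma == apparent with oob > apparent -> maximal overfitting
  expect_equal(err632plus(0.3, 0.4, 0.3, "loss"), 0.3)
  # gain metrics go through the 1 - value transform and back
  expect_equal(err632plus(0.95, 0.80, 0.5, "gain"),
               1 - err632plus(0.05, 0.20, 0.5, "loss"))
})

test_that("best estimate lies between apparent and capped mean OOB", {
  set.seed(3)
  for (i in 1:200) {
    a <- runif(1); o <- runif(1); g <- runif(1)
    est <- err632plus(a, o, g, "loss")
    lo <- min(a, min(o, g)); hi <- max(a, min(o, g))
    expect_true(est >= lo - 1e-12 && est <= hi + 1e-12)
  }
})

test_that("engine: determinism, OOB geometry and report shape", {
  set.seed(4)
  n <- 150
  d <- data.frame(x = rnorm(n))
  d$y <- as.integer(plogis(2 * d$x) > runif(n))
  fitter <- function(train) {
    m <- stats::glm(y ~ x, binomial, data = train)
    scores <- function(nd) stats::predict(m, nd, type = "response")
    list(predict = scores,
         aux = list(threshold = prevalence_threshold(scores(train),
                                                     mean(train$y))))
  }
  mets <- list(metric_auc(), metric_accuracy())
  b1 <- bootstrap_fit(d, fitter, "y", mets, B = 30, seed = 9)
  b2 <- bootstrap_fit(d, fitter, "y", mets, B = 30, seed = 9)
  expect_identical(b1$report, b2$report)
  expect_identical(b1$oob_pred, b2$oob_pred)
  # mean OOB set size within 3 SE of n(1-1/n)^n (~ n/e)
  expected <- n * (1 - 1 / n)^n
  se <- stats::sd(b1$oob_sizes) / sqrt(length(b1$oob_sizes))
  expect_lt(abs(mean(b1$oob_sizes) - expected), 3 * se)
  # OOB sets disjoint from their bootstrap sample by construction:
  # every OOB prediction row was absent from the iteration's fit
  expect_true(all(colSums(!is.na(b1$oob_pred)) == b1$oob_sizes))
  expect_equal(b1$report$metric, c("auc", "accuracy"))
})

test_that("a memorising fitter is caught by the 0.632+ correction", {
  set.seed(5)
  n <- 120
  d <- data.frame(x = rnorm(n), y = rbinom(n, 1, 0.5))  # pure noise labels
  # 1-nearest-neighbour memoriser
  fitter <- function(train) {
    list(predict = function(nd) {
      idx <- vapply(nd$x, function(v) which.min(abs(train$x - v)),
                    integer(1))
      train$y[idx]
    }, aux = list(threshold = 0.5))
  }
  b <- bootstrap_fit(d, fitter, "y", list(metric_accuracy()), B = 40,
                     seed = 10)
  r <- b$report
  expect_equal(r$apparent, 1)                  # memorised training data
  expect_lt(r$mean_oob, 1)                     # honest out-of-bag accuracy
  expect_true(r$best < r$apparent && r$best > r$mean_oob - 1e-12)
})

test_that("degenerate bootstrap case: constant data gives zero loss", {
  d <- data.frame(y = rep(2, 20))
  fitter <- function(train)
    list(predict = function(nd) rep(mean(train$y), nrow(nd)), aux = NULL)
  b <- bootstrap_fit(d, fitter, "y", list(metric_rmse()), B = 1, seed = 1)
  expect_equal(b$report$apparent, 0)
  expect_equal(b$report$mean_oob, 0)
})
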
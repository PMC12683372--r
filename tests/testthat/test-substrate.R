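# Zero-one-inflated substrate cover models.

# generator for ZOIB observations used as the recovery oracle
r_zoib <- function(n, p0, p1, shape = c(2, 2)) {
  u <- runif(n)
  v <- numeric(n)
  v[u < p0] <- 0
  v[u >= p0 & u < p0 + p1] <- 1
  interior <- u >= p0 + p1
  v[interior] <- rbeta(sum(interior), shape[1], shape[2])
  v
}

test_that("degenerate cover distributions give degenerate predictions", {
  d <- data.frame(x = rnorm(50))
  d$cov0 <- 0
  f0 <- suppressWarnings(fit_substrate(d, "cov0", "x"))
  p0 <- predict(f0, d)
  expect_true(all(p0$expected < 0.05))
  d$cov1 <- 1
  f1 <- suppressWarnings(fit_substrate(d, "cov1", "x"))
  expect_true(all(predict(f1, d)$expected > 0.95))
})

test_that("expected cover is the mixture mean", {
  # hand-built fit: p0 = 0.2, unconditional p1 = 0.3, mu = 0.4 -> 0.5
  fit <- structure(list(
    m0 = bivalvepop:::fit_constant(0.2),
    m1 = bivalvepop:::fit_constant(0.3 / (1 - 0.2)),
    mu = bivalvepop:::fit_constant(stats::qlogis(0.4)),
    covariates = character(), ranges = list()),
    class = "zoib_fit")
  pr <- predict(fit, data.frame(x = 1:3))
  expect_equal(pr$p0, rep(0.2, 3))
  expect_equal(pr$p1, rep(0.3, 3), tolerance = 1e-12)
  expect_equal(pr$expected, rep(0.3 + 0.5 * 0.4, 3), tolerance = 1e-12)
  # mixture normalisation: p0 + p1 + P(interior) = 1
  expect_equal(pr$p0 + pr$p1 + (1 - pr$p0 - pr$p1), rep(1, 3))
  # point-mass limits
  f_p0 <- structure(list(m0 = bivalvepop:::fit_constant(1),
                         m1 = bivalvepop:::fit_constant(0),
                         mu = bivalvepop:::fit_constant(0),
                         covariates = character(), ranges = list()),
                    class = "zoib_fit")
  expect_equal(predict(f_p0, data.frame(x = 1))$expected, 0)
})

test_that("covariate-free ZOIB parameters are recovered", {
  set.seed(1)
  v <- r_zoib(2000, p0 = 0.3, p1 = 0.2)
  d <- data.frame(cover = v)
  fit <- fit_substrate(d, "cover", character())
  pr <- predict(fit, d[1, , drop = FALSE])
  expect_lt(abs(pr$p0 - 0.3), 0.05)
  expect_lt(abs(pr$p1 - 0.2), 0.05)
  expect_lt(abs(pr$mu - 0.5), 0.05)
})

test_that("covariate-driven cover is recovered with positive rank correlation", {
  set.seed(2)
  n <- 1200
  d <- data.frame(depth = runif(n, 0, 10), slope = rnorm(n))
  latent <- plogis(1.5 - 0.4 * d$depth + 0.3 * d$slope)
  u <- runif(n)
  d$cover <- ifelse(u < 0.25 * (1 - latent) * 2, 0,
                    ifelse(u > 1 - 0.2 * latent * 2, 1,
                           plogis(qlogis(latent) + rnorm(n, 0, 0.7))))
  truth <- latent
  fit <- fit_substrate(d, "cover", c("depth", "slope"),
                       substrate_config(max_iter = 150))
  pr <- predict(fit, d)
  expect_gt(stats::cor(pr$expected, truth, method = "spearman"), 0.5)
  expect_true(all(pr$p0 >= 0 & pr$p1 >= 0 & pr$p0 + pr$p1 <= 1 + 1e-9))
  expect_true(all(pr$expected >= 0 & pr$expected <= 1))
})

test_that("substrate metrics agree with a straight-line reimplementation", {
  set.seed(3)
  v <- r_zoib(300, 0.25, 0.15)
  d <- data.frame(cover = v, x = rnorm(300))
  fit <- fit_substrate(d, "cover", character())
  m <- substrate_metrics(fit, d, "cover")
  pr <- predict(fit, d)
  expect_equal(m$zero_acc, sum((pr$p0 >= 0.5) == (v == 0)) / 300)
  expect_equal(m$one_acc, sum((pr$p1 >= 0.5) == (v == 1)) / 300)
  # constant expected cover -> R^2 undefined, accuracies still defined
  expect_true(is.na(m$r2) || (m$r2 >= 0 && m$r2 <= 1))
  # perfect component predictions: both accuracies 1
  fitp <- structure(list(m0 = list(predict = function(nd) as.numeric(nd$cover == 0)),
                         m1 = list(predict = function(nd) {
                           p0 <- as.numeric(nd$cover == 0)
                           ifelse(p0 == 1, 0, as.numeric(nd$cover == 1))
                         }),
                         mu = bivalvepop:::fit_constant(0),
                         covariates = character(), ranges = list()),
                    class = "zoib_fit")
  mp <- substrate_metrics(fitp, d, "cover")
  expect_equal(mp$zero_acc, 1); expect_equal(mp$one_acc, 1)
})

test_that("extrapolation beyond the training hull is flagged", {
  set.seed(4)
  d <- data.frame(cover = r_zoib(100, 0.2, 0.2), depth = runif(100, 2, 8))
  fit <- fit_substrate(d, "cover", "depth",
                       substrate_config(max_iter = 30))
  pr <- predict(fit, data.frame(depth = c(5, 11)))
  expect_equal(pr$extrapolated, c(FALSE, TRUE))
})

test_that("substrate pipeline validates under the bootstrap engine", {
  set.seed(5)
  s <- tiny_seascape(seed = 51, n = 40)
  tr <- constant_truth(s, 1)
  sv <- sample_sites(s, tr, flat_design(250), seed = 6)
  fit <- substrate_pipeline(sv, "P_HARD_obs",
                            c("depth", "slope", "X"),
                            cells = seascape_cells(s), B = 6, seed = 7,
                            config = substrate_config(max_iter = 60))
  r <- fit$report
  # apparent fit at least as good as the corrected best estimate
  expect_gte(r$apparent[r$metric == "r2"], r$best[r$metric == "r2"] - 1e-9)
  expect_true(all(fit$map$expected >= 0 & fit$map$expected <= 1))
})
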
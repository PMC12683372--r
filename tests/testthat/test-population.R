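# The three population estimators and biomass conversion.

test_that("stratification partitions the mask exactly", {
  s <- tiny_seascape(seed = 41)
  strat <- zone_stratification(s)
  expect_equal(sum(strat$areas$area_m2), sum(s$mask) * cell_area(s))
  expect_equal(sum(strat$areas$n_cells), nrow(strat$cells))
  # depth exactly 10 lands in the last stratum (closure)
  expect_equal(depth_stratum_of(10, c(0, 0.5, 3, 6, 10)), 4L)
  expect_equal(depth_stratum_of(0.5, c(0, 0.5, 3, 6, 10)), 2L)
  expect_true(is.na(depth_stratum_of(10.5, c(0, 0.5, 3, 6, 10))))
})

test_that("Method 1 reproduces the stratified-sampling closed forms", {
  # two strata: A1=1e4, d1=2, s1^2=1, n1=5; A2=5e3, d2=0.4, s2^2=0.1, n2=5
  mk <- function(mu, s2, n) {
    v <- scale(rnorm(n))[, 1]                   # exact mean 0, sd 1
    mu + sqrt(s2) * v
  }
  set.seed(1)
  d1 <- mk(2, 1, 5); d2 <- mk(0.4, 0.1, 5)
  sv <- data.frame(Y = 0.5, depth = c(rep(1, 5), rep(7, 5)),
                   density_sp = c(d1, d2))
  strat <- toy_stratification(
    data.frame(zone = 1, stratum = 1:2, n_cells = c(100, 50),
               area_m2 = c(1e4, 5e3)),
    data.frame(zone = 1, stratum = c(rep(1, 100), rep(2, 50)), cell = 1:150),
    n_zones = 1, depth_breaks = c(0, 5, 10))
  est <- method1(sv, strat, "density_sp")
  expect_equal(est$N, 1e4 * 2 + 5e3 * 0.4, tolerance = 1e-9)
  expect_equal(est$se, sqrt(1e8 * 1 / 5 + 2.5e7 * 0.1 / 5), tolerance = 1e-9)
  expect_equal(sum(est$breakdown$N), est$N)
  # constant density: SE 0; all-zero counts: estimate 0
  svc <- data.frame(Y = 0.5, depth = rep(1, 5), density_sp = 2)
  strat1 <- toy_stratification(
    data.frame(zone = 1, stratum = 1, n_cells = 100, area_m2 = 1e4),
    data.frame(zone = 1, stratum = 1, cell = 1:100),
    n_zones = 1, depth_breaks = c(0, 10))
  e1 <- method1(svc, strat1, "density_sp")
  expect_equal(e1$N, 20000); expect_equal(e1$se, 0)
  svz <- within(svc, density_sp <- 0)
  expect_equal(method1(svz, strat1, "density_sp")$N, 0)
})

test_that("Method 1 pools across zones for empty strata", {
  sv <- data.frame(Y = c(0.1, 0.1, 0.1), depth = rep(1, 3),
                   density_sp = c(1, 2, 3))
  strat <- toy_stratification(
    data.frame(zone = 1:2, stratum = 1, n_cells = c(10, 10),
               area_m2 = c(1e3, 1e3)),
    data.frame(zone = rep(1:2, each = 10), stratum = 1, cell = 1:20),
    n_zones = 2, depth_breaks = c(0, 10))
  expect_warning(est <- method1(sv, strat, "density_sp"), "pooled mean")
  # zone 2 (no sites) borrows the pooled depth-stratum mean of 2
  expect_equal(est$N, 1e3 * 2 + 1e3 * 2)
})

test_that("Method 2 matches exhaustive enumeration on a toy grid", {
  # 10 cells in one stratum, known scores, two thresholds
  scores <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  th <- c(0.45, 0.75)
  cells <- data.frame(zone = 1, stratum = 1, cell = 1:10)
  strat <- toy_stratification(
    data.frame(zone = 1, stratum = 1, n_cells = 10, area_m2 = 1000),
    cells, cell_area = 100, n_zones = 1, depth_breaks = c(0, 10))
  sv <- data.frame(Y = 0.5, depth = rep(2, 4),
                   density_sp = c(0, 2, 4, 0))       # presence mean 3
  est <- method2(sv, strat, "density_sp", scores, th)
  # enumeration oracle: occupied areas 6*100 and 3*100 -> mean 450
  occ <- c(sum(scores >= 0.45), sum(scores >= 0.75)) * 100
  expect_equal(est$N, mean(occ) * 3)
  dvar <- stats::var(c(2, 4)) / 2
  expect_equal(est$se, sqrt(3^2 * stats::sd(occ)^2 + mean(occ)^2 * dvar))
  # thresholds above every score: nothing occupied
  e0 <- method2(sv, strat, "density_sp", scores, c(1.5))
  expect_equal(e0$N, 0)
  # identical thresholds + all sites present: fixed-area extrapolation
  sv2 <- data.frame(Y = 0.5, depth = rep(2, 3), density_sp = c(1, 2, 3))
  e2 <- method2(sv2, strat, "density_sp", scores, c(0.05, 0.05))
  expect_equal(e2$N, 1000 * 2)
})

test_that("Method 3 is a calibrated ratio with scaling invariance", {
  # direct arithmetic: S = {100, 120}, rho = {1.0, 1.2} -> 110/1.1 = 100
  counts <- c(100, 20)
  scores <- c(0.9, 0.4)
  th <- c(0.5, 0.3)
  S_b <- vapply(th, function(t) sum(counts[scores >= t]), numeric(1))
  expect_equal(S_b, c(100, 120))
  est <- method3(counts, scores, th, c(1.0, 1.2))
  expect_equal(est$N, 100)
  # rho == 1: plain mean of masked sums; rho == 2: halved
  expect_equal(method3(counts, scores, th, c(1, 1))$N, 110)
  expect_equal(method3(counts, scores, th, c(2, 2))$N, 55)
  # scaling all counts by c scales rho by c and leaves N unchanged
  c_fac <- 3.7
  e_sc <- method3(c_fac * counts, scores, th, c_fac * c(1.0, 1.2))
  expect_equal(e_sc$N, est$N)
  expect_error(method3(counts, scores, th, c(NA, NA)), "no defined")
})

test_that("biomass conversion propagates errors", {
  e <- list(N = 1e6, se = 0)
  b <- biomass(e, w = 1, w_se = 0)
  expect_equal(b$tonnes, 1); expect_equal(b$se, 0)
  # SE(w) = 0: SE(B) = w * SE(N) exactly
  e2 <- list(N = 1e6, se = 2e5)
  b2 <- biomass(e2, w = 2.5)
  expect_equal(b2$se, 2.5 * 2e5 / 1e6)
  expect_warning(b3 <- biomass(e2, w = NA), "omitted")
  expect_true(is.na(b3$tonnes))
})
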
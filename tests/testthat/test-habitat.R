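# Habitat summaries, overlap and central depth ranges.

test_that("subsampling is deterministic and bounded", {
  d <- data.frame(x = 1:500)
  s1 <- subsample_cells(d, 100, seed = 1)
  s2 <- subsample_cells(d, 100, seed = 1)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100)
  expect_identical(subsample_cells(d, 500, seed = 1), d)
  expect_warning(all_d <- subsample_cells(d, 600, seed = 1), "taking all")
  expect_identical(all_d, d)
})

test_that("subsample availability converges on full-mask proportions", {
  set.seed(2)
  d <- data.frame(depth = runif(4000, 0, 10), exposure = 10^runif(4000, 3, 5))
  full_frac <- mean(d$depth < 5)
  fracs <- vapply(1:30, function(i)
    mean(subsample_cells(d, 400, seed = i)$depth < 5), numeric(1))
  se <- sqrt(full_frac * (1 - full_frac) / 400)  # ~hypergeometric scale
  expect_lt(abs(mean(fracs) - full_frac), 3 * se / sqrt(30))
})

test_that("habitat stratification matches hand tabulation", {
  # 12 cells: depths in two bins, both exposure classes
  d <- data.frame(
    depth = c(0.2, 0.3, 0.4, 0.2, 0.7, 0.8, 0.9, 0.6, 0.7, 0.2, 0.3, 0.8),
    exposure = c(rep(1e3, 9), rep(2e4, 3)))
  pres <- list(sp = c(1, 0, 1, 0, 1, 1, 0, 0, 1, 1, 0, 1))
  dens <- list(sp = c(2, 0, 4, 0, 1, 1, 0, 0, 2, 6, 0, 4))
  h <- stratify_habitat(d, pres, dens)
  r1 <- h[h$depth_lo == 0 & h$exposure_class == "sheltered", ]
  expect_equal(r1$available, 4)
  expect_equal(r1$occ_sp, 2 / 4)
  expect_equal(r1$dens_sp, 6 / 4)
  r2 <- h[h$depth_lo == 0 & h$exposure_class == "exposed", ]
  expect_equal(r2$available, 2)         # cells 10, 11
  expect_equal(r2$occ_sp, 1 / 2)
  # conservation: shares sum to 1 and re-multiply to the species total
  expect_equal(sum(h$share_sp, na.rm = TRUE), 1)
  expect_equal(sum(h$share_sp, na.rm = TRUE) * sum(dens$sp), sum(dens$sp))
  # occupancy 1 in every non-empty bin for a ubiquitous species
  h2 <- stratify_habitat(d, list(a = rep(1, 12)))
  expect_true(all(h2$occ_a[h2$available > 0] == 1))
})

test_that("overlap table matches full enumeration on the 10-cell toy", {
  A <- as.integer(1:10 %in% 1:4)
  B <- as.integer(1:10 %in% 3:6)
  C <- as.integer(1:10 %in% 7)
  ot <- overlap_table(list(A = A, B = B, C = C))
  gp <- function(lbl) ot$combinations$pct[ot$combinations$species == lbl]
  expect_equal(gp("none"), 30)
  expect_equal(gp("A"), 20)
  expect_equal(gp("A+B"), 20)
  expect_equal(gp("B"), 20)
  expect_equal(gp("C"), 10)
  expect_equal(sum(ot$combinations$pct), 100)
  expect_equal(unname(ot$total_pct), c(40, 40, 10))
  # T equals the sum of combinations containing the species
  expect_equal(ot$total_pct[["A"]], gp("A") + gp("A+B"))
  # disjoint layers: no pairwise combinations
  ot2 <- overlap_table(list(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1)))
  expect_true(all(ot2$combinations$pct[grepl("\\+", ot2$combinations$species)] == 0))
  # identical layers: only "none" and "all three" non-zero
  ot3 <- overlap_table(list(a = c(1, 1, 0), b = c(1, 1, 0), c = c(1, 1, 0)))
  nz <- ot3$combinations[ot3$combinations$pct > 0, "species"]
  expect_setequal(nz, c("none", "a+b+c"))
  expect_error(overlap_table(list(a = 1:3, b = 1:2, c = 1:3)), "misaligned")
})

test_that("central range is the shortest window and is monotone in mass", {
  # all mass in the first bin
  expect_equal(central_range(c(1, 0, 0), c(0, 0.5, 1, 1.5)), c(0, 0.5))
  # exhaustive-window oracle: {0.5, 0.3, 0.2} at mass 0.8 -> [0, 1)
  expect_equal(central_range(c(0.5, 0.3, 0.2), c(0, 0.5, 1, 1.5)), c(0, 1))
  # uniform shares over [0,10): 16 of 20 bins, tie broken shallow
  u <- rep(1 / 20, 20)
  expect_equal(central_range(u, seq(0, 10, 0.5)), c(0, 8))
  # monotonicity: larger mass never gives a shorter interval
  set.seed(3)
  sh <- diff(sort(c(0, runif(9), 1)))
  w1 <- diff(central_range(sh, seq(0, 5, 0.5), mass = 0.5))
  w2 <- diff(central_range(sh, seq(0, 5, 0.5), mass = 0.9))
  expect_gte(w2, w1)
  expect_error(central_range(c(1, 0), c(0, 1, 2), mass = 1.5), "mass")
})

test_that("importance scaling and partial dependence behave", {
  set.seed(4)
  n <- 300
  d <- data.frame(x = runif(n, -2, 2), junk = rnorm(n))
  d$y <- 2 * d$x + 1
  fit <- bivalvepop:::fit_gbt(d, "y", c("x", "junk"),
                              gbt_params(eta = 0.1, nrounds = 200),
                              objective = "reg:squarederror")
  ip <- importance_and_partials(fit, d, c("x", "junk"), grid_n = 15)
  expect_equal(ip$importance$scaled[ip$importance$variable == "x"], 100)
  expect_lt(ip$importance$scaled[ip$importance$variable == "junk"], 10)
  # partial dependence of a pure function model reproduces it on the grid
  f <- function(nd) 2 * nd$x + 1
  ip2 <- importance_and_partials(f, d, c("x", "junk"), grid_n = 11)
  expect_equal(ip2$partials$x$yhat, 2 * ip2$partials$x$value + 1)
  # junk variable has a flat curve under the pure model
  expect_equal(diff(range(ip2$partials$junk$yhat)), 0)
  # permutation fallback ranks the signal variable first
  expect_gt(ip2$importance$scaled[ip2$importance$variable == "x"],
            ip2$importance$scaled[ip2$importance$variable == "junk"])
})
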
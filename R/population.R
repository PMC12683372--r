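# Population-size estimators with propagated standard errors.
#
# Method 1: design-based stratified extrapolation of mean observed
#   densities (presences and absences) over zone x depth-stratum areas.
# Method 2: mean observed presence densities times the area predicted
#   occupied at each bootstrap cut-off threshold, with product-variance
#   error propagation.
# Method 3: the thresholded abundance-model count map, divided by the mean
#   calibration ratio between predicted and observed individuals on
#   omitted sites.
#
# Per-iteration quantities are bootstrap replicates of statistics computed
# from a single data set, so their spread (SD across iterations, not
# SD/sqrt(B)) is used as the bootstrap standard error.

#' Zone x depth stratification of a seascape
#'
#' Five (by default) equal partitions of the coastal position `Y` crossed
#' with depth strata (half-open `[a, b)`, last closed at the deepest
#' break); areas come from the masked grid at `cell_size^2` m^2 per cell.
#'
#' @param seascape A `seascape`.
#' @param n_zones Number of coastal zones.
#' @param depth_breaks Depth stratum boundaries (m).
#' @return Object of class `zone_stratification`: `areas` data.frame
#'   (zone, stratum, area_m2, n_cells), assignment helpers and the cell
#'   table with `zone`/`stratum` labels.
#' @export
zone_stratification <- function(seascape, n_zones = 5,
                                depth_breaks = c(0, 0.5, 3, 6, 10)) {
  cells <- seascape_cells(seascape)
  cells$stratum <- depth_stratum_of(cells$depth, depth_breaks)
  cells$zone <- zone_of(cells$Y, n_zones)
  keep <- !is.na(cells$stratum)
  cells <- cells[keep, , drop = FALSE]
  a <- cell_area(seascape)
  k <- length(depth_breaks) - 1L
  grid <- expand.grid(zone = seq_len(n_zones), stratum = seq_len(k))
  cnt <- mapply(function(z, s) sum(cells$zone == z & cells$stratum == s),
                grid$zone, grid$stratum)
  areas <- data.frame(grid, n_cells = cnt, area_m2 = cnt * a)
  structure(list(areas = areas, n_zones = n_zones,
                 depth_breaks = depth_breaks, cell_area = a,
                 cells = cells),
            class = "zone_stratification")
}

new_population_estimate <- function(method, N, se, breakdown = NULL,
                                    details = list()) {
  if (!is.finite(N) || N < 0) stop("invalid population estimate")
  structure(c(list(method = method, N = N, se = se,
                   breakdown = breakdown), details),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("Method %s population estimate: %.4g +/- %.3g individuals\n",
              x$method, x$N, x$se))
  invisible(x)
}

# assign survey sites to zone/stratum of a stratification
site_strata <- function(survey, strat) {
  data.frame(zone = zone_of(survey$Y, strat$n_zones),
             stratum = depth_stratum_of(survey$depth, strat$depth_breaks))
}

#' Method 1: stratified extrapolation of mean observed densities
#'
#' `N = sum over (zone, stratum) of area * mean site density` (presences
#' and absences), with the classical stratified-sampling variance
#' `sum(area^2 * s^2 / n)`.  A stratum with no sites borrows the mean of
#' the same depth stratum pooled across zones; strata with fewer than two
#' sites use the pooled depth-stratum variance (both flagged in the
#' breakdown).
#'
#' @param survey Survey table with `Y`, `depth` and the species density
#'   column.
#' @param strat A [zone_stratification()].
#' @param density_col Name of the site density column (ind m^-2).
#' @return A `population_estimate` with per-(zone, stratum) breakdown.
#' @export
method1 <- function(survey, strat, density_col) {
  d <- survey[[density_col]]
  if (is.null(d)) stop("no column ", density_col)
  ss <- site_strata(survey, strat)
  br <- strat$areas
  br$n <- br$mean <- br$var <- NA_real_
  br$pooled_mean <- br$pooled_var <- FALSE
  for (i in seq_len(nrow(br))) {
    sel <- ss$zone == br$zone[i] & ss$stratum == br$stratum[i] & !is.na(ss$stratum)
    br$n[i] <- sum(sel)
    if (br$n[i] >= 1) br$mean[i] <- mean(d[sel])
    if (br$n[i] >= 2) br$var[i] <- stats::var(d[sel])
  }
  # pooled depth-stratum fallbacks across zones
  for (s in unique(br$stratum)) {
    rows <- br$stratum == s
    pool_sel <- ss$stratum == s & !is.na(ss$stratum)
    pm <- if (any(pool_sel)) mean(d[pool_sel]) else 0
    pv <- if (sum(pool_sel) >= 2) stats::var(d[pool_sel]) else 0
    miss_m <- rows & !is.finite(br$mean)
    if (any(miss_m & br$area_m2 > 0))
      warning("stratum ", s, ": ", sum(miss_m),
              " zone(s) without sites; pooled mean used")
    br$mean[miss_m] <- pm; br$pooled_mean[miss_m] <- TRUE
    miss_v <- rows & !is.finite(br$var)
    br$var[miss_v] <- pv; br$pooled_var[miss_v] <- TRUE
  }
  br$N <- br$area_m2 * br$mean
  br$var_N <- br$area_m2^2 * br$var / pmax(br$n, 1)
  new_population_estimate("1", sum(br$N), sqrt(sum(br$var_N)),
                          breakdown = br)
}

#' Method 2: presence densities times predicted occupied area
#'
#' For each bootstrap threshold `t_b` the occupied area of every
#' (zone, stratum) is the summed area of cells whose occurrence score is
#' `>= t_b`.  The estimate multiplies the across-iteration mean occupied
#' area by the mean observed density at presence sites (`d+`), per
#' (zone, stratum); the SE combines the sampling variance of `d+` and the
#' bootstrap spread of the area by first-order product propagation,
#' assuming independence, summed over strata.  A (zone, stratum) without
#' presence sites borrows the pooled depth-stratum presence mean across
#' zones; if the depth stratum has none at all it contributes 0 with a
#' warning.
#'
#' @param survey Survey table.
#' @param strat A [zone_stratification()].
#' @param density_col Site density column.
#' @param scores Occurrence scores for the cells of `strat$cells` (same
#'   order).
#' @param thresholds The per-iteration thresholds `t_b`.
#' @return A `population_estimate` with breakdown.
#' @export
method2 <- function(survey, strat, density_col, scores, thresholds) {
  if (length(scores) != nrow(strat$cells))
    stop("scores must match the stratification cells")
  if (length(thresholds) < 1) stop("no thresholds")
  d <- survey[[density_col]]
  ss <- site_strata(survey, strat)
  pres <- d > 0
  a <- strat$cell_area
  br <- strat$areas
  br$occ_area <- br$occ_area_se <- br$dplus <- br$dplus_var <- NA_real_
  br$n_pres <- NA_integer_
  br$pooled <- FALSE
  for (i in seq_len(nrow(br))) {
    csel <- strat$cells$zone == br$zone[i] & strat$cells$stratum == br$stratum[i]
    occ_b <- vapply(thresholds, function(t) sum(scores[csel] >= t) * a,
                    numeric(1))
    br$occ_area[i] <- mean(occ_b)
    br$occ_area_se[i] <- if (length(occ_b) > 1) stats::sd(occ_b) else 0
    sel <- ss$zone == br$zone[i] & ss$stratum == br$stratum[i] &
      !is.na(ss$stratum) & pres
    br$n_pres[i] <- sum(sel)
    if (br$n_pres[i] >= 1) {
      br$dplus[i] <- mean(d[sel])
      br$dplus_var[i] <- if (br$n_pres[i] >= 2)
        stats::var(d[sel]) / br$n_pres[i] else NA_real_
    }
  }
  for (s in unique(br$stratum)) {
    rows <- br$stratum == s
    pool_sel <- ss$stratum == s & !is.na(ss$stratum) & pres
    if (any(pool_sel)) {
      pm <- mean(d[pool_sel])
      pv <- if (sum(pool_sel) >= 2)
        stats::var(d[pool_sel]) / sum(pool_sel) else 0
    } else {
      warning("depth stratum ", s,
              ": no presence sites; contributes 0")
      pm <- 0; pv <- 0
    }
    fix <- rows & (!is.finite(br$dplus))
    br$dplus[fix] <- pm; br$pooled[fix] <- TRUE
    fixv <- rows & (!is.finite(br$dplus_var))
    br$dplus_var[fixv] <- pv
  }
  br$N <- br$occ_area * br$dplus
  br$var_N <- br$dplus^2 * br$occ_area_se^2 + br$occ_area^2 * br$dplus_var
  new_population_estimate("2", sum(br$N), sqrt(sum(br$var_N)),
                          breakdown = br)
}

#' Method 3: calibrated model-based population total
#'
#' For each bootstrap iteration the predicted count map is delimited by the
#' iteration's cut-off threshold, `S_b = sum(count * [score >= t_b])`; the
#' estimate is `mean(S_b) / mean(rho_b)` with `rho_b` the per-iteration
#' calibration ratios.  The SE propagates the bootstrap SDs of `S_b` and
#' `rho_b` through the ratio to first order.
#'
#' @param counts Predicted individuals per cell (aligned with `scores`).
#' @param scores Occurrence scores per cell.
#' @param thresholds Per-iteration thresholds `t_b`.
#' @param rho Per-iteration calibration ratios (>= 1 defined entry).
#' @return A `population_estimate` with per-iteration sums `S_b`.
#' @export
method3 <- function(counts, scores, thresholds, rho) {
  if (length(counts) != length(scores)) stop("counts/scores length mismatch")
  rho <- rho[is.finite(rho)]
  if (length(rho) < 1) stop("no defined calibration ratios")
  S_b <- vapply(thresholds, function(t) sum(counts[scores >= t], na.rm = TRUE),
                numeric(1))
  Sbar <- mean(S_b); rbar <- mean(rho)
  N <- Sbar / rbar
  se_S <- if (length(S_b) > 1) stats::sd(S_b) else 0
  se_r <- if (length(rho) > 1) stats::sd(rho) else 0
  se <- N * sqrt((se_S / Sbar)^2 + (se_r / rbar)^2)
  new_population_estimate("3", N, se,
                          details = list(S_b = S_b, rho_b = rho))
}

#' Convert a population estimate to biomass
#'
#' `B = N * w` converted to metric tonnes, with
#' `SE(B) = sqrt(N^2 SE(w)^2 + w^2 SE(N)^2)`.
#'
#' @param estimate A `population_estimate` (or a list with `N` and `se`).
#' @param w Mean individual weight in grams (> 0).
#' @param w_se Standard error of the mean weight (grams).
#' @return List with `tonnes` and `se`.
#' @export
biomass <- function(estimate, w, w_se = 0) {
  if (!is.finite(w) || w <= 0) {
    warning("missing or non-positive mean weight; biomass omitted")
    return(list(tonnes = NA_real_, se = NA_real_))
  }
  N <- estimate$N; seN <- estimate$se
  list(tonnes = N * w / 1e6,
       se = sqrt(N^2 * w_se^2 + w^2 * seN^2) / 1e6)
}
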
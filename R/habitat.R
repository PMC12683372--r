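# Post-prediction ecological summaries: occupancy and abundance by depth
# and exposure strata, species overlap, central depth ranges, variable
# importance and partial dependence.

#' Subsample cells from a prediction map
#'
#' Uniform sample without replacement from the masked cells; used to keep
#' summary computations cheap on multi-million-cell maps (the study
#' protocol uses n = 10,000).
#'
#' @param cells Cell table (e.g. [seascape_cells()] with predictions
#'   attached).
#' @param n Sample size; if `n >= nrow(cells)` the whole table is returned
#'   with a warning.
#' @param seed Integer seed.
#' @export
subsample_cells <- function(cells, n = 10000, seed = 1) {
  set.seed(seed)
  if (n >= nrow(cells)) {
    if (n > nrow(cells)) warning("n exceeds cell count; taking all cells")
    return(cells)
  }
  cells[sort(sample.int(nrow(cells), n)), , drop = FALSE]
}

#' Depth x exposure habitat summary
#'
#' Groups cells into 0.5 m depth bins over 0-10 m and sheltered/exposed
#' classes (sheltered: exposure < `exposure_split`), and tabulates per bin
#' and class the available cell count and, per species, the occupied
#' proportion, mean density and share of the species' total abundance.
#'
#' @param cells Cell table with `depth` and `exposure` columns.
#' @param presence Named list of binary presence vectors (one per
#'   species), aligned with `cells`.
#' @param density Named list of density vectors (same names); optional.
#' @param bin_width Depth bin width in metres.
#' @param exposure_split Wave-exposure split; exactly at the split counts
#'   as exposed.
#' @return data.frame of class `habitat_summary`: `depth_lo`, `depth_hi`,
#'   `exposure_class`, `available`, and per species `occ_<sp>`,
#'   `dens_<sp>`, `share_<sp>`.  Shares per species sum to 1 over all
#'   bins x classes (when total abundance is positive).
#' @export
stratify_habitat <- function(cells, presence, density = NULL,
                             bin_width = 0.5, exposure_split = 1e4) {
  breaks <- seq(0, 10, by = bin_width)
  bin <- depth_stratum_of(cells$depth, breaks)
  cls <- ifelse(cells$exposure < exposure_split, "sheltered", "exposed")
  keep <- !is.na(bin)
  grid <- expand.grid(bin = seq_len(length(breaks) - 1L),
                      exposure_class = c("sheltered", "exposed"),
                      stringsAsFactors = FALSE)
  out <- data.frame(depth_lo = breaks[grid$bin],
                    depth_hi = breaks[grid$bin + 1L],
                    exposure_class = grid$exposure_class)
  out$available <- mapply(function(b, cl)
    sum(keep & bin == b & cls == cl), grid$bin, grid$exposure_class)
  for (sp in names(presence)) {
    pr <- as.numeric(presence[[sp]])
    de <- if (!is.null(density)) density[[sp]] else NULL
    occ <- dens <- share <- rep(NA_real_, nrow(out))
    tot <- if (!is.null(de)) sum(de[keep]) else NA_real_
    for (i in seq_len(nrow(out))) {
      sel <- keep & bin == grid$bin[i] & cls == grid$exposure_class[i]
      if (any(sel)) {
        occ[i] <- mean(pr[sel])
        if (!is.null(de)) {
          dens[i] <- mean(de[sel])
          share[i] <- if (is.finite(tot) && tot > 0) sum(de[sel]) / tot
          else NA_real_
        }
      }
    }
    out[[paste0("occ_", sp)]] <- occ
    if (!is.null(de)) {
      out[[paste0("dens_", sp)]] <- dens
      out[[paste0("share_", sp)]] <- share
    }
  }
  class(out) <- c("habitat_summary", "data.frame")
  out
}

#' Species overlap table
#'
#' Tabulates the eight presence combinations of three species as
#' percentages of the masked cells, plus each species' total occupancy `T`
#' and the percentage of its occupied cells where it occurs alone.
#'
#' @param presence Named list of exactly three aligned binary vectors.
#' @return List of class `overlap_table`: `combinations` (data.frame with
#'   the 8 combination percentages, summing to 100), `total_pct` (T per
#'   species) and `alone_pct_of_occupied`.
#' @export
overlap_table <- function(presence) {
  if (length(presence) != 3) stop("exactly three species required")
  lens <- vapply(presence, length, integer(1))
  if (length(unique(lens)) != 1) stop("presence layers misaligned")
  n <- lens[1]
  A <- as.logical(presence[[1]]); B <- as.logical(presence[[2]])
  C <- as.logical(presence[[3]])
  nm <- names(presence)
  combos <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE),
                        c = c(FALSE, TRUE))
  pct <- mapply(function(a, b, c)
    100 * sum(A == a & B == b & C == c) / n, combos$a, combos$b, combos$c)
  label <- apply(combos, 1, function(r) {
    on <- nm[as.logical(r)]
    if (length(on) == 0) "none" else paste(on, collapse = "+")
  })
  comb <- data.frame(species = label, pct = pct)
  total <- c(100 * mean(A), 100 * mean(B), 100 * mean(C))
  names(total) <- nm
  alone <- c(if (any(A)) 100 * sum(A & !B & !C) / sum(A) else NA_real_,
             if (any(B)) 100 * sum(B & !A & !C) / sum(B) else NA_real_,
             if (any(C)) 100 * sum(C & !A & !B) / sum(C) else NA_real_)
  names(alone) <- nm
  structure(list(combinations = comb, total_pct = total,
                 alone_pct_of_occupied = alone),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("presence combinations (% of masked cells):\n")
  print(x$combinations, row.names = FALSE, digits = 3)
  cat("total occupancy T (%):\n"); print(round(x$total_pct, 1))
  invisible(x)
}

#' Shortest central depth range holding a given abundance mass
#'
#' The shortest contiguous run of depth bins whose summed abundance share
#' reaches `mass`; ties are broken toward the shallower start.
#'
#' @param shares Per-bin abundance shares (must sum to ~1).
#' @param breaks Bin boundaries, length `length(shares) + 1`.
#' @param mass Required mass in (0, 1\] (default 0.80).
#' @return Numeric `c(lower, upper)` depth interval.
#' @export
central_range <- function(shares, breaks = seq(0, by = 0.5,
                                               length.out = length(shares) + 1),
                          mass = 0.80) {
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]")
  if (length(breaks) != length(shares) + 1) stop("breaks/shares mismatch")
  k <- length(shares)
  best <- NULL
  for (len in seq_len(k)) {
    for (start in seq_len(k - len + 1)) {
      if (sum(shares[start:(start + len - 1)]) >= mass - 1e-12) {
        best <- c(breaks[start], breaks[start + len])
        break
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) best <- c(breaks[1], breaks[k + 1])
  best
}

#' Scaled variable importance and partial dependence
#'
#' Importance is the learner's internal gain measure where available
#' (boosted trees), otherwise permutation importance (mean increase in
#' prediction RMSE over `n_perm` shuffles); either way rescaled so the
#' most important variable scores 100.  Partial dependence of a variable
#' is the mean prediction over the data with that variable fixed at each
#' of `grid_n` equally spaced values of its observed range.
#'
#' @param model A fit with a `predict(newdata)` function and optionally a
#'   `booster` (xgboost handle), e.g. from `fit_gbt`; or any
#'   `function(newdata)` returning predictions.
#' @param data Data to average over (and to measure ranges from).
#' @param covariates Variables to score.
#' @param grid_n Grid points per partial-dependence curve.
#' @param n_perm Permutation repeats for the fallback importance.
#' @param seed Integer seed (permutation fallback).
#' @return List with `importance` (data.frame: variable, raw, scaled) and
#'   `partials` (named list of data.frames `value`, `yhat`).
#' @export
importance_and_partials <- function(model, data, covariates, grid_n = 20,
                                    n_perm = 5, seed = 1) {
  predfun <- if (is.function(model)) model else model$predict
  booster <- if (!is.function(model)) model$booster else NULL

  raw <- stats::setNames(rep(0, length(covariates)), covariates)
  if (!is.null(booster)) {
    imp <- xgboost::xgb.importance(model = booster)
    raw[imp$Feature[imp$Feature %in% covariates]] <-
      imp$Gain[imp$Feature %in% covariates]
  } else {
    set.seed(seed)
    base <- predfun(data)
    for (v in covariates) {
      if (stats::sd(data[[v]]) == 0) next    # constant: importance 0
      inc <- numeric(n_perm)
      for (i in seq_len(n_perm)) {
        d2 <- data
        d2[[v]] <- sample(d2[[v]])
        inc[i] <- sqrt(mean((predfun(d2) - base)^2))
      }
      raw[v] <- mean(inc)
    }
  }
  scaled <- if (max(raw) > 0) 100 * raw / max(raw) else raw
  importance <- data.frame(variable = covariates, raw = unname(raw),
                           scaled = unname(scaled))

  partials <- lapply(covariates, function(v) {
    r <- range(data[[v]])
    grid <- if (r[1] == r[2]) r[1] else seq(r[1], r[2], length.out = grid_n)
    yhat <- vapply(grid, function(g) {
      d2 <- data; d2[[v]] <- g
      mean(predfun(d2))
    }, numeric(1))
    data.frame(value = grid, yhat = yhat)
  })
  names(partials) <- covariates
  list(importance = importance, partials = partials)
}
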
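# Predictor preparation and collinearity screening.
#
# Coordinates are rotated to align the axes with the alongshore and
# in-offshore gradients of the coastline, then min-max normalised; the
# predictor table is screened stepwise on the variance inflation factor
# (VIF) and pruned so each aggregation family (min/max/median/mean of the
# same base quantity) keeps a single representative.

#' Rotate coordinates and min-max normalise
#'
#' Rigid counter-clockwise rotation by `angle_deg` about the data centroid,
#' followed by per-axis min-max normalisation to \[0, 1\].  The default 14
#' degrees compensates for the inclination of a NNW-trending shoreline so
#' that the resulting `X` is an in-offshore and `Y` an alongshore position.
#'
#' @param east,north Coordinates in metres (same length, >= 2 points).
#' @param angle_deg Rotation angle in degrees; positive = counter-clockwise.
#' @return A data.frame with columns `X` and `Y` in \[0, 1\].  An axis that
#'   is constant after rotation is mapped to 0 with a warning.
#' @export
rotate_and_normalize <- function(east, north, angle_deg = 14) {
  if (length(east) != length(north)) stop("east/north lengths differ")
  if (length(east) < 2) stop("need at least 2 points")
  th <- angle_deg * pi / 180
  ce <- mean(east); cn <- mean(north)
  e <- east - ce; n <- north - cn
  xr <- cos(th) * e - sin(th) * n
  yr <- sin(th) * e + cos(th) * n
  mm <- function(v, axis) {
    r <- range(v)
    if (r[1] == r[2]) {
      warning("axis ", axis, " constant after rotation; mapped to 0")
      return(rep(0, length(v)))
    }
    (v - r[1]) / (r[2] - r[1])
  }
  data.frame(X = mm(xr, "X"), Y = mm(yr, "Y"))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from an ordinary
#' least-squares regression (with intercept) of column `j` on all other
#' columns.  Perfectly collinear columns are reported as `Inf` rather than
#' raising an error.
#'
#' @param x A data.frame of numeric predictor columns (>= 2 columns, more
#'   rows than columns, no constant column).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least 2 predictor columns")
  if (nrow(x) <= ncol(x)) stop("need more rows than columns")
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) stop("constant column: ",
                          paste(names(x)[sds == 0], collapse = ", "))
  out <- vapply(seq_along(x), function(j) {
    fit <- stats::lm(x[[j]] ~ ., data = x[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits warn
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- names(x)
  out
}

new_screen_report <- function(log, retained, final_vifs, threshold) {
  structure(list(removed = log, retained = retained,
                 final_vifs = final_vifs, threshold = threshold),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("VIF screening report (threshold ", x$threshold, ")\n", sep = "")
  if (nrow(x$removed) == 0) cat("  nothing removed\n") else {
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("  step %d: removed %s (VIF %.3g, %s)\n", i,
                  x$removed$variable[i], x$removed$vif[i], x$removed$rule[i]))
  }
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Stepwise VIF screening
#'
#' Repeatedly removes the single highest-VIF variable (ties broken toward
#' the later column, for determinism) and recomputes, until all VIFs fall
#' below `threshold` or fewer than two variables remain.
#'
#' @param x Predictor data.frame.
#' @param threshold VIF threshold (conventional conservative value 5).
#' @return A `screen_report`: ordered removal log (`variable`, `vif`,
#'   `rule`), retained variables and their final VIFs.
#' @export
screen_vif <- function(x, threshold = 5) {
  x <- as.data.frame(x)
  log <- data.frame(variable = character(), vif = numeric(),
                    rule = character())
  repeat {
    if (ncol(x) < 2) break
    v <- vif(x)
    if (all(v < threshold)) break
    worst <- max(v)
    j <- max(which(v == worst))     # later column on ties
    log <- rbind(log, data.frame(variable = names(x)[j], vif = worst,
                                 rule = paste0("VIF>", threshold)))
    x <- x[, -j, drop = FALSE]
  }
  fv <- if (ncol(x) >= 2) vif(x) else stats::setNames(rep(NA_real_, ncol(x)),
                                                      names(x))
  new_screen_report(log, names(x), fv, threshold)
}

#' Prune aggregation families to one representative
#'
#' Among surviving variables, any family of aggregations of the same base
#' quantity (e.g. `{Max.Chl, Mean.Chl}`) with more than one member loses
#' its highest-VIF member, repeatedly, until each family has a single
#' representative.
#'
#' @param x Predictor data.frame (typically the retained columns of a
#'   [screen_vif()] pass).
#' @param families Named list: base quantity -> character vector of variant
#'   column names.  An empty list prunes nothing.
#' @return A `screen_report` whose removal log carries rule
#'   `"family-pruned"`.
#' @export
prune_families <- function(x, families = list()) {
  x <- as.data.frame(x)
  log <- data.frame(variable = character(), vif = numeric(),
                    rule = character())
  repeat {
    multi <- Filter(function(f) sum(f %in% names(x)) > 1, families)
    if (length(multi) == 0 || ncol(x) < 2) break
    v <- vif(x)
    cand <- unlist(lapply(multi, function(f) intersect(f, names(x))))
    worst <- cand[which.max(v[cand])]
    log <- rbind(log, data.frame(variable = worst, vif = v[[worst]],
                                 rule = "family-pruned"))
    x <- x[, setdiff(names(x), worst), drop = FALSE]
  }
  fv <- if (ncol(x) >= 2) vif(x) else stats::setNames(rep(NA_real_, ncol(x)),
                                                      names(x))
  new_screen_report(log, names(x), fv, NA_real_)
}
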
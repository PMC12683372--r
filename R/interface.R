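# File formats, validation, and end-to-end orchestration.

#' Observed prevalence from presence counts
#'
#' @param n_present Number of sites where the species was recorded.
#' @param n_sites Total number of surveyed sites.
#' @param percent Return a percentage (default) instead of a proportion.
#' @export
prevalence <- function(n_present, n_sites, percent = TRUE) {
  if (n_sites <= 0 || n_present < 0 || n_present > n_sites)
    stop("invalid counts")
  p <- n_present / n_sites
  if (percent) 100 * p else p
}

#' Write / read a survey table as CSV
#'
#' `read_survey` validates on read: sampled areas must be positive and
#' counts non-negative integers; offending rows are dropped with a message
#' and counted in `attr(x, "n_rejected")`.
#'
#' @param survey A survey table.
#' @param path CSV path.
#' @return `read_survey` returns a `survey_table` data.frame.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(as.data.frame(survey), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  x <- utils::read.csv(path)
  req <- c("site", "cell", "depth", "method", "area")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("survey file lacks required column(s): ",
         paste(miss, collapse = ", "))
  cnt_cols <- grep("^count_", names(x), value = TRUE)
  bad <- !is.finite(x$area) | x$area <= 0
  for (cc in cnt_cols) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    bad <- bad | !is.finite(v) | v < 0 | v != round(v)
  }
  if (any(bad)) {
    message(sum(bad), " invalid row(s) rejected on read")
    x <- x[!bad, , drop = FALSE]
  }
  attr(x, "n_rejected") <- sum(bad)
  class(x) <- c("survey_table", "data.frame")
  x
}

#' Write / read a seascape as a plain-text array archive
#'
#' The seascape is stored as a directory holding `layers.csv` (one row per
#' cell, one column per covariate band) and `meta.json` naming the bands
#' and grid geometry; values round-trip at full double precision.
#'
#' @param seascape A `seascape`.
#' @param dir Directory to create/read.
#' @return `read_seascape` returns a `seascape`.
#' @export
write_seascape <- function(seascape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(lapply(seascape$layers, as.vector))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   file.path(dir, "layers.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(nrow = seascape$nrow, ncol = seascape$ncol,
               cell_size = seascape$cell_size,
               layers = names(seascape$layers))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_seascape
#' @export
read_seascape <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, "layers.csv"))
  if (nrow(df) != meta$nrow * meta$ncol)
    stop("layer table does not match grid dimensions")
  miss <- setdiff(meta$layers, names(df))
  if (length(miss) > 0)
    stop("misaligned band(s): ", paste(miss, collapse = ", "))
  layers <- lapply(meta$layers, function(nm)
    matrix(df[[nm]], meta$nrow, meta$ncol))
  names(layers) <- meta$layers
  structure(list(nrow = meta$nrow, ncol = meta$ncol,
                 cell_size = meta$cell_size, layers = layers,
                 mask = layers$depth >= 0 & layers$depth <= 10),
            class = "seascape")
}

#' Default covariate set used by the occurrence and abundance models
#'
#' Wave exposure enters on the log10 scale through a derived column
#' `log_exposure` added by [prepare_model_covariates()].
#'
#' @export
default_covariates <- function() {
  c("depth", "log_exposure", "X", "Y", "slope", "distance",
    "P_HARD", "P_SOFT", "SAV")
}

#' Add derived model covariates to a site or cell table
#'
#' @param data Site or cell table with an `exposure` column.
#' @export
prepare_model_covariates <- function(data) {
  if (!is.null(data$exposure)) data$log_exposure <- log10(data$exposure)
  data
}

#' Run the full estimation pipeline for one or more species
#'
#' Orchestrates, on one survey and seascape: VIF screening of the model
#' covariates, occurrence modelling with prevalence-matched thresholds,
#' conditional abundance modelling with ROE/smearing corrections, the
#' three population estimators, and the habitat summary.  Fully
#' reproducible given `seed`.
#'
#' @param survey Survey table (e.g. from [sample_sites()]).
#' @param seascape The seascape to predict over.
#' @param species Character vector of species names (suffixes of the
#'   `count_` columns).
#' @param covariates Model covariates (default [default_covariates()]).
#' @param B Bootstrap iterations.
#' @param seed Integer seed.
#' @param occ_cfg,abund_cfg Stage configurations.
#' @param weights Optional named list `species -> c(w, w_se)` of mean
#'   individual weights in grams for biomass conversion.
#' @param subsample_n Cells used for the habitat summary.
#' @return List of class `pipeline_result` with `screen`, and per species:
#'   `occurrence`, `abundance`, `estimates` (Methods 1-3), `biomass`,
#'   plus `habitat` and `overlap` (with >= 3 species).
#' @export
run_pipeline <- function(survey, seascape, species,
                         covariates = default_covariates(), B = 100,
                         seed = 1, occ_cfg = occ_config(),
                         abund_cfg = abund_config(), weights = NULL,
                         subsample_n = 10000) {
  survey <- prepare_model_covariates(survey)
  strat <- zone_stratification(seascape)
  cells <- prepare_model_covariates(strat$cells)

  screen <- screen_vif(survey[, covariates, drop = FALSE])

  out <- list(screen = screen, species = list(), seed = seed, B = B)
  pres_layers <- list(); dens_layers <- list()
  for (k in seq_along(species)) {
    sp <- species[k]
    occ <- occurrence_pipeline(survey, sp, covariates, B = B,
                               seed = seed + 1000L * k, config = occ_cfg)
    ab <- abundance_pipeline(survey, sp, covariates, occ, B = B,
                             seed = seed + 1000L * k + 500L,
                             config = abund_cfg)
    occ_map <- predict(occ, cells)
    cells_ab <- cells; cells_ab$P_presence <- occ_map$score
    ab_map <- predict(ab, cells_ab, cell_area = cell_area(seascape))

    dcol <- paste0("density_", sp)
    est1 <- method1(survey, strat, dcol)
    est2 <- method2(survey, strat, dcol, occ_map$score, occ$thresholds)
    est3 <- method3(ab_map$count, occ_map$score, occ$thresholds, ab$rho_b)

    bio <- if (!is.null(weights[[sp]]))
      biomass(est3, weights[[sp]][1],
              if (length(weights[[sp]]) > 1) weights[[sp]][2] else 0)
    else NULL

    pres_layers[[sp]] <- occ_map$presence
    dens_layers[[sp]] <- ab_map$density * occ_map$presence
    out$species[[sp]] <- list(occurrence = occ, abundance = ab,
                              estimates = list(method1 = est1,
                                               method2 = est2,
                                               method3 = est3),
                              biomass = bio)
  }

  sub <- subsample_cells(cbind(cells,
                               as.data.frame(pres_layers),
                               stats::setNames(as.data.frame(dens_layers),
                                               paste0(".d_", species))),
                         n = subsample_n, seed = seed)
  out$habitat <- stratify_habitat(
    sub, presence = as.list(sub[, species, drop = FALSE]),
    density = stats::setNames(as.list(sub[, paste0(".d_", species),
                                          drop = FALSE]), species))
  if (length(species) == 3)
    out$overlap <- overlap_table(pres_layers)
  class(out) <- "pipeline_result"
  out
}

#' Serialise the headline numbers of a pipeline run to JSON
#'
#' @param result A `pipeline_result`.
#' @param path Output JSON path.
#' @export
write_report <- function(result, path) {
  rep <- list(seed = result$seed, B = result$B,
              screen_retained = result$screen$retained)
  for (sp in names(result$species)) {
    r <- result$species[[sp]]
    rep[[sp]] <- list(
      occurrence = as.list(stats::setNames(r$occurrence$report$best,
                                           r$occurrence$report$metric)),
      threshold = r$occurrence$threshold,
      abundance = as.list(stats::setNames(r$abundance$report$best,
                                          r$abundance$report$metric)),
      corrections = list(a = r$abundance$a, b = r$abundance$b,
                         D = r$abundance$D),
      estimates = lapply(r$estimates, function(e)
        list(N = e$N, se = e$se)),
      biomass = r$biomass)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Population-recovery experiment on synthetic seascapes with known truth
#'
#' Repeats, `n_rep` times: generate a seascape and a study-like species
#' truth layer, survey `8 * sites_per_stratum` sites with the default
#' depth-by-exposure stratified design, run the occurrence and abundance pipelines (B
#' bootstrap iterations, fixed boosted-tree hyperparameters), and compute
#' the Method 1 and Method 3 population estimates with their standard
#' errors alongside the true total.  Used to check SE calibration
#' (coverage of +/- 2 SE intervals) and relative error of the model-based
#' versus the design-based estimator.
#'
#' @param n_rep Number of replicates.
#' @param nrow,ncol Grid size (default 200 x 200).
#' @param sites_per_stratum Sites per (depth stratum, exposure class)
#'   stratum; 100 gives ~800 sites.
#' @param B Bootstrap iterations per replicate.
#' @param seed Integer seed.
#' @param params Species truth parameters (default: the mussel-like
#'   species).
#' @return data.frame with one row per replicate: true total, Method 1 and
#'   Method 3 estimates, SEs, coverage indicators and relative errors.
#' @export
recovery_experiment <- function(n_rep = 50, nrow = 200, ncol = 200,
                                sites_per_stratum = 100, B = 25, seed = 1,
                                params = species_defaults()$mussel) {
  res <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    s_i <- seed + 97L * i
    ss <- generate_seascape(nrow, ncol, seed = s_i)
    tr <- generate_truth(ss, params, seed = s_i + 1L)
    design <- sampling_design(sites_per_stratum = sites_per_stratum)
    sv <- sample_sites(ss, list(sp = tr), design, seed = s_i + 2L)
    sv <- prepare_model_covariates(sv)
    strat <- zone_stratification(ss)
    cells <- prepare_model_covariates(strat$cells)
    covs <- default_covariates()

    occ <- occurrence_pipeline(sv, "sp", covs, B = B, seed = s_i + 3L)
    ab <- abundance_pipeline(sv, "sp", covs, occ, B = B, seed = s_i + 4L)
    occ_map <- predict(occ, cells)
    cells_ab <- cells; cells_ab$P_presence <- occ_map$score
    ab_map <- predict(ab, cells_ab, cell_area = cell_area(ss))

    est1 <- method1(sv, strat, "density_sp")
    est2 <- suppressWarnings(
      method2(sv, strat, "density_sp", occ_map$score, occ$thresholds))
    est3 <- method3(ab_map$count, occ_map$score, occ$thresholds, ab$rho_b)
    truth_total <- true_population(tr, ss)
    res[[i]] <- data.frame(
      rep = i, truth = truth_total,
      m1 = est1$N, m1_se = est1$se, m2 = est2$N, m2_se = est2$se,
      m3 = est3$N, m3_se = est3$se)
  }
  out <- do.call(rbind, res)
  out$m1_covered <- abs(out$m1 - out$truth) <= 2 * out$m1_se
  out$m2_covered <- abs(out$m2 - out$truth) <= 3 * out$m2_se
  out$m3_covered <- abs(out$m3 - out$truth) <= 2 * out$m3_se
  out$m1_rel_err <- (out$m1 - out$truth) / out$truth
  out$m2_rel_err <- (out$m2 - out$truth) / out$truth
  out$m3_rel_err <- (out$m3 - out$truth) / out$truth
  out
}
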
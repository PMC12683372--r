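# Shared fixtures: all built in code, kept small for speed.

# small seascape reused across files (regenerated per file; cheap)
tiny_seascape <- function(seed = 3, n = 60) generate_seascape(n, n, seed = seed)

# a single-stratum design covering the whole 0-10 m mask with quadrats
flat_design <- function(n_sites, area = 1) {
  sampling_design(depth_breaks = c(0, 10), n_zones = 1,
                  sites_per_stratum = n_sites, quadrat_area = area,
                  quadrat_max_depth = 10, quadrat_switch = Inf)
}

# truth with occupancy probability ~1 everywhere and constant density d
constant_truth <- function(seascape, d, seed = 1) {
  generate_truth(seascape,
                 hurdle_params(20, c(depth = 0), log(d), c(depth = 0), 0),
                 seed = seed)
}

# hand-built zone_stratification for toy estimator tests
toy_stratification <- function(areas_df, cells_df, cell_area = 100,
                               n_zones = max(areas_df$zone),
                               depth_breaks = c(0, 10)) {
  structure(list(areas = areas_df, n_zones = n_zones,
                 depth_breaks = depth_breaks, cell_area = cell_area,
                 cells = cells_df),
            class = "zone_stratification")
}

# fast boosted-tree settings for model tests
fast_gbt <- gbt_params(eta = 0.2, nrounds = 40, max_depth = 3,
                       min_child_weight = 2)
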
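#' Desk-scale preset
#'
#' A reduced problem size for desktop-scale experiments: 500 synthetic
#' founder lines, a 2,000-marker panel, 300 QTL per trait-environment,
#' 1,000 bulk-up lines per genomic-selection cycle (200 intercross families
#' x 5 seeds; 300 x 4 F2 seeds in phenotypic selection), a 0.1 mid-parent
#' pre-filter on the F1-pair enumeration before in-silico projection, a
#' 200 x 100 genetic algorithm and 10 replicates. Trial-stage sizes are
#' unchanged.
#'
#' @return list with `founder_args`, `arch_args`, `scenario_args` and
#'   `n_replicates`.
#' @export
desk_preset <- function() {
  list(founder_args = list(n_lines = 500, burn_in_generations = 50,
                           ancestral_maf_shape = 0.2, min_maf = 0.01),
       map_args = list(n_chromosomes = 7, snp_range = c(900, 1100),
                       length_range = c(192.7, 429.7)),
       arch_args = list(n_qtl = 300, n_markers = 2000),
       scenario_args = list(seeds_per_family = 5, ps_f2_per_family = 4,
                            intercross_prefilter = 0.1,
                            ga = list(pop_size = 200, iterations = 100,
                                      mutation = 0.001, elite_fraction = 0.2)),
       n_replicates = 10)
}

#' Build a synthetic founder set under a preset
#'
#' @param seed integer seed.
#' @param preset a preset list (default [desk_preset()]).
#' @return a founder `breeding_pop` (see [simulate_founders()]).
#' @export
make_founders <- function(seed = 1, preset = desk_preset()) {
  map <- do.call(build_map, c(preset$map_args, list(seed = seed)))
  do.call(simulate_founders,
          c(list(map = map, seed = seed + 1L), preset$founder_args))
}

#' The benchmark scenario set
#'
#' The six generation-interval scenarios compared against the phenotypic
#' benchmark: SSD and aSSD bulk-up with Stage-2 and F6 parent recycling, and
#' F2 / F1 recycling (for which the bulk-up method does not affect the
#' generation interval; the SSD variant is used).
#'
#' @param scenario_args overrides applied to every scenario (e.g. from a
#'   preset).
#' @return named list of `scenario_config`s.
#' @export
benchmark_scenarios <- function(scenario_args = list()) {
  names <- c("GS_SSD_STG2", "GS_aSSD_STG2", "GS_SSD_F6", "GS_aSSD_F6",
             "GS_SSD_F2", "GS_SSD_F1")
  stats::setNames(lapply(names, function(n)
    do.call(scenario_preset, c(list(name = n), scenario_args))), names)
}

#' Run the benchmark comparison at desk scale
#'
#' Generates synthetic founders, runs the phenotypic benchmark and the six
#' generation-interval scenarios for 8 breeding cycles (genomic selection
#' branching after cycle 3), and summarizes annual rates.
#'
#' @param seed integer seed for everything.
#' @param n_replicates replicates (default from the preset).
#' @param preset problem-size preset.
#' @param scenarios scenario list (default [benchmark_scenarios()] under the
#'   preset).
#' @param founders optionally reuse a founder population.
#' @return list: `metrics` (per-cycle table), `rates` (see
#'   [per_year_rates()]), `founders`.
#' @export
run_benchmark <- function(seed = 1, n_replicates = NULL,
                          preset = desk_preset(), scenarios = NULL,
                          founders = NULL) {
  if (is.null(n_replicates)) n_replicates <- preset$n_replicates
  if (is.null(founders)) founders <- make_founders(seed, preset)
  if (is.null(scenarios)) scenarios <- benchmark_scenarios(preset$scenario_args)
  ps <- do.call(scenario_preset,
                c(list(name = "PS_STG2"), preset$scenario_args))
  metrics <- run_experiment(scenarios, founders, n_replicates = n_replicates,
                            base_seed = seed + 2L, ps_config = ps,
                            arch_args = preset$arch_args)
  list(metrics = metrics, rates = per_year_rates(metrics), founders = founders)
}
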
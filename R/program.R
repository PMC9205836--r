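#' Scenario configuration
#'
#' Fully specifies one breeding strategy. The named presets (see
#' [scenario_preset()]) reproduce the nine benchmark scenarios: phenotypic
#' selection with family bulk-up and Stage-2 parent recycling, and genomic
#' selection with field (`SSD`) or glasshouse-accelerated (`aSSD`) single
#' seed descent crossed with parent recycling at Stage 2, F6, F2 or F1.
#'
#' @param name scenario label.
#' @param selection `"PS"` (phenotypic) or `"GS"` (genomic).
#' @param bulkup `"family"` (PS bulk-up F3--F5), `"SSD"` (field, 4 years
#'   F3--F6) or `"aSSD"` (glasshouse, 1.5 years).
#' @param parent_stage stage parents are recycled from: `"STG2"`, `"F6"`,
#'   `"F2"` or `"F1"`.
#' @param n_parents,n_primary_crosses,parent_usage_cap crossing-block sizes
#'   (defaults 150, 300, 4).
#' @param n_intercross_families F1 intercross families (default 200).
#' @param seeds_per_family F2 seeds per intercross family entering bulk-up
#'   (default 20; families x seeds = 4000 bulk-up lines).
#' @param ps_f2_per_family F2 seeds per primary-cross family in PS
#'   (default 20).
#' @param pyt_size,stage1_size,stage2_size,pool_add trial-stage sizes
#'   (defaults 800, 400, 200, 80).
#' @param f5_cull fraction of F5 single plants dropped on low single-plant
#'   seed yield in PS (default 0.3).
#' @param pyt_rep_fraction fraction of PYT entries with 2 replicates.
#' @param single_plant_inflation residual-variance inflation of single-plant
#'   records (default 2).
#' @param intercross_prefilter fraction of F1 pairs kept (by mid-parent GEBV
#'   index) before in-silico projection (1 = full enumeration).
#' @param n_virtual,target_gen projection settings (20 virtual descendants,
#'   F8).
#' @param f2_phenotyping add F2-family phenotypes to the training set.
#' @param n_f2_families families phenotyped per cycle (default 50).
#' @param diversity_preservation select parents with the genetic-algorithm
#'   diversity objective instead of plain truncation.
#' @param lambda1,lambda2 GA penalties on mean relationship and fixed-allele
#'   count (defaults 1, 1e-6).
#' @param ga list of GA parameters (`pop_size`, `iterations`, `mutation`,
#'   `elite_fraction`).
#' @param weights selection-index weights (disease resistance, grain weight,
#'   grain yield).
#' @param training_window training cycles kept (default 3).
#' @param entry_mean_plots nominal plots per entry mean, sets the shrinkage
#'   reliability of training phenotypes (default 4).
#' @param n_segments OHV segments per chromosome (default 5).
#' @param mutation_rate,xo_lambda meiosis parameters.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom",
                            selection = c("GS", "PS"),
                            bulkup = c("SSD", "aSSD", "family"),
                            parent_stage = c("STG2", "F6", "F2", "F1"),
                            n_parents = 150, n_primary_crosses = 300,
                            parent_usage_cap = 4,
                            n_intercross_families = 200, seeds_per_family = 20,
                            ps_f2_per_family = 20,
                            pyt_size = 800, stage1_size = 400,
                            stage2_size = 200, pool_add = 80,
                            f5_cull = 0.3, pyt_rep_fraction = 0.2,
                            single_plant_inflation = 2,
                            intercross_prefilter = 1, n_virtual = 20,
                            target_gen = 8,
                            f2_phenotyping = FALSE, n_f2_families = 50,
                            diversity_preservation = FALSE,
                            lambda1 = 1, lambda2 = 1e-6,
                            ga = list(pop_size = 2000, iterations = 1000,
                                      mutation = 0.001, elite_fraction = 0.2),
                            weights = c(0.3, 0.3, 0.4),
                            training_window = 3, entry_mean_plots = 4,
                            n_segments = 5,
                            mutation_rate = 0.001, xo_lambda = 1) {
  cfg <- list(name = name, selection = match.arg(selection),
              bulkup = match.arg(bulkup), parent_stage = match.arg(parent_stage),
              n_parents = n_parents, n_primary_crosses = n_primary_crosses,
              parent_usage_cap = parent_usage_cap,
              n_intercross_families = n_intercross_families,
              seeds_per_family = seeds_per_family,
              ps_f2_per_family = ps_f2_per_family,
              pyt_size = pyt_size, stage1_size = stage1_size,
              stage2_size = stage2_size, pool_add = pool_add,
              f5_cull = f5_cull, pyt_rep_fraction = pyt_rep_fraction,
              single_plant_inflation = single_plant_inflation,
              intercross_prefilter = intercross_prefilter,
              n_virtual = n_virtual, target_gen = target_gen,
              f2_phenotyping = f2_phenotyping, n_f2_families = n_f2_families,
              diversity_preservation = diversity_preservation,
              lambda1 = lambda1, lambda2 = lambda2, ga = ga,
              weights = weights, training_window = training_window,
              entry_mean_plots = entry_mean_plots, n_segments = n_segments,
              mutation_rate = mutation_rate, xo_lambda = xo_lambda)
  if (cfg$selection == "PS" && cfg$bulkup != "family")
    stop("phenotypic selection uses the family bulk-up")
  if (cfg$selection == "GS" && cfg$bulkup == "family")
    stop("genomic selection uses SSD or aSSD bulk-up")
  class(cfg) <- "scenario_config"
  cfg
}

#' Named benchmark scenarios
#'
#' @param name one of `PS_STG2`, `GS_SSD_STG2`, `GS_SSD_F6`, `GS_SSD_F2`,
#'   `GS_SSD_F1`, `GS_aSSD_STG2`, `GS_aSSD_F6`, `GS_aSSD_F2`, `GS_aSSD_F1`,
#'   plus the optioned variants `GS_aSSD_F2_PH` (50 F2 families phenotyped),
#'   `GS_SSD_F2_PH`, and `_DP` variants of any GS scenario (genetic-algorithm
#'   diversity preservation).
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scenario_preset <- function(name, ...) {
  base <- name
  opts <- list(...)
  if (grepl("_PH$", base)) {
    opts$f2_phenotyping <- TRUE
    base <- sub("_PH$", "", base)
  }
  if (grepl("_DP$", base)) {
    opts$diversity_preservation <- TRUE
    base <- sub("_DP$", "", base)
  }
  m <- regmatches(base, regexec("^(PS|GS)(?:_(SSD|aSSD))?_(STG2|F6|F2|F1)$", base))[[1]]
  if (length(m) == 0) stop("unknown scenario: ", name)
  args <- list(name = name, selection = m[2],
               bulkup = if (m[2] == "PS") "family" else m[3],
               parent_stage = m[4])
  do.call(scenario_config, utils::modifyList(args, opts))
}

#' Generation interval and phenotype pipeline of a scenario
#'
#' Sums the stage durations of the breeding cycle up to the parent-recycling
#' stage. Components (years): crossing to F1/F1i 0.5; one further selfing
#' season to F2 0.5; bulk-up to F6 4 (field SSD) or 1.5 (glasshouse aSSD);
#' PYT, Stage 1 and Stage 2 one year each plus 0.5 for seed processing and
#' parent selection. The PS cycle (family bulk-up F3--F5 with an F5
#' single-plant year and a seed-increase season before PYT) totals 8 years.
#' `pipeline_years` is when a cycle's Stage-2 phenotypes mature and become
#' available for training, regardless of where parents are recycled.
#'
#' @param config a `scenario_config` or a scenario name.
#' @return list: `interval` (generation interval in years) and
#'   `pipeline_years`.
#' @export
timeline <- function(config) {
  if (is.character(config)) config <- scenario_preset(config)
  if (config$selection == "PS")
    return(list(interval = 8, pipeline_years = 8))
  bulk <- switch(config$bulkup, SSD = 4, aSSD = 1.5,
                 stop("unknown bulk-up: ", config$bulkup))
  t_f2 <- 1
  trials <- 3.5
  interval <- switch(config$parent_stage,
                     F1 = 0.5,
                     F2 = t_f2,
                     F6 = t_f2 + bulk,
                     STG2 = t_f2 + bulk + trials)
  list(interval = interval, pipeline_years = t_f2 + bulk + trials)
}

# ---------------------------------------------------------------------------
# Program state and cycle bodies
# ---------------------------------------------------------------------------

#' Initialize a program state
#'
#' Builds the germplasm pool from the founder lines, assigns each founder a
#' historical advanced-trial phenotype record (2 replicates x 2 environments;
#' the base set is assumed to have been trialed before the program starts, so
#' phenotypic parent selection from the pool is defined), and samples the
#' cycle-1 parents at random from the base population.
#'
#' @param founders a `breeding_pop` of inbred founder lines.
#' @param arch a `trait_arch` sampled on the founders.
#' @param config a `scenario_config`.
#' @return a `program_state`: germplasm pool, pool phenotypes, training
#'   archive, current parents, calendar time and metrics.
#' @export
init_program_state <- function(founders, arch, config) {
  rec <- run_trial(founders, "stage", arch)
  ph <- entry_means(rec, ids = founders$meta$id)
  parents <- sort(sample.int(pop_size(founders), config$n_parents))
  scheme <- segment_scheme(founders$map, arch$marker_loci, config$n_segments)
  structure(list(pool = founders, pool_ph = ph, archive = list(),
                 parents = parents, time = 0, cycle = 1L,
                 scheme = scheme, effects = NULL, effects_key = "",
                 metrics = list(), counter = 0L),
            class = "program_state")
}

# Aggregate gain / diversity of a parent cohort, one metrics row.
.measure <- function(state, arch, config, scenario, replicate) {
  g <- tbv_all(state$pool, arch, state$parents)$trait_mean
  gain <- (colMeans(g) - arch$base_mean) / arch$base_sd
  div <- diversity_report(state$pool, arch, state$parents)
  row <- data.frame(scenario = scenario, replicate = replicate,
                    cycle = state$cycle, time = state$time,
                    gain_aggregate = sum(arch$weights[names(gain)] * gain),
                    t(gain),
                    tbv_var_aggregate = div$aggregate_tbv_var,
                    naf = div$naf, pct_fixed = div$pct_fixed,
                    mean_rel = div$mean_offdiag_grm,
                    check.names = FALSE)
  for (t in arch$traits) row[[paste0("acc_", t)]] <- NA_real_
  row
}

.next_ids <- function(state, stage, n) {
  ids <- sprintf("%s_c%02d_%06d", stage, state$cycle, state$counter + seq_len(n))
  state$counter <- state$counter + n
  list(state = state, ids = ids)
}

.relabel <- function(state, pop, stage) {
  nx <- .next_ids(state, stage, pop_size(pop))
  pop$meta$id <- nx$ids
  pop$meta$stage <- stage
  pop$meta$cycle <- state$cycle
  list(state = nx$state, pop = pop)
}

# Random mating under a per-parent usage cap: shuffle parent slots into
# pairs, then repair self-pairs by swapping mates with another pair.
.random_crosses <- function(n_parents, n_crosses, cap) {
  if (is.finite(cap)) {
    slots <- rep(seq_len(n_parents), cap)
    if (length(slots) < 2 * n_crosses)
      stop("invalid config: cap of ", cap, " on ", n_parents,
           " parents cannot yield ", n_crosses, " crosses")
    if (length(slots) > 2 * n_crosses) slots <- sample(slots, 2 * n_crosses)
  } else {
    slots <- sample.int(n_parents, 2 * n_crosses, replace = TRUE)
  }
  slots <- sample(slots)
  a <- slots[seq_len(n_crosses)]
  b <- slots[n_crosses + seq_len(n_crosses)]
  for (i in which(a == b)) {
    j <- which(a != a[i] & b != a[i])
    if (length(j) == 0)
      stop("invalid config: cannot avoid selfing in random mating")
    j <- j[1]
    tmp <- b[j]; b[j] <- b[i]; b[i] <- tmp
  }
  cbind(a, b)
}

# Select the next cycle's parents from the germplasm pool.
.choose_parents <- function(state, config, arch) {
  n_pool <- pop_size(state$pool)
  if (n_pool < config$n_parents)
    stop("invalid config: pool of ", n_pool, " cannot supply ",
         config$n_parents, " parents")
  if (config$selection == "PS") {
    idx <- selection_index(state$pool_ph, config$weights)
    state$parents <- sort(truncate_select(idx, config$n_parents))
  } else {
    gv <- gebv(state$effects, state$pool, arch$marker_loci)
    idx <- selection_index(gv, config$weights)
    if (config$diversity_preservation) {
      sel <- ga_select_parents(dose(state$pool, arch$marker_loci), idx,
                               n_parents = config$n_parents,
                               lambda1 = config$lambda1, lambda2 = config$lambda2,
                               pop_size = config$ga$pop_size,
                               iterations = config$ga$iterations,
                               mutation = config$ga$mutation,
                               elite_fraction = config$ga$elite_fraction,
                               ref_freq = arch$base_marker_freq)
      state$parents <- sel$selected
    } else {
      state$parents <- sort(truncate_select(idx, config$n_parents))
    }
  }
  state
}

# Fit (or reuse) marker effects from the archive as of the current calendar.
.fit_effects <- function(state, config, arch) {
  tr <- assemble_training(state$archive, fit_time = state$time,
                          window = config$training_window)
  key <- paste(length(tr$ids), paste(range(tr$cycle), collapse = "-"),
               sum(tr$source == "f2_family"))
  if (identical(key, state$effects_key)) return(state)
  h2e <- arch$h2 / (arch$h2 + (1 - arch$h2) / config$entry_mean_plots)
  state$effects <- estimate_marker_effects(tr, traits = arch$traits,
                                           h2_eff = h2e[arch$traits],
                                           fitted_at_cycle = state$cycle)
  state$effects_key <- key
  state
}

# Add selected lines to the germplasm pool (with their entry-mean phenotypes
# when available).
.add_to_pool <- function(state, pop, idx, ph = NULL) {
  add <- pop_subset(pop, idx)
  state$pool <- pop_bind(state$pool, add)
  extra <- matrix(NA_real_, length(idx), ncol(state$pool_ph),
                  dimnames = list(add$meta$id, colnames(state$pool_ph)))
  if (!is.null(ph)) extra[, colnames(ph)] <- ph[idx, , drop = FALSE]
  state$pool_ph <- rbind(state$pool_ph, extra)
  state
}

#' Run one phenotypic-selection breeding cycle
#'
#' From the current 150 parents: 300 random primary crosses under the
#' usage cap, F2 seeds per family, family bulk-up to F5 single plants, a 30%
#' cull on a noisy single-plant grain-yield record, random entry to the PYT,
#' then phenotype-index selection PYT -> Stage 1 -> Stage 2, with the Stage-2
#' selections joining the germplasm pool. Stage-1 entrants' entry means are
#' archived as future training records (phenotypes mature `pipeline_years`
#' after crossing).
#'
#' @param state a `program_state`.
#' @param config a `scenario_config` with `selection = "PS"`.
#' @param arch a `trait_arch`.
#' @return the updated `program_state`.
#' @export
run_ps_cycle <- function(state, config, arch) {
  tl <- timeline(config)
  mu <- config$mutation_rate
  prs <- .random_crosses(length(state$parents), config$n_primary_crosses,
                         config$parent_usage_cap)
  f1 <- cross(state$pool, state$parents[prs[, 1]], state$parents[prs[, 2]],
              mutation_rate = mu, xo_lambda = config$xo_lambda)
  rl <- .relabel(state, f1, "F1"); state <- rl$state; f1 <- rl$pop
  f2 <- self_line(f1, n_seeds = config$ps_f2_per_family, mutation_rate = mu,
                  xo_lambda = config$xo_lambda, stage = "F2")
  f5 <- ssd_advance(f2, 3, mutation_rate = mu, xo_lambda = config$xo_lambda,
                    stage = "F5")
  rl <- .relabel(state, f5, "F5"); state <- rl$state; f5 <- rl$pop
  yield <- phenotype(f5, arch, "grain_yield",
                     resid_inflation = config$single_plant_inflation)
  keep <- truncate_select(yield, round((1 - config$f5_cull) * pop_size(f5)))
  pyt_n <- min(config$pyt_size, length(keep))
  pyt <- pop_subset(f5, sort(sample(keep, pyt_n)))
  rl <- .relabel(state, pyt, "PYT"); state <- rl$state; pyt <- rl$pop
  rec_pyt <- run_trial(pyt, "pyt", arch, pyt_rep_fraction = config$pyt_rep_fraction)
  idx <- selection_index(entry_means(rec_pyt, pyt$meta$id), config$weights)
  s1 <- pop_subset(pyt, sort(truncate_select(idx, min(config$stage1_size, pop_size(pyt)))))
  s1$meta$stage <- "STG1"
  rec_s1 <- run_trial(s1, "stage", arch)
  idx <- selection_index(entry_means(rec_s1, s1$meta$id), config$weights)
  s2 <- pop_subset(s1, sort(truncate_select(idx, min(config$stage2_size, pop_size(s1)))))
  s2$meta$stage <- "STG2"
  rec_s2 <- run_trial(s2, "stage", arch)
  rec_adv <- rbind(rec_s1, rec_s2)
  ph_s2 <- entry_means(rec_adv[rec_adv$id %in% s2$meta$id, ], s2$meta$id)
  idx <- selection_index(ph_s2, config$weights)
  sel <- truncate_select(idx, min(config$pool_add, pop_size(s2)))
  state <- .add_to_pool(state, s2, sort(sel), ph_s2)
  ph_s1 <- entry_means(rec_adv, s1$meta$id)
  state$archive[[length(state$archive) + 1]] <- list(
    cycle = state$cycle, avail_time = state$time + tl$pipeline_years,
    X = dose(s1, arch$marker_loci), y = ph_s1[, arch$traits, drop = FALSE],
    source = "stage_trial", ids = s1$meta$id)
  state$time <- state$time + tl$interval
  state$cycle <- state$cycle + 1L
  state
}

#' Run one genomic-selection breeding cycle
#'
#' From the current parents (GEBV-index or GA selected): OHV-optimal primary
#' crosses, in-silico-projected F1 intercross selection, F2 seed production,
#' single-seed-descent bulk-up to F6, GEBV selection into the PYT, GEBV
#' selection at PYT and Stage 2 with phenotype-index selection at Stage 1.
#' Parents are recycled to the germplasm pool at `config$parent_stage`
#' (F1 intercross plants, F2 seeds, F6 lines, or the Stage-2 selections) by
#' GEBV index. Stage-1 entrants are archived as training records that mature
#' `pipeline_years` after crossing; optionally 50 field-grown F2 families are
#' phenotyped and added to the training archive (maturing after one season).
#'
#' @param state a `program_state` (must hold fitted marker `effects`).
#' @param config a `scenario_config` with `selection = "GS"`.
#' @param arch a `trait_arch`.
#' @return the updated `program_state`.
#' @export
run_gs_cycle <- function(state, config, arch) {
  if (is.null(state$effects)) stop("marker effects missing; fit before the GS cycle")
  tl <- timeline(config)
  mu <- config$mutation_rate
  eff <- state$effects
  ml <- arch$marker_loci
  w <- config$weights
  crs <- select_primary_crosses(state$pool, state$parents, eff, state$scheme,
                                ml, n_crosses = config$n_primary_crosses,
                                usage_cap = config$parent_usage_cap, weights = w)
  f1 <- cross(state$pool, crs$mother, crs$father, mutation_rate = mu,
              xo_lambda = config$xo_lambda)
  rl <- .relabel(state, f1, "F1"); state <- rl$state; f1 <- rl$pop
  ic <- select_intercrosses(f1, eff, state$scheme, ml,
                            n_select = config$n_intercross_families,
                            criterion = "mean_plus_sd",
                            prefilter = config$intercross_prefilter,
                            n_virtual = config$n_virtual,
                            target_gen = config$target_gen, weights = w,
                            xo_lambda = config$xo_lambda)
  f1i <- cross(f1, ic$a, ic$b, mutation_rate = mu, xo_lambda = config$xo_lambda)
  rl <- .relabel(state, f1i, "F1i"); state <- rl$state; f1i <- rl$pop
  recycle <- function(state, pop) {
    gv <- gebv(eff, pop, ml)
    idx <- selection_index(gv, w)
    sel <- sort(truncate_select(idx, min(config$pool_add, pop_size(pop))))
    .add_to_pool(state, pop, sel)
  }
  acc <- NULL
  if (config$parent_stage == "F1") {
    acc <- accuracy(eff, f1i, arch)
    state <- recycle(state, f1i)
  }
  f2 <- self_line(f1i, n_seeds = config$seeds_per_family, mutation_rate = mu,
                  xo_lambda = config$xo_lambda, stage = "F2")
  f2$meta$family <- rep(f1i$meta$id, each = config$seeds_per_family)
  rl <- .relabel(state, f2, "F2"); state <- rl$state; f2 <- rl$pop
  if (config$parent_stage == "F2") {
    acc <- accuracy(eff, f2, arch)
    state <- recycle(state, f2)
  }
  if (config$f2_phenotyping) {
    empty <- new_training_set(matrix(0, 0, length(ml)),
                              matrix(0, 0, length(arch$traits),
                                     dimnames = list(NULL, arch$traits)),
                              integer(0))
    fam <- add_f2_family_records(empty, f2, arch,
                                 n_families = config$n_f2_families,
                                 resid_inflation = config$single_plant_inflation,
                                 cycle = state$cycle)
    state$archive[[length(state$archive) + 1]] <- list(
      cycle = state$cycle, avail_time = state$time + 1,
      X = fam$X, y = fam$y, source = "f2_family", ids = fam$ids)
  }
  f6 <- ssd_advance(f2, 4, mutation_rate = mu, xo_lambda = config$xo_lambda,
                    stage = "F6")
  rl <- .relabel(state, f6, "F6"); state <- rl$state; f6 <- rl$pop
  if (config$parent_stage %in% c("F6", "STG2")) acc <- accuracy(eff, f6, arch)
  if (config$parent_stage == "F6") state <- recycle(state, f6)
  gv <- gebv(eff, f6, ml)
  idx <- selection_index(gv, w)
  pyt <- pop_subset(f6, sort(truncate_select(idx, min(config$pyt_size, pop_size(f6)))))
  pyt$meta$stage <- "PYT"
  rec_pyt <- run_trial(pyt, "pyt", arch, pyt_rep_fraction = config$pyt_rep_fraction)
  gv <- gebv(eff, pyt, ml)
  idx <- selection_index(gv, w)
  s1 <- pop_subset(pyt, sort(truncate_select(idx, min(config$stage1_size, pop_size(pyt)))))
  s1$meta$stage <- "STG1"
  rec_s1 <- run_trial(s1, "stage", arch)
  idx <- selection_index(entry_means(rec_s1, s1$meta$id), config$weights)
  s2 <- pop_subset(s1, sort(truncate_select(idx, min(config$stage2_size, pop_size(s1)))))
  s2$meta$stage <- "STG2"
  rec_s2 <- run_trial(s2, "stage", arch)
  if (config$parent_stage == "STG2") state <- recycle(state, s2)
  rec_adv <- rbind(rec_s1, rec_s2)
  ph_s1 <- entry_means(rec_adv, s1$meta$id)
  state$archive[[length(state$archive) + 1]] <- list(
    cycle = state$cycle, avail_time = state$time + tl$pipeline_years,
    X = dose(s1, ml), y = ph_s1[, arch$traits, drop = FALSE],
    source = "stage_trial", ids = s1$meta$id)
  state$acc_last <- acc
  state$time <- state$time + tl$interval
  state$cycle <- state$cycle + 1L
  state
}

#' Run a replicated scenario experiment
#'
#' For each replicate: resample the cycle-1 parents from the base
#' population, run the phenotypic-selection program for `warmup_cycles`
#' cycles, then branch -- the PS benchmark continues to `n_cycles`, and every
#' GS scenario restarts from the common warm-start state and runs cycles
#' `warmup_cycles + 1` to `n_cycles`. A final parent selection after the last
#' cycle closes each branch, so per-branch metrics span cycle starts
#' `1 .. n_cycles + 1`. The QTL architecture is resampled per replicate.
#'
#' @param scenarios list of GS `scenario_config`s (the PS benchmark is always
#'   run; pass `ps_config` to override its settings).
#' @param founders a `breeding_pop` of founder lines.
#' @param n_replicates number of replicates (default 50).
#' @param base_seed integer seed controlling everything.
#' @param warmup_cycles shared phenotypic cycles before branching (default 3).
#' @param n_cycles total breeding cycles (default 8).
#' @param ps_config the PS benchmark configuration.
#' @param arch_args list of arguments for [sample_architecture()]
#'   (e.g. `n_qtl`, `n_markers`).
#' @param include_ps run the PS benchmark branch beyond the warm start
#'   (default TRUE; branch comparisons across experiments sharing founders
#'   and `base_seed` are paired, because the warm start is bit-identical).
#' @return data.frame of per-cycle metrics: scenario, replicate, cycle,
#'   calendar time, per-trait and aggregate gain (base-population additive SD
#'   units), aggregate TBV variance, fixed-allele count and percentage, mean
#'   genomic relationship of the parents, and per-trait GEBV accuracy of the
#'   cycle's selection candidates (GS cycles).
#' @export
run_experiment <- function(scenarios, founders, n_replicates = 50,
                           base_seed = 1, warmup_cycles = 3, n_cycles = 8,
                           ps_config = scenario_preset("PS_STG2"),
                           arch_args = list(), include_ps = TRUE) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  set.seed(base_seed)
  rep_seeds <- sample.int(2^31 - 1, n_replicates)
  out <- list()
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    arch <- do.call(sample_architecture,
                    c(list(founders = founders,
                           seed = sample.int(2^31 - 1, 1)), arch_args))
    state <- init_program_state(founders, arch, ps_config)
    warm <- list()
    for (cyc in seq_len(warmup_cycles)) {
      if (cyc > 1) state <- .choose_parents(state, ps_config, arch)
      warm[[cyc]] <- .measure(state, arch, ps_config, "warmup", r)
      state <- run_ps_cycle(state, ps_config, arch)
    }
    snapshot <- state
    branches <- c(if (include_ps) list(ps_config), scenarios)
    for (b in seq_along(branches)) {
      cfg <- branches[[b]]
      st <- snapshot
      set.seed((rep_seeds[r] + 104729 * b) %% (2^31 - 1))
      if (cfg$selection == "GS") {
        tl <- timeline(cfg)
        st$time <- snapshot$time       # branch clock starts at warm-start end
      }
      for (cyc in (warmup_cycles + 1):n_cycles) {
        if (cfg$selection == "GS") st <- .fit_effects(st, cfg, arch)
        st <- .choose_parents(st, cfg, arch)
        row <- .measure(st, arch, cfg, cfg$name, r)
        st$acc_last <- NULL
        st <- if (cfg$selection == "GS") run_gs_cycle(st, cfg, arch)
              else run_ps_cycle(st, cfg, arch)
        if (!is.null(st$acc_last))
          row[paste0("acc_", names(st$acc_last))] <- st$acc_last
        out[[length(out) + 1]] <- row
      }
      if (cfg$selection == "GS") st <- .fit_effects(st, cfg, arch)
      st <- .choose_parents(st, cfg, arch)
      out[[length(out) + 1]] <- .measure(st, arch, cfg, cfg$name, r)
      for (wrow in warm) {
        wrow$scenario <- cfg$name
        out[[length(out) + 1]] <- wrow
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$scenario, res$replicate, res$cycle), ]
}

#' Annual rates of gain and diversity change
#'
#' For each scenario and replicate, the annual rate of a metric over the
#' post-branching phase (cycle starts `from` to the final row):
#' `(value_end - value_start) / (time_end - time_start)`. The summary
#' averages rates over replicates and expresses each genomic-selection
#' scenario's aggregate-gain rate as a percentage change over the phenotypic
#' benchmark: `(rate_GS - rate_PS) / rate_PS * 100`.
#'
#' @param metrics the table from [run_experiment()].
#' @param from first cycle of the reporting window (default 4, the branch
#'   point).
#' @param ps_name scenario name of the phenotypic benchmark.
#' @return list: `per_replicate` (rates per scenario x replicate) and
#'   `summary` (mean rates with `pct_vs_ps` for the aggregate gain).
#' @export
per_year_rates <- function(metrics, from = 4, ps_name = "PS_STG2") {
  cols <- c("gain_aggregate", "tbv_var_aggregate", "pct_fixed", "mean_rel")
  sp <- split(metrics, list(metrics$scenario, metrics$replicate), drop = TRUE)
  pr <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$cycle), ]
    d <- d[d$cycle >= from, ]
    if (nrow(d) < 2) return(NULL)
    dt <- d$time[nrow(d)] - d$time[1]
    if (dt <= 0) stop("zero elapsed years in reporting window")
    rates <- (as.numeric(d[nrow(d), cols]) - as.numeric(d[1, cols])) / dt
    data.frame(scenario = d$scenario[1], replicate = d$replicate[1],
               t(stats::setNames(rates, paste0("rate_", cols))))
  }))
  rownames(pr) <- NULL
  agg <- stats::aggregate(pr[, -(1:2)], by = list(scenario = pr$scenario), mean)
  ps_rate <- agg$rate_gain_aggregate[agg$scenario == ps_name]
  agg$pct_vs_ps <- if (length(ps_rate) == 1 && ps_rate != 0)
    (agg$rate_gain_aggregate - ps_rate) / ps_rate * 100 else NA_real_
  list(per_replicate = pr, summary = agg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$name, ": ", x$selection, ", bulk-up ", x$bulkup,
      ", parents from ", x$parent_stage,
      if (x$f2_phenotyping) ", +F2 phenotyping" else "",
      if (x$diversity_preservation) ", +diversity GA" else "", "\n", sep = "")
  cat("  interval ", timeline(x)$interval, " years\n", sep = "")
  invisible(x)
}
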
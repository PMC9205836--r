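# micro-scale founders shared by the program tests
prog_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      map <- build_map(3, c(450, 500), c(150, 250), seed = 40)
      f <- simulate_founders(map, 150, burn_in_generations = 20, seed = 41)
      cache <<- list(founders = f)
    }
    cache
  }
})

test_that("the nine benchmark generation intervals are reproduced", {
  expected <- c(PS_STG2 = 8, GS_SSD_STG2 = 8.5, GS_SSD_F6 = 5, GS_SSD_F2 = 1,
                GS_SSD_F1 = 0.5, GS_aSSD_STG2 = 6, GS_aSSD_F6 = 2.5,
                GS_aSSD_F2 = 1, GS_aSSD_F1 = 0.5)
  got <- sapply(names(expected), function(n) timeline(n)$interval)
  expect_equal(got, expected)
  expect_equal(timeline("GS_aSSD_F2")$pipeline_years, 6)
  expect_equal(timeline("GS_SSD_F1")$pipeline_years, 8.5)
})

test_that("scenario presets parse option suffixes", {
  s <- scenario_preset("GS_aSSD_F2_PH")
  expect_true(s$f2_phenotyping)
  expect_equal(s$bulkup, "aSSD")
  expect_equal(s$parent_stage, "F2")
  d <- scenario_preset("GS_SSD_STG2_DP")
  expect_true(d$diversity_preservation)
  expect_error(scenario_preset("GS_F9"), "unknown scenario")
  expect_error(scenario_config(selection = "PS", bulkup = "SSD"), "family")
})

test_that("a phenotypic cycle moves the right cohort sizes through the stages", {
  fx <- prog_fixture()
  cfg <- do.call(scenario_config,
                 c(list(name = "PS", selection = "PS", bulkup = "family",
                        parent_stage = "STG2"), micro_args()))
  set.seed(42)
  arch <- sample_architecture(fx$founders, n_qtl = 50, n_markers = 500,
                              seed = 43)
  state <- init_program_state(fx$founders, arch, cfg)
  expect_length(state$parents, cfg$n_parents)
  state2 <- run_ps_cycle(state, cfg, arch)
  expect_equal(pop_size(state2$pool), 150 + cfg$pool_add)
  expect_length(state2$archive, 1)
  expect_equal(nrow(state2$archive[[1]]$X), cfg$stage1_size)
  expect_equal(state2$archive[[1]]$avail_time, 8)
  expect_equal(state2$time, 8)
  expect_false(any(duplicated(state2$pool$meta$id)))
  expect_true(all(is.finite(state2$pool_ph[state2$pool$meta$stage == "STG2",
                                           arch$traits])))
})

test_that("the F5 single-plant cull keeps the configured fraction", {
  # cull retains 70% of single plants before random PYT entry
  cfg <- do.call(scenario_config,
                 c(list(selection = "PS", bulkup = "family",
                        parent_stage = "STG2"), micro_args()))
  n_f2 <- cfg$n_primary_crosses * cfg$ps_f2_per_family
  expect_equal(round((1 - cfg$f5_cull) * n_f2), 84)
})

test_that("random mating respects the usage cap and avoids selfing", {
  set.seed(44)
  for (r in 1:20) {
    prs <- pulsegs:::.random_crosses(150, 300, 4)
    expect_equal(nrow(prs), 300)
    expect_true(all(prs[, 1] != prs[, 2]))
    expect_lte(max(table(c(prs))), 4)
  }
})

test_that("neutral advancement shows no systematic TBV trend", {
  fx <- prog_fixture()
  arch <- sample_architecture(fx$founders, n_qtl = 50, n_markers = 500,
                              seed = 45)
  set.seed(46)
  drifts <- replicate(20, {
    pop <- pop_subset(fx$founders, sample.int(150, 40))
    g0 <- mean(tbv_all(pop, arch)$trait_mean[, "grain_yield"])
    for (gen in 1:3) {
      pop <- cross(pop, sample.int(40, 40, TRUE), sample.int(40, 40, TRUE),
                   mutation_rate = 0)
    }
    mean(tbv_all(pop, arch)$trait_mean[, "grain_yield"]) - g0
  })
  expect_lt(abs(mean(drifts)), 3 * sd(drifts) / sqrt(20))
})

test_that("a full micro experiment emits the metrics schema and shares its warm start", {
  fx <- prog_fixture()
  args <- micro_args()
  scen <- list(do.call(scenario_preset, c(list(name = "GS_SSD_STG2"), args)),
               do.call(scenario_preset, c(list(name = "GS_SSD_F2"), args)))
  ps <- do.call(scenario_preset, c(list(name = "PS_STG2"), args))
  m <- run_experiment(scen, fx$founders, n_replicates = 1, base_seed = 47,
                      warmup_cycles = 2, n_cycles = 4, ps_config = ps,
                      arch_args = list(n_qtl = 50, n_markers = 500))
  expect_setequal(unique(m$scenario), c("PS_STG2", "GS_SSD_STG2", "GS_SSD_F2"))
  need <- c("scenario", "replicate", "cycle", "time", "gain_aggregate",
            "grain_yield", "tbv_var_aggregate", "naf", "pct_fixed",
            "mean_rel", "acc_grain_yield")
  expect_true(all(need %in% colnames(m)))
  # warm-start rows are bit-identical across branches
  warm <- m[m$cycle <= 2, ]
  for (cyc in 1:2) {
    vals <- warm$gain_aggregate[warm$cycle == cyc]
    expect_equal(length(unique(vals)), 1)
  }
  # branch calendars advance by their generation intervals
  for (s in c("GS_SSD_STG2", "GS_SSD_F2")) {
    d <- m[m$scenario == s & m$cycle >= 3, ]
    expect_equal(unique(diff(d$time)), timeline(s)$interval)
  }
  # GS rows carry accuracy for the selection candidates
  expect_true(all(is.finite(m$acc_grain_yield[m$scenario == "GS_SSD_F2" &
                                                m$cycle %in% 3:4])))
})

test_that("training sets freeze under early recycling and refresh under late recycling", {
  fx <- prog_fixture()
  args <- micro_args()
  arch <- sample_architecture(fx$founders, n_qtl = 50, n_markers = 500,
                              seed = 48)
  ps <- do.call(scenario_preset, c(list(name = "PS_STG2"), args))
  set.seed(49)
  state <- init_program_state(fx$founders, arch, ps)
  for (cyc in 1:3) {
    if (cyc > 1) state <- pulsegs:::.choose_parents(state, ps, arch)
    state <- run_ps_cycle(state, ps, arch)
  }
  run_branch <- function(name, cycles = 3) {
    cfg <- do.call(scenario_preset, c(list(name = name), args))
    st <- state
    keys <- character(0)
    for (i in seq_len(cycles)) {
      st <- pulsegs:::.fit_effects(st, cfg, arch)
      keys <- c(keys, st$effects_key)
      st <- pulsegs:::.choose_parents(st, cfg, arch)
      st <- run_gs_cycle(st, cfg, arch)
    }
    keys
  }
  keys_f2 <- run_branch("GS_SSD_F2")
  expect_equal(length(unique(keys_f2)), 1)    # frozen at the warm-start cycles
  keys_stg2 <- run_branch("GS_SSD_STG2")
  expect_gt(length(unique(keys_stg2)), 1)     # refreshes as phenotypes mature
  keys_ph <- run_branch("GS_SSD_F2_PH")
  expect_gt(length(unique(keys_ph)), 1)       # F2 phenotypes refresh training
})

test_that("annual-rate summaries do the arithmetic they claim", {
  mk_row <- function(scenario, cycle, time, gain)
    data.frame(scenario = scenario, replicate = 1, cycle = cycle, time = time,
               gain_aggregate = gain, tbv_var_aggregate = 1, pct_fixed = 0,
               mean_rel = 0)
  m <- rbind(mk_row("PS_STG2", 4, 0, 0), mk_row("PS_STG2", 9, 20, 2),
             mk_row("GS_X", 4, 0, 0), mk_row("GS_X", 9, 5, 2))
  r <- per_year_rates(m)
  expect_equal(r$summary$rate_gain_aggregate[r$summary$scenario == "PS_STG2"],
               0.1)
  expect_equal(r$summary$rate_gain_aggregate[r$summary$scenario == "GS_X"],
               0.4)
  expect_equal(r$summary$pct_vs_ps[r$summary$scenario == "GS_X"], 300)
  expect_equal((0.14 - 0.10) / 0.10 * 100, 40)  # percentage formula
  m$time <- 0
  expect_error(per_year_rates(m), "zero elapsed")
})
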
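#' Sample a multi-trait, multi-environment QTL architecture
#'
#' Three traits (disease resistance, grain weight, grain yield) are simulated
#' in two environments. A marker panel of `n_markers` loci is drawn first;
#' QTL are drawn from the remaining loci, so markers act on predictions only
#' through linkage disequilibrium with QTL. Each (trait, environment) has
#' `n_qtl` QTL: a common core of `round(overlap * n_qtl)` loci shared by all
#' six trait-environment sets (so the pairwise locus overlap between traits
#' within an environment and between environments within a trait equals
#' `overlap`), plus set-specific loci. Effects are N(0, 1); for a given
#' trait, the effect pair of a shared locus in the two environments is drawn
#' from a bivariate standard normal with correlation `env_cor[trait]`
#' (genotype-by-environment interaction); between traits effects are
#' independent (correlation 0).
#'
#' The founder population's true-breeding-value statistics are recorded in
#' the architecture: per (trait, environment) additive variance (frozen as
#' the genetic variance in the residual model) and the per-trait additive SD
#' of the environment-mean TBV, the unit in which genetic gain is reported.
#'
#' @param founders a `breeding_pop` of founder lines.
#' @param n_qtl QTL per trait-environment combination (default 1000).
#' @param overlap fraction of each QTL set shared across traits and
#'   environments (default 0.7).
#' @param h2 named per-trait narrow-sense heritabilities.
#' @param env_cor named per-trait effect correlations between environments.
#' @param weights per-trait selection-index weights, also used for aggregate
#'   gain and aggregate TBV variance.
#' @param n_markers size of the marker panel.
#' @param seed integer seed.
#' @return An object of class `trait_arch`.
#' @export
sample_architecture <- function(founders, n_qtl = 1000, overlap = 0.7,
                                h2 = c(disease_resistance = 0.5,
                                       grain_weight = 0.75,
                                       grain_yield = 0.25),
                                env_cor = c(disease_resistance = 0.8,
                                            grain_weight = 0.8,
                                            grain_yield = 0.4),
                                weights = c(disease_resistance = 0.3,
                                            grain_weight = 0.3,
                                            grain_yield = 0.4),
                                n_markers = 30000, seed = 1) {
  stopifnot(inherits(founders, "breeding_pop"))
  map <- founders$map
  traits <- names(h2)
  envs <- c("env1", "env2")
  if (any(h2 <= 0 | h2 > 1)) stop("invalid config: h2 must be in (0, 1]")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  n_core <- round(overlap * n_qtl)
  n_uniq <- n_qtl - n_core
  need <- n_core + length(traits) * length(envs) * n_uniq
  if (n_markers + need > map$n_loci)
    stop("invalid config: map has ", map$n_loci, " loci but ",
         n_markers + need, " are needed for markers and QTL")
  marker_loci <- sort(sample.int(map$n_loci, n_markers))
  pool <- setdiff(seq_len(map$n_loci), marker_loci)
  core <- sample(pool, n_core)
  pool <- setdiff(pool, core)
  qtl <- list()
  for (t in traits) {
    z1 <- stats::rnorm(n_core)
    z2 <- stats::rnorm(n_core)
    rho <- env_cor[[t]]
    core_eff <- cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
    qtl[[t]] <- list()
    for (e in seq_along(envs)) {
      uniq <- if (n_uniq > 0) sample(pool, n_uniq) else integer(0)
      pool <- setdiff(pool, uniq)
      qtl[[t]][[envs[e]]] <- list(
        loci = c(core, uniq),
        eff = c(core_eff[, e], stats::rnorm(n_uniq))
      )
    }
  }
  arch <- structure(list(
    traits = traits, envs = envs, h2 = h2, env_cor = env_cor,
    weights = weights, overlap = overlap, n_qtl = n_qtl,
    marker_loci = marker_loci, qtl = qtl,
    base_marker_freq = allele_freq(founders, marker_loci),
    base_var = NULL, base_sd = NULL, base_mean = NULL
  ), class = "trait_arch")
  g <- tbv_all(founders, arch)
  arch$base_var <- apply(g$per_env, c(2, 3), stats::var)     # env x trait
  arch$base_sd <- apply(g$trait_mean, 2, stats::sd)
  arch$base_mean <- colMeans(g$trait_mean)
  arch
}

#' True breeding value
#'
#' Sum over QTL of allele dose (0/1/2) times the allele substitution effect.
#'
#' @param pop a `breeding_pop`.
#' @param arch a `trait_arch`.
#' @param trait trait name.
#' @param environment environment name.
#' @param inds individual indices (default all).
#' @return numeric vector of TBVs.
#' @export
tbv <- function(pop, arch, trait, environment = "env1",
                inds = seq_len(pop_size(pop))) {
  q <- arch$qtl[[trait]][[environment]]
  drop(dose(pop, q$loci, inds) %*% q$eff)
}

#' All true breeding values of a population
#'
#' @param pop a `breeding_pop`.
#' @param arch a `trait_arch`.
#' @param inds individual indices (default all).
#' @return list: `per_env` (n x envs x traits array) and `trait_mean`
#'   (n x traits, TBV averaged over environments).
#' @export
tbv_all <- function(pop, arch, inds = seq_len(pop_size(pop))) {
  n <- length(inds)
  per_env <- array(NA_real_, c(n, length(arch$envs), length(arch$traits)),
                   dimnames = list(NULL, arch$envs, arch$traits))
  for (t in arch$traits) for (e in arch$envs)
    per_env[, e, t] <- tbv(pop, arch, t, e, inds)
  list(per_env = per_env,
       trait_mean = apply(per_env, c(1, 3), mean))
}

#' Simulate a phenotype
#'
#' Phenotype = TBV + e with e ~ N(0, sigma2_e), where
#' sigma2_e = ((1 - h2) / h2) * sigma2_g and sigma2_g is the founder
#' population's additive variance for the (trait, environment), frozen at
#' architecture creation so residual noise does not shrink as selection
#' depletes variance. `resid_inflation` multiplies sigma2_e (used for noisy
#' single-plant records).
#'
#' @inheritParams tbv
#' @param resid_inflation multiplier on the residual variance.
#' @param h2_override replace the trait's heritability (e.g. 1 for noiseless
#'   diagnostics).
#' @return numeric vector of phenotypes.
#' @export
phenotype <- function(pop, arch, trait, environment = "env1",
                      inds = seq_len(pop_size(pop)), resid_inflation = 1,
                      h2_override = NULL) {
  h2 <- if (is.null(h2_override)) arch$h2[[trait]] else h2_override
  if (h2 <= 0 || h2 > 1) stop("invalid config: h2 must be in (0, 1]")
  g <- tbv(pop, arch, trait, environment, inds)
  s2e <- resid_inflation * (1 - h2) / h2 * arch$base_var[environment, trait]
  g + stats::rnorm(length(g), 0, sqrt(s2e))
}

#' Run a phenotyping trial
#'
#' Emits one record per plot in a tidy table. Designs:
#' \describe{
#'   \item{`pyt`}{preliminary yield trial: one environment (`env1`), a
#'     fraction `pyt_rep_fraction` of entries get 2 replicates, the rest 1
#'     (partial replication).}
#'   \item{`stage`}{advanced trial: 2 replicates x 2 environments for every
#'     entry.}
#'   \item{`single_plant`}{one plot in `env1` with residual variance
#'     multiplied by `resid_inflation` (low single-plant heritability).}
#'   \item{`f2_family_plot`}{same layout as `single_plant`; used for
#'     field-grown F2 plants.}
#' }
#'
#' @param pop a `breeding_pop` of trial entries.
#' @param design one of `"pyt"`, `"stage"`, `"single_plant"`, `"f2_family_plot"`.
#' @param arch a `trait_arch`.
#' @param pyt_rep_fraction fraction of PYT entries with 2 replicates.
#' @param resid_inflation residual-variance inflation for single-plant plots.
#' @return data.frame with columns `id`, `trait`, `environment`, `rep`,
#'   `value`, `stage`, `cycle`.
#' @export
run_trial <- function(pop, design = c("stage", "pyt", "single_plant", "f2_family_plot"),
                      arch, pyt_rep_fraction = 0.2, resid_inflation = 2) {
  design <- match.arg(design)
  n <- pop_size(pop)
  if (n == 0) stop("invalid input: empty population")
  layout <- switch(design,
    stage = expand.grid(env = arch$envs, rep = 1:2, stringsAsFactors = FALSE),
    pyt = data.frame(env = "env1", rep = 1L),
    data.frame(env = "env1", rep = 1L))
  infl <- if (design %in% c("single_plant", "f2_family_plot")) resid_inflation else 1
  twice <- if (design == "pyt" && pyt_rep_fraction > 0)
    sample.int(n, round(pyt_rep_fraction * n)) else integer(0)
  out <- list()
  for (t in arch$traits) {
    for (r in seq_len(nrow(layout))) {
      v <- phenotype(pop, arch, t, layout$env[r], resid_inflation = infl)
      out[[length(out) + 1]] <- data.frame(
        id = pop$meta$id, trait = t, environment = layout$env[r],
        rep = layout$rep[r], value = v, stage = pop$meta$stage,
        cycle = pop$meta$cycle, stringsAsFactors = FALSE)
    }
    if (length(twice)) {
      v <- phenotype(pop, arch, t, "env1", inds = twice, resid_inflation = infl)
      out[[length(out) + 1]] <- data.frame(
        id = pop$meta$id[twice], trait = t, environment = "env1",
        rep = 2L, value = v, stage = pop$meta$stage[twice],
        cycle = pop$meta$cycle[twice], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Entry means of trial records
#'
#' Pools an entry's plot records per trait across replicates and
#' environments; the aggregation used for phenotype-based selection and for
#' training-set phenotypes.
#'
#' @param records a tidy record table from [run_trial()] (rows may span
#'   several trials).
#' @param ids optional id order for the output (default: order of appearance).
#' @return numeric matrix, entries x traits.
#' @export
entry_means <- function(records, ids = unique(records$id)) {
  traits <- unique(records$trait)
  out <- matrix(NA_real_, length(ids), length(traits),
                dimnames = list(ids, traits))
  for (t in traits) {
    r <- records[records$trait == t, ]
    m <- tapply(r$value, r$id, mean)
    out[, t] <- m[ids]
  }
  out
}

#' @export
print.trait_arch <- function(x, ...) {
  cat("<trait_arch> ", length(x$traits), " traits x ", length(x$envs),
      " environments, ", x$n_qtl, " QTL each (overlap ", x$overlap, ")\n",
      "  markers: ", length(x$marker_loci), "; h2: ",
      paste(names(x$h2), x$h2, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
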
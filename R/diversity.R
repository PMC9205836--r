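#' Multi-trait selection index
#'
#' Per candidate, the weighted sum of cohort-standardized trait values
#' (GEBVs, OHVs or phenotype means): `sum_t w_t * z_t` with
#' `z_t = (v_t - mean_t) / sd_t` over the cohort. Standardization makes the
#' index invariant to trait scale. A trait whose cohort SD is zero
#' contributes 0 with a warning.
#'
#' @param values numeric matrix, candidates x traits (a vector is treated as
#'   one trait).
#' @param weights per-trait weights (default 0.3 disease resistance, 0.3
#'   grain weight, 0.4 grain yield).
#' @param sds optional externally supplied per-trait SDs (skips the cohort
#'   SD).
#' @param center subtract the cohort mean before scaling (default TRUE;
#'   ranking is unaffected either way).
#' @return numeric vector of index scores.
#' @export
selection_index <- function(values, weights = c(0.3, 0.3, 0.4), sds = NULL,
                            center = TRUE) {
  values <- as.matrix(values)
  weights <- rep_len(weights, ncol(values))
  out <- numeric(nrow(values))
  for (t in seq_len(ncol(values))) {
    s <- if (is.null(sds)) stats::sd(values[, t]) else sds[t]
    if (is.na(s) || s <= 1e-10 * max(1, abs(mean(values[, t])))) {
      warning("zero SD for trait column ", t, "; term set to 0")
      next
    }
    z <- (values[, t] - if (center) mean(values[, t]) else 0) / s
    out <- out + weights[t] * z
  }
  out
}

#' Truncation selection
#'
#' Top-`n` candidates by index value, ties broken deterministically by
#' ascending position (id order).
#'
#' @param index_values numeric vector of scores.
#' @param n number to select.
#' @return integer indices of the selected candidates, best first.
#' @export
truncate_select <- function(index_values, n) {
  if (n > length(index_values)) stop("cannot select ", n, " from ",
                                     length(index_values), " candidates")
  order(-index_values, seq_along(index_values))[seq_len(n)]
}

#' Genomic relationship matrix (VanRaden)
#'
#' `G = Z Z' / (2 * sum(p * (1 - p)))` with `Z = M - 2p` the centred allele
#' doses and `p` the allele frequencies of the reference cohort (by default
#' the cohort itself, so per-cycle mean relationships are within-cohort).
#'
#' @param M numeric matrix of allele doses (individuals x loci), or a
#'   `breeding_pop` (then `loci` selects the panel).
#' @param p optional reference allele frequencies (default: column means of
#'   `M` / 2).
#' @param loci marker loci when `M` is a population.
#' @return list: `G` (the relationship matrix) and `mean_offdiag`.
#' @export
grm <- function(M, p = NULL, loci = NULL) {
  if (inherits(M, "breeding_pop"))
    M <- dose(M, if (is.null(loci)) seq_len(M$map$n_loci) else loci)
  if (nrow(M) < 2) stop("need at least 2 individuals")
  if (is.null(p)) p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all reference loci fixed; GRM undefined")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  n <- nrow(G)
  list(G = G, mean_offdiag = (sum(G) - sum(diag(G))) / (n * (n - 1)))
}

#' Genetic-diversity report for a cohort
#'
#' Computes the number (and percentage) of marker-panel loci with no allelic
#' variation in the cohort (NAF; a heterozygote at a locus means it is not
#' fixed), the mean off-diagonal of the VanRaden GRM, the per-trait TBV
#' variance (environment-mean TBV) and the aggregate TBV variance weighted by
#' the selection-index weights. Higher TBV variance, lower NAF and lower mean
#' relationship imply higher genetic diversity.
#'
#' The GRM is centred with the base population's allele frequencies (stored
#' in the architecture): with the cohort's own frequencies the off-diagonal
#' mean is structurally pinned near `-(1+F)/(n-1)` (the centred doses sum to
#' zero), so relatedness accumulating over breeding cycles is only visible
#' against a fixed reference.
#'
#' @param pop a `breeding_pop` (the cohort, e.g. a cycle's parents).
#' @param arch a `trait_arch`.
#' @param inds cohort indices.
#' @return list with `naf`, `pct_fixed`, `mean_offdiag_grm`, `tbv_var`
#'   (named per trait), `aggregate_tbv_var`.
#' @export
diversity_report <- function(pop, arch, inds = seq_len(pop_size(pop))) {
  M <- dose(pop, arch$marker_loci, inds)
  k <- length(inds)
  fixed0 <- colSums(M == 0) == k
  fixed2 <- colSums(M == 2) == k
  naf <- sum(fixed0 | fixed2)
  g <- tbv_all(pop, arch, inds)$trait_mean
  v <- apply(g, 2, stats::var)
  ref_p <- arch$base_marker_freq
  list(naf = naf,
       pct_fixed = 100 * naf / length(arch$marker_loci),
       mean_offdiag_grm = if (k >= 2) grm(M, p = ref_p)$mean_offdiag else NA_real_,
       tbv_var = v,
       aggregate_tbv_var = sum(arch$weights[names(v)] * v))
}

#' Genetic-algorithm parent selection with diversity penalties
#'
#' Maximizes `f = mean(index) - lambda1 * meanREL - lambda2 * NAF` over
#' subsets of exactly `n_parents` candidates, where `meanREL` is the mean
#' off-diagonal of the pool GRM restricted to the subset and `NAF` the number
#' of marker loci fixed within the subset. Subsets are encoded as membership
#' bit-vectors; the initial population contains the truncation-selection set
#' (top `n_parents` by index) plus random subsets; each generation keeps the
#' `elite_fraction` fittest unchanged, fills the rest with one-point
#' crossover of random elite pairs plus per-bit mutation, and repairs
#' cardinality by toggling the lowest-index (when over) or highest-index
#' (when under) candidates. The best-ever subset is tracked and returned.
#'
#' @param pool_M allele-dose matrix of the candidate pool (individuals x
#'   marker panel), or a `breeding_pop`.
#' @param index_values per-candidate selection-index values.
#' @param n_parents subset cardinality (default 150).
#' @param lambda1 penalty on the mean relationship (default 1).
#' @param lambda2 penalty on the fixed-allele count (default 1e-6).
#' @param pop_size,iterations,mutation,elite_fraction GA parameters
#'   (defaults 2000, 1000, 0.001, 0.2).
#' @param loci marker loci when `pool_M` is a population.
#' @param ref_freq reference allele frequencies for GRM centring (e.g. the
#'   base population's, putting the relationship penalty on the same scale
#'   as the reported diversity metrics); default: pool frequencies.
#' @param trace record the best fitness per iteration.
#' @return list: `selected` (indices into the pool, class `parent_set`),
#'   `fitness`, `mean_index`, `mean_rel`, `naf`, and optionally `trace`.
#' @export
ga_select_parents <- function(pool_M, index_values, n_parents = 150,
                              lambda1 = 1, lambda2 = 1e-6, pop_size = 2000,
                              iterations = 1000, mutation = 0.001,
                              elite_fraction = 0.2, loci = NULL,
                              ref_freq = NULL, trace = FALSE) {
  if (inherits(pool_M, "breeding_pop"))
    pool_M <- dose(pool_M, if (is.null(loci)) seq_len(pool_M$map$n_loci) else loci)
  n <- nrow(pool_M)
  if (n < n_parents) stop("infeasible: pool of ", n, " smaller than n_parents")
  storage.mode(pool_M) <- "integer"
  G <- grm(pool_M, p = ref_freq)$G
  rank_desc <- rank(-index_values, ties.method = "first")
  subsets <- matrix(0L, n_parents, pop_size)
  subsets[, 1] <- which(rank_desc <= n_parents)        # truncation seed
  for (s in seq_len(pop_size)[-1]) subsets[, s] <- sample.int(n, n_parents)
  n_elite <- max(1L, round(elite_fraction * pop_size))
  n_off <- pop_size - n_elite
  rows <- seq_len(n)
  best <- NULL
  tr <- if (trace) numeric(iterations) else NULL
  elite_fit <- NULL           # carried-over elites keep their fitness
  for (it in seq_len(iterations)) {
    if (is.null(elite_fit)) {
      fit <- cpp_ga_fitness(G, pool_M, subsets, index_vals = index_values,
                            l1 = lambda1, l2 = lambda2)
    } else {
      new_cols <- (n_elite + 1):pop_size
      fit_new <- cpp_ga_fitness(G, pool_M,
                                subsets[, new_cols, drop = FALSE],
                                index_vals = index_values,
                                l1 = lambda1, l2 = lambda2)
      fit <- lapply(stats::setNames(nm = names(fit_new)), function(f)
        c(elite_fit[[f]], fit_new[[f]]))
    }
    o <- order(-fit$fitness)
    if (is.null(best) || fit$fitness[o[1]] > best$fitness) {
      b <- o[1]
      best <- list(selected = sort(subsets[, b]), fitness = fit$fitness[b],
                   mean_index = fit$mean_index[b], mean_rel = fit$mean_rel[b],
                   naf = fit$naf[b])
    }
    if (trace) tr[it] <- best$fitness
    if (it == iterations) break
    elite <- subsets[, o[seq_len(n_elite)], drop = FALSE]
    elite_fit <- lapply(fit, function(v) v[o[seq_len(n_elite)]])
    EM <- matrix(FALSE, n, n_elite)
    EM[cbind(as.vector(elite), rep(seq_len(n_elite), each = n_parents))] <- TRUE
    pa <- sample.int(n_elite, n_off, replace = TRUE)
    pb <- sample.int(n_elite, n_off, replace = TRUE)
    cut <- sample.int(n - 1, n_off, replace = TRUE)
    mask <- outer(rows, cut, "<=")
    M_off <- (EM[, pa, drop = FALSE] & mask) | (EM[, pb, drop = FALSE] & !mask)
    M_off <- xor(M_off, matrix(stats::runif(n * n_off) < mutation, n, n_off))
    ks <- colSums(M_off)
    for (s in which(ks != n_parents)) {
      memb <- M_off[, s]
      if (ks[s] > n_parents) {                 # drop lowest-index members
        on <- which(memb)
        memb[on[order(-rank_desc[on])][seq_len(ks[s] - n_parents)]] <- FALSE
      } else {                                 # add highest-index outsiders
        off <- which(!memb)
        memb[off[order(rank_desc[off])][seq_len(n_parents - ks[s])]] <- TRUE
      }
      M_off[, s] <- memb
    }
    # column-wise extraction of member indices
    idx_list <- which(M_off, arr.ind = TRUE)
    subsets <- cbind(elite, matrix(idx_list[order(idx_list[, 2], idx_list[, 1]), 1],
                                   n_parents, n_off))
  }
  class(best) <- "parent_set"
  if (trace) best$trace <- tr
  best
}

#' @export
print.parent_set <- function(x, ...) {
  cat("<parent_set> ", length(x$selected), " parents; fitness ",
      signif(x$fitness, 4), " (mean index ", signif(x$mean_index, 4),
      ", mean rel ", signif(x$mean_rel, 4), ", NAF ", x$naf, ")\n", sep = "")
  invisible(x)
}
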
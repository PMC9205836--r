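# Small in-code fixtures shared across test files.

# A map with explicit, evenly spaced loci (endpoints included so every
# crossover falls between observable loci).
even_map <- function(n_chr = 2, loci_per_chr = 50, len = 100) {
  new_genetic_map(replicate(n_chr, seq(0, len, length.out = loci_per_chr),
                            simplify = FALSE),
                  rep(len, n_chr))
}

# Population from explicit haplotype matrices (0/1 integer, loci x n).
pop_from_haps <- function(h1, h2, map, ...) {
  new_population(matrix(as.raw(h1), nrow(h1)), matrix(as.raw(h2), nrow(h2)),
                 map, ...)
}

# Fully homozygous population from an allele matrix (0/1, loci x n).
pop_homozygous <- function(alleles, map, ...) {
  pop_from_haps(alleles, alleles, map, ...)
}

# A heterozygous-everywhere diploid (hap1 all 0, hap2 all 1).
pop_het_everywhere <- function(map, n = 1) {
  L <- map$n_loci
  pop_from_haps(matrix(0L, L, n), matrix(1L, L, n), map)
}

# Cached small founder set + architecture for prediction/trait tests.
small_founders <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      map <- build_map(3, c(430, 470), c(150, 250), seed = 11)
      cache <<- simulate_founders(map, 300, burn_in_generations = 30,
                                  seed = 12)
    }
    cache
  }
})

small_arch <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sample_architecture(small_founders(), n_qtl = 60,
                                    n_markers = 500, seed = 13)
    }
    cache
  }
})

# Micro-scale scenario overrides so whole-program tests stay fast.
micro_args <- function() {
  list(n_parents = 20, n_primary_crosses = 40, parent_usage_cap = 4,
       n_intercross_families = 25, seeds_per_family = 4,
       ps_f2_per_family = 3, pyt_size = 80, stage1_size = 40,
       stage2_size = 20, pool_add = 10, intercross_prefilter = 0.3,
       n_virtual = 10, n_f2_families = 10,
       ga = list(pop_size = 60, iterations = 30, mutation = 0.005,
                 elite_fraction = 0.2))
}
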
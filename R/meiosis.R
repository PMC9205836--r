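#' Simulate gametes
#'
#' Meiosis with Poisson recombination: per chromosome the crossover count is
#' drawn from Poisson(`xo_lambda`) (default 1, i.e. one expected crossover per
#' chromosome regardless of map length), crossover positions are uniform on
#' (0, chromosome length), and the gamete copies alternating parental
#' haplotype segments starting from a fair-coin choice of haplotype. There is
#' no crossover interference; chromosomes with zero crossovers transmit an
#' intact haplotype. After copying, each locus flips allele independently with
#' probability `mutation_rate`.
#'
#' @param pop a `breeding_pop`.
#' @param parents integer vector of parent indices; one gamete is produced per
#'   entry (repeat an index for several gametes from the same parent).
#' @param mutation_rate per-locus, per-gamete allele-flip probability
#'   (default 0.001).
#' @param xo_lambda expected crossovers per chromosome (default 1).
#' @return raw matrix, `n_loci x length(parents)`, one gamete per column.
#' @export
make_gametes <- function(pop, parents, mutation_rate = 0.001, xo_lambda = 1) {
  m <- pop$map
  cpp_gametes(pop$H1, pop$H2, as.integer(parents),
              as.integer(m$starts), m$pos, m$chr_len, xo_lambda, mutation_rate)
}

#' @rdname make_gametes
#' @param parent a single parent index.
#' @return `make_gamete`: a raw vector of length `n_loci`.
#' @export
make_gamete <- function(pop, parent = 1L, mutation_rate = 0.001, xo_lambda = 1) {
  make_gametes(pop, parent, mutation_rate, xo_lambda)[, 1]
}

#' Cross individuals
#'
#' Each progeny receives one independent gamete from its mother and one from
#' its father. `mothers`/`fathers` are recycled against each other; with
#' `n_progeny > 1` every (mother, father) pair is repeated that many times.
#'
#' @param pop a `breeding_pop` holding the parents.
#' @param mothers,fathers parent indices (equal length after recycling).
#' @param n_progeny progeny per pair.
#' @param mutation_rate,xo_lambda see [make_gametes()].
#' @param stage,cycle metadata tags for the progeny.
#' @return a `breeding_pop` of progeny; `family` records the parent pair.
#' @export
cross <- function(pop, mothers, fathers, n_progeny = 1, mutation_rate = 0.001,
                  xo_lambda = 1, stage = "F1", cycle = NA) {
  k <- max(length(mothers), length(fathers))
  mothers <- rep_len(as.integer(mothers), k)
  fathers <- rep_len(as.integer(fathers), k)
  mo <- rep(mothers, each = n_progeny)
  fa <- rep(fathers, each = n_progeny)
  H1 <- make_gametes(pop, mo, mutation_rate, xo_lambda)
  H2 <- make_gametes(pop, fa, mutation_rate, xo_lambda)
  fam <- paste(pop$meta$id[mo], pop$meta$id[fa], sep = "x")
  new_population(H1, H2, pop$map,
                 id = paste0(fam, "_", seq_along(mo)),
                 stage = stage, cycle = if (is.na(cycle)) 0L else cycle,
                 family = fam)
}

#' Self individuals
#'
#' Selfing is a cross of an individual with itself.
#'
#' @param pop a `breeding_pop`.
#' @param inds indices of the individuals to self (default: all).
#' @param n_seeds seeds per individual.
#' @inheritParams cross
#' @return a `breeding_pop` of selfed progeny.
#' @export
self_line <- function(pop, inds = seq_len(pop_size(pop)), n_seeds = 1,
                      mutation_rate = 0.001, xo_lambda = 1, stage = "F2",
                      cycle = NA) {
  cross(pop, inds, inds, n_progeny = n_seeds, mutation_rate = mutation_rate,
        xo_lambda = xo_lambda, stage = stage, cycle = cycle)
}

#' Single seed descent
#'
#' Advances every individual by `n_generations` chained single-seed selfings:
#' one random seed is carried forward per line per generation, so output line
#' `i` descends from input line `i`. Expected per-locus heterozygosity halves
#' each generation (mutation aside).
#'
#' @param pop a `breeding_pop`.
#' @param n_generations number of selfing generations (>= 1).
#' @inheritParams cross
#' @param stage stage tag of the final generation (default advances the
#'   numeric part of an `F<g>` tag when recognisable, else `"SSD"`).
#' @return a `breeding_pop`, same size and order as the input.
#' @export
ssd_advance <- function(pop, n_generations, mutation_rate = 0.001,
                        xo_lambda = 1, stage = NULL) {
  stopifnot(n_generations >= 1)
  out <- pop
  n <- pop_size(pop)
  for (g in seq_len(n_generations)) {
    H1 <- make_gametes(out, seq_len(n), mutation_rate, xo_lambda)
    H2 <- make_gametes(out, seq_len(n), mutation_rate, xo_lambda)
    out$H1 <- H1
    out$H2 <- H2
  }
  if (is.null(stage)) {
    g0 <- suppressWarnings(as.integer(sub("^F", "", pop$meta$stage[1])))
    stage <- if (!is.na(g0)) paste0("F", g0 + n_generations) else "SSD"
  }
  out$meta$stage <- rep_len(stage, n)
  out
}
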
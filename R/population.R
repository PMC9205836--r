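#' Population container
#'
#' A population stores diploid genotypes as two haplotype matrices (`H1`,
#' `H2`, raw 0/1, loci in rows and individuals in columns), the genetic map
#' they are aligned to, and per-individual metadata (`id`, `stage` -- a
#' filial/trial-stage tag such as `"F2"` or `"STG2"` --, breeding `cycle` and
#' `family`, the identifier of the originating cross).
#'
#' @param H1,H2 raw matrices, `n_loci x n` haplotypes.
#' @param map the `genetic_map` the haplotypes are aligned to.
#' @param id character or integer identifiers (unique within the population).
#' @param stage stage tag, recycled to length `n`.
#' @param cycle breeding-cycle index, recycled.
#' @param family originating-cross identifier, recycled.
#' @return An object of class `breeding_pop`.
#' @export
new_population <- function(H1, H2, map, id = NULL, stage = "founder",
                           cycle = 0L, family = NA_character_) {
  stopifnot(inherits(map, "genetic_map"), is.raw(H1), is.raw(H2))
  if (!identical(dim(H1), dim(H2))) stop("haplotype matrices must match")
  if (nrow(H1) != map$n_loci) stop("haplotype length does not match map")
  n <- ncol(H1)
  if (is.null(id)) id <- paste0("ind_", seq_len(n))
  structure(list(
    H1 = H1, H2 = H2, map = map,
    meta = data.frame(id = as.character(id),
                      stage = rep_len(as.character(stage), n),
                      cycle = rep_len(as.integer(cycle), n),
                      family = rep_len(as.character(family), n),
                      stringsAsFactors = FALSE)
  ), class = "breeding_pop")
}

#' Number of individuals in a population
#' @param pop a `breeding_pop`.
#' @export
pop_size <- function(pop) ncol(pop$H1)

#' Subset a population by individual
#' @param pop a `breeding_pop`.
#' @param idx integer indices (columns) to keep, in order.
#' @export
pop_subset <- function(pop, idx) {
  idx <- as.integer(idx)
  new_population(pop$H1[, idx, drop = FALSE], pop$H2[, idx, drop = FALSE],
                 pop$map, id = pop$meta$id[idx], stage = pop$meta$stage[idx],
                 cycle = pop$meta$cycle[idx], family = pop$meta$family[idx])
}

#' Concatenate populations on the same map
#' @param ... `breeding_pop` objects sharing one map.
#' @export
pop_bind <- function(...) {
  pops <- list(...)
  if (length(pops) == 1 && is.list(pops[[1]]) && !inherits(pops[[1]], "breeding_pop"))
    pops <- pops[[1]]
  map <- pops[[1]]$map
  for (p in pops) if (p$map$n_loci != map$n_loci) stop("populations on different maps")
  meta <- do.call(rbind, lapply(pops, function(p) p$meta))
  new_population(do.call(cbind, lapply(pops, function(p) p$H1)),
                 do.call(cbind, lapply(pops, function(p) p$H2)),
                 map, id = meta$id, stage = meta$stage, cycle = meta$cycle,
                 family = meta$family)
}

#' Allele dose matrix
#'
#' Counts of the "1" allele (0, 1 or 2) for the requested individuals at the
#' requested loci; individuals in rows, so `dose(pop, loci) %*% beta` is a
#' vector of genomic values.
#'
#' @param pop a `breeding_pop`.
#' @param loci 1-based global locus indices (default: all loci).
#' @param inds individual indices (default: all).
#' @return numeric matrix, `length(inds) x length(loci)`.
#' @export
dose <- function(pop, loci = seq_len(pop$map$n_loci), inds = seq_len(pop_size(pop))) {
  cpp_dose(pop$H1, pop$H2, as.integer(loci), as.integer(inds))
}

#' Per-locus heterozygosity of a population
#' @param pop a `breeding_pop`.
#' @return numeric vector, fraction of heterozygous individuals per locus.
#' @export
heterozygosity <- function(pop) {
  rowMeans(pop$H1 != pop$H2)
}

#' Allele frequencies of the "1" allele
#' @param pop a `breeding_pop`.
#' @param loci locus indices (default all).
#' @export
allele_freq <- function(pop, loci = seq_len(pop$map$n_loci)) {
  (rowMeans(pop$H1[loci, , drop = FALSE] == as.raw(1)) +
   rowMeans(pop$H2[loci, , drop = FALSE] == as.raw(1))) / 2
}

#' @export
print.breeding_pop <- function(x, ...) {
  cat("<breeding_pop> ", pop_size(x), " individuals x ", x$map$n_loci,
      " loci (", x$map$n_chr, " chromosomes)\n", sep = "")
  st <- table(x$meta$stage)
  cat("  stages: ", paste(names(st), st, sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}
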
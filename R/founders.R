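#' Simulate a fully inbred founder population
#'
#' Synthetic stand-in for a base set of inbred lines. Ancestral allele
#' frequencies are drawn per locus from a symmetric Beta(`ancestral_maf_shape`,
#' `ancestral_maf_shape`) (small shape values give the U-shaped frequency
#' spectrum typical of diversity panels); a random-mating population of
#' `2 * n_lines` individuals is gene-dropped through `burn_in_generations`
#' meioses (mutation off) to build within-chromosome linkage disequilibrium;
#' each line is then finished by doubling one sampled gamete, giving instant
#' and complete homozygosity. Loci whose realized minor allele frequency falls
#' below `min_maf` in the finished lines are dropped, and the returned
#' population carries the pruned map.
#'
#' @param map a `genetic_map` (typically from [build_map()]).
#' @param n_lines number of inbred lines (>= 2).
#' @param burn_in_generations random-mating generations before line doubling.
#' @param ancestral_maf_shape shape of the symmetric Beta ancestral frequency
#'   distribution.
#' @param min_maf minor-allele-frequency filter applied to the finished lines.
#' @param seed integer seed; identical seeds give bit-identical populations.
#' @param xo_lambda expected crossovers per chromosome during the burn-in.
#' @return A `breeding_pop` of `n_lines` fully homozygous lines, with
#'   attributes `retained_loci` (1-based indices into the input map of the
#'   loci that survived the MAF filter) and `ancestral_freq` (their ancestral
#'   allele frequencies).
#' @export
simulate_founders <- function(map, n_lines, burn_in_generations = 50,
                              ancestral_maf_shape = 0.2, min_maf = 0.01,
                              seed = 1, xo_lambda = 1) {
  stopifnot(inherits(map, "genetic_map"), n_lines >= 2)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  L <- map$n_loci
  n2 <- 2L * as.integer(n_lines)
  p <- stats::rbeta(L, ancestral_maf_shape, ancestral_maf_shape)
  draw_hap <- function() {
    matrix(as.raw(stats::runif(L * n2) < p), nrow = L, ncol = n2)
  }
  anc <- new_population(draw_hap(), draw_hap(), map, stage = "ancestral")
  for (g in seq_len(burn_in_generations)) {
    mo <- sample.int(n2, n2, replace = TRUE)
    fa <- sample.int(n2, n2, replace = TRUE)
    anc$H1 <- make_gametes(anc, mo, mutation_rate = 0, xo_lambda = xo_lambda)
    anc$H2 <- make_gametes(anc, fa, mutation_rate = 0, xo_lambda = xo_lambda)
  }
  picked <- sample.int(n2, n_lines)
  G <- make_gametes(anc, picked, mutation_rate = 0, xo_lambda = xo_lambda)
  f <- rowMeans(G == as.raw(1))
  keep <- which(pmin(f, 1 - f) >= min_maf)
  if (length(keep) == 0)
    stop("degenerate population: all loci monomorphic or below the MAF filter after burn-in")
  pop <- new_population(G[keep, , drop = FALSE], G[keep, , drop = FALSE],
                        map_subset(map, keep),
                        id = sprintf("base_%04d", seq_len(n_lines)),
                        stage = "founder")
  attr(pop, "retained_loci") <- keep
  attr(pop, "ancestral_freq") <- p[keep]
  pop
}

#' Load founder genotypes from a file
#'
#' Reads fully inbred founder lines from either a delimited genotype matrix
#' (lines x loci, allele doses 0/1/2, `NA` for missing, header row of locus
#' ids `"chrom:index"`, first column line ids; the dialect written by
#' [write_genotype_matrix()]) or a VCF of biallelic SNPs (GT field). The
#' standard panel filters are applied: loci with call rate below
#' `min_call_rate` or minor allele frequency below `min_maf` are dropped, and
#' if more loci remain than `n_markers` a random (seeded) subsample of exactly
#' `n_markers` is kept. Heterozygous founder calls are either rejected
#' (`het = "error"`) or set missing (`het = "missing"`, the default); missing
#' calls are then filled with the locus major allele so the returned lines are
#' fully homozygous. Because the input carries no genetic-map coordinates,
#' loci are placed evenly along chromosomes of length `chr_len` (recycled).
#'
#' @param path file to read.
#' @param format `"matrix"` or `"vcf"`.
#' @param min_call_rate minimum fraction of non-missing calls per locus.
#' @param min_maf minimum minor allele frequency.
#' @param n_markers subsample retained loci down to this count (`Inf` keeps all).
#' @param het `"missing"` or `"error"`: handling of heterozygous calls.
#' @param chr_len chromosome length(s) in cM for the constructed map.
#' @param seed seed for the marker subsample.
#' @return A `breeding_pop` of homozygous lines with attribute
#'   `retained_loci` (locus ids kept, in map order).
#' @export
load_genotypes <- function(path, format = c("matrix", "vcf"),
                           min_call_rate = 0.5, min_maf = 0.01,
                           n_markers = 30000, het = c("missing", "error"),
                           chr_len = c(313.0, 341.2, 429.7, 192.7, 319.1, 346.0, 288.4),
                           seed = 1) {
  format <- match.arg(format)
  het <- match.arg(het)
  if (format == "matrix") {
    tab <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                                      check.names = FALSE, row.names = 1),
                    error = function(e) stop("unparsable genotype matrix: ",
                                             conditionMessage(e)))
    geno <- as.matrix(tab)
    loc_chr <- as.integer(sub(":.*$", "", colnames(geno)))
    ids <- rownames(geno)
  } else {
    v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("unparsable VCF: ", conditionMessage(e)))
    gt <- vcfR::extract.gt(v, element = "GT")
    conv <- function(x) {
      x <- sub("\\|", "/", x)
      out <- rep(NA_real_, length(x))
      out[x %in% c("0/0")] <- 0
      out[x %in% c("0/1", "1/0")] <- 1
      out[x %in% c("1/1")] <- 2
      out
    }
    geno <- t(apply(gt, 1, conv))          # loci x lines
    colnames(geno) <- colnames(gt)
    geno <- t(geno)                        # lines x loci
    loc_chr <- as.integer(factor(vcfR::getCHROM(v)))
    alt <- vcfR::getALT(v)
    if (any(grepl(",", alt))) stop("multi-allelic sites are not supported")
    ids <- rownames(geno)
  }
  if (nrow(geno) < 2) stop("invalid input: fewer than 2 lines")
  if (any(geno == 1, na.rm = TRUE)) {
    if (het == "error") stop("heterozygous founder calls present")
    geno[geno == 1] <- NA
  }
  call_rate <- colMeans(!is.na(geno))
  f <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- which(call_rate >= min_call_rate & !is.na(maf) & maf >= min_maf)
  if (length(keep) == 0) stop("no loci pass the filters")
  if (length(keep) > n_markers) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    keep <- sort(sample(keep, n_markers))
  }
  geno <- geno[, keep, drop = FALSE]
  loc_chr <- loc_chr[keep]
  # fill missing with the major allele
  for (j in seq_len(ncol(geno))) {
    miss <- is.na(geno[, j])
    if (any(miss)) geno[miss, j] <- if (mean(geno[!miss, j]) >= 1) 2 else 0
  }
  ord <- order(loc_chr)
  geno <- geno[, ord, drop = FALSE]
  loc_chr <- loc_chr[ord]
  chrs <- sort(unique(loc_chr))
  chr_len <- rep_len(chr_len, length(chrs))
  pos <- lapply(seq_along(chrs), function(i) {
    k <- sum(loc_chr == chrs[i])
    seq(0, chr_len[i], length.out = k + 2)[2:(k + 1)]
  })
  map <- new_genetic_map(pos, chr_len)
  H <- matrix(as.raw(t(geno) / 2), nrow = ncol(geno))
  pop <- new_population(H, H, map, id = ids, stage = "founder")
  attr(pop, "retained_loci") <- colnames(geno)
  pop
}

#' Write / read the delimited genotype-matrix dialect
#'
#' Lines x loci allele doses (0/1/2), tab-separated, header row of locus ids
#' `"chrom:index"` (0-based within-chromosome index), first column line ids.
#'
#' @param pop a `breeding_pop`.
#' @param path output file.
#' @export
write_genotype_matrix <- function(pop, path) {
  m <- pop$map
  within <- unlist(lapply(diff(m$starts), function(k) seq_len(k) - 1L))
  ids <- paste0(m$chrom, ":", within)
  d <- dose(pop)
  dimnames(d) <- list(pop$meta$id, ids)
  utils::write.table(d, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Save / load a founder population container
#'
#' Single-file binary container (versioned) for replicate reuse.
#'
#' @param pop a `breeding_pop`.
#' @param path file path.
#' @export
write_founders <- function(pop, path) {
  saveRDS(list(container = "pulsegs_founders", version = 1L, pop = pop), path)
  invisible(path)
}

#' @rdname write_founders
#' @export
read_founders <- function(path) {
  x <- readRDS(path)
  if (!identical(x$container, "pulsegs_founders"))
    stop("not a pulsegs founder container")
  x$pop
}
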
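#' Build a genetic map
#'
#' Constructs the shared genome coordinate frame used by meiosis, the QTL
#' architecture and the marker panel: `n_chromosomes` chromosomes, each with a
#' locus count drawn uniformly from `snp_range` and a length drawn uniformly
#' from `length_range` (centimorgans). Locus positions are drawn uniformly on
#' the chromosome and sorted. Defaults emulate a lentil genome: 7 chromosomes
#' with 3200--5200 loci each and map lengths between 192.7 and 429.7 cM.
#'
#' Loci are addressed by their 0-based within-chromosome index or, more
#' commonly, by their 1-based global index into the flattened locus order
#' (chromosome 1 first). The map is purely genetic; no physical coordinates.
#'
#' @param n_chromosomes number of chromosomes.
#' @param snp_range length-2 vector, inclusive range for per-chromosome locus
#'   counts.
#' @param length_range length-2 vector, range for chromosome lengths in cM.
#' @param seed integer seed; the same seed reproduces the map exactly.
#' @return An object of class `genetic_map`: a list with `n_chr`, `chr_len`
#'   (cM per chromosome), `pos` (flat vector of locus positions), `chrom`
#'   (chromosome of each locus), `starts` (0-based chromosome offsets, length
#'   `n_chr + 1`) and `n_loci`.
#' @examples
#' map <- build_map(2, c(50, 60), c(100, 150), seed = 1)
#' map$n_loci
#' @export
build_map <- function(n_chromosomes = 7, snp_range = c(3200, 5200),
                      length_range = c(192.7, 429.7), seed = 1) {
  stopifnot(length(snp_range) == 2, length(length_range) == 2)
  if (n_chromosomes < 1 || any(snp_range <= 0) || any(length_range <= 0))
    stop("chromosome count, locus counts and lengths must be positive")
  if (snp_range[1] > snp_range[2] || length_range[1] > length_range[2])
    stop("ranges must be ordered (low, high)")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  counts <- if (snp_range[1] == snp_range[2]) rep(snp_range[1], n_chromosomes)
            else sample(seq(snp_range[1], snp_range[2]), n_chromosomes, replace = TRUE)
  lens <- stats::runif(n_chromosomes, length_range[1], length_range[2])
  pos <- lapply(seq_len(n_chromosomes), function(c) sort(stats::runif(counts[c], 0, lens[c])))
  new_genetic_map(pos, lens)
}

#' Assemble a genetic map from explicit positions
#'
#' @param pos list of numeric vectors, locus positions (cM) per chromosome;
#'   must be strictly increasing within a chromosome.
#' @param chr_len numeric vector of chromosome lengths (cM).
#' @return A `genetic_map` (see [build_map()]).
#' @export
new_genetic_map <- function(pos, chr_len) {
  stopifnot(length(pos) == length(chr_len))
  for (c in seq_along(pos)) {
    p <- pos[[c]]
    if (length(p) == 0) stop("chromosome ", c, " has no loci")
    if (any(diff(p) <= 0)) stop("locus positions must be strictly increasing")
    if (p[1] < 0 || p[length(p)] > chr_len[c])
      stop("locus positions must lie in [0, chr_len]")
  }
  counts <- vapply(pos, length, integer(1))
  structure(list(
    n_chr = length(chr_len),
    chr_len = as.numeric(chr_len),
    pos = unlist(pos, use.names = FALSE),
    chrom = rep(seq_along(chr_len), counts),
    starts = c(0L, cumsum(counts)),
    n_loci = sum(counts)
  ), class = "genetic_map")
}

#' Restrict a map to a subset of loci
#'
#' Used to drop filtered loci and to run in-silico projections on the marker
#' panel only (the recombination process at a subset of loci is the exact
#' marginal of the full-map process).
#'
#' @param map a `genetic_map`.
#' @param loci increasing vector of 1-based global locus indices to keep.
#' @return A `genetic_map` over the kept loci (chromosome lengths unchanged).
#' @export
map_subset <- function(map, loci) {
  stopifnot(inherits(map, "genetic_map"))
  loci <- as.integer(loci)
  if (any(diff(loci) <= 0)) stop("loci must be strictly increasing")
  if (loci[1] < 1 || loci[length(loci)] > map$n_loci) stop("locus index out of range")
  chrom <- map$chrom[loci]
  pos <- split(map$pos[loci], factor(chrom, levels = seq_len(map$n_chr)))
  keep_chr <- lengths(pos) > 0
  m <- new_genetic_map(pos[keep_chr], map$chr_len[keep_chr])
  m
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map> ", x$n_chr, " chromosomes, ", x$n_loci, " loci, ",
      round(sum(x$chr_len), 1), " cM total\n", sep = "")
  invisible(x)
}

# Save/restore .Random.seed so seeded constructors do not disturb the
# caller's RNG stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
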
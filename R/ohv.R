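#' Segment scheme for optimal haploid values
#'
#' Partitions the marker panel of each chromosome into `n_segments`
#' contiguous segments with marker counts differing by at most one (equal
#' marker counts, not equal cM).
#'
#' @param map a `genetic_map`.
#' @param marker_loci global locus indices of the marker panel.
#' @param n_segments segments per chromosome (default 5).
#' @return An object of class `segment_scheme`: `segment` (segment id per
#'   marker, 1-based, global across chromosomes) and `n_segments` (total).
#' @export
segment_scheme <- function(map, marker_loci, n_segments = 5) {
  chrom <- map$chrom[marker_loci]
  seg <- integer(length(marker_loci))
  off <- 0L
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    k <- min(n_segments, length(idx))
    seg[idx] <- off + as.integer(cut(seq_along(idx), k, labels = FALSE))
    off <- off + k
  }
  structure(list(segment = seg, n_segments = off), class = "segment_scheme")
}

#' Haplotype value of a segment
#'
#' Sum over the segment's marker loci of the haplotype's allele dose times
#' the marker substitution effect.
#'
#' @param hap numeric/integer/raw vector of haplotype alleles over the marker
#'   panel.
#' @param beta marker effects aligned to the panel.
#' @param segment_loci indices (into the panel) of the segment's markers.
#' @return a single haplotype value.
#' @export
haplotype_value <- function(hap, beta, segment_loci = seq_along(beta)) {
  sum(as.numeric(hap[segment_loci]) * beta[segment_loci])
}

# Per-segment haplotype values of every haplotype column: n_segments x n.
.segment_hv <- function(Hm, beta, scheme) {
  rowsum(matrix(as.integer(Hm), nrow(Hm)) * beta, scheme$segment)
}

#' Optimal haploid value
#'
#' For each individual, the sum over segments of the better of its two
#' haplotype values: the genomic value of the best inbred line extractable
#' from the individual by recombining whole segments. With `doubling = TRUE`
#' the sum is multiplied by 2 (diploid-equivalent scale, so that a fully
#' inbred individual's OHV equals its GEBV); default off.
#'
#' @param pop a `breeding_pop`.
#' @param effects a `marker_effects` (or a matrix of per-trait effect
#'   vectors).
#' @param scheme a `segment_scheme` over the marker panel.
#' @param marker_loci global locus indices of the marker panel.
#' @param inds individual indices.
#' @param doubling report on the diploid scale.
#' @return numeric matrix, individuals x traits.
#' @export
ohv <- function(pop, effects, scheme, marker_loci, inds = seq_len(pop_size(pop)),
                doubling = FALSE) {
  B <- if (inherits(effects, "marker_effects")) effects$beta else as.matrix(effects)
  H1 <- pop$H1[marker_loci, inds, drop = FALSE]
  H2 <- pop$H2[marker_loci, inds, drop = FALSE]
  out <- matrix(NA_real_, length(inds), ncol(B),
                dimnames = list(NULL, colnames(B)))
  for (t in seq_len(ncol(B))) {
    A1 <- .segment_hv(H1, B[, t], scheme)
    A2 <- .segment_hv(H2, B[, t], scheme)
    out[, t] <- colSums(pmax(A1, A2)) * (if (doubling) 2 else 1)
  }
  out
}

#' Selection index over per-trait OHVs
#'
#' Weighted sum of cohort-standardized per-trait values; identical to
#' [selection_index()] and provided under the OHV name for symmetry.
#'
#' @param values numeric matrix, candidates x traits.
#' @param weights per-trait index weights (default 0.3, 0.3, 0.4).
#' @param sds optional externally supplied cohort SDs.
#' @return numeric vector of index scores.
#' @export
ohv_index <- function(values, weights = c(0.3, 0.3, 0.4), sds = NULL) {
  selection_index(values, weights, sds)
}

# Pair scores for all candidate crosses: per trait, the OHV of the virtual
# cross, i.e. the per-segment maximum over the union of the two parents'
# haplotypes (for inbred parents this is the deterministic F1's OHV).
.cross_ohv_pairs <- function(pop, B, scheme, marker_loci, parents) {
  n <- length(parents)
  H1 <- pop$H1[marker_loci, parents, drop = FALSE]
  H2 <- pop$H2[marker_loci, parents, drop = FALSE]
  out <- array(0, c(n, n, ncol(B)))
  for (t in seq_len(ncol(B))) {
    m <- pmax(.segment_hv(H1, B[, t], scheme), .segment_hv(H2, B[, t], scheme))
    acc <- matrix(0, n, n)
    for (s in seq_len(nrow(m)))
      acc <- acc + pmax(matrix(m[s, ], n, n), matrix(m[s, ], n, n, byrow = TRUE))
    out[, , t] <- acc
  }
  out
}

#' Select primary crosses by optimal haploid value
#'
#' Enumerates all unordered parent pairs, scores each candidate cross by the
#' OHV selection index of the virtual F1 (per-segment maximum over the union
#' of the two parents' haplotypes; for fully inbred parents the F1 is
#' deterministic), and greedily accepts crosses in descending index order,
#' skipping pairs that would push either parent past `usage_cap`, until
#' `n_crosses` are accepted. Ties break by ascending parent indices.
#'
#' @param pop a `breeding_pop` holding the candidate parents.
#' @param parents indices of the parents (e.g. the 150 selected lines).
#' @param effects a `marker_effects`.
#' @param scheme a `segment_scheme`.
#' @param marker_loci marker-panel locus indices.
#' @param n_crosses number of crosses to select (default 300).
#' @param usage_cap maximum times any parent may be used (default 4;
#'   `Inf` disables the cap).
#' @param weights index weights.
#' @return data.frame with columns `mother`, `father` (indices into `pop`),
#'   `score` (index of the virtual cross), ordered as accepted.
#' @export
select_primary_crosses <- function(pop, parents, effects, scheme, marker_loci,
                                   n_crosses = 300, usage_cap = 4,
                                   weights = c(0.3, 0.3, 0.4)) {
  n <- length(parents)
  if (is.finite(usage_cap) && n_crosses > n * usage_cap / 2)
    stop("invalid config: cap of ", usage_cap, " on ", n,
         " parents cannot yield ", n_crosses, " crosses")
  B <- if (inherits(effects, "marker_effects")) effects$beta else as.matrix(effects)
  sc <- .cross_ohv_pairs(pop, B, scheme, marker_loci, parents)
  ut <- which(upper.tri(sc[, , 1]), arr.ind = TRUE)
  vals <- vapply(seq_len(dim(sc)[3]), function(t) sc[, , t][upper.tri(sc[, , t])],
                 numeric(nrow(ut)))
  idx <- selection_index(vals, weights)
  ord <- order(-idx, ut[, 1], ut[, 2])
  used <- integer(n)
  sel_i <- sel_j <- integer(0)
  sel_s <- numeric(0)
  for (k in ord) {
    i <- ut[k, 1]; j <- ut[k, 2]
    if (used[i] < usage_cap && used[j] < usage_cap) {
      sel_i <- c(sel_i, i); sel_j <- c(sel_j, j); sel_s <- c(sel_s, idx[k])
      used[i] <- used[i] + 1L
      used[j] <- used[j] + 1L
      if (length(sel_i) == n_crosses) break
    }
  }
  # With an exactly-tight cap the single greedy pass can strand the last
  # usage slots on one parent; repair by re-pairing with an accepted cross
  # (duplicate crosses are allowed during repair).
  S <- matrix(-Inf, n, n)
  S[ut] <- idx
  S[ut[, 2:1]] <- idx
  while (length(sel_i) < n_crosses) {
    capi <- which(used < usage_cap)
    if (length(capi) >= 2) {
      sub <- S[capi, capi, drop = FALSE]
      best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      i <- capi[best[1]]; j <- capi[best[2]]
      sel_i <- c(sel_i, min(i, j)); sel_j <- c(sel_j, max(i, j))
      sel_s <- c(sel_s, S[i, j])
      used[i] <- used[i] + 1L; used[j] <- used[j] + 1L
    } else if (length(capi) == 1 && usage_cap - used[capi] >= 2) {
      p <- capi
      cand <- which(sel_i != p & sel_j != p)
      if (length(cand) == 0)
        stop("invalid config: cannot complete ", n_crosses, " crosses under the cap")
      drop_k <- cand[which.min(sel_s[cand])]
      i <- sel_i[drop_k]; j <- sel_j[drop_k]
      sel_i <- sel_i[-drop_k]; sel_j <- sel_j[-drop_k]; sel_s <- sel_s[-drop_k]
      sel_i <- c(sel_i, min(p, i), min(p, j))
      sel_j <- c(sel_j, max(p, i), max(p, j))
      sel_s <- c(sel_s, S[p, i], S[p, j])
      used[p] <- used[p] + 2L
    } else {
      stop("invalid config: only ", length(sel_i),
           " feasible crosses under the cap")
    }
  }
  data.frame(mother = parents[sel_i], father = parents[sel_j], score = sel_s)
}

#' Project a cross to near-inbred progeny in silico
#'
#' For each candidate pair, simulates `n_virtual` independent single-seed-
#' descent descendants: one gamete from each parent forms the cross progeny,
#' which is then selfed `target_gen - 1` times (default F8, i.e. 7 selfing
#' meioses), mutation off, on the marker panel only (the marginal
#' recombination process at a locus subset is exact). Each virtual line is
#' scored per trait by its GEBV; the index standardizes per-trait scores by
#' their SD over the pooled virtual progeny of all pairs.
#'
#' @param pop a `breeding_pop` holding the candidate parents (typically F1s).
#' @param pairs 2-column matrix of parent indices (one row per cross).
#' @param effects a `marker_effects`.
#' @param marker_loci marker-panel locus indices.
#' @param n_virtual virtual descendants per cross (default 20).
#' @param target_gen filial generation of the virtual lines (default 8).
#' @param weights index weights.
#' @param xo_lambda expected crossovers per chromosome.
#' @return data.frame with one row per pair: `a`, `b` (parent indices),
#'   per-trait score means (`mean_<trait>`), and `mean`/`sd` of the virtual
#'   progeny index.
#' @export
project_inbred_progeny <- function(pop, pairs, effects, marker_loci,
                                   n_virtual = 20, target_gen = 8,
                                   weights = c(0.3, 0.3, 0.4), xo_lambda = 1) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  B <- if (inherits(effects, "marker_effects")) effects$beta else as.matrix(effects)
  mmap <- map_subset(pop$map, marker_loci)
  sc <- cpp_project_pairs(pop$H1[marker_loci, , drop = FALSE],
                          pop$H2[marker_loci, , drop = FALSE],
                          pairs, as.integer(n_virtual),
                          as.integer(target_gen - 1),
                          as.integer(mmap$starts), mmap$pos, mmap$chr_len,
                          xo_lambda, B)
  idx <- selection_index(sc, weights, center = FALSE)
  grp <- rep(seq_len(nrow(pairs)), each = n_virtual)
  out <- data.frame(a = pairs[, 1], b = pairs[, 2])
  for (t in seq_len(ncol(B)))
    out[[paste0("mean_", colnames(B)[t])]] <- rowsum(sc[, t], grp)[, 1] / n_virtual
  out$mean <- rowsum(idx, grp)[, 1] / n_virtual
  sq <- rowsum(idx^2, grp)[, 1] / n_virtual
  out$sd <- sqrt(pmax(0, (sq - out$mean^2) * n_virtual / max(1, n_virtual - 1)))
  out
}

#' Select F1 intercrosses
#'
#' Enumerates all unordered pairs of F1s, optionally pre-filters candidates
#' by mid-parent GEBV index (keeping the top `prefilter` fraction), and ranks
#' the surviving pairs either by the in-silico projection criterion
#' `mean_plus_sd` (mean + 1 SD of the virtual near-inbred progeny's GEBV
#' index; the default) or by `mean_ohv` (the OHV index of the virtual cross,
#' no projection). Returns the top `n_select` pairs.
#'
#' @param pop a `breeding_pop` of F1 individuals.
#' @param effects a `marker_effects`.
#' @param scheme a `segment_scheme` (used by `mean_ohv`).
#' @param marker_loci marker-panel locus indices.
#' @param n_select number of intercross families (default 200).
#' @param criterion `"mean_plus_sd"` or `"mean_ohv"`.
#' @param prefilter fraction of pairs kept by mid-parent GEBV index before
#'   projection (default 1 = no pre-filter).
#' @param n_virtual,target_gen,weights,xo_lambda see
#'   [project_inbred_progeny()].
#' @param f1_inds indices of the F1s in `pop` (default all).
#' @return data.frame of selected pairs with their criterion `score`
#'   (descending), columns `a`, `b` indexing into `pop`.
#' @export
select_intercrosses <- function(pop, effects, scheme, marker_loci,
                                n_select = 200,
                                criterion = c("mean_plus_sd", "mean_ohv"),
                                prefilter = 1, n_virtual = 20, target_gen = 8,
                                weights = c(0.3, 0.3, 0.4), xo_lambda = 1,
                                f1_inds = seq_len(pop_size(pop))) {
  criterion <- match.arg(criterion)
  n <- length(f1_inds)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  if (nrow(ut) < n_select) stop("fewer candidate pairs than n_select")
  if (criterion == "mean_ohv") {
    sc <- .cross_ohv_pairs(pop, if (inherits(effects, "marker_effects"))
      effects$beta else as.matrix(effects), scheme, marker_loci, f1_inds)
    vals <- vapply(seq_len(dim(sc)[3]), function(t) sc[, , t][upper.tri(sc[, , t])],
                   numeric(nrow(ut)))
    score <- selection_index(vals, weights)
    ord <- order(-score, ut[, 1], ut[, 2])[seq_len(n_select)]
    return(data.frame(a = f1_inds[ut[ord, 1]], b = f1_inds[ut[ord, 2]],
                      score = score[ord]))
  }
  keep <- seq_len(nrow(ut))
  if (prefilter < 1) {
    gv <- gebv(effects, pop, marker_loci, f1_inds)
    midx <- selection_index(gv, weights)
    mp <- (midx[ut[, 1]] + midx[ut[, 2]]) / 2
    keep <- order(-mp)[seq_len(max(n_select, ceiling(prefilter * nrow(ut))))]
  }
  pairs <- cbind(f1_inds[ut[keep, 1]], f1_inds[ut[keep, 2]])
  pr <- project_inbred_progeny(pop, pairs, effects, marker_loci,
                               n_virtual = n_virtual, target_gen = target_gen,
                               weights = weights, xo_lambda = xo_lambda)
  score <- pr$mean + pr$sd
  ord <- order(-score, pr$a, pr$b)[seq_len(n_select)]
  data.frame(a = pr$a[ord], b = pr$b[ord], score = score[ord],
             mean = pr$mean[ord], sd = pr$sd[ord])
}
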
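#' Construct a training set
#'
#' A training set pairs marker genotypes with entry-mean phenotypes. F2
#' family records carry fractional genotype values in `[0, 2]` (family mean
#' doses); stage-trial records are ordinary 0/1/2 doses.
#'
#' @param X numeric matrix, records x marker panel (allele doses).
#' @param y numeric matrix, records x traits (entry-mean phenotypes).
#' @param cycle integer vector, breeding cycle of origin per record.
#' @param source character vector, `"stage_trial"` or `"f2_family"`.
#' @param ids record identifiers (the phenotyped lines/families).
#' @return An object of class `training_set`.
#' @export
new_training_set <- function(X, y, cycle, source = "stage_trial", ids = rownames(X)) {
  stopifnot(nrow(X) == nrow(y))
  if (is.null(ids)) ids <- paste0("rec_", seq_len(nrow(X)))
  structure(list(X = X, y = as.matrix(y), cycle = as.integer(rep_len(cycle, nrow(X))),
                 source = rep_len(source, nrow(X)), ids = as.character(ids)),
            class = "training_set")
}

#' Estimate marker substitution effects (ridge regression / SNP-BLUP)
#'
#' Fits, per trait, the linear model `y = 1 mu + X beta + e` with a common
#' normal shrinkage prior on all marker effects: the posterior mean is the
#' ridge solution `beta = (Xc' Xc + lambda I)^-1 Xc' (y - ybar)` with `Xc`
#' column-centred. This is the posterior mean of Bayesian ridge regression
#' with a known variance ratio, computed in closed form (deterministic); a
#' single-site Gibbs sampler backend is available for fidelity checks. The
#' default shrinkage uses the standard marker-variance normalization
#' `lambda = 2 * sum(p(1-p)) * (1 - h2_eff) / h2_eff`, with `p` the training
#' allele frequencies and `h2_eff` the reliability (heritability) of the
#' entry-mean phenotypes. When there are fewer records than markers the
#' equivalent dual system (`n x n`) is solved instead.
#'
#' @param training a `training_set`.
#' @param traits traits to fit (default: all columns of `training$y`).
#' @param h2_eff per-trait entry-mean heritability used for the default
#'   shrinkage (recycled; default 0.5).
#' @param lambda optional explicit ridge parameter (overrides `h2_eff`).
#' @param backend `"closed_form"` (default) or `"gibbs"`.
#' @param gibbs_iter,gibbs_burnin Gibbs sampler length and burn-in.
#' @param fitted_at_cycle bookkeeping tag.
#' @return An object of class `marker_effects`: per-trait `beta` (matrix,
#'   markers x traits), `intercept`, `lambda`, the training record ids
#'   (`training_ids`, used to enforce leave-cycle-out accuracy evaluation)
#'   and `fitted_at_cycle`.
#' @export
estimate_marker_effects <- function(training, traits = colnames(training$y),
                                    h2_eff = 0.5, lambda = NULL,
                                    backend = c("closed_form", "gibbs"),
                                    gibbs_iter = 400, gibbs_burnin = 100,
                                    fitted_at_cycle = NA_integer_) {
  backend <- match.arg(backend)
  X <- training$X
  if (nrow(X) < 2) stop("need at least 2 training records")
  h2_eff <- rep_len(h2_eff, length(traits))
  p <- colMeans(X) / 2
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  beta <- matrix(0, ncol(X), length(traits),
                 dimnames = list(colnames(X), traits))
  mu <- lam <- stats::setNames(numeric(length(traits)), traits)
  K <- NULL
  for (i in seq_along(traits)) {
    y <- training$y[, traits[i]]
    mu[i] <- mean(y)
    if (stats::var(y) == 0) {
      warning("all-constant phenotypes for ", traits[i], "; zero effects")
      next
    }
    lam[i] <- if (is.null(lambda))
      max(2 * sum(p * (1 - p)), .Machine$double.eps) *
        (1 - h2_eff[i]) / h2_eff[i] else lambda
    yc <- y - mu[i]
    if (backend == "gibbs") {
      beta[, i] <- .ridge_gibbs(Xc, yc, lam[i], gibbs_iter, gibbs_burnin)
    } else if (nrow(Xc) < ncol(Xc)) {
      if (is.null(K)) K <- tcrossprod(Xc)          # shared across traits
      a <- solve(K + diag(lam[i], nrow(K)), yc)
      beta[, i] <- drop(crossprod(Xc, a))
    } else {
      A <- crossprod(Xc)
      diag(A) <- diag(A) + lam[i]
      beta[, i] <- drop(solve(A, crossprod(Xc, yc)))
    }
  }
  structure(list(beta = beta, intercept = mu, lambda = lam,
                 training_ids = training$ids,
                 fitted_at_cycle = as.integer(fitted_at_cycle)),
            class = "marker_effects")
}

# Single-site Gibbs sampler for ridge with fixed variance ratio; the chain's
# posterior mean converges to the closed-form ridge solution.
.ridge_gibbs <- function(Xc, yc, lam, iter, burnin) {
  m <- ncol(Xc)
  xx <- colSums(Xc^2)
  s2e <- stats::var(yc)
  b <- numeric(m)
  resid <- yc
  acc <- numeric(m)
  for (it in seq_len(iter)) {
    for (j in seq_len(m)) {
      r_j <- resid + Xc[, j] * b[j]
      denom <- xx[j] + lam
      mean_j <- sum(Xc[, j] * r_j) / denom
      b_new <- stats::rnorm(1, mean_j, sqrt(s2e / denom))
      resid <- r_j - Xc[, j] * b_new
      b[j] <- b_new
    }
    if (it > burnin) acc <- acc + b
  }
  acc / (iter - burnin)
}

#' Genomic estimated breeding values
#'
#' Per individual, the dot product of marker allele doses with the estimated
#' marker effects (no intercept, consistent with the centred fit).
#'
#' @param effects a `marker_effects`.
#' @param pop a `breeding_pop`, or `NULL` if `X` is given.
#' @param marker_loci global locus indices of the marker panel in `pop`'s map.
#' @param inds individual indices.
#' @param X optional precomputed dose matrix (individuals x markers).
#' @return numeric matrix, individuals x traits.
#' @export
gebv <- function(effects, pop = NULL, marker_loci = NULL,
                 inds = if (!is.null(pop)) seq_len(pop_size(pop)), X = NULL) {
  if (is.null(X)) {
    stopifnot(!is.null(pop), !is.null(marker_loci))
    X <- dose(pop, marker_loci, inds)
  }
  X %*% effects$beta
}

#' Assemble the training set from a program archive
#'
#' Collects the stage-trial records whose phenotypes are available by
#' `fit_time` on the simulated calendar (a cycle's Stage phenotypes mature
#' only `pipeline_years` after its crossing, so early parent recycling runs
#' ahead of phenotype availability) and keeps those from the `window` most
#' recent phenotyped cycles. F2-family records obey the same window.
#'
#' The cycle window applies per record source: the `window` most recent
#' phenotyped cycles of stage trials, plus the `window` most recent cycles
#' of F2-family records. F2-family phenotypes are additions to the training
#' set and never displace the (older but far more replicated) stage-trial
#' records.
#'
#' @param archive a list of per-cycle entries, each a list with elements
#'   `cycle`, `avail_time` (calendar year the phenotypes mature), `X`, `y`,
#'   `source`, `ids` (see [new_training_set()]).
#' @param fit_time calendar time of the fit (default `Inf`: everything).
#' @param window number of most recent phenotyped cycles to keep per source
#'   (default 3).
#' @return a `training_set`.
#' @export
assemble_training <- function(archive, fit_time = Inf, window = 3) {
  avail <- Filter(function(a) a$avail_time <= fit_time, archive)
  if (length(avail) == 0)
    stop("no phenotyped cycles available yet; run a phenotypic-selection warm start first")
  srcs <- vapply(avail, function(a) a$source[1], character(1))
  cycs <- vapply(avail, function(a) as.numeric(a$cycle), numeric(1))
  keep <- logical(length(avail))
  for (s in unique(srcs)) {
    kc <- utils::tail(sort(unique(cycs[srcs == s])), window)
    keep <- keep | (srcs == s & cycs %in% kc)
  }
  avail <- avail[keep]
  new_training_set(
    X = do.call(rbind, lapply(avail, `[[`, "X")),
    y = do.call(rbind, lapply(avail, `[[`, "y")),
    cycle = unlist(lapply(avail, function(a) rep(a$cycle, nrow(a$X)))),
    source = unlist(lapply(avail, function(a) rep_len(a$source, nrow(a$X)))),
    ids = unlist(lapply(avail, `[[`, "ids")))
}

#' Add F2-family records to a training set
#'
#' Each phenotyped F2 family contributes the equivalent of one individual:
#' the record's genotype vector is the mean allele dose across the family's
#' members (fractional, in `[0, 2]`) and its phenotype is the mean of the
#' members' field records per trait.
#'
#' @param training a `training_set`.
#' @param f2_pop a `breeding_pop` of field-grown F2 plants with `family`
#'   metadata.
#' @param arch a `trait_arch` (marker panel and phenotype model).
#' @param n_families number of families to phenotype (default 50); if more
#'   are requested than exist, all are used with a warning.
#' @param resid_inflation residual inflation of the single-plant F2 records.
#' @param cycle cycle tag for the new records.
#' @return the extended `training_set`.
#' @export
add_f2_family_records <- function(training, f2_pop, arch, n_families = 50,
                                  resid_inflation = 2, cycle = NA) {
  fams <- unique(f2_pop$meta$family)
  if (n_families > length(fams)) {
    warning("only ", length(fams), " F2 families available; using all")
    n_families <- length(fams)
  }
  fams <- sample(fams, n_families)
  recs <- run_trial(pop_subset(f2_pop, which(f2_pop$meta$family %in% fams)),
                    "f2_family_plot", arch, resid_inflation = resid_inflation)
  sub <- which(f2_pop$meta$family %in% fams)
  Xs <- dose(f2_pop, arch$marker_loci, sub)
  fam_of <- f2_pop$meta$family[sub]
  Xfam <- rowsum(Xs, fam_of) / as.vector(table(fam_of)[sort(unique(fam_of))])
  recs$id <- f2_pop$meta$family[match(recs$id, f2_pop$meta$id)]
  yfam <- entry_means(recs, ids = rownames(Xfam))
  new_training_set(
    X = rbind(training$X, Xfam),
    y = rbind(training$y, yfam[, colnames(training$y), drop = FALSE]),
    cycle = c(training$cycle, rep(as.integer(cycle), nrow(Xfam))),
    source = c(training$source, rep("f2_family", nrow(Xfam))),
    ids = c(training$ids, rownames(Xfam)))
}

#' Prediction accuracy of GEBVs
#'
#' Pearson correlation between GEBVs and true breeding values (TBV averaged
#' over the two environments per trait). The evaluation enforces the
#' leave-cycle-out discipline: it is an error for the cohort to intersect the
#' records the marker effects were fitted on.
#'
#' @param effects a `marker_effects`.
#' @param pop cohort to rank (>= 3 individuals).
#' @param arch a `trait_arch`.
#' @param inds cohort indices.
#' @return named numeric vector of per-trait accuracies; `NA` (with a
#'   warning) for traits whose GEBVs have zero variance.
#' @export
accuracy <- function(effects, pop, arch, inds = seq_len(pop_size(pop))) {
  if (length(inds) < 3) stop("cohort must have at least 3 individuals")
  if (any(pop$meta$id[inds] %in% effects$training_ids))
    stop("cohort intersects the training records; leave-cycle-out violated")
  ghat <- gebv(effects, pop, arch$marker_loci, inds)
  g <- tbv_all(pop, arch, inds)$trait_mean
  out <- stats::setNames(rep(NA_real_, ncol(ghat)), colnames(ghat))
  for (t in colnames(ghat)) {
    if (stats::sd(ghat[, t]) == 0) {
      warning("zero-variance GEBVs for ", t)
    } else out[t] <- stats::cor(ghat[, t], g[, t])
  }
  out
}

#' @export
print.marker_effects <- function(x, ...) {
  cat("<marker_effects> ", nrow(x$beta), " markers x ", ncol(x$beta),
      " traits (fitted at cycle ", x$fitted_at_cycle, ")\n", sep = "")
  invisible(x)
}
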
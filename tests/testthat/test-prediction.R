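test_that("ridge recovers a single-marker effect with the closed-form shrinkage", {
  set.seed(1)
  n <- 30
  X <- matrix(1, n, 5)               # constant markers carry no signal
  xk <- rbinom(n, 2, 0.5)
  X[, 3] <- xk
  y <- 2 * xk
  lam <- 7
  tr <- new_training_set(X, cbind(t1 = y), cycle = 1)
  eff <- estimate_marker_effects(tr, lambda = lam)
  xc <- xk - mean(xk)
  expect_equal(unname(eff$beta[3, 1]), sum(xc * y) / (sum(xc^2) + lam),
               tolerance = 1e-10)
  expect_equal(unname(eff$beta[c(1, 2, 4, 5), 1]), rep(0, 4))
})

test_that("ridge is invariant to record order and matches a dense solve", {
  set.seed(2)
  n <- 50; m <- 200
  X <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- X %*% rnorm(m, 0, 0.1) + rnorm(n)
  tr <- new_training_set(X, cbind(t1 = drop(y)), cycle = 1)
  eff <- estimate_marker_effects(tr, h2_eff = 0.6)
  perm <- sample(n)
  tr2 <- new_training_set(X[perm, ], cbind(t1 = drop(y)[perm]), cycle = 1)
  eff2 <- estimate_marker_effects(tr2, h2_eff = 0.6)
  expect_equal(eff$beta, eff2$beta, tolerance = 1e-9)
  # brute-force primal solve oracle
  Xc <- scale(X, scale = FALSE)
  lam <- unname(eff$lambda[1])
  bref <- solve(crossprod(Xc) + diag(lam, m), crossprod(Xc, y - mean(y)))
  expect_lt(max(abs(eff$beta[, 1] - bref)), 1e-8)
})

test_that("constant phenotypes give zero effects with a warning", {
  X <- matrix(rbinom(40, 2, 0.5), 10, 4)
  tr <- new_training_set(X, cbind(t1 = rep(3, 10)), cycle = 1)
  expect_warning(eff <- estimate_marker_effects(tr), "constant")
  expect_true(all(eff$beta == 0))
})

test_that("the Gibbs backend agrees with the closed form", {
  set.seed(3)
  n <- 50; m <- 80
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  y <- X %*% rnorm(m, 0, 0.2) + rnorm(n)
  tr <- new_training_set(X, cbind(t1 = drop(y)), cycle = 1)
  cf <- estimate_marker_effects(tr, h2_eff = 0.5)
  gb <- estimate_marker_effects(tr, h2_eff = 0.5, backend = "gibbs",
                                gibbs_iter = 600, gibbs_burnin = 100)
  expect_gt(cor(cf$beta[, 1], gb$beta[, 1]), 0.98)
  expect_lt(mean(abs(cf$beta[, 1] - gb$beta[, 1])), 0.1 * sd(cf$beta[, 1]) + 0.01)
})

test_that("GEBVs are linear in the effects and match a loop oracle", {
  f <- small_founders()
  arch <- small_arch()
  eff <- list(beta = matrix(rnorm(500 * 2), 500, 2,
                            dimnames = list(NULL, c("a", "b"))),
              training_ids = character(0))
  class(eff) <- "marker_effects"
  g <- gebv(eff, f, arch$marker_loci, inds = 1:5)
  d <- dose(f, arch$marker_loci, 1:5)
  for (i in 1:5) expect_equal(unname(g[i, "a"]), sum(d[i, ] * eff$beta[, "a"]))
  eff2 <- eff; eff2$beta <- 2 * eff$beta
  expect_equal(gebv(eff2, f, arch$marker_loci, inds = 1:5), 2 * g)
  eff0 <- eff; eff0$beta[] <- 0
  expect_true(all(gebv(eff0, f, arch$marker_loci, inds = 1:5) == 0))
})

test_that("training assembly follows the calendar and the cycle window", {
  mk <- function(cyc, avail) list(cycle = cyc, avail_time = avail,
                                  X = matrix(cyc, 2, 3),
                                  y = matrix(cyc, 2, 2,
                                             dimnames = list(NULL, c("a", "b"))),
                                  source = "stage_trial",
                                  ids = paste0("c", cyc, "_", 1:2))
  archive <- list(mk(1, 8), mk(2, 16), mk(3, 24), mk(4, 32.5), mk(5, 41))
  tr <- assemble_training(archive, fit_time = 24)
  expect_setequal(unique(tr$cycle), 1:3)
  expect_equal(nrow(tr$X), 6)
  # a later fit with no newly matured phenotypes is unchanged
  tr2 <- assemble_training(archive, fit_time = 28)
  expect_identical(tr2$cycle, tr$cycle)
  # once cycle-4 phenotypes mature, the window slides
  tr3 <- assemble_training(archive, fit_time = 32.5)
  expect_setequal(unique(tr3$cycle), 2:4)
  tr4 <- assemble_training(archive, fit_time = 100, window = 1)
  expect_setequal(unique(tr4$cycle), 5)
  expect_error(assemble_training(archive, fit_time = 0), "warm start")
  # F2-family records never evict stage-trial cycles: windows are per source
  mkf <- function(cyc, avail) {
    a <- mk(cyc, avail)
    a$source <- "f2_family"
    a$ids <- paste0("f", a$ids)
    a
  }
  arch2 <- list(mk(1, 8), mk(2, 16), mk(3, 24),
                mkf(4, 25), mkf(5, 26), mkf(6, 27), mkf(7, 28))
  tr5 <- assemble_training(arch2, fit_time = 28)
  expect_setequal(unique(tr5$cycle[tr5$source == "stage_trial"]), 1:3)
  expect_setequal(unique(tr5$cycle[tr5$source == "f2_family"]), 5:7)
})

test_that("F2 family records average genotype and phenotype across members", {
  f <- small_founders()
  arch <- small_arch()
  # family of identical homozygous individuals: record equals any member
  fam <- pop_subset(f, rep(4, 3))
  fam$meta$id <- paste0("m", 1:3)
  fam$meta$family <- "famA"
  empty <- new_training_set(matrix(0, 0, 500),
                            matrix(0, 0, 3, dimnames = list(NULL, arch$traits)),
                            integer(0))
  set.seed(4)
  tr <- add_f2_family_records(empty, fam, arch, n_families = 1)
  expect_equal(nrow(tr$X), 1)
  expect_equal(drop(tr$X), unname(dose(f, arch$marker_loci, 4)[1, ]))
  expect_equal(tr$source, "f2_family")
  # two members with doses 0 and 2 average to 1
  map <- even_map(1, 10)
  p2 <- pop_from_haps(matrix(c(rep(0L, 10), rep(1L, 10)), 10),
                      matrix(c(rep(0L, 10), rep(1L, 10)), 10), map)
  p2$meta$family <- "famB"
  arch2 <- list(marker_loci = 1:10, traits = "t",
                envs = c("env1", "env2"), h2 = c(t = 0.5),
                weights = c(t = 1),
                qtl = list(t = list(env1 = list(loci = 1, eff = 0),
                                    env2 = list(loci = 1, eff = 0))),
                base_var = matrix(1, 2, 1, dimnames = list(c("env1", "env2"), "t")))
  class(arch2) <- "trait_arch"
  empty2 <- new_training_set(matrix(0, 0, 10),
                             matrix(0, 0, 1, dimnames = list(NULL, "t")),
                             integer(0))
  tr2 <- add_f2_family_records(empty2, p2, arch2, n_families = 1)
  expect_true(all(tr2$X == 1))
  expect_warning(add_f2_family_records(empty2, p2, arch2, n_families = 5),
                 "available")
})

test_that("accuracy is 1 for oracle effects, near 0 for random ones", {
  f <- small_founders()
  arch <- small_arch()
  # diagnostic architecture whose marker panel IS the QTL set, shared by
  # both environments with identical effects
  q <- arch$qtl$grain_weight$env1
  diag_arch <- arch
  diag_arch$marker_loci <- q$loci
  for (t in diag_arch$traits)
    diag_arch$qtl[[t]] <- list(env1 = q, env2 = q)
  eff <- list(beta = matrix(q$eff, length(q$eff), 3,
                            dimnames = list(NULL, arch$traits)),
              training_ids = character(0))
  class(eff) <- "marker_effects"
  acc <- accuracy(eff, f, diag_arch, inds = 1:100)
  expect_equal(unname(acc), rep(1, 3), tolerance = 1e-10)
  # random effects: mean accuracy over replicates straddles zero
  set.seed(5)
  r <- replicate(20, {
    effr <- list(beta = matrix(rnorm(500 * 3), 500, 3,
                               dimnames = list(NULL, arch$traits)),
                 training_ids = character(0))
    class(effr) <- "marker_effects"
    accuracy(effr, f, arch, inds = 1:100)[["grain_yield"]]
  })
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(20))
})

test_that("accuracy enforces the leave-cycle-out discipline", {
  f <- small_founders()
  arch <- small_arch()
  eff <- list(beta = matrix(0.1, 500, 3, dimnames = list(NULL, arch$traits)),
              training_ids = f$meta$id[5])
  class(eff) <- "marker_effects"
  expect_error(accuracy(eff, f, arch, inds = 1:10), "leave-cycle-out")
  expect_error(accuracy(eff, f, arch, inds = 1:2), "at least 3")
})

test_that("accuracy improves with training-set size", {
  f <- small_founders()
  arch <- small_arch()
  h2e <- arch$h2 / (arch$h2 + (1 - arch$h2) / 4)
  set.seed(6)
  accs <- sapply(1:6, function(r) {
    rec <- run_trial(f, "stage", arch)
    em <- entry_means(rec, f$meta$id)
    X <- dose(f, arch$marker_loci)
    test_idx <- 251:300
    fit_one <- function(train_idx) {
      tr <- new_training_set(X[train_idx, ], em[train_idx, arch$traits],
                             cycle = 1, ids = f$meta$id[train_idx])
      eff <- estimate_marker_effects(tr, traits = arch$traits,
                                     h2_eff = h2e[arch$traits])
      mean(accuracy(eff, f, arch, inds = test_idx))
    }
    c(small = fit_one(1:60), large = fit_one(1:250))
  })
  expect_gt(mean(accs["large", ]), mean(accs["small", ]))
})
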
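# shared toy population: 3 chromosomes, explicit marker panel
ohv_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      map <- even_map(3, 40)
      set.seed(10)
      n <- 12
      pop <- pop_from_haps(matrix(rbinom(120 * n, 1, 0.5), 120, n),
                           matrix(rbinom(120 * n, 1, 0.5), 120, n), map)
      beta <- matrix(rnorm(120 * 3), 120, 3,
                     dimnames = list(NULL, c("dr", "gw", "gy")))
      scheme <- segment_scheme(map, 1:120, n_segments = 5)
      cache <<- list(pop = pop, beta = beta, scheme = scheme, map = map)
    }
    cache
  }
})

test_that("haplotype values are plain weighted sums", {
  expect_equal(haplotype_value(c(1, 0, 1), c(0.5, -1, 2)), 2.5)
  expect_equal(haplotype_value(rep(0, 5), rnorm(5)), 0)
  set.seed(1)
  hap <- rbinom(30, 1, 0.5); b <- rnorm(30)
  expect_equal(haplotype_value(hap, b, 11:20), sum(hap[11:20] * b[11:20]))
})

test_that("OHV of a homozygote equals its GEBV (doubling on)", {
  fx <- ohv_fixture()
  hom <- pop_homozygous(matrix(as.integer(fx$pop$H1), 120), fx$map)
  o2 <- ohv(hom, fx$beta, fx$scheme, 1:120, doubling = TRUE)
  o1 <- ohv(hom, fx$beta, fx$scheme, 1:120, doubling = FALSE)
  g <- dose(hom, 1:120) %*% fx$beta
  expect_equal(o2, unname(g), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(o1 * 2, o2)
})

test_that("OHV dominates both whole-haplotype values and is exact per segment", {
  fx <- ohv_fixture()
  o <- ohv(fx$pop, fx$beta, fx$scheme, 1:120)
  h1 <- matrix(as.integer(fx$pop$H1), 120)
  h2 <- matrix(as.integer(fx$pop$H2), 120)
  for (t in 1:3) {
    hv1 <- colSums(h1 * fx$beta[, t])
    hv2 <- colSums(h2 * fx$beta[, t])
    expect_true(all(o[, t] >= pmax(hv1, hv2) - 1e-12))
    # per-segment max oracle
    oracle <- sapply(seq_len(12), function(i) {
      s <- 0
      for (sg in unique(fx$scheme$segment)) {
        loci <- which(fx$scheme$segment == sg)
        s <- s + max(sum(h1[loci, i] * fx$beta[loci, t]),
                     sum(h2[loci, i] * fx$beta[loci, t]))
      }
      s
    })
    expect_equal(unname(o[, t]), oracle, tolerance = 1e-12)
  }
})

test_that("one whole-genome segment returns the better haplotype; finer nested schemes never lower OHV", {
  fx <- ohv_fixture()
  one <- structure(list(segment = rep(1L, 120), n_segments = 1L),
                   class = "segment_scheme")
  o <- ohv(fx$pop, fx$beta, one, 1:120)
  h1 <- matrix(as.integer(fx$pop$H1), 120)
  h2 <- matrix(as.integer(fx$pop$H2), 120)
  for (t in 1:3)
    expect_equal(unname(o[, t]),
                 pmax(colSums(h1 * fx$beta[, t]), colSums(h2 * fx$beta[, t])))
  # nested refinement: split every segment of the chromosome scheme in two
  coarse <- segment_scheme(fx$map, 1:120, n_segments = 2)
  fine <- coarse
  fine$segment <- coarse$segment * 2L
  for (sg in unique(coarse$segment)) {
    loci <- which(coarse$segment == sg)
    fine$segment[loci[seq_len(floor(length(loci) / 2))]] <- sg * 2L - 1L
  }
  fine$n_segments <- length(unique(fine$segment))
  oc <- ohv(fx$pop, fx$beta, coarse, 1:120)
  of <- ohv(fx$pop, fx$beta, fine, 1:120)
  expect_true(all(of >= oc - 1e-12))
})

test_that("segment schemes partition the panel with near-equal counts", {
  fx <- ohv_fixture()
  counts <- table(fx$scheme$segment)
  expect_equal(sum(counts), 120)
  expect_lte(max(counts) - min(counts), 1)
  expect_equal(fx$scheme$n_segments, 15)
})

test_that("the OHV index reduces correctly for degenerate weights", {
  set.seed(2)
  v <- matrix(rnorm(30), 10, 3)
  expect_equal(ohv_index(v, c(1, 0, 0)),
               drop(scale(v[, 1])), ignore_attr = TRUE)
  z <- scale(v)
  expect_equal(ohv_index(v, c(0.3, 0.3, 0.4)),
               drop(z %*% c(0.3, 0.3, 0.4)), ignore_attr = TRUE)
})

test_that("unconstrained greedy cross selection is a plain sort; caps bind", {
  fx <- ohv_fixture()
  eff <- structure(list(beta = fx$beta), class = "marker_effects")
  sel <- select_primary_crosses(fx$pop, 1:12, eff, fx$scheme, 1:120,
                                n_crosses = 10, usage_cap = Inf)
  expect_equal(sel$score, sort(sel$score, decreasing = TRUE))
  expect_equal(nrow(sel), 10)
  sel1 <- select_primary_crosses(fx$pop, 1:12, eff, fx$scheme, 1:120,
                                 n_crosses = 6, usage_cap = 1)
  expect_false(any(duplicated(c(sel1$mother, sel1$father))))
  expect_error(select_primary_crosses(fx$pop, 1:12, eff, fx$scheme, 1:120,
                                      n_crosses = 30, usage_cap = 2),
               "invalid config")
})

test_that("greedy cap-constrained selection matches the exhaustive oracle", {
  fx <- ohv_fixture()
  eff <- structure(list(beta = fx$beta), class = "marker_effects")
  # independent oracle: score all 15 pairs by explicit 4-haplotype segment
  # maxima, then find the lexicographically best feasible triple
  h <- list(matrix(as.integer(fx$pop$H1[, 1:6]), 120),
            matrix(as.integer(fx$pop$H2[, 1:6]), 120))
  seg_hv <- function(hap, t) {
    sapply(unique(fx$scheme$segment), function(sg)
      sum(hap[fx$scheme$segment == sg] * fx$beta[fx$scheme$segment == sg, t]))
  }
  pairs <- t(combn(6, 2))
  raw <- sapply(1:3, function(t) {
    apply(pairs, 1, function(pr) {
      m <- pmax(pmax(seg_hv(h[[1]][, pr[1]], t), seg_hv(h[[2]][, pr[1]], t)),
                pmax(seg_hv(h[[1]][, pr[2]], t), seg_hv(h[[2]][, pr[2]], t)))
      sum(m)
    })
  })
  score <- drop(scale(raw) %*% c(0.3, 0.3, 0.4))
  feasible <- function(set) {
    all(table(c(pairs[set, ])) <= 2)
  }
  combos <- t(combn(15, 3))
  lex_greater <- function(x, y) {
    for (i in seq_along(x)) {
      if (x[i] > y[i] + 1e-12) return(TRUE)
      if (x[i] < y[i] - 1e-12) return(FALSE)
    }
    FALSE
  }
  best <- NULL
  for (k in seq_len(nrow(combos))) {
    if (!feasible(combos[k, ])) next
    sc <- sort(score[combos[k, ]], decreasing = TRUE)
    if (is.null(best) || lex_greater(sc, best)) best <- sc
  }
  sel <- select_primary_crosses(fx$pop, 1:6, eff, fx$scheme, 1:120,
                                n_crosses = 3, usage_cap = 2)
  expect_equal(sort(sel$score, decreasing = TRUE), best, tolerance = 1e-9)
})

test_that("projection of a selfed inbred is deterministic at the parental value", {
  map <- even_map(2, 30)
  set.seed(3)
  alle <- matrix(rbinom(60, 1, 0.5), 60, 1)
  pop <- pop_homozygous(cbind(alle, alle), map)
  beta <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  eff <- structure(list(beta = beta), class = "marker_effects")
  pr <- suppressWarnings(
    project_inbred_progeny(pop, cbind(1, 2), eff, 1:60, n_virtual = 10))
  expect_equal(pr$sd, 0)
  expect_equal(pr$mean_a, sum(2 * alle * beta[, 1]))
})

test_that("projected progeny means converge to the mid-parent value", {
  map <- even_map(2, 40)
  set.seed(4)
  pop <- pop_homozygous(matrix(rbinom(160, 1, 0.5), 80, 2), map)
  beta <- matrix(rnorm(80), 80, 1, dimnames = list(NULL, "t"))
  eff <- structure(list(beta = beta), class = "marker_effects")
  pr <- project_inbred_progeny(pop, cbind(1, 2), eff, 1:80,
                               n_virtual = 2000, weights = 1)
  gv <- dose(pop, 1:80) %*% beta
  mid <- mean(gv)                                  # additive expectation
  # estimate the progeny-score SD from an explicit meiosis-module sample
  set.seed(6)
  prog <- cross(pop, rep(1, 400), rep(2, 400), mutation_rate = 0)
  prog <- ssd_advance(prog, 7, mutation_rate = 0)
  sc2 <- drop(dose(prog) %*% beta)
  expect_lt(abs(pr$mean_t - mid), 4 * sd(sc2) / sqrt(2000))
  expect_lt(abs(mean(sc2) - mid), 4 * sd(sc2) / sqrt(400))
})

test_that("intercross selection is deterministic under a fixed seed and ranks dominant crosses first", {
  fx <- ohv_fixture()
  eff <- structure(list(beta = fx$beta, training_ids = character(0)),
                   class = "marker_effects")
  set.seed(5)
  a <- select_intercrosses(fx$pop, eff, fx$scheme, 1:120, n_select = 5,
                           n_virtual = 15)
  set.seed(5)
  b <- select_intercrosses(fx$pop, eff, fx$scheme, 1:120, n_select = 5,
                           n_virtual = 15)
  expect_identical(a, b)
  expect_equal(a$score, sort(a$score, decreasing = TRUE))
  # mean_ohv criterion agrees with a brute-force recomputation
  mo <- select_intercrosses(fx$pop, eff, fx$scheme, 1:120, n_select = 3,
                            criterion = "mean_ohv")
  expect_equal(nrow(mo), 3)
  expect_true(all(mo$a < mo$b))
})
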
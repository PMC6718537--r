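cond54 <- factor(rep(c("young", "aged"), c(5, 4)), levels = c("young", "aged"))

test_that("count tabulation matches a nested-loop tally and conserves events", {
  ss <- make_sample_set(n = 80, seed = 14)
  pooled <- pool_events(ss, per_sample_cap = NULL)
  model <- cut_tree(build_tree(pooled), k = 7)
  full <- assign_full(model, ss)
  counts <- tabulate_counts(full, ss, 7)
  expect_identical(counts, oracle_tally(full, names(ss$tables), 7L))
  expect_equal(unname(colSums(counts)), rep(80, 9))
  expect_identical(sum(counts), nrow(full))
  # minimal example: one sample, labels (1,1,2)
  lab <- structure(data.frame(sample_id = "s1", event = 1:3,
                              cluster = c(1L, 1L, 2L)),
                   class = c("cluster_labels", "data.frame"))
  one <- make_sample_set(n = 3)
  one$tables <- one$tables["y1"]; names(one$tables) <- "s1"
  one$tables$s1$sample_id <- "s1"
  cts <- tabulate_counts(lab, one, 2)
  expect_identical(as.vector(cts[, "s1"]), c(2L, 1L))
  lab$cluster[1] <- 9L
  expect_error(tabulate_counts(lab, one, 2), "outside")
})

test_that("size factors implement median-of-ratios exactly", {
  # all columns identical: every factor is 1
  same <- matrix(rep(c(5, 10, 20), 4), 3, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(estimate_size_factors(same)), rep(1, 4))
  # doubling column: s = (1/sqrt(2), sqrt(2)) by direct evaluation
  two <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  expect_equal(unname(estimate_size_factors(two)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # random matrices vs the independently coded oracle
  set.seed(101)
  for (i in 1:20) {
    m <- matrix(rpois(15 * 9, 60) + 1L, 15, 9,
                dimnames = list(NULL, paste0("s", 1:9)))
    expect_equal(unname(estimate_size_factors(m)), oracle_size_factors(m),
                 tolerance = 1e-10)
    # invariant to row order
    expect_equal(estimate_size_factors(m[sample(15), ]),
                 estimate_size_factors(m), tolerance = 1e-12)
  }
  # scale invariance: scaling one sample scales its factor relative to the
  # others by the same amount (the geometric-mean reference shifts, so the
  # ratio is the exact invariant)
  m <- matrix(rpois(15 * 9, 60) + 1L, 15, 9,
              dimnames = list(NULL, paste0("s", 1:9)))
  m2 <- m; m2[, 3] <- m2[, 3] * 4L
  sf1 <- estimate_size_factors(m); sf2 <- estimate_size_factors(m2)
  expect_equal(unname(sf2[3] / sf2[5]), unname(sf1[3] / sf1[5]) * 4,
               tolerance = 1e-10)
  # degenerate: no all-positive row falls back with a warning
  z <- rbind(c(0, 5, 5), c(5, 0, 5))
  colnames(z) <- paste0("s", 1:3)
  expect_warning(s <- estimate_size_factors(z), "fall")
  expect_true(all(s > 0))
})

test_that("dispersion estimation floors Poisson data and recovers true alpha", {
  set.seed(33)
  s <- rep(1, 9)
  # Poisson counts: at least half the estimates sit exactly at the floor and
  # the rest stay tiny (the Cox-Reid adjustment is unbiased, so estimates do
  # not all collapse to zero the way an unadjusted MLE would)
  pois <- t(replicate(100, rpois(9, 200)))
  colnames(pois) <- paste0("s", 1:9)
  a_pois <- estimate_dispersions(pois, s, cond54)
  expect_gte(mean(a_pois <= 1e-8 + 1e-12), 0.5)
  expect_identical(unname(median(a_pois)), 1e-8)
  expect_lt(quantile(a_pois, 0.99), 0.02)
  # identical counts across samples: zero excess variance, alpha at floor
  flat <- matrix(100, 3, 9, dimnames = list(NULL, paste0("s", 1:9)))
  expect_equal(unname(estimate_dispersions(flat, s, cond54)), rep(1e-8, 3))
  # NB alpha = 0.2: median estimate in [0.1, 0.4] over 2000 clusters
  nb <- t(replicate(2000, rnbinom(9, size = 1 / 0.2, mu = 500)))
  colnames(nb) <- paste0("s", 1:9)
  a_nb <- estimate_dispersions(nb, s, cond54)
  expect_gte(median(a_nb), 0.1)
  expect_lte(median(a_nb), 0.4)
})

test_that("Wald test reduces to the Poisson GLM in the small-dispersion limit", {
  set.seed(55)
  x <- model.matrix(~cond54)
  for (i in 1:10) {
    sj <- runif(9, 0.5, 2)
    cts <- matrix(rpois(15 * 9, outer(runif(15, 20, 300), sj)), 15, 9,
                  dimnames = list(NULL, paste0("s", 1:9)))
    res <- nb_wald_test(cts, sj, rep(1e-8, 15), cond54)
    for (r in c(1, 8, 15)) {
      g <- glm(cts[r, ] ~ cond54 + offset(log(sj)), family = poisson())
      z <- summary(g)$coefficients[2, 3]
      expect_equal(res$stat[r], z, tolerance = 1e-3)
    }
  }
})

test_that("degenerate and null count patterns give the documented results", {
  # identical counts everywhere: log2fc = 0, p = 1
  flat <- matrix(50, 4, 9, dimnames = list(NULL, paste0("s", 1:9)))
  s <- rep(1, 9)
  res <- nb_wald_test(flat, s, rep(1e-8, 4), cond54)
  expect_equal(res$log2FoldChange, rep(0, 4), tolerance = 1e-8)
  expect_equal(res$pvalue, rep(1, 4), tolerance = 1e-8)
  # an all-zero cluster is reported NA and excluded from the BH m
  mix <- rbind(rep(0L, 9), matrix(rpois(27, 80), 3, 9))
  colnames(mix) <- paste0("s", 1:9)
  a <- estimate_dispersions(mix, s, cond54)
  expect_true(is.na(a[1]))
  res2 <- nb_wald_test(mix, s, a, cond54)
  expect_true(is.na(res2$pvalue[1]) && is.na(res2$padj[1]))
  expect_identical(res2$direction[1], "none")
  expect_equal(res2$padj[-1], adjust_bh(res2$pvalue[-1]))
})

test_that("BH adjustment follows the hand-applied step-up rule", {
  expect_equal(adjust_bh(0.01), 0.01)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # worked example: q_(i) = min over j >= i of m * p_(j) / j
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(adjust_bh(p), c(0.02, 4 * 0.04 / 3, 4 * 0.04 / 3, 0.8))
  # permutation invariance up to reordering
  set.seed(2)
  pv <- runif(20)
  perm <- sample(20)
  expect_equal(adjust_bh(pv[perm])[order(perm)], adjust_bh(pv))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  # NA propagates and shrinks m
  pna <- c(0.01, NA, 0.02)
  expect_equal(adjust_bh(pna), c(0.02, NA, 0.02))
})

test_that("Wald z is invariant to a common rescaling of the size factors", {
  set.seed(77)
  cts <- matrix(rpois(15 * 9, 150) + 1L, 15, 9,
                dimnames = list(NULL, paste0("s", 1:9)))
  s1 <- estimate_size_factors(cts)
  r1 <- nb_wald_test(cts, s1, rep(1e-8, 15), cond54)
  # a global factor shifts every offset equally and is absorbed by the
  # intercept, leaving the condition z untouched
  r2 <- nb_wald_test(cts, s1 * 7.3, rep(1e-8, 15), cond54)
  expect_equal(r2$stat, r1$stat, tolerance = 1e-6)
  expect_equal(r2$log2FoldChange, r1$log2FoldChange, tolerance = 1e-8)
})

test_that("direction labels encode the documented fold-change sign convention", {
  set.seed(88)
  up <- c(rpois(5, 50), rpois(4, 400))   # enriched in aged (non-reference)
  down <- c(rpois(5, 400), rpois(4, 50)) # enriched in young (reference)
  cts <- rbind(up, down, matrix(rpois(7 * 9, 100), 7, 9))
  colnames(cts) <- paste0("s", 1:9)
  res <- da_test(cts, cond54)
  expect_identical(res$direction[1], "enriched_in_other")
  expect_gt(res$log2FoldChange[1], 0)
  expect_identical(res$direction[2], "enriched_in_reference")
  expect_lt(res$log2FoldChange[2], 0)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(99)
  for (i in 1:5) {
    m <- matrix(rpois(15 * 9, 120) + 1L, 15, 9,
                dimnames = list(paste0("c", 1:15), paste0("s", 1:9)))
    expect_equal(unname(estimate_size_factors(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-10)
  }
})
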
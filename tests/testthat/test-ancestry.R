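# Hybrid index, interspecific heterozygosity and hybrid classification.

test_that("polarization recodes calls to counts of the B-associated allele", {
  calls <- rbind(c(0L, 2L, 1L), c(2L, 0L, 1L))
  gm <- toy_gm(calls)
  fr <- data.frame(locus_id = c("L1", "L2", "L3"),
                   p_a = c(0, 1, 0.9), p_b = c(1, 0, 0.05))
  pol <- polarize(gm, fr, c("L1", "L2", "L3"))
  # L1: alt already B-associated; L2 and L3: B allele is ref, so flip
  expect_identical(unname(pol$calls[1, ]), c(0L, 0L, 1L))
  expect_identical(unname(pol$calls[2, ]), c(2L, 2L, 1L))
  expect_equal(pol$bfreqs$p_b, c(1, 1, 0.95))
  expect_equal(pol$bfreqs$p_a, c(0, 0, 0.1))
  expect_identical(pol$bfreqs$flipped, c(FALSE, TRUE, TRUE))
  expect_error(polarize(gm, data.frame(locus_id = "L1", p_a = .5, p_b = .5),
                        "L1"), "p_a == p_b")
})

test_that("hybrid index at fixed loci equals the allele-counting closed form", {
  pa <- rep(0, 6); pb <- rep(1, 6)
  expect_equal(ml_hybrid_index(rep(1L, 6), pa, pb)$h, 0.5, tolerance = 1e-9)
  expect_equal(ml_hybrid_index(rep(0L, 6), pa, pb)$h, 0)
  expect_equal(ml_hybrid_index(rep(2L, 6), pa, pb)$h, 1)
  set.seed(5)
  for (i in 1:25) {
    g <- sample(0:2, 40, replace = TRUE)
    g[sample(40, 5)] <- NA
    fit <- ml_hybrid_index(g, rep(0, 40), rep(1, 40))
    expect_equal(fit$h, sum(g, na.rm = TRUE) / (2 * sum(!is.na(g))),
                 tolerance = 1e-9)
    expect_equal(fit$n_loci, sum(!is.na(g)))
  }
})

test_that("ML hybrid index agrees with a brute-force grid search", {
  grid_mle <- function(g, pa, pb) {
    hs <- seq(0, 1, by = 1e-4)
    ll <- vapply(hs, function(h) {
      q <- h * pb + (1 - h) * pa
      sum(dbinom(g, 2, q, log = TRUE))
    }, numeric(1))
    hs[which.max(ll)]
  }
  # the two-locus worked example with non-fixed frequencies
  expect_equal(ml_hybrid_index(c(2L, 1L), c(0.1, 0.2), c(0.9, 0.9))$h,
               grid_mle(c(2L, 1L), c(0.1, 0.2), c(0.9, 0.9)),
               tolerance = 1e-3)
  set.seed(9)
  for (i in 1:10) {
    n <- 12
    pa <- runif(n, 0, 0.25); pb <- runif(n, 0.75, 1)
    g <- rbinom(n, 2, runif(1))
    expect_equal(ml_hybrid_index(g, pa, pb)$h, grid_mle(g, pa, pb),
                 tolerance = 1e-3)
  }
})

test_that("hybrid index is invariant to locus order and missing-locus drop", {
  set.seed(31)
  pa <- runif(20, 0, 0.2); pb <- runif(20, 0.8, 1)
  g <- rbinom(20, 2, 0.6); g[c(3, 11)] <- NA
  h0 <- ml_hybrid_index(g, pa, pb)$h
  perm <- sample(20)
  expect_equal(ml_hybrid_index(g[perm], pa[perm], pb[perm])$h, h0,
               tolerance = 1e-8)
  keep <- !is.na(g)
  expect_equal(ml_hybrid_index(g[keep], pa[keep], pb[keep])$h, h0,
               tolerance = 1e-8)
})

test_that("support interval brackets the MLE and is undefined when all missing", {
  fit <- ml_hybrid_index(c(1L, 1L, 0L, 2L), rep(0, 4), rep(1, 4))
  expect_true(fit$lo <= fit$h && fit$h <= fit$hi)
  expect_true(fit$lo < fit$hi)
  none <- ml_hybrid_index(c(NA, NA), rep(0, 2), rep(1, 2))
  expect_true(is.na(none$h))
  expect_identical(none$n_loci, 0L)
})

test_that("interspecific heterozygosity counts polarized heterozygotes", {
  expect_equal(interspecific_heterozygosity(rep(1L, 10)), 1)
  expect_equal(interspecific_heterozygosity(rep(0L, 10)), 0)
  expect_equal(interspecific_heterozygosity(rep(2L, 10)), 0)
  expect_equal(interspecific_heterozygosity(c(1L, 1L, 0L, 2L, NA)), 0.5)
  expect_true(is.na(interspecific_heterozygosity(c(NA_integer_, NA))))
})

test_that("classification follows the h/H rules of the hybrid-class scheme", {
  expect_equal(as.character(classify_hybrid(0.5, 0.9)), "F1")
  expect_equal(as.character(classify_hybrid(0.1, 0.2)), "BACKCROSS_A")
  expect_equal(as.character(classify_hybrid(1, 0)), "PURE_B")
  expect_equal(as.character(classify_hybrid(0, 0)), "PURE_A")
  expect_equal(as.character(classify_hybrid(0.5, 0.3)), "MULTIGEN")
  # boundary h resolves to the backcross class
  expect_equal(as.character(classify_hybrid(0.25, 0.3)), "BACKCROSS_A")
  expect_equal(as.character(classify_hybrid(0.75, 0.3)), "BACKCROSS_B")
  # high heterozygosity outside the window is F1-like with a boundary flag
  high <- classify_hybrid(0.2, 0.9)
  expect_equal(as.character(high), "F1")
  expect_true(attr(high, "boundary"))
  expect_false(attr(classify_hybrid(0.5, 0.9), "boundary"))
})

test_that("classification is a total partition of the unit square", {
  hs <- seq(0, 1, length.out = 101)
  het <- seq(0, 1, length.out = 101)
  classes <- character(0)
  for (h in hs) for (H in het) {
    cls <- as.character(classify_hybrid(h, H))
    expect_length(cls, 1)
    classes <- union(classes, cls)
  }
  expect_setequal(classes, c("PURE_A", "BACKCROSS_A", "MULTIGEN", "F1",
                             "BACKCROSS_B", "PURE_B"))
})

test_that("simulated pedigree classes recover their expected h and H", {
  cfg <- sim_config(n_loci = 50, frac_fixed = 1, frac_strong = 0,
                    n_parental_A = 20, n_parental_B = 20,
                    class_counts = c(F1 = 50, F2 = 50, BC1_B = 100),
                    missing_rate = 0, seed = 77)
  sim <- simulate_hybridzone(cfg)
  fr <- estimate_parental_freqs(sim$gm)
  pol <- polarize(sim$gm, fr, select_differentiated(
    allele_freq_differential(fr), 1))
  adm <- group_samples(sim$gm, "ADMIXED_CANDIDATE")
  anc <- estimate_ancestry(pol, adm)
  tr <- sim$truth[match(adm, sim$truth$sample_id), ]

  # F1: h = 0.5 exactly, H = 1
  f1 <- anc[tr$class == "F1", ]
  expect_true(all(f1$h == 0.5))
  expect_true(all(f1$het == 1))
  # BC1 to B: mean h within 3 MC SEs of 0.75 (per-locus variance p(1-p)/2L
  # per individual; SE of the mean over m individuals)
  bc <- anc[tr$class == "BC1_B", ]
  se <- sqrt(0.75 * 0.25 / (2 * 50) / nrow(bc))
  expect_lt(abs(mean(bc$h) - 0.75), 3 * se)
  expect_gt(mean(bc$hybrid_class == "BACKCROSS_B"), 0.5)
  # F2: mean H within 3 MC SEs of 0.5
  f2 <- anc[tr$class == "F2", ]
  se_h <- sqrt(0.5 * 0.5 / 50 / nrow(f2))
  expect_lt(abs(mean(f2$het) - 0.5), 3 * se_h)

  # triangle constraint at fixed loci: H <= 2 min(h, 1-h)
  expect_true(all(anc$het <= 2 * pmin(anc$h, 1 - anc$h) + 1e-9))
})

test_that("estimates equal the counting estimator for parental references", {
  cfg <- sim_config(n_loci = 50, frac_fixed = 1, frac_strong = 0,
                    n_parental_A = 10, n_parental_B = 10,
                    class_counts = c(F1 = 2), missing_rate = 0, seed = 3)
  sim <- simulate_hybridzone(cfg)
  fr <- estimate_parental_freqs(sim$gm)
  pol <- polarize(sim$gm, fr, sim$fixed_ids)
  anc <- estimate_ancestry(pol)
  a_rows <- anc$sample_id %in% group_samples(sim$gm, "PARENTAL_A")
  b_rows <- anc$sample_id %in% group_samples(sim$gm, "PARENTAL_B")
  expect_true(all(anc$h[a_rows] == 0))
  expect_true(all(anc$h[b_rows] == 1))
  expect_identical(anc$hybrid_class[a_rows], rep("PURE_A", sum(a_rows)))
})
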
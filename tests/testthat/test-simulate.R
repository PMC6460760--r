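# The synthetic hybrid-zone generator: determinism, Mendelian mechanics and
# the statistical structure downstream stages assume.

test_that("simulation is a pure function of its config", {
  cfg <- sim_config(n_loci = 80, seed = 500)
  s1 <- simulate_hybridzone(cfg)
  s2 <- simulate_hybridzone(cfg)
  expect_identical(s1$gm$calls, s2$gm$calls)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$plumage, s2$plumage)
  expect_identical(simulate_parental_freqs(cfg), simulate_parental_freqs(cfg))
  s3 <- simulate_hybridzone(sim_config(n_loci = 80, seed = 501))
  expect_false(identical(s1$gm$calls, s3$gm$calls))
  expect_error(sim_config(n_loci = 10), "seed")
})

test_that("true frequencies have the configured delta structure", {
  cfg <- sim_config(n_loci = 400, frac_fixed = 0.1, frac_strong = 0.15,
                    seed = 510)
  fr <- simulate_parental_freqs(cfg)
  expect_equal(sum(fr$locus_class == "fixed"), 40)
  expect_true(all(fr$delta_true[fr$locus_class == "fixed"] == 1))
  expect_true(all(fr$delta_true[fr$locus_class == "strong"] >= 0.8))
  expect_true(all(fr$delta_true[fr$locus_class == "weak"] < 0.8))
  # all-fixed degenerate config
  all_fixed <- simulate_parental_freqs(
    sim_config(n_loci = 30, frac_fixed = 1, frac_strong = 0, seed = 1))
  expect_true(all(all_fixed$delta_true == 1))
})

test_that("sampled parental genotypes follow HWE and the missing rate", {
  cfg <- sim_config(n_loci = 500, frac_fixed = 0, frac_strong = 0,
                    diff_beta_params = c(1, 1), seed = 520)
  fr <- simulate_parental_freqs(cfg)
  calls <- sample_parental_genotypes(fr, 50, "A", missing_rate = 0.2,
                                     seed = 521)
  miss <- mean(is.na(calls))
  ci <- qbinom(c(0.005, 0.995), length(calls), 0.2) / length(calls)
  expect_gt(miss, ci[1]); expect_lt(miss, ci[2])
  # heterozygosity near 2p(1-p) at mid-frequency loci
  mid <- which(abs(fr$p_a - 0.5) < 0.05)
  het <- mean(calls[, mid] == 1L, na.rm = TRUE)
  expect_lt(abs(het - 0.5), 0.05)
  # fixed loci on side A are all reference homozygotes
  frf <- simulate_parental_freqs(
    sim_config(n_loci = 50, frac_fixed = 1, seed = 522))
  expect_true(all(sample_parental_genotypes(frf, 10, "A", seed = 1) == 0L))
  expect_true(all(sample_parental_genotypes(frf, 10, "B", seed = 1) == 2L))
})

test_that("breeding is Mendelian with optional transmission distortion", {
  frf <- simulate_parental_freqs(
    sim_config(n_loci = 200, frac_fixed = 1, seed = 530))
  pa <- hzadmix:::.new_parental(frf, "A")
  pb <- hzadmix:::.new_parental(frf, "B")
  f1 <- breed(pa, pb, seed = 531)
  # F1 at fixed loci: heterozygous everywhere, ancestry exactly 1/2
  expect_true(all(f1$a[1, ] + f1$a[2, ] == 1L))
  expect_equal(mean(f1$o), 0.5)

  # offspring alleles are a subset of parental alleles at every locus
  f2 <- breed(f1, f1, seed = 532)
  for (l in seq_len(50)) {
    expect_true(all(f2$a[, l] %in% c(f1$a[, l])))
  }

  # b = +0.5 forces transmission of the B-origin allele from heterozygotes
  forced <- breed(f1, f1, bias = 0.5, seed = 533)
  expect_true(all(forced$a[1, ] + forced$a[2, ] == 2L))
  expect_equal(mean(forced$o), 1)
})

test_that("pedigree classes realize their expected ancestry and truth table", {
  cfg <- sim_config(n_loci = 50, frac_fixed = 1, frac_strong = 0,
                    class_counts = c(F1 = 100, BC1_B = 200, MULTIGEN_3 = 10),
                    missing_rate = 0, seed = 540)
  out <- simulate_class_sample(cfg)
  expect_equal(nrow(out$truth), 310)
  expect_equal(nrow(out$calls), 310)

  f1 <- out$truth[out$truth$class == "F1", ]
  expect_true(all(f1$ancestry_true == 0.5))
  expect_true(all(f1$het_true == 1))

  bc <- out$truth[out$truth$class == "BC1_B", ]
  se <- sqrt(0.75 * 0.25 / (2 * 50) / nrow(bc))
  expect_lt(abs(mean(bc$ancestry_true) - 0.75), 3 * se)

  mg <- out$truth[out$truth$class == "MULTIGEN_3", ]
  expect_true(all(mg$ancestry_true > 0 & mg$ancestry_true < 1))
})

test_that("empirical delta tracks true delta at moderate parental sizes", {
  cfg <- sim_config(n_loci = 300, frac_fixed = 0.1, frac_strong = 0.2,
                    n_parental_A = 50, n_parental_B = 50,
                    class_counts = c(F1 = 2), missing_rate = 0, seed = 550)
  sim <- simulate_hybridzone(cfg)
  fr <- estimate_parental_freqs(sim$gm)
  d <- allele_freq_differential(fr)
  err <- abs(d$delta - sim$freqs_true$delta_true)
  expect_gte(mean(err <= 0.1), 0.95)
})

test_that("plumage is monotone in ancestry with trait-specific noise", {
  # zero noise: scores are the exact deterministic map of ancestry
  cfg0 <- sim_config(n_loci = 20, frac_fixed = 1, plumage_noise_sd = 0,
                     class_counts = c(F1 = 3, PURE_B = 2), seed = 560)
  tr <- data.frame(sample_id = c("x", "y"), ancestry_true = c(0.5, 1))
  rec <- simulate_plumage(tr, cfg0)
  expect_identical(unlist(rec[1, c("head", "cheek_patch", "chest",
                                   "upper_abdomen", "lower_abdomen", "rump")],
                          use.names = FALSE),
                   c(2L, 1L, 2L, 2L, 2L, 2L))
  expect_identical(unlist(rec[2, c("head", "cheek_patch", "chest",
                                   "upper_abdomen", "lower_abdomen", "rump")],
                          use.names = FALSE),
                   c(4L, 2L, 4L, 4L, 4L, 4L))

  # noise 0.1, n = 200: plumage hybrid index tracks ancestry (Spearman)
  cfg <- sim_config(n_loci = 20, frac_fixed = 1, plumage_noise_sd = 0.1,
                    class_counts = c(PURE_A = 40, BC1_A = 40, F2 = 40,
                                     BC1_B = 40, PURE_B = 40),
                    missing_rate = 0, seed = 561)
  out <- simulate_class_sample(cfg)
  rec <- simulate_plumage(out$truth, cfg, seed = 562)
  hi <- plumage_hybrid_index(rec)$plumage_hi
  rho <- cor(hi, out$truth$ancestry_true, method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("geography places intermediates inside the planted zone", {
  cfg <- sim_config(n_loci = 20, frac_fixed = 1, plumage_noise_sd = 0.05,
                    lat_range = c(-30, -28), lon_range = c(150, 152),
                    class_counts = c(PURE_A = 15, F1 = 6, F2 = 10,
                                     PURE_B = 15),
                    missing_rate = 0, seed = 570)
  sim <- simulate_hybridzone(cfg)
  expect_identical(sim$plumage,
                   simulate_hybridzone(cfg)$plumage)  # same seed, same coords
  # pure A reference individuals sit at the northern end
  pa_lat <- sim$plumage$latitude[sim$truth$class == "PURE_A" &
                                   grepl("^PA", sim$truth$sample_id)]
  expect_true(all(pa_lat > -28.8))
  # end to end: the plumage zone profile recovers an in-range band
  hi <- plumage_hybrid_index(sim$plumage)
  zp <- zone_profile(hi)
  expect_true(zp$zone_lat_bounds[1] >= -30 - 1e-9)
  expect_true(zp$zone_lat_bounds[2] <= -28 + 1e-9)
  expect_gte(zp$n_intermediate, 5)
})
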
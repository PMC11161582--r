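test_that("models are pure functions of their seed", {
  m1 <- simulate_model(4, 3, seed = 11)
  m2 <- simulate_model(4, 3, seed = 11)
  expect_identical(m1, m2)
  t1 <- simulate_genotypes(m1, c(P01 = 10, P02 = 10), seed = 5)
  t2 <- simulate_genotypes(m2, c(P01 = 10, P02 = 10), seed = 5)
  expect_identical(t1$a1, t2$a1)
})

test_that("private alleles are injected at the stated frequency, nowhere else", {
  spec <- data.frame(pop = "P02", locus = "L01", allele = 999L, freq = 0.3)
  m <- simulate_model(3, 2, private_spec = spec, seed = 2)
  expect_equal(m$freqs$P02$L01[["999"]], 0.3)
  expect_false("999" %in% names(m$freqs$P01$L01))
  expect_false("999" %in% names(m$freqs$P03$L01))
  for (p in m$pops) for (l in m$loci)
    expect_equal(sum(m$freqs[[p]][[l]]), 1, tolerance = 1e-12)
  expect_error(simulate_model(2, 2, private_spec = transform(spec, freq = 1)),
               "< 1")
})

test_that("high concentration collapses differentiation", {
  m <- simulate_model(5, 4, concentration = 1e7, seed = 3)
  spread <- sapply(m$loci, function(l)
    max(abs(m$freqs$P01[[l]] - m$freqs$P05[[l]])))
  expect_lt(max(spread), 0.01)
})

test_that("f controls homozygosity: f = 1 all homozygous, f = 0 near HWE", {
  m1 <- simulate_model(1, 5, f = 1, seed = 4)
  t1 <- simulate_genotypes(m1, c(P01 = 40), seed = 4)
  expect_true(all(t1$a1 == t1$a2))
  m0 <- simulate_model(1, 1, alleles_per_locus = 2, concentration = 1e7,
                       f = 0, seed = 5)
  m0$freqs$P01$L01[] <- c(0.5, 0.5)
  t0 <- simulate_genotypes(m0, c(P01 = 2000), seed = 6)
  ho <- mean(t0$a1 != t0$a2)
  expect_lt(abs(ho - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("both Wahlund mechanisms produce a heterozygote deficit", {
  m <- simulate_model(1, 10, f = 0.2, concentration = 50, seed = 7)
  tw <- simulate_genotypes(m, c(P01 = 300), seed = 8,
                           mechanism = "wahlund")
  fw <- fis_test(tw, list(P01 = sample_ids(tw)), n_randomizations = 0)$f
  expect_gt(fw, 0.05)
})

test_that("market sampling follows the mixture and keeps the truth", {
  m <- simulate_model(3, 4, seed = 9)
  sp <- market_spec("M", c(P01 = 1), 25)
  mk <- simulate_market(m, sp, seed = 10)
  expect_true(all(mk$meta$true_source == "P01"))
  expect_true(all(mk$meta$class == "market"))
  expect_equal(n_ind(simulate_market(m, market_spec("M", c(P01 = 1), 0))), 0L)
  # multinomial envelope at 1000 draws, weights 0.7 / 0.3 (99% two-sided)
  sp2 <- market_spec("M", c(P01 = 0.7, P02 = 0.3), 1000)
  mk2 <- simulate_market(m, sp2, seed = 11)
  n1 <- sum(mk2$meta$true_source == "P01")
  expect_true(n1 >= qbinom(0.005, 1000, 0.7) &&
                n1 <= qbinom(0.995, 1000, 0.7))
})

test_that("corrupt_genotypes injects duplicates, missingness and nulls", {
  m <- simulate_model(1, 8, f = 0, seed = 12)
  tab <- simulate_genotypes(m, c(P01 = 50), seed = 13)
  # duplicates only: table unchanged apart from the copies
  dup <- corrupt_genotypes(tab, duplicate_rate = 0.04, seed = 14)
  expect_equal(n_ind(dup), 52L)
  pairs <- find_matches(dup, max_mismatch_loci = 0, min_shared_loci = 8)
  expect_equal(nrow(pairs), 2L)
  expect_identical(dup$a1[1:50, ], tab$a1)
  # missingness rate is respected
  mis <- corrupt_genotypes(tab, missing_rate = 0.2, seed = 15)
  expect_lt(abs(mean(is.na(mis$a1)) - 0.2), 3 * sqrt(0.16 / 400))
})

test_that("null alleles bias Ho down and Brookfield-1 recovers the rate", {
  m <- simulate_model(1, 1, alleles_per_locus = 6, concentration = 1e6,
                      f = 0, seed = 16)
  tab <- simulate_genotypes(m, c(P01 = 500), seed = 17)
  nul <- corrupt_genotypes(tab,
                           null_allele_spec = data.frame(locus = "L01",
                                                         freq = 0.15),
                           seed = 18)
  est <- null_alleles(nul, sample_ids(nul), "L01", n_mc = 200, seed = 19)
  expect_lt(abs(est$brookfield1 - 0.15), 0.05)
  expect_gt(est$chakraborty, 0)
})
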
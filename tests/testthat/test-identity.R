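test_that("find_matches honours the mismatch budget and missing data", {
  tab <- tiny_table(list(L1 = rbind(c(100, 102), c(100, 102), c(100, 104)),
                         L2 = rbind(c(106, 106), c(106, 106), c(106, 106)),
                         L3 = rbind(c(108, 110), c(NA, NA), c(108, 110))),
                    pop = rep("A", 3))
  m0 <- find_matches(tab, max_mismatch_loci = 0, min_shared_loci = 2)
  expect_equal(nrow(m0), 1L)  # i1-i2 match (L3 missing never mismatches)
  expect_setequal(c(m0$id1, m0$id2), c("i1", "i2"))
  m1 <- find_matches(tab, max_mismatch_loci = 1, min_shared_loci = 2)
  expect_equal(nrow(m1), 3L)  # one locus of slack matches every pair
  expect_error(find_matches(tab, min_shared_loci = 4), "exceeds")
  # symmetric in individual order
  perm <- tab[c(3, 1, 2), ]
  mp <- find_matches(perm, max_mismatch_loci = 0, min_shared_loci = 2)
  expect_equal(nrow(mp), 1L)
  expect_setequal(c(mp$id1, mp$id2), c("i1", "i2"))
})

test_that("eleven injected duplicate pairs are all recovered", {
  m <- simulate_model(2, 20, f = 0.1, seed = 71)
  tab <- simulate_genotypes(m, c(P01 = 270, P02 = 280), seed = 72)
  dup <- corrupt_genotypes(tab, duplicate_rate = 0.02, seed = 73)
  expect_equal(n_ind(dup) - n_ind(tab), 11L)
  found <- find_matches(dup, max_mismatch_loci = 0, min_shared_loci = 15)
  expect_equal(nrow(found), 11L)
})

test_that("pgen and psex follow their formulas", {
  tab <- hwe_table(100, c(`100` = .5, `102` = .5), seed = 81)
  af <- allele_counts(tab)
  g_het <- list(L1 = c(100, 102))
  expect_equal(pgen(g_het, af, "A", f = 0),
               2 * prod(af_freq(af, "A", "L1")))
  g_hom <- list(L1 = c(100, 100))
  p <- af_freq(af, "A", "L1")[["100"]]
  expect_equal(pgen(g_hom, af, "A", f = 0.2), p^2 + 0.2 * p * (1 - p))
  expect_equal(psex(0.5, 2), 0.5)
  expect_warning(p0 <- psex(0.5, 1), "n < 2")
  expect_equal(p0, 0)
  # unseen allele gets the floor 1/(2N + 1)
  g_new <- list(L1 = c(999, 999))
  expect_equal(pgen(g_new, af, "A"), (1 / 201)^2)
})

test_that("psex matches the Monte-Carlo chance of a repeat genotype", {
  pg <- 2 * .6 * .4  # pgen of the het genotype under p = (0.6, 0.4)
  n <- 6
  set.seed(83)
  reps <- 20000
  # direct simulation: n-1 other individuals, P(at least one equals the het)
  hits <- replicate(reps, {
    a <- matrix(sample(c(100, 102), 2 * (n - 1), TRUE, c(.6, .4)), ncol = 2)
    any(apply(a, 1, function(g) all(sort(g) == c(100, 102))))
  })
  expect_lt(abs(mean(hits) - psex(pg, n)), 3 * sqrt(0.25 / reps))
})

test_that("PI indices match hand values and the sibling bound", {
  pf <- c(`100` = .5, `102` = .5)
  v <- pangotrace:::pi_locus(pf, n = 100)
  expect_equal(v[["PI"]], 0.375)       # 2(0.0625) + 0.25
  expect_equal(v[["PIsibs"]], 0.59375) # 0.25 + 0.25 + 0.125 - 0.03125
  # uPI -> PI as n grows
  v_big <- pangotrace:::pi_locus(pf, n = 1e5)
  expect_lt(abs(v_big[["uPI"]] - v_big[["PI"]]) / v_big[["PI"]], 1e-3)
  # sibling bound holds for arbitrary frequency vectors
  set.seed(84)
  for (r in 1:25) {
    p <- as.numeric(pangotrace:::rdirichlet(1, rep(0.8, sample(2:8, 1))))
    w <- pangotrace:::pi_locus(p, n = 50)
    expect_gte(w[["PIsibs"]] + 1e-12, w[["PI"]])
    expect_gte(w[["PIsibs"]] + 1e-12, w[["uPI"]])
  }
})

test_that("cumulative indices shrink with added loci; uPI needs n >= 4", {
  tab <- hwe_table(30, c(`100` = .4, `102` = .35, `104` = .25), n_loci = 5,
                   seed = 85)
  pi <- probability_of_identity(allele_counts(tab), "A")
  expect_equal(nrow(pi$per_locus), 5L)
  cp <- cumprod(pi$per_locus$PI)
  expect_true(all(diff(cp) <= 0))
  expect_equal(pi$cumulative[["PI"]], prod(pi$per_locus$PI))
  small <- hwe_table(1, c(`100` = .5, `102` = .5), seed = 86)
  pi_small <- probability_of_identity(allele_counts(small), "A")
  expect_true(is.na(pi_small$per_locus$uPI))  # < 4 gene copies
})

test_that("min_loci_for_pi reproduces the five-locus threshold", {
  # all per-locus PI = 0.375: 0.375^5 ~ 0.0074 < 0.01 but 0.375^4 > 0.01
  expect_equal(min_loci_for_pi(rep(0.375, 20), 0.01), 5L)
  expect_equal(min_loci_for_pi(c(0.5, 0.375), 1), 1L)
  expect_true(is.na(min_loci_for_pi(0.5, 0.01)))
})
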
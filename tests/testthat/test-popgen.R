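test_that("diversity reproduces textbook values on toy configurations", {
  # one locus, genotypes {het, hom}: Ho = 0.5; p = (0.75, 0.25) so
  # He = 1 - (0.5625 + 0.0625) = 0.375; uHe = (4/3) He at n = 2
  tab <- tiny_table(list(L1 = rbind(c(100, 102), c(100, 100))), pop = c("A", "A"))
  d <- diversity(tab)$summary
  expect_equal(d$Ho, 0.5)
  expect_equal(d$He, 0.375)
  expect_equal(d$uHe, 4 / 3 * 0.375)
  # equifrequent het/hom case: Ho = He = 0.5
  tab2 <- tiny_table(list(L1 = rbind(c(100, 102), c(100, 102))), pop = c("A", "A"))
  d2 <- diversity(tab2)$summary
  expect_equal(d2$Ho, 1)
  expect_equal(d2$He, 0.5)
  # monomorphic locus
  tab3 <- tiny_table(list(L1 = rbind(c(100, 100), c(100, 100))), pop = c("A", "A"))
  d3 <- diversity(tab3)$summary
  expect_equal(d3$Ho, 0)
  expect_equal(d3$He, 0)
  expect_equal(d3$Na, 1)
})

test_that("uHe >= He always, approaching equality for large n", {
  set.seed(31)
  for (r in 1:20) {
    pf <- as.numeric(pangotrace:::rdirichlet(1, rep(1, 4)))
    names(pf) <- c(100, 102, 104, 106)
    tab <- hwe_table(10, pf, seed = r)
    d <- diversity(tab)$by_locus
    expect_gte(d$uHe + 1e-12, d$He)
  }
  big <- diversity(hwe_table(5000, c(`100` = .5, `102` = .5), seed = 1))
  expect_lt(big$summary$uHe - big$summary$He, 1e-3)
})

test_that("allelic richness equals the enumeration oracle and its limits", {
  tab <- tiny_table(list(L1 = rbind(c(100, 100), c(102, 102))), pop = c("A", "A"))
  af <- allele_counts(tab)
  # counts {A:2, B:2}, g = 2: enumerate all C(4,2) = 6 subsets -> 5/3
  expect_equal(allelic_richness(af, g = 2)$A_R["A", "L1"], 5 / 3)
  # g = N recovers the observed allele count
  expect_equal(allelic_richness(af, g = 4)$A_R["A", "L1"], 2)
  # single allele: A_R = 1 for any g
  mono <- tiny_table(list(L1 = rbind(c(100, 100), c(100, 100))), pop = c("A", "A"))
  expect_equal(allelic_richness(allele_counts(mono), g = 2)$A_R["A", "L1"], 1)
  expect_error(allelic_richness(af, g = 1), ">= 2")
  expect_error(allelic_richness(af, g = 6), "exceeds")
})

test_that("A_R never exceeds Na and matches brute force on random counts", {
  set.seed(77)
  tab <- hwe_table(4, c(`100` = .4, `102` = .3, `104` = .2, `106` = .1),
                   n_loci = 4, seed = 7)
  af <- allele_counts(tab)
  ar <- allelic_richness(af, g = 3)
  for (l in af$loci) {
    expect_lte(ar$A_R["A", l], length(af$counts$A[[l]]))
    oracle <- brute_rarefaction(af$counts, l, "A", 3)
    expect_equal(ar$A_R["A", l], oracle$distinct, tolerance = 1e-12)
  }
})

test_that("Weir-Cockerham f hits the maximal-excess bound and recovers truth", {
  # all individuals heterozygous A/B -> f = -1
  tab <- tiny_table(list(L1 = rbind(c(100, 102), c(100, 102), c(100, 102))),
                    pop = rep("A", 3))
  expect_equal(fis_test(tab, n_randomizations = 0)$f, -1)
  # all loci monomorphic -> undefined
  mono <- tiny_table(list(L1 = rbind(c(100, 100), c(100, 100))), pop = c("A", "A"))
  expect_true(is.na(fis_test(mono, n_randomizations = 0)$f))
  # f = 0.2 recovered within +-0.05 at n = 500 (also an acceptance check)
  m <- simulate_model(1, 10, f = 0.2, concentration = 1e6, seed = 21)
  tab2 <- simulate_genotypes(m, c(P01 = 500), seed = 22)
  f_hat <- fis_test(tab2, n_randomizations = 0)$f
  expect_lt(abs(f_hat - 0.2), 0.05)
})

test_that("HWE chi-square matches hand-computed statistics", {
  # perfect HWE counts AA 25 / Aa 50 / aa 25 -> chi2 = 0, p = 1
  calls <- rbind(matrix(rep(c(100, 100), 25), ncol = 2, byrow = TRUE),
                 matrix(rep(c(100, 102), 50), ncol = 2, byrow = TRUE),
                 matrix(rep(c(102, 102), 25), ncol = 2, byrow = TRUE))
  tab <- tiny_table(list(L1 = calls), pop = rep("A", 100))
  h <- hwe_test(tab, sample_ids(tab), "L1")
  expect_equal(h$statistic, 0)
  expect_equal(h$p, 1)
  # AA 50 / aa 50: expected 25/50/25 -> chi2 = 100, p < 1e-20
  calls2 <- rbind(matrix(rep(c(100, 100), 50), ncol = 2, byrow = TRUE),
                  matrix(rep(c(102, 102), 50), ncol = 2, byrow = TRUE))
  tab2 <- tiny_table(list(L1 = calls2), pop = rep("A", 100))
  h2 <- hwe_test(tab2, sample_ids(tab2), "L1")
  expect_equal(h2$statistic, 100)
  expect_lt(h2$p, 1e-20)
  # exact MC agrees with chi2 on a large balanced sample
  tab3 <- hwe_table(300, c(`100` = .5, `102` = .5), seed = 33)
  p_chi <- hwe_test(tab3, sample_ids(tab3), "L1")$p
  p_mc <- hwe_test(tab3, sample_ids(tab3), "L1", method = "exact_mc",
                   n_mc = 1000, seed = 34)$p
  expect_lt(abs(p_chi - p_mc), 0.12)
  expect_warning(hwe_test(tiny_table(list(L1 = rbind(c(100, 100), c(100, 100))),
                                     pop = c("A", "A")),
                          c("i1", "i2"), "L1"), "monomorphic")
})

test_that("LD test flags a locus paired with itself and rejects bad input", {
  set.seed(41)
  tab <- hwe_table(40, c(`100` = .5, `102` = .3, `104` = .2), n_loci = 1,
                   seed = 42)
  dup <- genotype_table(cbind(L1 = tab$a1[, 1], L2 = tab$a1[, 1]),
                        cbind(L1 = tab$a2[, 1], L2 = tab$a2[, 1]),
                        tab$meta)
  r <- ld_test(dup, sample_ids(dup), c("L1", "L2"), n_randomizations = 99,
               seed = 43)
  expect_lte(r$p, 1 / 100)
  expect_error(ld_test(dup, sample_ids(dup), c("L1", "L2"),
                       n_randomizations = 0), "positive")
})

test_that("null-allele estimators follow their defining formulas", {
  # He = 0.5, Ho = 0.4: Chakraborty = 0.1111, Brookfield1 = 0.0667
  # build 50 genotypes: 20 het, 30 hom with allele freqs (0.5, 0.5)
  calls <- rbind(matrix(rep(c(100, 102), 20), ncol = 2, byrow = TRUE),
                 matrix(rep(c(100, 100), 15), ncol = 2, byrow = TRUE),
                 matrix(rep(c(102, 102), 15), ncol = 2, byrow = TRUE))
  tab <- tiny_table(list(L1 = calls), pop = rep("A", 50))
  est <- null_alleles(tab, sample_ids(tab), "L1", n_mc = 100, seed = 44)
  expect_equal(est$He, 0.5)
  expect_equal(est$Ho, 0.4)
  expect_equal(est$chakraborty, 0.1 / 0.9, tolerance = 1e-12)
  expect_equal(est$brookfield1, 0.1 / 1.5, tolerance = 1e-12)
  # Ho = He -> both zero (25/50/25 has Ho = He = 0.5)
  calls2 <- rbind(matrix(rep(c(100, 100), 25), ncol = 2, byrow = TRUE),
                  matrix(rep(c(100, 102), 50), ncol = 2, byrow = TRUE),
                  matrix(rep(c(102, 102), 25), ncol = 2, byrow = TRUE))
  tab2 <- tiny_table(list(L1 = calls2), pop = rep("A", 100))
  est2 <- null_alleles(tab2, sample_ids(tab2), "L1", n_mc = 50, seed = 45)
  expect_equal(est2$chakraborty, 0)
  expect_equal(est2$brookfield1, 0)
})

test_that("theta = 1 at fixation, ~0 within one population, label-invariant", {
  fixed <- tiny_table(list(L1 = rbind(c(100, 100), c(100, 100),
                                      c(102, 102), c(102, 102))),
                      pop = c("A", "A", "B", "B"))
  fst <- pairwise_fst(fixed, n_permutations = 0)
  expect_equal(fst$theta["A", "B"], 1)
  # relabeling alleles leaves theta unchanged
  relab <- tiny_table(list(L1 = rbind(c(300, 300), c(300, 300),
                                      c(118, 118), c(118, 118))),
                      pop = c("A", "A", "B", "B"))
  expect_equal(pairwise_fst(relab, n_permutations = 0)$theta["A", "B"], 1)
  # two samples from one panmictic population: theta near 0, p not small
  tab <- hwe_table(120, c(`100` = .4, `102` = .3, `104` = .3), n_loci = 6,
                   seed = 51)
  part <- list(X = sample_ids(tab)[1:60], Y = sample_ids(tab)[61:120])
  fst0 <- pairwise_fst(tab, part, n_permutations = 199, seed = 52)
  expect_lt(abs(fst0$theta["X", "Y"]), 0.02)
  expect_gt(fst0$p["X", "Y"], 0.05)
})

test_that("theta recovers the model-expected differentiation", {
  # Dirichlet concentration 19 -> expected theta 0.05 (also acceptance)
  m <- simulate_model(2, 20, concentration = 19, f = 0, seed = 53)
  tab <- simulate_genotypes(m, c(P01 = 200, P02 = 200), seed = 54)
  th <- pairwise_fst(tab, n_permutations = 0)$theta["P01", "P02"]
  expect_lt(abs(th - expected_fst(19)), 0.02)
})

test_that("Mantel test recovers perfect correlation and hand Pearson", {
  g <- matrix(0, 3, 3)
  g[lower.tri(g)] <- c(1, 2, 3)
  g <- g + t(g)
  expect_equal(mantel_ibd(g, g, n_permutations = 10, seed = 1)$r, 1)
  h <- matrix(0, 3, 3)
  h[lower.tri(h)] <- c(1, 2, 3.5)
  h <- h + t(h)
  r <- mantel_ibd(g, h, n_permutations = 10, seed = 1)$r
  expect_equal(r, cor(c(1, 2, 3), c(1, 2, 3.5)))
  expect_error(mantel_ibd(matrix(1, 3, 3), h, 10), "constant")
})

test_that("Edwards chord distance is metric-like and drives IBD detection", {
  m <- simulate_model(6, 12, concentration = 15, ibd_strength = 0.9,
                      f = 0.1, seed = 61)
  tab <- simulate_genotypes(m, stats::setNames(rep(15, 6), m$pops), seed = 62)
  d <- edwards_distance(tab)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[!is.na(d)] >= 0))
  geo <- geo_dist_matrix(tab)
  ibd <- mantel_ibd(d, geo, n_permutations = 199, seed = 63)
  expect_gt(ibd$r, 0)
  expect_lt(ibd$p, 0.05)
  # agrees with vegan's Mantel statistic on the same matrices
  vr <- suppressWarnings(vegan::mantel(as.dist(d), as.dist(geo),
                                       permutations = 99))$statistic
  expect_equal(ibd$r, unname(vr), tolerance = 1e-10)
})
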
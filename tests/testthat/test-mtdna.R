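make_aln <- function(seqs) {
  do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
}

test_that("haplotype collapsing groups identical sequences, strict policy", {
  aln <- make_aln(list(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGA"))
  h <- collapse_haplotypes(aln)
  expect_equal(nrow(h$haplotypes), 2L)
  expect_setequal(h$members$H1, c("a", "b", "c"))
  # strict policy drops ambiguity
  aln2 <- make_aln(list(a = "ACGT", b = "ACNT", c = "ACGA"))
  h2 <- collapse_haplotypes(aln2)
  expect_equal(h2$dropped, "b")
  expect_equal(nrow(h2$haplotypes), 2L)
  h2k <- collapse_haplotypes(aln2, missing_policy = "keep")
  expect_equal(length(h2k$assignment), 3L)
  # order invariance: same partition of sequence IDs (labels may differ)
  h3 <- collapse_haplotypes(aln[c(4, 2, 3, 1), ])
  part <- function(hs) sort(vapply(hs$members, function(m)
    paste(sort(m), collapse = "+"), character(1)))
  expect_equal(unname(part(h3)), unname(part(h)))
})

test_that("diversity statistics match hand-computed values", {
  # 4 sequences, 2 haplotypes at 2/2: Hd = (4/3)(1 - 0.5) = 2/3
  aln <- make_aln(list(a = "AAAA", b = "AAAA", c = "AAAT", d = "AAAT"))
  d <- diversity_stats(aln)
  expect_equal(d$Hd, 2 / 3)
  expect_equal(d$S, 1L)
  expect_equal(d$h, 2L)
  # all unique -> Hd = 1
  aln2 <- make_aln(list(a = "AAAA", b = "AAAT", c = "AATT"))
  expect_equal(diversity_stats(aln2)$Hd, 1)
  # two 402-bp sequences differing at one site: pi = 1/402
  s <- paste(rep("A", 402), collapse = "")
  s2 <- sub("^A", "T", s)
  expect_equal(diversity_stats(make_aln(list(a = s, b = s2)))$pi, 1 / 402)
  expect_error(diversity_stats(make_aln(list(a = "AAAA"))), ">= 2")
})

test_that("K2P distance follows its closed form and matches ape", {
  expect_equal(k2p_from_pq(0, 0), 0)
  expect_equal(k2p_from_pq(0.1, 0.05),
               -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_equal(round(k2p_from_pq(0.1, 0.05), 4), 0.1702)
  expect_equal(k2p_from_pq(0.5, 0.3), Inf)  # saturated pair flagged
  # identical sequences at distance zero; symmetry; K2P >= p-distance
  sim <- simulate_mtdna(n_per_lineage = c(6, 6), seq_length = 300,
                        mutations_per_seq = 4, seed = 111)
  D <- k2p_matrix(sim$alignment)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  P <- pangotrace:::pairwise_differences(sim$alignment) / 300
  expect_true(all(D + 1e-12 >= P))
  ape_d <- as.matrix(ape::dist.dna(ape::as.DNAbin(sim$alignment),
                                   model = "K80",
                                   pairwise.deletion = TRUE))
  expect_equal(unname(D), unname(ape_d), tolerance = 1e-10)
})

test_that("NJ tree separates simulated lineages with strong support", {
  sim <- simulate_mtdna(n_per_lineage = c(8, 8), n_fixed_diff = 23,
                        mutations_per_seq = 1, seed = 112)
  tr <- nj_tree(sim$alignment, n_bootstrap = 50, seed = 113)
  expect_s3_class(tr$tree, "phylo")
  expect_match(tr$newick, "^\\(")
  # the A lineage forms a clade: its tips share an exclusive ancestor
  phy <- ape::root(tr$tree, outgroup = names(sim$lineage)[sim$lineage == "B"][1],
                   resolve.root = TRUE)
  a_tips <- names(sim$lineage)[sim$lineage == "A"]
  expect_true(ape::is.monophyletic(phy, a_tips))
})

test_that("lineage assignment is exact on divergent lineages, ties flagged", {
  sim <- simulate_mtdna(n_per_lineage = c(15, 15), n_fixed_diff = 23,
                        mutations_per_seq = 2, seed = 114)
  ids <- names(sim$lineage)
  query_ids <- c(sample(ids[sim$lineage == "A"], 4),
                 sample(ids[sim$lineage == "B"], 2))
  ref_ids <- setdiff(ids, query_ids)
  res <- assign_lineage(sim$alignment[query_ids, , drop = FALSE],
                        sim$alignment[ref_ids, , drop = FALSE],
                        sim$lineage[ref_ids])
  expect_equal(res$lineage, unname(sim$lineage[query_ids]))
  # short query: unassigned with diagnostic
  short <- sim$alignment[query_ids[1], , drop = FALSE]
  short[, 60:402] <- "N"
  res2 <- assign_lineage(short, sim$alignment[ref_ids, , drop = FALSE],
                         sim$lineage[ref_ids], min_overlap = 100)
  expect_true(is.na(res2$lineage))
  expect_match(res2$reason, "overlap")
})

test_that("mismatch model limits: equilibrium curve and raggedness bound", {
  # tau = 0, theta0 = theta1 = theta: geometric equilibrium curve
  theta <- 3
  jj <- 0:10
  expect_equal(pangotrace:::mismatch_expected(jj, 0, theta, theta),
               theta^jj / (1 + theta)^(jj + 1), tolerance = 1e-12)
  # single-class distribution (all pairs identical) has raggedness 2
  expect_equal(raggedness(1), 2)
  expect_equal(raggedness(c(0.5, 0.5)), 0.5)  # 0.25 + 0 + 0.25
})

test_that("mismatch analysis fits expansion data and is well-formed", {
  sim <- simulate_mtdna(n_per_lineage = c(40, 0), seq_length = 402,
                        mutations_per_seq = 3, seed = 115)
  aln <- sim$alignment[names(sim$lineage)[sim$lineage == "A"], ]
  fit <- mismatch_analysis(aln, n_bootstrap = 60, seed = 116)
  expect_equal(sum(fit$histogram), choose(40, 2))
  expect_gte(fit$tau, 0)
  expect_gte(fit$theta1, fit$theta0)
  expect_gt(fit$p_ssd, 0)
  expect_lte(fit$p_ssd, 1)
  expect_gt(fit$p_raggedness, 0)
  # star-like post-expansion data: smooth unimodal mismatch, expansion
  # not rejected
  expect_gt(fit$p_raggedness, 0.05)
})
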
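test_that("rarefaction reproduces the worked two-population example", {
  # pop1 {A:2, B:2}, pop2 {A:4}, g = 2 gene copies:
  # pop1 expected private = 5/6 (allele B only; B present in a C(4,2)
  # subset with probability 5/6 and absent from pop2 with certainty)
  tab <- tiny_table(list(L1 = rbind(c(100, 102), c(100, 102),
                                    c(100, 100), c(100, 100))),
                    pop = c("P1", "P1", "P2", "P2"))
  af <- allele_counts(tab)
  cv <- rarefy_private_alleles(af, g_max = 2, unit = "genes")
  expect_equal(cv$private$L1$P1[["2"]], 5 / 6)
  # the shared allele A can still look private to P2 when P1's subsample
  # misses it: 1 x C(2,2)/C(4,2) = 1/6 (enumeration)
  expect_equal(cv$private$L1$P2[["2"]], 1 / 6)
  # g = full sample: paf equals the observed private allele count and a
  # shared allele contributes exactly zero
  cv_full <- rarefy_private_alleles(af, g_max = 4, unit = "genes")
  expect_equal(cv_full$private$L1$P1[["4"]], 1)
  expect_equal(cv_full$private$L1$P2[["4"]], 0)
  expect_equal(cv_full$distinct$L1$P1[["4"]], 2)
  expect_error(rarefy_private_alleles(af, g_max = 5, unit = "genes"),
               "exceeds")
})

test_that("rarefaction equals brute-force enumeration on random instances", {
  set.seed(91)
  for (r in 1:3) {
    # 3 populations, 2 loci, N <= 8 gene copies each
    sizes <- c(P1 = 4, P2 = 3, P3 = 4)
    calls <- lapply(1:2, function(l) {
      do.call(rbind, lapply(seq_len(sum(sizes)), function(i)
        sample(c(100, 102, 104), 2, TRUE)))
    })
    names(calls) <- c("L1", "L2")
    tab <- tiny_table(calls, pop = rep(names(sizes), sizes))
    af <- allele_counts(tab)
    g <- 3
    cv <- rarefy_private_alleles(af, g_max = g, unit = "genes")
    for (l in af$loci) for (p in af$pops) {
      oracle <- brute_rarefaction(af$counts, l, p, g)
      expect_equal(cv$distinct[[l]][[p]][[as.character(g)]],
                   oracle$distinct, tolerance = 1e-12)
      expect_equal(cv$private[[l]][[p]][[as.character(g)]],
                   oracle$private, tolerance = 1e-12)
    }
  }
})

test_that("paf is non-increasing as populations are added to the set", {
  set.seed(92)
  m <- simulate_model(4, 3, concentration = 5, seed = 93)
  tab <- simulate_genotypes(m, stats::setNames(rep(12, 4), m$pops), seed = 94)
  af3 <- allele_counts(tab, pop_map(tab)[1:3])
  af4 <- allele_counts(tab, pop_map(tab))
  c3 <- rarefy_private_alleles(af3, g_max = 5)
  c4 <- rarefy_private_alleles(af4, g_max = 5)
  for (l in c3$loci) for (p in c3$pops[1:3])
    expect_lte(c4$private[[l]][[p]][["5"]],
               c3$private[[l]][[p]][["5"]] + 1e-12)
  # distinct-allele curves are non-decreasing in g; private <= distinct
  for (l in c4$loci) for (p in c4$pops) {
    expect_true(all(diff(c4$distinct[[l]][[p]]) >= -1e-12))
    expect_true(all(c4$private[[l]][[p]] <=
                      c4$distinct[[l]][[p]] + 1e-12))
  }
})

test_that("locus selection applies the threshold-and-trend rule", {
  fake <- structure(list(
    private = list(L1 = list(A = c(`2` = .1, `3` = .2, `4` = .45, `5` = .5),
                             B = c(`2` = .1, `3` = .2, `4` = .38, `5` = .39)),
                   L2 = list(A = c(`2` = .7, `3` = .68, `4` = .6, `5` = .5),
                             B = c(`2` = .2, `3` = .3, `4` = .41, `5` = .405))),
    distinct = list(), g_values = 2:5, unit = "individuals",
    pops = c("A", "B"), loci = c("L1", "L2")),
    class = "rarefaction_curves")
  sel <- select_tracing_loci(fake, paf_threshold = 0.4, g_star = 5,
                             slope_tolerance = 0.02)
  key <- paste(sel$locus, sel$pop)
  expect_true("L1 A" %in% key)        # 0.5 increasing
  expect_false("L1 B" %in% key)       # below threshold
  expect_false("L2 A" %in% key)       # declining by 0.1 > tolerance
  expect_true("L2 B" %in% key)        # 0.405, slope -0.005 within tolerance
  expect_error(select_tracing_loci(fake, g_star = 9), "curve range")
})

test_that("observed private alleles: recovery, exclusion, degenerate case", {
  tab <- tiny_table(list(L1 = rbind(c(100, 102), c(100, 100),
                                    c(100, 100), c(100, 104))),
                    pop = c("P1", "P1", "P2", "P2"))
  obs <- observed_private_alleles(allele_counts(tab))
  expect_setequal(obs$allele, c(102L, 104L))
  expect_equal(obs$pop[obs$allele == 102], "P1")
  expect_false(100 %in% obs$allele)  # shared allele excluded
  # empty second population -> warning, everything trivially private
  tab2 <- tiny_table(list(L1 = rbind(c(100, 102), c(NA, NA))),
                     pop = c("P1", "P2"))
  expect_warning(obs2 <- observed_private_alleles(allele_counts(tab2)),
                 "empty")
  expect_equal(nrow(obs2), 2L)
})

test_that("panel building intersects the two evidence lines", {
  cand <- data.frame(locus = "L1", pop = "P", paf = .5, slope = 0)
  obs <- data.frame(locus = c("L1", "L2"), allele = c(201L, 203L),
                    pop = c("P", "P"), count = c(3, 3),
                    freq = c(.2, .2), stringsAsFactors = FALSE)
  panel <- build_panel(cand, obs)
  expect_equal(nrow(panel), 1L)
  expect_equal(panel$allele, 201L)
  expect_warning(empty <- build_panel(cand[0, ], obs), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("assignment uses panel alleles, flags conflicts, conserves counts", {
  panel <- structure(data.frame(locus = c("L1", "L2"),
                                allele = c(201L, 203L),
                                pop = c("P1", "P2"),
                                stringsAsFactors = FALSE),
                     class = c("tracing_panel", "data.frame"))
  mk <- tiny_table(list(L1 = rbind(c(100, 201), c(100, 100), c(100, 201)),
                        L2 = rbind(c(100, 100), c(100, 100), c(203, 203))),
                   pop = rep("M", 3), class = "market")
  a <- assign_sources(mk, panel)
  expect_equal(nrow(a), 2L)           # i2 carries no panel allele
  expect_equal(a$sources[a$id == "i1"], "P1")
  expect_true(a$conflict[a$id == "i3"])  # evidence for P1 and P2
  s <- trace_summary(a)
  expect_equal(sum(s), 1L)            # only the non-conflicted assignment
  s2 <- trace_summary(a, include_conflicted = TRUE)
  expect_equal(sum(s2), 3L)           # conflicted counted once per source
})

test_that("injected private alleles are recovered verbatim by the pipeline", {
  sc <- simulate_scenario(seed = 42)
  tab <- filter_by_completeness(sc$table)
  tr <- suppressWarnings(trace_pipeline(tab))
  inj <- paste(sc$private_spec$locus, sc$private_spec$allele,
               sc$private_spec$pop)
  obs <- paste(tr$observed$locus, tr$observed$allele, tr$observed$pop)
  # every injected allele carried by retained reference individuals of a
  # population that survived rarefaction is recovered as observed-private
  present <- vapply(seq_len(nrow(sc$private_spec)), function(k) {
    p <- sc$private_spec$pop[k]
    if (!p %in% tr$curves$pops) return(FALSE)
    ii <- tab$meta$class == "reference" & tab$meta$pop %in% p
    l <- sc$private_spec$locus[k]
    any(tab$a1[ii, l] == sc$private_spec$allele[k] |
          tab$a2[ii, l] == sc$private_spec$allele[k], na.rm = TRUE)
  }, logical(1))
  expect_true(any(present))
  expect_true(all(inj[present] %in% obs))
})
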
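# Small builders used across the suite.

# tiny table from a list of per-locus genotype pairs:
# tiny_table(list(L1 = rbind(c(100, 102), c(100, 100))), pop = c("A", "A"))
tiny_table <- function(calls, pop = NULL, class = "reference", ids = NULL,
                       lon = NULL, lat = NULL) {
  n <- nrow(calls[[1]])
  if (is.null(ids)) ids <- paste0("i", seq_len(n))
  a1 <- sapply(calls, function(m) pmin(m[, 1], m[, 2]))
  a2 <- sapply(calls, function(m) pmax(m[, 1], m[, 2]))
  if (n == 1) { a1 <- t(a1); a2 <- t(a2) }
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- names(calls)
  meta <- data.frame(id = ids, class = class, stringsAsFactors = FALSE)
  if (!is.null(pop)) meta$pop <- pop
  if (!is.null(lon)) meta$lon <- lon
  if (!is.null(lat)) meta$lat <- lat
  genotype_table(a1, a2, meta)
}

# genotype table drawn under HWE (f = 0) from one frequency vector,
# identical loci
hwe_table <- function(n, pf, n_loci = 1, seed = 1, pop = "A") {
  rs <- pangotrace:::local_seed(seed)
  on.exit(rs$restore())
  alleles <- as.integer(names(pf))
  a1 <- matrix(0L, n, n_loci)
  a2 <- matrix(0L, n, n_loci)
  for (l in seq_len(n_loci)) {
    g1 <- sample(alleles, n, TRUE, pf)
    g2 <- sample(alleles, n, TRUE, pf)
    a1[, l] <- pmin(g1, g2)
    a2[, l] <- pmax(g1, g2)
  }
  colnames(a1) <- colnames(a2) <- paste0("L", seq_len(n_loci))
  rownames(a1) <- rownames(a2) <- paste0("i", seq_len(n))
  genotype_table(a1, a2, data.frame(id = rownames(a1), pop = pop,
                                    class = "reference",
                                    stringsAsFactors = FALSE))
}

# equilibrium SMM genotype table for bottleneck calibration/power studies
smm_table <- function(seed, n_ind, n_loci, theta, decline_factor = 1,
                      t_decline = 0) {
  rs <- pangotrace:::local_seed(seed)
  on.exit(rs$restore())
  a1 <- matrix(NA_integer_, n_ind, n_loci)
  a2 <- a1
  for (l in seq_len(n_loci)) {
    st <- 300L + simulate_smm_locus(2 * n_ind, theta, "SMM",
                                    decline_factor = decline_factor,
                                    t_decline = t_decline)
    g1 <- st[seq_len(n_ind)]
    g2 <- st[n_ind + seq_len(n_ind)]
    a1[, l] <- pmin(g1, g2)
    a2[, l] <- pmax(g1, g2)
  }
  colnames(a1) <- colnames(a2) <- paste0("L", seq_len(n_loci))
  rownames(a1) <- rownames(a2) <- paste0("i", seq_len(n_ind))
  genotype_table(a1, a2)
}

# brute-force rarefaction oracle: expected distinct / private alleles over
# all C(N, g) gene-copy subsets, by full enumeration (N <= ~10)
brute_rarefaction <- function(counts_by_pop, locus, focal, g) {
  pops <- names(counts_by_pop)
  copies <- lapply(pops, function(p) {
    cnt <- counts_by_pop[[p]][[locus]]
    rep(as.integer(names(cnt)), cnt)
  })
  names(copies) <- pops
  subsets_alleles <- function(x, g) {
    idx <- utils::combn(length(x), g)
    apply(idx, 2, function(ii) unique(x[ii]), simplify = FALSE)
  }
  focal_sets <- subsets_alleles(copies[[focal]], g)
  e_distinct <- mean(vapply(focal_sets, length, integer(1)))
  other_sets <- lapply(setdiff(pops, focal), function(p)
    subsets_alleles(copies[[p]], g))
  # expected private: for each allele, P(seen in focal subset) *
  # prod P(missed in each other pop's subset) -- computed by enumeration
  alleles <- unique(unlist(copies))
  e_private <- 0
  for (a in alleles) {
    p_seen <- mean(vapply(focal_sets, function(s) a %in% s, logical(1)))
    p_missed <- vapply(other_sets, function(sets)
      mean(vapply(sets, function(s) !(a %in% s), logical(1))), numeric(1))
    e_private <- e_private + p_seen * prod(p_missed)
  }
  list(distinct = e_distinct, private = e_private)
}
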
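# Locus-equilibrium diagnostics: HWE, linkage disequilibrium, null alleles.

# genotype counts and HWE expectations for one population x locus
hwe_setup <- function(x, ids, locus) {
  idx <- match(ids, sample_ids(x))
  l <- match(locus, loci_names(x))
  g1 <- x$a1[idx, l]; g2 <- x$a2[idx, l]
  typed <- !is.na(g1)
  list(g1 = g1[typed], g2 = g2[typed], n = sum(typed))
}

hwe_chi2_stat <- function(g1, g2) {
  n <- length(g1)
  lo <- pmin(g1, g2)  # canonical unordered pairs
  g2 <- pmax(g1, g2)
  g1 <- lo
  alleles <- sort(unique(c(g1, g2)))
  k <- length(alleles)
  obs <- table(factor(paste(g1, g2), levels = {
    pr <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    paste(alleles[pr[, 1]], alleles[pr[, 2]])
  }))
  pf <- (tabulate(match(g1, alleles), k) + tabulate(match(g2, alleles), k)) /
    (2 * n)
  pr <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  expd <- ifelse(pr[, 1] == pr[, 2],
                 n * pf[pr[, 1]]^2,
                 2 * n * pf[pr[, 1]] * pf[pr[, 2]])
  keep <- expd > 0
  sum((as.numeric(obs)[keep] - expd[keep])^2 / expd[keep])
}

#' Hardy-Weinberg equilibrium test for one population and locus
#'
#' `chi2`: goodness-of-fit of genotype counts against HWE expectations from
#' the observed allele frequencies, `df = k(k-1)/2`. `exact_mc`: Monte-Carlo
#' exact test that re-pairs the observed gene copies at random and compares
#' the chi-square statistic (add-one rule).
#'
#' @param x a [genotype_table()]
#' @param ids sample IDs of the population tested
#' @param locus locus name
#' @param method `"chi2"` (default, GenAlEx behaviour) or `"exact_mc"`
#' @param n_mc Monte-Carlo replicates for `exact_mc`
#' @param seed integer seed
#' @return list `p`, `statistic`, `df`, `method`
#' @export
hwe_test <- function(x, ids, locus, method = c("chi2", "exact_mc"),
                     n_mc = 2000, seed = 1) {
  method <- match.arg(method)
  s <- hwe_setup(x, ids, locus)
  if (s$n < 2L) stop("need >= 2 typed genotypes")
  k <- length(unique(c(s$g1, s$g2)))
  if (k < 2L) {
    warning("monomorphic locus: p = 1")
    return(list(p = 1, statistic = 0, df = 0, method = method))
  }
  stat <- hwe_chi2_stat(s$g1, s$g2)
  df <- k * (k - 1) / 2
  if (method == "chi2")
    return(list(p = stats::pchisq(stat, df, lower.tail = FALSE),
                statistic = stat, df = df, method = method))
  rs <- local_seed(seed)
  on.exit(rs$restore())
  copies <- c(s$g1, s$g2)
  hits <- 0L
  for (r in seq_len(n_mc)) {
    sh <- sample(copies)
    if (hwe_chi2_stat(sh[seq_len(s$n)], sh[s$n + seq_len(s$n)]) >= stat)
      hits <- hits + 1L
  }
  list(p = perm_pvalue(hits, n_mc), statistic = stat, df = df,
       method = method)
}

#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' G-test on the two-locus genotype contingency table among individuals
#' typed at both loci; the null distribution permutes one locus's genotypes
#' among individuals (add-one rule). Use [p_adjust_bonferroni()] across
#' pairs.
#'
#' @param x a [genotype_table()]
#' @param ids sample IDs of the population tested
#' @param locus_pair character vector of two locus names
#' @param n_randomizations permutations (> 0)
#' @param seed integer seed
#' @return list `p`, `G`, `degenerate`
#' @export
ld_test <- function(x, ids, locus_pair, n_randomizations = 1000, seed = 1) {
  if (n_randomizations <= 0) stop("n_randomizations must be positive")
  stopifnot(length(locus_pair) == 2)
  idx <- match(ids, sample_ids(x))
  l1 <- match(locus_pair[1], loci_names(x))
  l2 <- match(locus_pair[2], loci_names(x))
  gA <- paste(x$a1[idx, l1], x$a2[idx, l1])
  gB <- paste(x$a1[idx, l2], x$a2[idx, l2])
  typed <- !is.na(x$a1[idx, l1]) & !is.na(x$a1[idx, l2])
  gA <- gA[typed]; gB <- gB[typed]
  if (sum(typed) < 5L) stop("need >= 5 individuals typed at both loci")
  g_stat <- function(a, b) {
    tab <- table(a, b)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- as.numeric(tab)
    2 * sum(o[o > 0] * log(o[o > 0] / e[o > 0]))
  }
  if (length(unique(gA)) < 2L || length(unique(gB)) < 2L) {
    warning("degenerate two-locus table: p = 1")
    return(list(p = 1, G = 0, degenerate = TRUE))
  }
  G_obs <- g_stat(gA, gB)
  rs <- local_seed(seed)
  on.exit(rs$restore())
  hits <- 0L
  for (r in seq_len(n_randomizations))
    if (g_stat(gA, sample(gB)) >= G_obs) hits <- hits + 1L
  list(p = perm_pvalue(hits, n_randomizations), G = G_obs,
       degenerate = FALSE)
}

#' Bonferroni correction helper
#'
#' @param p numeric vector of p-values
#' @export
p_adjust_bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")

#' Null-allele diagnostics for one population and locus
#'
#' Estimates the null-allele frequency from the heterozygote deficit:
#' Chakraborty `r = (He - Ho) / (He + Ho)` and Brookfield-1
#' `r = (He - Ho) / (1 + He)`, with a Monte-Carlo p-value comparing the
#' observed per-allele homozygote counts to their HWE expectation
#' (samples of the same size drawn from the observed allele frequencies;
#' upper tail on total homozygote count, add-one rule). Negative estimates
#' are reported as such when Ho > He.
#'
#' @param x a [genotype_table()]
#' @param ids sample IDs of the population tested
#' @param locus locus name
#' @param n_mc Monte-Carlo replicates
#' @param seed integer seed
#' @return list `chakraborty`, `brookfield1`, `p`, `Ho`, `He`
#' @export
null_alleles <- function(x, ids, locus, n_mc = 2000, seed = 1) {
  s <- hwe_setup(x, ids, locus)
  alleles <- sort(unique(c(s$g1, s$g2)))
  if (length(alleles) < 2L) stop("locus is monomorphic in this population")
  n <- s$n
  pf <- (tabulate(match(s$g1, alleles), length(alleles)) +
           tabulate(match(s$g2, alleles), length(alleles))) / (2 * n)
  Ho <- mean(s$g1 != s$g2)
  He <- 1 - sum(pf^2)
  ch <- (He - Ho) / (He + Ho)
  bf <- (He - Ho) / (1 + He)
  rs <- local_seed(seed)
  on.exit(rs$restore())
  hom_obs <- sum(s$g1 == s$g2)
  hits <- 0L
  for (r in seq_len(n_mc)) {
    g1 <- sample(alleles, n, replace = TRUE, prob = pf)
    g2 <- sample(alleles, n, replace = TRUE, prob = pf)
    if (sum(g1 == g2) >= hom_obs) hits <- hits + 1L
  }
  list(chakraborty = ch, brookfield1 = bf, p = perm_pvalue(hits, n_mc),
       Ho = Ho, He = He)
}
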
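# Cornuet-Luikart heterozygosity-excess bottleneck test under SMM and TPM,
# backed by the coalescent simulator in src/coalescent.cpp.

# geometric success parameter giving the requested multi-step variance:
# var[Geom on {1,2,...}] = (1-q)/q^2  =>  q = (-1 + sqrt(1 + 4 v)) / (2 v)
geom_q_from_variance <- function(variance) {
  if (variance <= 0) return(1)
  (-1 + sqrt(1 + 4 * variance)) / (2 * variance)
}

#' Simulate one equilibrium microsatellite locus
#'
#' Allele states (repeat scores) of `n_genes` gene copies under the neutral
#' coalescent with stepwise mutation. `model = "TPM"` adds, with probability
#' `1 - p_smm`, multi-step jumps of geometric magnitude with the stated
#' variance. `TPM` with `p_smm = 1` is exactly `SMM`.
#'
#' @param n_genes gene copies sampled
#' @param theta scaled mutation rate 4Nu of the present population
#' @param model `"SMM"` or `"TPM"`
#' @param p_smm single-step proportion for TPM (default 0.95)
#' @param variance geometric multi-step variance for TPM (default 12)
#' @param seed integer seed (NULL = use current RNG stream)
#' @param decline_factor ancestral/present population-size ratio (1 =
#'   constant size; 10 = a recent 10-fold decline)
#' @param t_decline time of the decline, in units of 2N_present generations
#' @return integer vector of allele states
#' @export
simulate_smm_locus <- function(n_genes, theta, model = c("SMM", "TPM"),
                               p_smm = 0.95, variance = 12, seed = NULL,
                               decline_factor = 1, t_decline = 0) {
  model <- match.arg(model)
  if (model == "SMM") p_smm <- 1
  if (!is.null(seed)) {
    rs <- local_seed(seed)
    on.exit(rs$restore())
  }
  cpp_sim_locus_demo(n_genes, theta, p_smm, geom_q_from_variance(variance),
                     decline_factor, t_decline)
}

# tune theta so that the pilot mean allele count hits k_target (bisection
# on log-theta)
tune_theta <- function(n_genes, k_target, p_smm, q_geom, n_pilot = 500,
                       tol = 0.25, lo = 1e-3, hi = 500) {
  f <- function(theta) cpp_mean_k(n_genes, theta, p_smm, q_geom, n_pilot)
  for (it in 1:24) {
    mid <- sqrt(lo * hi)
    mk <- f(mid)
    if (abs(mk - k_target) <= tol) return(mid)
    if (mk < k_target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Equilibrium heterozygosity sample conditional on the observed allele count
#'
#' Simulates coalescent genealogies of `n_genes` copies under SMM/TPM,
#' tuning theta by bisection so the pilot mean allele number matches
#' `k_observed`, then retains replicates with exactly `k_observed` alleles
#' and returns their unbiased heterozygosities (the `Heq` distribution of
#' the mutation-drift equilibrium).
#'
#' @inheritParams simulate_smm_locus
#' @param k_observed observed number of alleles (2..n_genes)
#' @param n_reps retained replicates
#' @param seed integer seed
#' @param n_pilot pilot replicates per bisection step
#' @param theta_spread half-width factor of the log-uniform theta window
#'   integrated by the conditioning (each attempt draws theta in
#'   `[theta/spread, theta*spread]`; 1 = fixed theta). A single plugged-in
#'   theta understates the uncertainty of the mutation parameter given one
#'   locus's allele count, which biases the conditional quantiles of He;
#'   the default window removes that bias (see the methods vignette).
#' @return list `heq`, `theta`
#' @export
simulate_heq <- function(n_genes, k_observed, model = c("SMM", "TPM"),
                         n_reps = 1000, seed = 1, p_smm = 0.95,
                         variance = 12, n_pilot = 500, theta_spread = 3) {
  model <- match.arg(model)
  if (k_observed < 2 || k_observed > n_genes)
    stop("k_observed must be in [2, n_genes]")
  stopifnot(theta_spread >= 1)
  if (model == "SMM") p_smm <- 1
  q_geom <- geom_q_from_variance(variance)
  rs <- local_seed(seed)
  on.exit(rs$restore())
  theta <- tune_theta(n_genes, k_observed, p_smm, q_geom, n_pilot)
  max_tries <- 400L * n_reps
  heq <- cpp_heq_conditional(n_genes, k_observed, theta / theta_spread,
                             theta * theta_spread, p_smm, q_geom,
                             n_reps, max_tries)
  if (length(heq) < n_reps)
    warning(sprintf("only %d of %d conditional replicates obtained",
                    length(heq), n_reps))
  list(heq = heq, theta = theta)
}

#' Heterozygosity-excess bottleneck test
#'
#' For each polymorphic locus of a population, compares the observed
#' unbiased heterozygosity with the equilibrium distribution `Heq` expected
#' under mutation-drift equilibrium given the observed allele count
#' ([simulate_heq()]). A recent bottleneck leaves He above `Heq` (allele
#' numbers drop faster than heterozygosity). Because the conditional `Heq`
#' distribution is left-skewed, centring loci on its mean biases the signs
#' positive even at equilibrium; each locus is therefore scored by its
#' conditional quantile `u = P(Heq <= He)` (mid-rank, add-one smoothed),
#' which is uniform under mutation-drift equilibrium, and loci are combined
#' with a Wilcoxon signed-rank test on `u - 1/2` (exact distribution for
#' <= 25 loci, normal approximation beyond). Standardized differences
#' `(He - mean(Heq)) / sd(Heq)` are reported per locus for inspection.
#'
#' @param x a [genotype_table()]
#' @param ids sample IDs of the tested population
#' @param model `"SMM"` or `"TPM"`
#' @param n_reps conditional equilibrium replicates per locus
#' @param seed integer seed
#' @param p_smm,variance TPM parameters
#' @return list with `per_locus` (data frame: locus, n_genes, k, He,
#'   Heq_mean, Heq_sd, std_diff, u), `p_excess`, `p_deficit`,
#'   `p_two_sided`, `model`, `n_loci_used`, `excluded`
#' @export
bottleneck_test <- function(x, ids, model = c("SMM", "TPM"),
                            n_reps = 10000, seed = 1, p_smm = 0.95,
                            variance = 12) {
  model <- match.arg(model)
  idx <- match(ids, sample_ids(x))
  loci <- loci_names(x)
  seeds <- derive_seeds(seed, length(loci))
  rows <- list()
  excluded <- character(0)
  for (l in seq_along(loci)) {
    g1 <- x$a1[idx, l]; g2 <- x$a2[idx, l]
    typed <- !is.na(g1)
    al <- c(g1[typed], g2[typed])
    ng <- length(al)
    k <- length(unique(al))
    if (k < 2L) {
      excluded <- c(excluded, loci[l])
      next
    }
    pf <- as.numeric(table(al)) / ng
    He <- ng / (ng - 1) * (1 - sum(pf^2))
    eq <- simulate_heq(ng, k, model, n_reps = n_reps, seed = seeds[l],
                       p_smm = p_smm, variance = variance)
    m <- mean(eq$heq); s <- stats::sd(eq$heq)
    u <- (sum(eq$heq < He) + 0.5 * sum(eq$heq == He) + 0.5) /
      (length(eq$heq) + 1)
    rows[[length(rows) + 1L]] <- data.frame(
      locus = loci[l], n_genes = ng, k = k, He = He, Heq_mean = m,
      Heq_sd = s, std_diff = if (s > 0) (He - m) / s else NA_real_,
      u = u, stringsAsFactors = FALSE)
  }
  if (length(excluded))
    message("monomorphic loci excluded: ", paste(excluded, collapse = ", "))
  per_locus <- do.call(rbind, rows)
  if (is.null(per_locus) || nrow(per_locus) < 4L)
    stop("need >= 4 polymorphic loci for the Wilcoxon test")
  d <- per_locus$u - 0.5
  exact <- nrow(per_locus) <= 25
  wt <- function(alt) suppressWarnings(
    stats::wilcox.test(d, alternative = alt, mu = 0, exact = exact)$p.value)
  list(per_locus = per_locus,
       p_excess = wt("greater"), p_deficit = wt("less"),
       p_two_sided = wt("two.sided"),
       model = if (model == "SMM") "SMM"
       else sprintf("TPM(p_smm=%.2f, variance=%.3g)", p_smm, variance),
       n_loci_used = nrow(per_locus), excluded = excluded)
}
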
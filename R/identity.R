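# Individual identification: genotype matching, probability-of-identity
# indices and the chance-match probability used to de-duplicate samples.

#' Find matching multilocus genotypes
#'
#' Reports pairs of individuals identical at all mutually typed loci
#' (missing never counts as mismatch), requiring at least `min_shared_loci`
#' comparable loci and allowing up to `max_mismatch_loci` mismatching loci.
#' Symmetric and invariant to individual order.
#'
#' @param x a [genotype_table()]
#' @param max_mismatch_loci mismatch budget (default 0: exact matches)
#' @param min_shared_loci minimum mutually typed loci for a comparable pair
#' @return data frame: id1, id2, shared_loci, mismatches
#' @export
find_matches <- function(x, max_mismatch_loci = 0, min_shared_loci = 1) {
  if (min_shared_loci > n_loci(x))
    stop("min_shared_loci exceeds the number of loci")
  n <- n_ind(x)
  ids <- sample_ids(x)
  # code each call as one integer; NA stays NA
  code <- x$a1 * 10000L + x$a2
  out <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    ci <- code[i, ]
    for (j in (i + 1L):n) {
      cj <- code[j, ]
      comp <- !is.na(ci) & !is.na(cj)
      shared <- sum(comp)
      if (shared < min_shared_loci) next
      mm <- sum(ci[comp] != cj[comp])
      if (mm <= max_mismatch_loci)
        out[[length(out) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j], shared_loci = shared,
          mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id1 = character(0), id2 = character(0),
                      shared_loci = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Probability of a multilocus genotype, and of encountering it twice
#'
#' `pgen()` multiplies per-locus genotype probabilities under an optional
#' inbreeding adjustment: `p^2 + f p (1-p)` for homozygotes and
#' `2 p q (1-f)` for heterozygotes. Alleles absent from the reference
#' frequencies receive the floor `1 / (2N + 1)` so that market genotypes
#' never get probability zero. `psex()` is the chance of seeing the genotype
#' more than once among `n` individuals: `1 - (1 - pgen)^(n-1)`.
#'
#' @param genotype two-row matrix or list of length-2 vectors: one allele
#'   pair per locus, named by locus (NA pair = untyped, skipped)
#' @param af an [allele_counts()] result
#' @param pop reference population in `af` providing the frequencies
#' @param f inbreeding adjustment in `[0, 1)`
#' @return `pgen()`: the multilocus genotype probability
#' @export
pgen <- function(genotype, af, pop, f = 0) {
  loci <- names(genotype)
  stopifnot(!is.null(loci), all(loci %in% af$loci))
  pr <- 1
  for (l in loci) {
    g <- genotype[[l]]
    if (anyNA(g)) next
    n <- af$n_genes[pop, l]
    pf <- af_freq(af, pop, l)
    floor_p <- 1 / (n + 1)  # n gene copies = 2N genotypes' copies
    p1 <- if (as.character(g[1]) %in% names(pf))
      pf[[as.character(g[1])]] else floor_p
    p2 <- if (as.character(g[2]) %in% names(pf))
      pf[[as.character(g[2])]] else floor_p
    pr <- pr * if (g[1] == g[2]) p1^2 + f * p1 * (1 - p1)
    else 2 * p1 * p2 * (1 - f)
  }
  pr
}

#' @rdname pgen
#' @param p a `pgen` value
#' @param n_population number of individuals in the comparison cohort
#' @export
psex <- function(p, n_population) {
  if (n_population < 2) {
    warning("psex undefined for n < 2; returning 0")
    return(0)
  }
  # -expm1((n-1) log1p(-p)) keeps precision for the tiny pgen values a
  # 20-locus genotype produces (1 - (1-p)^(n-1) underflows to 0)
  -expm1((n_population - 1) * log1p(-p))
}

# Per-locus identity indices from a frequency vector. `n` is the number of
# sampled gene copies behind the frequencies; with that convention the
# unbiased estimator has E[uPI(p_hat)] = PI(p_true) exactly (checked by
# Monte-Carlo in the tests) and uPI -> PI as n grows.
pi_locus <- function(pf, n = NULL) {
  a2 <- sum(pf^2); a3 <- sum(pf^3); a4 <- sum(pf^4)
  PI <- a4 + sum((2 * outer(pf, pf))[upper.tri(diag(length(pf)))]^2)
  PIsibs <- 0.25 + 0.5 * a2 + 0.5 * a2^2 - 0.25 * a4
  uPI <- NA_real_
  if (!is.null(n) && n >= 4) {
    uPI <- (n^3 * (2 * a2^2 - a4) - 2 * n^2 * (a3 + 2 * a2) +
              n * (9 * a2 + 2) - 6) /
      ((n - 1) * (n - 2) * (n - 3))
  }
  c(PI = PI, uPI = uPI, PIsibs = PIsibs)
}

#' Probability-of-identity indices
#'
#' Per-locus and cumulative (product over loci) probability of identity:
#' `PI = sum p_i^4 + sum_{i<j} (2 p_i p_j)^2`, its unbiased small-sample
#' estimator `uPI` (undefined and flagged for fewer than 4 sampled gene
#' copies), and the sibling-pair bound
#' `PIsibs = 0.25 + 0.5 a2 + 0.5 a2^2 - 0.25 a4` with `a_k = sum p_i^k`.
#'
#' @param af an [allele_counts()] result; frequencies should normally come
#'   from reference individuals only
#' @param pop population in `af` whose frequencies are used
#' @return list with `per_locus` (data frame: locus, n, PI, uPI, PIsibs) and
#'   `cumulative` (named vector of products over defined loci)
#' @export
probability_of_identity <- function(af, pop) {
  rows <- lapply(af$loci, function(l) {
    pf <- af_freq(af, pop, l)
    n_genes <- af$n_genes[pop, l]
    if (!length(pf))
      return(data.frame(locus = l, n = 0, PI = NA_real_, uPI = NA_real_,
                        PIsibs = NA_real_, stringsAsFactors = FALSE))
    v <- pi_locus(pf, n_genes)
    data.frame(locus = l, n = n_genes / 2, PI = v[["PI"]],
               uPI = v[["uPI"]], PIsibs = v[["PIsibs"]],
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  cum <- vapply(c("PI", "uPI", "PIsibs"), function(k)
    prod(per_locus[[k]], na.rm = TRUE), numeric(1))
  list(per_locus = per_locus, cumulative = cum)
}

#' Minimum number of loci to reach a target probability of identity
#'
#' Sorts loci by ascending per-locus PI (most informative first) and returns
#' the smallest k whose product drops below `threshold`; `NA_integer_` when
#' even all loci cannot reach it.
#'
#' @param per_locus_pi numeric vector of per-locus PI values
#' @param threshold target cumulative PI in `(0, 1)`
#' @export
min_loci_for_pi <- function(per_locus_pi, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  if (threshold >= 1) return(1L)
  pis <- sort(per_locus_pi[!is.na(per_locus_pi)])
  cp <- cumprod(pis)
  k <- which(cp < threshold)
  if (!length(k)) return(NA_integer_)
  k[1]
}

#' Full identity screen of a genotype table
#'
#' Convenience wrapper: exact genotype matches, per-match psex against the
#' pooled reference frequencies, and the PI table.
#'
#' @param x a [genotype_table()]
#' @param af reference [allele_counts()] (default: all reference individuals
#'   pooled into one frequency table)
#' @param f inbreeding adjustment passed to [pgen()]
#' @param min_shared_loci passed to [find_matches()]
#' @return list `matches` (with psex column), `pi`
#' @export
identity_screen <- function(x, af = NULL, f = 0, min_shared_loci = 10) {
  if (is.null(af)) {
    refs <- x$meta$id[x$meta$class == "reference"]
    if (!length(refs)) refs <- x$meta$id
    af <- allele_counts(x, list(all = refs))
  }
  pooled <- af$pops[1]
  matches <- find_matches(x, max_mismatch_loci = 0,
                          min_shared_loci = min_shared_loci)
  n_pop <- n_ind(x)
  if (nrow(matches)) {
    matches$psex <- vapply(seq_len(nrow(matches)), function(k) {
      i <- match(matches$id1[k], sample_ids(x))
      g <- lapply(seq_len(n_loci(x)), function(l) c(x$a1[i, l], x$a2[i, l]))
      names(g) <- loci_names(x)
      psex(pgen(g, af, pooled, f = f), n_pop)
    }, numeric(1))
  } else matches$psex <- numeric(0)
  list(matches = matches, pi = probability_of_identity(af, pooled))
}
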
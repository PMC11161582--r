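#' Per-population diversity statistics
#'
#' Computes, per population, the mean number of alleles per locus (Na),
#' observed heterozygosity (Ho, fraction of heterozygotes among typed
#' genotypes), expected heterozygosity (He = 1 - sum p_i^2) and unbiased
#' expected heterozygosity (uHe = 2n/(2n-1) * He, n = typed genotypes),
#' averaged over typed loci. Per-locus values are returned alongside.
#'
#' @param x a [genotype_table()]
#' @param partition population map (default reference populations)
#' @return list with `summary` (data frame: pop, N, Na, Ho, He, uHe) and
#'   `by_locus` (long data frame with per-locus values; loci with zero typed
#'   genotypes carry `NA` and are flagged in `undefined`)
#' @export
diversity <- function(x, partition = pop_map(x)) {
  validate_pop_map(x, partition)
  stopifnot(length(partition) > 0)
  loci <- loci_names(x)
  rows <- list()
  for (p in names(partition)) {
    idx <- match(partition[[p]], sample_ids(x))
    for (l in seq_along(loci)) {
      g1 <- x$a1[idx, l]; g2 <- x$a2[idx, l]
      typed <- !is.na(g1)
      n <- sum(typed)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          pop = p, locus = loci[l], n = 0L, Na = NA_real_, Ho = NA_real_,
          He = NA_real_, uHe = NA_real_, stringsAsFactors = FALSE)
        next
      }
      al <- c(g1[typed], g2[typed])
      pf <- as.numeric(table(al)) / (2 * n)
      He <- 1 - sum(pf^2)
      rows[[length(rows) + 1L]] <- data.frame(
        pop = p, locus = loci[l], n = n, Na = length(pf),
        Ho = mean(g1[typed] != g2[typed]),
        He = He, uHe = 2 * n / (2 * n - 1) * He, stringsAsFactors = FALSE)
    }
  }
  by_locus <- do.call(rbind, rows)
  agg <- function(v, pop) tapply(v, pop, mean, na.rm = TRUE)
  pops <- names(partition)
  summary <- data.frame(
    pop = pops,
    N = vapply(partition, length, integer(1))[pops],
    Na = as.numeric(agg(by_locus$Na, by_locus$pop)[pops]),
    Ho = as.numeric(agg(by_locus$Ho, by_locus$pop)[pops]),
    He = as.numeric(agg(by_locus$He, by_locus$pop)[pops]),
    uHe = as.numeric(agg(by_locus$uHe, by_locus$pop)[pops]),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, by_locus = by_locus,
       undefined = unique(by_locus$pop[is.na(by_locus$Na)]))
}

#' Rarefied allelic richness
#'
#' Hypergeometric rarefaction of allele counts to a standardized number of
#' gene copies `g`: `A_R = sum_i [1 - C(N - N_i, g) / C(N, g)]`, the expected
#' number of distinct alleles in a subsample of `g` gene copies. By the FSTAT
#' convention `g` defaults to the smallest non-zero `n_genes` over all
#' (population, locus) cells.
#'
#' @param af an [allele_counts()] result
#' @param g gene-copy count to rarefy to (>= 2)
#' @return list with `A_R` (populations x loci matrix), `mean` (per
#'   population) and `g`
#' @export
allelic_richness <- function(af, g = NULL) {
  ng <- af$n_genes
  if (is.null(g)) g <- min(ng[ng > 0])
  if (g < 2) stop("g must be >= 2")
  A <- matrix(NA_real_, length(af$pops), length(af$loci),
              dimnames = list(af$pops, af$loci))
  for (p in af$pops) for (l in af$loci) {
    N <- ng[p, l]
    if (N == 0L) next
    if (g > N)
      stop(sprintf("g = %d exceeds n_genes = %d for population %s at %s",
                   g, N, p, l))
    cnt <- af$counts[[p]][[l]]
    A[p, l] <- sum(1 - vapply(cnt, absence_prob, numeric(1), N = N, g = g))
  }
  list(A_R = A, mean = rowMeans(A, na.rm = TRUE), g = g)
}

# Weir & Cockerham (1984) within-population variance components summed over
# alleles and loci for one population. Returns c(b = ..., c = ...).
wc_bc_pop <- function(a1, a2) {
  bs <- 0; cs <- 0
  for (l in seq_len(ncol(a1))) {
    g1 <- a1[, l]; g2 <- a2[, l]
    typed <- !is.na(g1)
    n <- sum(typed)
    if (n < 2L) next
    g1 <- g1[typed]; g2 <- g2[typed]
    alleles <- unique(c(g1, g2))
    if (length(alleles) < 2L) next
    het <- g1 != g2
    for (a in alleles) {
      p <- (sum(g1 == a) + sum(g2 == a)) / (2 * n)
      h <- sum(het & (g1 == a | g2 == a)) / n
      bs <- bs + n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      cs <- cs + h / 2
    }
  }
  c(b = bs, c = cs)
}

#' Weir-Cockerham inbreeding coefficient with randomization test
#'
#' Multilocus f per population from the Weir & Cockerham (1984) variance
#' components (b, c summed over alleles and loci; loci contribute
#' complete-case). Significance of heterozygote deficit is assessed by
#' randomizing gene copies among individuals within the population (each
#' randomization re-pairs the 2n gene copies at every locus) and counting
#' randomized f >= observed f (one-tailed, add-one rule).
#'
#' @param x a [genotype_table()]
#' @param partition population map
#' @param n_randomizations randomizations for the p-value (0 = estimate only)
#' @param seed integer seed
#' @return data frame: pop, f, p (NA when not tested or undefined)
#' @export
fis_test <- function(x, partition = pop_map(x), n_randomizations = 1000,
                     seed = 1) {
  validate_pop_map(x, partition)
  rs <- local_seed(seed)
  on.exit(rs$restore())
  out <- data.frame(pop = names(partition), f = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(partition)) {
    idx <- match(partition[[k]], sample_ids(x))
    a1 <- x$a1[idx, , drop = FALSE]
    a2 <- x$a2[idx, , drop = FALSE]
    bc <- wc_bc_pop(a1, a2)
    if (bc[["b"]] + bc[["c"]] == 0) next  # all loci monomorphic: undefined
    f_obs <- 1 - bc[["c"]] / (bc[["b"]] + bc[["c"]])
    out$f[k] <- f_obs
    if (n_randomizations > 0) {
      hits <- 0L
      for (r in seq_len(n_randomizations)) {
        p1 <- a1; p2 <- a2
        for (l in seq_len(ncol(a1))) {
          typed <- which(!is.na(a1[, l]))
          if (length(typed) < 2L) next
          copies <- sample(c(a1[typed, l], a2[typed, l]))
          half <- length(typed)
          p1[typed, l] <- copies[seq_len(half)]
          p2[typed, l] <- copies[half + seq_len(half)]
        }
        bcr <- wc_bc_pop(p1, p2)
        fr <- 1 - bcr[["c"]] / (bcr[["b"]] + bcr[["c"]])
        if (!is.na(fr) && fr >= f_obs) hits <- hits + 1L
      }
      out$p[k] <- perm_pvalue(hits, n_randomizations)
    }
  }
  out
}

# Weir & Cockerham (1984) theta for two groups of individuals (multilocus,
# components summed over alleles and loci, complete-case per locus).
wc_theta_pair <- function(a1, a2, idx1, idx2) {
  num <- 0; den <- 0
  for (l in seq_len(ncol(a1))) {
    stats_by <- lapply(list(idx1, idx2), function(ii) {
      g1 <- a1[ii, l]; g2 <- a2[ii, l]
      typed <- !is.na(g1)
      list(g1 = g1[typed], g2 = g2[typed], n = sum(typed))
    })
    n1 <- stats_by[[1]]$n; n2 <- stats_by[[2]]$n
    if (n1 < 2L || n2 < 2L) next
    alleles <- unique(c(stats_by[[1]]$g1, stats_by[[1]]$g2,
                        stats_by[[2]]$g1, stats_by[[2]]$g2))
    if (length(alleles) < 2L) next
    nbar <- (n1 + n2) / 2
    nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
    for (a in alleles) {
      ph <- vapply(stats_by, function(s) {
        p <- (sum(s$g1 == a) + sum(s$g2 == a)) / (2 * s$n)
        h <- sum((s$g1 != s$g2) & (s$g1 == a | s$g2 == a)) / s$n
        c(p, h)
      }, numeric(2))
      p1 <- ph[1, 1]; p2 <- ph[1, 2]; h1 <- ph[2, 1]; h2 <- ph[2, 2]
      pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
      hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
      A <- nbar / nc *
        (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
      B <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      C <- hbar / 2
      num <- num + A
      den <- den + A + B + C
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Pairwise Weir-Cockerham theta with permutation tests
#'
#' Multilocus theta for every population pair; the p-value is the fraction
#' of permutations (individuals shuffled between the two populations,
#' add-one rule) with permuted theta >= observed.
#'
#' @param x a [genotype_table()]
#' @param partition population map (>= 2 populations)
#' @param n_permutations permutations per pair (0 = estimates only)
#' @param seed integer seed
#' @return list with `theta` and `p` (symmetric matrices, zero/NA diagonal)
#' @export
pairwise_fst <- function(x, partition = pop_map(x), n_permutations = 10000,
                         seed = 1) {
  validate_pop_map(x, partition)
  pops <- names(partition)
  stopifnot(length(pops) >= 2)
  rs <- local_seed(seed)
  on.exit(rs$restore())
  th <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  pv <- matrix(NA_real_, length(pops), length(pops),
               dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1):length(pops)) {
    idx1 <- match(partition[[i]], sample_ids(x))
    idx2 <- match(partition[[j]], sample_ids(x))
    t_obs <- wc_theta_pair(x$a1, x$a2, idx1, idx2)
    th[i, j] <- th[j, i] <- t_obs
    if (n_permutations > 0 && !is.na(t_obs)) {
      both <- c(idx1, idx2)
      hits <- 0L
      for (r in seq_len(n_permutations)) {
        perm <- sample(both)
        tp <- wc_theta_pair(x$a1, x$a2, perm[seq_along(idx1)],
                            perm[-seq_along(idx1)])
        if (!is.na(tp) && tp >= t_obs) hits <- hits + 1L
      }
      pv[i, j] <- pv[j, i] <- perm_pvalue(hits, n_permutations)
    }
  }
  list(theta = th, p = pv)
}

#' Cavalli-Sforza & Edwards chord distance between individuals
#'
#' Each individual's locus profile is its allele dosage vector (0, 1/2, 1);
#' the per-locus chord distance is `sqrt(2 * (1 - sum_a sqrt(x_a * y_a)))`
#' and distances are averaged over mutually typed loci.
#'
#' @param x a [genotype_table()]
#' @return symmetric individual-by-individual distance matrix (NA where two
#'   individuals share no typed locus)
#' @export
edwards_distance <- function(x) {
  n <- n_ind(x)
  acc <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (l in seq_len(n_loci(x))) {
    g1 <- x$a1[, l]; g2 <- x$a2[, l]
    typed <- !is.na(g1)
    if (sum(typed) < 2L) next
    alleles <- sort(unique(c(g1[typed], g2[typed])))
    dos <- matrix(0, n, length(alleles))
    dos[cbind(seq_len(n), match(g1, alleles))] <- 0.5
    ii <- cbind(seq_len(n), match(g2, alleles))
    dos[ii[typed, , drop = FALSE]] <- dos[ii[typed, , drop = FALSE]] + 0.5
    sq <- sqrt(dos)
    S <- tcrossprod(sq)
    S <- pmin(S, 1)
    dl <- sqrt(pmax(2 * (1 - S), 0))
    tt <- outer(typed, typed, `&`)
    acc[tt] <- acc[tt] + dl[tt]
    cnt[tt] <- cnt[tt] + 1L
  }
  d <- acc / cnt
  d[cnt == 0L] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(sample_ids(x), sample_ids(x))
  d
}

#' Geographic distance matrix from table metadata
#'
#' @param x a [genotype_table()] with `lon`/`lat` metadata
#' @param method `"greatcircle"` (haversine, km; default) or `"euclidean"`
#'   (planar on raw decimal degrees)
#' @export
geo_dist_matrix <- function(x, method = c("greatcircle", "euclidean")) {
  method <- match.arg(method)
  ll <- cbind(x$meta$lon, x$meta$lat)
  if (anyNA(ll)) stop("all individuals need lon/lat for geographic distance")
  if (method == "greatcircle") {
    d <- geosphere::distm(ll, fun = geosphere::distHaversine) / 1000
  } else {
    d <- as.matrix(stats::dist(ll))
  }
  dimnames(d) <- list(sample_ids(x), sample_ids(x))
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries; the p-value permutes the
#' row/column order of the first matrix (upper tail, add-one rule).
#'
#' @param genetic,geographic symmetric distance matrices in the same order
#' @param n_permutations number of permutations
#' @param seed integer seed
#' @return list `r`, `p`, `n_permutations`
#' @export
mantel_ibd <- function(genetic, geographic, n_permutations = 10000,
                       seed = 1) {
  stopifnot(identical(dim(genetic), dim(geographic)),
            nrow(genetic) == ncol(genetic))
  rs <- local_seed(seed)
  on.exit(rs$restore())
  n <- nrow(genetic)
  lower <- lower.tri(genetic)
  gx <- genetic[lower]
  gy <- geographic[lower]
  keep <- !is.na(gx) & !is.na(gy)
  if (stats::sd(gx[keep]) == 0 || stats::sd(gy[keep]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- stats::cor(gx[keep], gy[keep])
  hits <- 0L
  for (k in seq_len(n_permutations)) {
    ord <- sample.int(n)
    gp <- genetic[ord, ord][lower]
    rp <- stats::cor(gp[keep], gy[keep])
    if (!is.na(rp) && rp >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = perm_pvalue(hits, n_permutations),
       n_permutations = n_permutations)
}
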
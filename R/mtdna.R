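# Cytochrome-b workflow: haplotype collapsing, diversity statistics,
# K2P/NJ lineage assignment, and mismatch-distribution expansion tests.

#' Read an aligned FASTA file as a character matrix
#'
#' Thin wrapper over [ape::read.dna()]; errors when sequences are ragged.
#'
#' @param path FASTA path
#' @return character matrix (sequences x sites, uppercase)
#' @export
read_alignment <- function(path) {
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  if (is.list(d)) stop("sequences have unequal lengths: not an alignment")
  toupper(unclass(d))
}

as_alignment <- function(x) {
  if (is.matrix(x) && is.character(x)) return(toupper(x))
  if (inherits(x, "DNAbin")) return(toupper(as.character(as.matrix(x))))
  stop("expected a character matrix or DNAbin alignment")
}

#' Collapse an alignment into haplotypes
#'
#' Under the strict policy, sequences containing anything other than
#' unambiguous A/C/G/T are removed before collapsing; identical remaining
#' sequences are grouped into haplotypes (named H1, H2, ... in order of
#' first appearance).
#'
#' @param aln character matrix alignment (or `DNAbin`)
#' @param missing_policy `"strict"` (drop sequences with N/gaps/ambiguity,
#'   default) or `"keep"`
#' @return object of class `haplotype_set`: list `haplotypes` (character
#'   matrix, one row per haplotype), `members` (named list haplotype ->
#'   sequence IDs), `assignment` (named vector sequence -> haplotype),
#'   `dropped` (IDs removed by the policy)
#' @export
collapse_haplotypes <- function(aln, missing_policy = c("strict", "keep")) {
  missing_policy <- match.arg(missing_policy)
  aln <- as_alignment(aln)
  if (is.null(rownames(aln)))
    rownames(aln) <- paste0("seq", seq_len(nrow(aln)))
  dropped <- character(0)
  if (missing_policy == "strict") {
    clean <- apply(aln, 1, function(s) all(s %in% c("A", "C", "G", "T")))
    dropped <- rownames(aln)[!clean]
    aln <- aln[clean, , drop = FALSE]
  }
  if (!nrow(aln)) stop("no sequences left after filtering")
  key <- apply(aln, 1, paste, collapse = "")
  uniq <- unique(key)
  hap_names <- paste0("H", seq_along(uniq))
  assignment <- stats::setNames(hap_names[match(key, uniq)], rownames(aln))
  members <- split(names(assignment), assignment)
  members <- members[hap_names]
  haps <- aln[match(uniq, key), , drop = FALSE]
  rownames(haps) <- hap_names
  structure(list(haplotypes = haps, members = members,
                 assignment = assignment, dropped = dropped),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes from %d sequences (%d dropped)\n",
              nrow(x$haplotypes), length(x$assignment), length(x$dropped)))
  invisible(x)
}

#' Sequence diversity statistics
#'
#' Number of polymorphic sites S, haplotype number h, haplotype diversity
#' `Hd = n/(n-1) (1 - sum p_i^2)` over haplotype frequencies, and nucleotide
#' diversity `pi` (mean pairwise differences per site).
#'
#' @param aln character matrix alignment of the group (>= 2 sequences,
#'   unambiguous sites assumed; apply [collapse_haplotypes()] policy first)
#' @return list `S`, `h`, `Hd`, `pi`, `n`
#' @export
diversity_stats <- function(aln) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 2) stop("need >= 2 sequences")
  S <- sum(apply(aln, 2, function(col) length(unique(col)) > 1))
  key <- apply(aln, 1, paste, collapse = "")
  hf <- as.numeric(table(key)) / n
  Hd <- n / (n - 1) * (1 - sum(hf^2))
  dmat <- pairwise_differences(aln)
  pi <- mean(dmat[lower.tri(dmat)]) / ncol(aln)
  list(S = S, h = length(hf), Hd = Hd, pi = pi, n = n)
}

# pairwise raw difference counts (comparable = both unambiguous)
pairwise_differences <- function(aln) {
  n <- nrow(aln)
  base <- c("A", "C", "G", "T")
  num <- matrix(match(aln, base), n)  # NA for ambiguity/gap
  D <- matrix(0L, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- !is.na(num[i, ]) & !is.na(num[j, ])
    D[i, j] <- D[j, i] <- sum(num[i, comp] != num[j, comp])
  }
  D
}

#' Kimura 2-parameter distance matrix
#'
#' `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))` with P and Q the transition and
#' transversion proportions over mutually unambiguous sites (pairwise
#' deletion). Saturated pairs (non-positive log argument) are flagged `Inf`.
#'
#' @param aln character matrix alignment (or `DNAbin`)
#' @return symmetric numeric distance matrix
#' @export
k2p_matrix <- function(aln) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    a <- aln[i, ]; b <- aln[j, ]
    comp <- a %in% names(purine) & b %in% names(purine)
    a <- a[comp]; b <- b[comp]
    L <- length(a)
    if (L == 0) { D[i, j] <- D[j, i] <- NA_real_; next }
    diff <- a != b
    ts <- sum(diff & (purine[a] == purine[b]))  # A<->G, C<->T
    tv <- sum(diff) - ts
    D[i, j] <- D[j, i] <- k2p_from_pq(ts / L, tv / L)
  }
  D
}

#' @rdname k2p_matrix
#' @param P,Q transition and transversion proportions
#' @export
k2p_from_pq <- function(P, Q) {
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(Inf)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Neighbor-joining tree with bootstrap support
#'
#' Saitou-Nei NJ (via [ape::nj()]) on a K2P matrix; node support from
#' resampling alignment columns `n_bootstrap` times.
#'
#' @param aln character matrix alignment (>= 3 sequences)
#' @param n_bootstrap bootstrap replicates (0 = none)
#' @param seed integer seed
#' @return list `tree` (an `ape::phylo`, `node.label` carrying bootstrap
#'   percentages when requested) and `newick`
#' @export
nj_tree <- function(aln, n_bootstrap = 500, seed = 1) {
  aln <- as_alignment(aln)
  if (nrow(aln) < 3) stop("need >= 3 sequences for a tree")
  tr <- ape::nj(stats::as.dist(k2p_matrix(aln)))
  if (n_bootstrap > 0) {
    rs <- local_seed(seed)
    on.exit(rs$restore())
    bp <- ape::boot.phylo(tr, aln, function(m)
      ape::nj(stats::as.dist(k2p_matrix(m))), B = n_bootstrap,
      quiet = TRUE)
    tr$node.label <- round(100 * bp / n_bootstrap)
  }
  list(tree = tr, newick = ape::write.tree(tr))
}

# tip indices descending from each internal node of a phylo tree
clade_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  desc <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # edges listed parent->child; process children before parents
  ord <- order(tree$edge[, 1])
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (!is.null(desc[[ch]]) &&
          !all(desc[[ch]] %in% desc[[p]] %||% integer(0))) {
        desc[[p]] <- unique(c(desc[[p]], desc[[ch]]))
        done <- FALSE
      }
    }
    if (done) break
  }
  desc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign query sequences to reference lineages by NJ clustering
#'
#' Builds an NJ/K2P tree over references plus queries; each query takes the
#' lineage of the smallest clade containing it together with references of
#' a single lineage. Queries whose first reference-containing ancestor mixes
#' lineages are left unassigned with a tie/paraphyly diagnostic; queries
#' sharing fewer than `min_overlap` unambiguous sites with the references
#' are unassigned.
#'
#' @param query character matrix alignment of query sequences
#' @param reference character matrix alignment of reference sequences
#' @param lineages named character vector: reference ID -> lineage label
#' @param min_overlap minimum unambiguous sites per query (default 100)
#' @return data frame: id, lineage (NA when unassigned), reason
#' @export
assign_lineage <- function(query, reference, lineages, min_overlap = 100) {
  query <- as_alignment(query); reference <- as_alignment(reference)
  stopifnot(ncol(query) == ncol(reference))
  if (is.null(rownames(query)))
    rownames(query) <- paste0("q", seq_len(nrow(query)))
  stopifnot(all(rownames(reference) %in% names(lineages)))
  if (length(unique(lineages[rownames(reference)])) < 2)
    stop("references must cover >= 2 lineages")
  comb <- rbind(reference, query)
  tr <- ape::nj(stats::as.dist(k2p_matrix(comb)))
  desc <- clade_tips(tr)
  n_tip <- length(tr$tip.label)
  parent_of <- integer(n_tip + tr$Nnode)
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  is_ref <- tr$tip.label %in% rownames(reference)
  out <- lapply(rownames(query), function(q) {
    ok_sites <- sum(query[q, ] %in% c("A", "C", "G", "T"))
    if (ok_sites < min_overlap)
      return(data.frame(id = q, lineage = NA_character_,
                        reason = "insufficient overlap",
                        stringsAsFactors = FALSE))
    node <- match(q, tr$tip.label)
    repeat {
      node <- parent_of[node]
      if (node == 0L)
        return(data.frame(id = q, lineage = NA_character_,
                          reason = "no reference clade",
                          stringsAsFactors = FALSE))
      tips <- desc[[node]]
      refs_here <- tr$tip.label[tips][is_ref[tips]]
      if (length(refs_here)) {
        lin <- unique(lineages[refs_here])
        if (length(lin) == 1L)
          return(data.frame(id = q, lineage = unname(lin), reason = "",
                            stringsAsFactors = FALSE))
        return(data.frame(id = q, lineage = NA_character_,
                          reason = "tie/paraphyly",
                          stringsAsFactors = FALSE))
      }
    }
  })
  do.call(rbind, out)
}

# Expected relative mismatch frequencies under sudden demographic expansion
# (Rogers-Harpending model): coalescence hazard 1/theta1 until tau (back in
# time), 1/theta0 beyond; time in mutational units so a pair accumulates
# differences at rate 1. Closed form via regularized incomplete gamma.
mismatch_expected <- function(j, tau, theta0, theta1) {
  a <- 1 + 1 / theta1
  b <- 1 + 1 / theta0
  part1 <- (1 / theta1) * a^(-(j + 1)) * stats::pgamma(a * tau, j + 1)
  part2 <- exp(tau * (1 / theta0 - 1 / theta1)) * (1 / theta0) *
    b^(-(j + 1)) * stats::pgamma(b * tau, j + 1, lower.tail = FALSE)
  part1 + part2
}

#' Harpending's raggedness statistic
#'
#' `r = sum (x_i - x_{i-1})^2` over classes 0 .. d_max + 1 of the relative
#' mismatch frequencies, with the convention that the class before 0 and the
#' class after d_max are zero (so a single-class distribution has r = 2).
#'
#' @param freq relative frequencies of difference classes 0..d_max
#' @export
raggedness <- function(freq) {
  x <- c(0, freq, 0)
  sum(diff(x)^2)
}

# least-squares fit of (tau, theta0, theta1) to the observed relative
# mismatch frequencies; multi-start Nelder-Mead on a transformed scale
# keeping tau >= 0 and theta1 >= theta0 >= 0
fit_mismatch <- function(obs_freq) {
  jj <- seq_along(obs_freq) - 1
  ssd <- function(par) {
    tau <- exp(par[1]); th0 <- exp(par[2]); th1 <- th0 + exp(par[3])
    e <- mismatch_expected(jj, tau, th0, th1)
    sum((obs_freq - e)^2)
  }
  mean_d <- sum(jj * obs_freq)
  starts <- list(c(log(mean_d + 0.5), log(0.1), log(mean_d + 0.5)),
                 c(log(mean_d + 0.5), log(1), log(1)),
                 c(log(0.5), log(0.1), log(2 * mean_d + 1)),
                 c(log(2 * mean_d + 1), log(0.5), log(0.5)))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, ssd, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(tau = exp(best$par[1]), theta0 = exp(best$par[2]),
       theta1 = exp(best$par[2]) + exp(best$par[3]), ssd = best$value,
       converged = best$convergence == 0)
}

# coalescent simulation of pairwise-difference matrix under sudden
# expansion, infinite sites, time in mutational units (see above)
sim_expansion_differences <- function(n, tau, theta0, theta1) {
  total <- 2 * n - 1
  parent <- integer(total)
  blen <- numeric(total)
  t_now <- 0
  active <- seq_len(n)
  nxt <- n + 1L
  j <- n
  while (j > 1) {
    theta_now <- if (t_now < tau) theta1 else theta0
    rate <- j * (j - 1) / 2 / theta_now
    t_step <- stats::rexp(1, rate)
    if (t_now < tau && t_now + t_step > tau) {
      # crossing the expansion time: restart the draw under the old size
      blen[active] <- blen[active] + (tau - t_now)
      t_now <- tau
      next
    }
    blen[active] <- blen[active] + t_step
    t_now <- t_now + t_step
    pick <- sample(j, 2)
    c1 <- active[pick[1]]; c2 <- active[pick[2]]
    parent[c1] <- nxt; parent[c2] <- nxt
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
    j <- j - 1L
  }
  # tips under each node
  D <- matrix(0L, n, n)
  desc <- vector("list", total)
  for (v in seq_len(n)) desc[[v]] <- v
  for (v in seq_len(total - 1)) {
    # children created before parents: resolve in index order
    p <- parent[v]
    desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  all_tips <- seq_len(n)
  for (v in seq_len(total - 1)) {
    m <- stats::rpois(1, blen[v] / 2)
    if (m == 0) next
    inside <- desc[[v]]
    outside <- setdiff(all_tips, inside)
    D[inside, outside] <- D[inside, outside] + m
  }
  # each unordered pair was incremented on one side only; symmetrize
  D + t(D)
}

#' Mismatch-distribution analysis for sudden demographic expansion
#'
#' Builds the observed histogram of pairwise sequence differences, fits the
#' sudden-expansion model (tau, theta0, theta1) by least squares on the
#' relative frequencies, computes the sum of squared deviations (SSD) and
#' Harpending's raggedness, and derives p-values from a parametric
#' bootstrap: coalescent samples simulated under the fitted expansion, each
#' refitted, upper-tail comparison of SSD and raggedness
#' (`P(sim >= obs)`, add-one rule).
#'
#' @param aln character matrix alignment of the group
#' @param n_bootstrap bootstrap replicates (default 1000)
#' @param seed integer seed
#' @return object of class `mismatch_fit`: list `histogram` (counts by
#'   difference class 0..d_max), `tau`, `theta0`, `theta1`, `ssd`,
#'   `raggedness`, `p_ssd`, `p_raggedness`, `n`, `converged`
#' @export
mismatch_analysis <- function(aln, n_bootstrap = 1000, seed = 1) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 10) warning("fewer than 10 sequences: mismatch fit is fragile")
  D <- pairwise_differences(aln)
  dv <- D[lower.tri(D)]
  d_max <- max(dv)
  counts <- tabulate(dv + 1L, nbins = d_max + 1L)
  freq <- counts / sum(counts)
  fit <- fit_mismatch(freq)
  r_obs <- raggedness(freq)
  rs <- local_seed(seed)
  on.exit(rs$restore())
  hits_ssd <- 0L; hits_rag <- 0L
  if (n_bootstrap > 0) {
    for (b in seq_len(n_bootstrap)) {
      Ds <- sim_expansion_differences(n, fit$tau, fit$theta0, fit$theta1)
      dvs <- Ds[lower.tri(Ds)]
      fs <- tabulate(dvs + 1L, nbins = max(dvs) + 1L) / length(dvs)
      fit_s <- fit_mismatch(fs)
      if (fit_s$ssd >= fit$ssd) hits_ssd <- hits_ssd + 1L
      if (raggedness(fs) >= r_obs) hits_rag <- hits_rag + 1L
    }
  }
  structure(list(histogram = stats::setNames(counts, 0:d_max),
                 tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
                 ssd = fit$ssd, raggedness = r_obs,
                 p_ssd = if (n_bootstrap > 0)
                   perm_pvalue(hits_ssd, n_bootstrap) else NA_real_,
                 p_raggedness = if (n_bootstrap > 0)
                   perm_pvalue(hits_rag, n_bootstrap) else NA_real_,
                 n = n, converged = fit$converged),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf(
    "mismatch_fit: n = %d, tau = %.3f, theta0 = %.3f, theta1 = %.3f\n",
    x$n, x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.5f (p = %s), raggedness = %.5f (p = %s)\n",
              x$ssd, format(x$p_ssd), x$raggedness,
              format(x$p_raggedness)))
  invisible(x)
}

#' Synthetic two-lineage cytochrome-b style alignment
#'
#' Generates a random ancestral sequence, derives two lineage consensus
#' sequences separated by `n_fixed_diff` fixed differences, and samples
#' individual sequences with private Poisson mutations, mimicking the
#' structure of divergent mitochondrial clades.
#'
#' @param n_per_lineage sequences per lineage (length-2 vector or scalar)
#' @param seq_length sites (default 402, a cyt-b fragment length)
#' @param n_fixed_diff fixed differences between lineages (default 23)
#' @param mutations_per_seq mean private mutations per sequence
#' @param seed integer seed
#' @return list `alignment` (character matrix), `lineage` (named vector)
#' @export
simulate_mtdna <- function(n_per_lineage = c(30, 10), seq_length = 402,
                           n_fixed_diff = 23, mutations_per_seq = 2,
                           seed = 1) {
  rs <- local_seed(seed)
  on.exit(rs$restore())
  n_per_lineage <- rep_len(n_per_lineage, 2)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, seq_length, replace = TRUE)
  fixed_sites <- sample(seq_length, n_fixed_diff)
  cons <- list(A = anc, B = anc)
  for (s in fixed_sites)
    cons$B[s] <- sample(setdiff(bases, cons$A[s]), 1)
  seqs <- list(); lineage <- character(0)
  for (g in c("A", "B")) {
    ng <- n_per_lineage[match(g, c("A", "B"))]
    for (i in seq_len(ng)) {
      s <- cons[[g]]
      nm <- stats::rpois(1, mutations_per_seq)
      if (nm > 0) {
        sites <- sample(seq_length, min(nm, seq_length))
        for (site in sites)
          s[site] <- sample(setdiff(bases, s[site]), 1)
      }
      id <- sprintf("%s_%02d", g, i)
      seqs[[id]] <- s
      lineage[id] <- g
    }
  }
  aln <- do.call(rbind, seqs)
  list(alignment = aln, lineage = lineage)
}
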
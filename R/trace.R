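# Geographic tracing via generalized private-allele rarefaction:
# rarefied private-allele curves per (locus, population), locus selection,
# cross-filtering against observed private alleles, and screening of
# market/seizure genotypes for source assignment.

#' Generalized rarefaction of distinct and private alleles
#'
#' For a set S of reference populations, computes for every locus,
#' population j in S and subsample size g:
#' expected distinct alleles `E[A] = sum_i [1 - C(N_j - N_ji, g)/C(N_j, g)]`
#' and expected private alleles
#' `paf = sum_i [1 - C(N_j - N_ji, g)/C(N_j, g)] *
#'        prod_{k != j} C(N_k - N_ki, g)/C(N_k, g)`
#' (the allele is seen in j's subsample and missed in every other
#' population's subsample of the same size).
#'
#' @param af an [allele_counts()] result over the population set S
#' @param g_max largest subsample size; curves run g = 2..g_max
#' @param unit `"individuals"` (default: g individuals = 2g gene copies, as
#'   in rarefying "from 2 to 5 individuals") or `"genes"`
#' @return object of class `rarefaction_curves`: list with `distinct` and
#'   `private`, each a named list `[[locus]][[pop]]` of numeric vectors
#'   indexed by g, plus `g_values`, `unit`, `pops`, `loci`
#' @export
rarefy_private_alleles <- function(af, g_max, unit = c("individuals",
                                                       "genes")) {
  unit <- match.arg(unit)
  g_values <- 2:g_max
  gene_g <- if (unit == "individuals") 2L * g_values else g_values
  for (p in af$pops) for (l in af$loci) {
    if (max(gene_g) > af$n_genes[p, l])
      stop(sprintf(
        "g = %d gene copies exceeds n_genes = %d for population %s at %s",
        max(gene_g), af$n_genes[p, l], p, l))
  }
  distinct <- stats::setNames(vector("list", length(af$loci)), af$loci)
  private <- distinct
  for (l in af$loci) {
    alleles <- sort(unique(unlist(lapply(af$pops, function(p)
      names(af$counts[[p]][[l]])))))
    # absence probability per (pop, allele, g)
    distinct[[l]] <- stats::setNames(vector("list", length(af$pops)),
                                     af$pops)
    private[[l]] <- distinct[[l]]
    Q <- array(dim = c(length(af$pops), length(alleles), length(g_values)),
               dimnames = list(af$pops, alleles, g_values))
    for (p in af$pops) for (a in alleles) {
      Ni <- af$counts[[p]][[l]][a]
      if (is.na(Ni)) Ni <- 0
      for (gi in seq_along(g_values))
        Q[p, a, gi] <- absence_prob(af$n_genes[p, l], Ni, gene_g[gi])
    }
    for (p in af$pops) {
      pres <- 1 - Q[p, , , drop = FALSE]
      dim(pres) <- dim(Q)[2:3]
      others <- setdiff(af$pops, p)
      absent_elsewhere <- apply(Q[others, , , drop = FALSE], c(2, 3), prod)
      distinct[[l]][[p]] <- stats::setNames(colSums(pres), g_values)
      private[[l]][[p]] <- stats::setNames(
        colSums(pres * absent_elsewhere), g_values)
    }
  }
  structure(list(distinct = distinct, private = private,
                 g_values = g_values, unit = unit, pops = af$pops,
                 loci = af$loci),
            class = "rarefaction_curves")
}

#' @export
print.rarefaction_curves <- function(x, ...) {
  cat(sprintf(
    "rarefaction_curves: %d loci x %d populations, g = %d..%d %s\n",
    length(x$loci), length(x$pops), min(x$g_values), max(x$g_values),
    x$unit))
  invisible(x)
}

#' Select loci/populations with tracing-grade private-allele signal
#'
#' Keeps (locus, population) combinations whose rarefied expected
#' private-allele count at `g_star` exceeds `paf_threshold` and whose curve
#' has reached a plateau or is still increasing there (last-step slope
#' `paf(g_star) - paf(g_star - 1) >= -slope_tolerance`).
#'
#' @param curves a [rarefy_private_alleles()] result
#' @param paf_threshold minimum paf at `g_star` (default 0.4)
#' @param g_star evaluation subsample size (default 5)
#' @param slope_tolerance tolerated decline over the last step (default 0.01)
#' @return data frame: locus, pop, paf, slope
#' @export
select_tracing_loci <- function(curves, paf_threshold = 0.4, g_star = 5,
                                slope_tolerance = 0.01) {
  if (!g_star %in% curves$g_values || !(g_star - 1) %in% curves$g_values)
    stop("g_star (and g_star - 1) must lie within the curve range")
  out <- list()
  for (l in curves$loci) for (p in curves$pops) {
    v <- curves$private[[l]][[p]]
    paf <- v[[as.character(g_star)]]
    slope <- paf - v[[as.character(g_star - 1)]]
    if (paf > paf_threshold && slope >= -slope_tolerance)
      out[[length(out) + 1L]] <- data.frame(
        locus = l, pop = p, paf = paf, slope = slope,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(locus = character(0), pop = character(0),
                      paf = numeric(0), slope = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Alleles observed in exactly one reference population
#'
#' @param af an [allele_counts()] result over >= 2 reference populations
#' @return data frame: locus, allele, pop, count, freq
#' @export
observed_private_alleles <- function(af) {
  if (length(af$pops) < 2L) stop("need >= 2 populations")
  if (length(af$empty_pops))
    warning("empty population(s) make privacy trivial: ",
            paste(af$empty_pops, collapse = ", "))
  out <- list()
  for (l in af$loci) {
    seen <- list()
    for (p in af$pops) {
      cnt <- af$counts[[p]][[l]]
      for (a in names(cnt[cnt > 0])) seen[[a]] <- c(seen[[a]], p)
    }
    for (a in names(seen)) {
      if (length(seen[[a]]) == 1L) {
        p <- seen[[a]]
        out[[length(out) + 1L]] <- data.frame(
          locus = l, allele = as.integer(a), pop = p,
          count = unname(af$counts[[p]][[l]][a]),
          freq = unname(af$counts[[p]][[l]][a] / af$n_genes[p, l]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(locus = character(0), allele = integer(0),
                      pop = character(0), count = numeric(0),
                      freq = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# rarefied expected private contribution of a single allele: seen in the
# focal population's subsample of g gene copies and missed in every other
allele_private_paf <- function(af, locus, pop, allele, g) {
  a <- as.character(allele)
  Np <- af$n_genes[pop, locus]
  cnt <- af$counts[[pop]][[locus]][a]
  if (is.na(cnt)) cnt <- 0
  pres <- 1 - absence_prob(Np, cnt, g)
  abs_else <- 1
  for (k in setdiff(af$pops, pop)) {
    ck <- af$counts[[k]][[locus]][a]
    if (is.na(ck)) ck <- 0
    abs_else <- abs_else * absence_prob(af$n_genes[k, locus], ck, g)
  }
  pres * abs_else
}

#' Cross-filter rarefaction candidates with observed private alleles
#'
#' The tracing panel retains, at each (locus, population) kept by
#' [select_tracing_loci()], the private alleles actually observed in that
#' population — both lines of evidence must agree. When the frequency table
#' is supplied, each allele is additionally screened on its own merits:
#' it must be observed at least `min_count` times and its individual
#' rarefied private expectation at `g` gene copies must exceed
#' `allele_paf_threshold`. This guards against sampling-noise privates —
#' rare alleles that happen to be unobserved in the other reference samples
#' but are not truly private — which otherwise cause false assignments.
#'
#' @param candidates a [select_tracing_loci()] result
#' @param observed an [observed_private_alleles()] result
#' @param af optional [allele_counts()] table enabling the allele-level
#'   screen
#' @param g gene copies for the allele-level rarefaction (match the curves)
#' @param min_count minimum observed copies of a panel allele (default 2)
#' @param allele_paf_threshold minimum per-allele rarefied private
#'   expectation (default 0.4, matching the locus-level screen)
#' @return data frame (class `tracing_panel`): locus, allele, pop
#' @export
build_panel <- function(candidates, observed, af = NULL, g = 10,
                        min_count = 2, allele_paf_threshold = 0.4) {
  key_c <- paste(candidates$locus, candidates$pop)
  keep <- paste(observed$locus, observed$pop) %in% key_c
  if (!is.null(af)) {
    for (i in which(keep)) {
      if (observed$count[i] < min_count) {
        keep[i] <- FALSE
        next
      }
      contrib <- allele_private_paf(af, observed$locus[i], observed$pop[i],
                                    observed$allele[i], g)
      if (contrib <= allele_paf_threshold) keep[i] <- FALSE
    }
  }
  panel <- observed[keep, c("locus", "allele", "pop")]
  rownames(panel) <- NULL
  if (!nrow(panel)) warning("empty tracing panel")
  if (anyDuplicated(panel[, c("locus", "allele")]))
    stop("panel inconsistency: one (locus, allele) maps to several sources")
  class(panel) <- c("tracing_panel", class(panel))
  panel
}

#' Assign market/seizure individuals to source populations
#'
#' An individual is assigned to source P when it carries at least one panel
#' allele of P; individuals carrying panel alleles of several sources are
#' kept but flagged as conflicted. Missing genotypes at panel loci simply
#' contribute no evidence.
#'
#' @param x a [genotype_table()] of market/seizure individuals
#' @param panel a [build_panel()] result
#' @return data frame (one row per individual with evidence): id, market,
#'   sources (comma-joined), n_sources, conflict, evidence (locus:allele
#'   pairs)
#' @export
assign_sources <- function(x, panel) {
  stopifnot(all(panel$locus %in% loci_names(x)))
  out <- list()
  for (i in seq_len(n_ind(x))) {
    hits <- list()
    for (k in seq_len(nrow(panel))) {
      l <- match(panel$locus[k], loci_names(x))
      if (is.na(x$a1[i, l])) next
      if (x$a1[i, l] == panel$allele[k] || x$a2[i, l] == panel$allele[k])
        hits[[length(hits) + 1L]] <- panel[k, ]
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    srcs <- sort(unique(h$pop))
    out[[length(out) + 1L]] <- data.frame(
      id = sample_ids(x)[i], market = x$meta$pop[i],
      sources = paste(srcs, collapse = ","), n_sources = length(srcs),
      conflict = length(srcs) > 1L,
      evidence = paste(sprintf("%s:%d", h$locus, h$allele), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(id = character(0), market = character(0),
                      sources = character(0), n_sources = integer(0),
                      conflict = logical(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Market-by-source assignment summary
#'
#' Counts non-conflicted assignments per (market, source); a chord-diagram
#' ready matrix. Row sums equal the number of non-conflicted assigned
#' individuals per market.
#'
#' @param assignments an [assign_sources()] result
#' @param include_conflicted count conflicted individuals once per candidate
#'   source (default FALSE)
#' @return integer matrix markets x sources
#' @export
trace_summary <- function(assignments, include_conflicted = FALSE) {
  a <- if (include_conflicted) assignments
  else assignments[!assignments$conflict, , drop = FALSE]
  if (!nrow(a)) return(matrix(0L, 0, 0))
  pairs <- do.call(rbind, lapply(seq_len(nrow(a)), function(k)
    data.frame(market = a$market[k],
               source = strsplit(a$sources[k], ",")[[1]],
               stringsAsFactors = FALSE)))
  tab <- table(pairs$market, pairs$source)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' One-call tracing pipeline
#'
#' Rarefaction over the reference populations, locus selection,
#' cross-filtering, and screening of every market/seizure individual.
#'
#' @param x a [genotype_table()] containing reference and market/seizure
#'   individuals
#' @param g_star,paf_threshold,slope_tolerance see [select_tracing_loci()]
#' @param unit rarefaction unit, see [rarefy_private_alleles()]
#' @return list `curves`, `candidates`, `observed`, `panel`, `assignments`,
#'   `summary`
#' @export
trace_pipeline <- function(x, g_star = 5, paf_threshold = 0.4,
                           slope_tolerance = 0.01, unit = "individuals") {
  refs <- pop_map(x, classes = "reference")
  af <- allele_counts(x, refs)
  gene_g <- if (unit == "individuals") 2L * g_star else g_star
  ok <- apply(af$n_genes, 1, function(v) all(v >= gene_g))
  if (!all(ok))
    warning("populations dropped from rarefaction (too few gene copies): ",
            paste(names(ok)[!ok], collapse = ", "))
  af_r <- allele_counts(x, refs[ok])
  curves <- rarefy_private_alleles(af_r, g_max = g_star, unit = unit)
  candidates <- select_tracing_loci(curves, paf_threshold, g_star,
                                    slope_tolerance)
  observed <- observed_private_alleles(af_r)
  panel <- build_panel(candidates, observed, af = af_r, g = gene_g,
                       allele_paf_threshold = paf_threshold)
  mk <- x[x$meta$class %in% c("market", "seizure"), ]
  assignments <- assign_sources(mk, panel)
  list(curves = curves, candidates = candidates, observed = observed,
       panel = panel, assignments = assignments,
       summary = trace_summary(assignments))
}
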
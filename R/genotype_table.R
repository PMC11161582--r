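#' Diploid microsatellite genotype table
#'
#' The central container of the package: an individuals x loci table of
#' unordered diploid allele calls plus per-individual metadata. Allele codes
#' are positive integers (fragment sizes in bp); a missing genotype is stored
#' as `NA` in both allele slots. Calls are stored sorted ascending
#' (`a1 <= a2`) so that genotype comparison is canonical.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two alleles
#'   of each call; `NA` in both marks a missing genotype. Row names are sample
#'   IDs, column names locus names. Unsorted pairs are sorted on construction.
#' @param meta data frame of per-individual metadata with at least a column
#'   `id` matching the row names of `a1`. Recognised optional columns:
#'   `pop` (population label), `class` (one of `"reference"`, `"market"`,
#'   `"seizure"`), `lon`, `lat` (WGS84 decimal degrees), `lineage`
#'   (mtDNA lineage label), `true_source` (generator truth for synthetic
#'   market individuals), `duplicate_of` (ID copied by [corrupt_genotypes()]).
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(a1, a2, meta = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("a1 and a2 must have identical dimensions")
  if (is.null(rownames(a1)) && nrow(a1) > 0)
    rownames(a1) <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(colnames(a1)) && ncol(a1) > 0)
    colnames(a1) <- paste0("L", seq_len(ncol(a1)))
  dimnames(a2) <- dimnames(a1)
  if (anyDuplicated(rownames(a1)))
    stop("sample IDs must be unique")
  # canonicalize: both NA together, pairs sorted ascending
  na1 <- is.na(a1); na2 <- is.na(a2)
  if (any(na1 != na2))
    stop("half-missing calls are not representable: both alleles must be NA")
  if (any(c(a1, a2) <= 0L, na.rm = TRUE))
    stop("allele codes must be positive integers (0 is not a valid allele)")
  swap <- !na1 & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  ids <- rownames(a1)
  if (is.null(meta)) meta <- data.frame(id = ids, stringsAsFactors = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"id" %in% names(meta)) stop("meta must contain an 'id' column")
  if (!setequal(meta$id, ids) || nrow(meta) != length(ids))
    stop("meta$id must match the table's sample IDs exactly")
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  for (col in c("pop", "class", "lineage", "true_source", "duplicate_of"))
    if (!col %in% names(meta)) meta[[col]] <- rep(NA_character_, nrow(meta))
  for (col in c("lon", "lat"))
    if (!col %in% names(meta)) meta[[col]] <- rep(NA_real_, nrow(meta))
  bad_class <- !is.na(meta$class) &
    !meta$class %in% c("reference", "market", "seizure")
  if (any(bad_class))
    stop("class must be one of reference/market/seizure")
  structure(list(a1 = a1, a2 = a2, meta = meta), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci\n",
              n_ind(x), n_loci(x)))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  cls <- table(x$meta$class, useNA = "ifany")
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n")
  np <- length(unique(stats::na.omit(x$meta$pop)))
  cat(sprintf("  populations labelled: %d\n", np))
  invisible(x)
}

#' @rdname genotype_table
#' @param x a `genotype_table`
#' @export
n_ind <- function(x) nrow(x$a1)

#' @rdname genotype_table
#' @export
n_loci <- function(x) ncol(x$a1)

#' @rdname genotype_table
#' @export
loci_names <- function(x) colnames(x$a1)

#' @rdname genotype_table
#' @export
sample_ids <- function(x) rownames(x$a1)

#' Subset a genotype table by individuals and/or loci
#'
#' @param x a `genotype_table`
#' @param i sample IDs, indices or logical vector selecting individuals
#' @param j locus names, indices or logical vector selecting loci
#' @param ... unused
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_ind(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  if (is.character(i)) i <- match(i, sample_ids(x))
  genotype_table(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                 x$meta[i, , drop = FALSE])
}

#' Combine genotype tables sharing the same loci
#'
#' @param ... `genotype_table` objects with identical locus sets
#' @export
rbind_tables <- function(...) {
  tabs <- list(...)
  loci <- loci_names(tabs[[1]])
  for (t in tabs)
    if (!identical(loci_names(t), loci)) stop("locus sets differ")
  meta_cols <- Reduce(union, lapply(tabs, function(t) names(t$meta)))
  metas <- lapply(tabs, function(t) {
    m <- t$meta
    for (col in setdiff(meta_cols, names(m))) m[[col]] <- NA
    m[, meta_cols, drop = FALSE]
  })
  genotype_table(do.call(rbind, lapply(tabs, `[[`, "a1")),
                 do.call(rbind, lapply(tabs, `[[`, "a2")),
                 do.call(rbind, metas))
}

#' Population map: named partition of individuals
#'
#' A population map is a named list mapping population labels to character
#' vectors of sample IDs. Populations must be disjoint and every ID must
#' exist in the table. `pop_map()` builds the map from the `pop` metadata
#' column, by default restricted to reference-class individuals.
#'
#' @param x a `genotype_table`
#' @param classes which sample classes to include (default `"reference"`;
#'   use `NULL` for all)
#' @return named list of sample-ID vectors
#' @export
pop_map <- function(x, classes = "reference") {
  m <- x$meta
  keep <- !is.na(m$pop)
  if (!is.null(classes)) keep <- keep & m$class %in% classes
  split(m$id[keep], m$pop[keep])
}

#' @rdname pop_map
#' @param partition a candidate population map
#' @export
validate_pop_map <- function(x, partition) {
  ids <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(ids) > 0L) stop("populations must be disjoint")
  if (!all(ids %in% sample_ids(x)))
    stop("population map contains IDs absent from the table")
  invisible(partition)
}

#' Retain individuals genotyped at a minimum fraction of loci
#'
#' Mirrors the usual quality filter for microsatellite datasets (e.g. keeping
#' individuals typed at >= 75% of loci, i.e. >= 15 of 20 markers).
#' Idempotent; preserves individual order.
#'
#' @param x a `genotype_table`
#' @param min_fraction minimum fraction of non-missing loci in `[0, 1]`
#' @export
filter_by_completeness <- function(x, min_fraction = 0.75) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  frac <- rowMeans(!is.na(x$a1))
  x[frac >= min_fraction, ]
}

#' Per-population allele counts and frequencies
#'
#' Counts gene copies per (population, locus) over non-missing calls only;
#' `n_genes = 2 x` the number of typed genotypes. This is the input to
#' allelic richness, rarefaction and the identity indices.
#'
#' @param x a `genotype_table`
#' @param partition population map (default [pop_map()] of `x`)
#' @return An object of class `allele_freq_table`: a list with elements
#'   `counts` (`counts[[pop]][[locus]]` = named vector of gene-copy counts),
#'   `n_genes` (populations x loci matrix), `pops`, `loci`, and
#'   `empty_pops` (populations with zero typed genotypes everywhere, flagged).
#' @export
allele_counts <- function(x, partition = pop_map(x)) {
  validate_pop_map(x, partition)
  pops <- names(partition)
  loci <- loci_names(x)
  n_genes <- matrix(0L, length(pops), length(loci),
                    dimnames = list(pops, loci))
  counts <- stats::setNames(vector("list", length(pops)), pops)
  for (p in pops) {
    idx <- match(partition[[p]], sample_ids(x))
    counts[[p]] <- stats::setNames(vector("list", length(loci)), loci)
    for (l in seq_along(loci)) {
      al <- c(x$a1[idx, l], x$a2[idx, l])
      al <- al[!is.na(al)]
      tb <- table(al)
      cnt <- stats::setNames(as.integer(tb), names(tb))
      counts[[p]][[l]] <- cnt
      n_genes[p, l] <- length(al)
    }
  }
  structure(list(counts = counts, n_genes = n_genes, pops = pops,
                 loci = loci,
                 empty_pops = pops[rowSums(n_genes) == 0L]),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d populations x %d loci\n",
              length(x$pops), length(x$loci)))
  if (length(x$empty_pops))
    cat("  empty populations:", paste(x$empty_pops, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname allele_counts
#' @param af an `allele_freq_table`
#' @param pop,locus population and locus name
#' @return `af_freq()`: named numeric vector of allele frequencies (empty when
#'   no gene copies were typed). Frequencies sum to 1 within 1e-12.
#' @export
af_freq <- function(af, pop, locus) {
  cnt <- af$counts[[pop]][[locus]]
  n <- af$n_genes[pop, locus]
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  cnt / n
}

#' Merge two allele-frequency tables by summing counts
#'
#' Used when pooling populations; counts are additive under population union.
#'
#' @param af an `allele_freq_table`
#' @param pops populations to pool
#' @param name label for the pooled population
#' @export
pool_populations <- function(af, pops, name = paste(pops, collapse = "+")) {
  stopifnot(all(pops %in% af$pops))
  loci <- af$loci
  pooled <- stats::setNames(vector("list", length(loci)), loci)
  ng <- integer(length(loci))
  for (l in seq_along(loci)) {
    all_alleles <- sort(unique(unlist(lapply(pops, function(p)
      names(af$counts[[p]][[l]])))))
    cnt <- stats::setNames(numeric(length(all_alleles)), all_alleles)
    for (p in pops) {
      cp <- af$counts[[p]][[l]]
      cnt[names(cp)] <- cnt[names(cp)] + cp
    }
    pooled[[l]] <- cnt
    ng[l] <- sum(af$n_genes[pops, l])
  }
  keep <- setdiff(af$pops, pops)
  counts <- af$counts[keep]
  counts[[name]] <- pooled
  n_genes <- rbind(af$n_genes[keep, , drop = FALSE],
                   matrix(ng, 1, dimnames = list(name, loci)))
  structure(list(counts = counts, n_genes = n_genes,
                 pops = c(keep, name), loci = loci,
                 empty_pops = c(keep, name)[rowSums(n_genes) == 0L]),
            class = "allele_freq_table")
}
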
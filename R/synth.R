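#' Synthetic population models for diploid microsatellite data
#'
#' Builds a `population_model`: per-population, per-locus allele frequency
#' vectors derived from a shared ancestral vector by Dirichlet perturbation,
#' with optional spatial structuring of the perturbations
#' (isolation-by-distance), per-population inbreeding/Wahlund coefficients,
#' and injected population-private alleles at controlled frequencies.
#'
#' Differentiation is governed by `concentration`: each population's
#' frequency vector is drawn `Dirichlet(concentration * p_ancestral)`, so
#' every allele has among-population variance `p(1-p)/(concentration + 1)`
#' and the model-expected Weir-Cockerham theta is
#' `1 / (concentration + 1)` (see [expected_fst()]). `ibd_strength` in
#' `[0, 1]` tilts each population's ancestral target along a geographic
#' gradient between two endpoint frequency vectors, producing a positive
#' Mantel correlation between genetic and geographic distance; 0 disables it.
#'
#' @param n_pops number of reference populations
#' @param n_loci number of loci
#' @param alleles_per_locus alleles segregating per locus (>= 2); allele codes
#'   are a 2-bp ladder starting at 100, mimicking dinucleotide repeats
#' @param concentration Dirichlet concentration (> 0); large = panmixia
#' @param ibd_strength spatial gradient weight in `[0, 1]`
#' @param f per-population inbreeding/Wahlund coefficient; scalar or vector
#'   recycled over populations
#' @param private_spec data frame with columns `pop, locus, allele, freq`:
#'   alleles forced present at `freq` in exactly one population and absent
#'   elsewhere
#' @param seed integer seed; the model is a pure function of its arguments
#' @param bbox numeric `c(lon_min, lon_max, lat_min, lat_max)` within which
#'   population coordinates are drawn (default roughly Cameroon/Gabon)
#' @return an object of class `population_model`
#' @export
simulate_model <- function(n_pops, n_loci, alleles_per_locus = 8,
                           concentration = 40, ibd_strength = 0,
                           f = 0.168, private_spec = NULL, seed = 1,
                           bbox = c(9, 14, 1.5, 6)) {
  stopifnot(n_pops >= 1, alleles_per_locus >= 2, concentration > 0,
            ibd_strength >= 0, ibd_strength <= 1)
  if (!is.null(private_spec) && any(private_spec$freq >= 1))
    stop("private allele frequency must be < 1")
  rs <- local_seed(seed)
  on.exit(rs$restore())
  pops <- paste0("P", sprintf("%02d", seq_len(n_pops)))
  loci <- paste0("L", sprintf("%02d", seq_len(n_loci)))
  coords <- data.frame(
    pop = pops,
    lon = stats::runif(n_pops, bbox[1], bbox[2]),
    lat = stats::runif(n_pops, bbox[3], bbox[4]),
    stringsAsFactors = FALSE)
  # gradient position in [0,1] along the main (lon+lat) diagonal
  proj <- (coords$lon - bbox[1]) / (bbox[2] - bbox[1]) +
    (coords$lat - bbox[3]) / (bbox[4] - bbox[3])
  w <- (proj - min(proj)) / max(proj - min(proj), 1e-12)
  f <- rep_len(f, n_pops)
  names(f) <- pops
  freqs <- stats::setNames(vector("list", n_pops), pops)
  for (p in pops) freqs[[p]] <- stats::setNames(vector("list", n_loci), loci)
  ladder <- 100L + 2L * (seq_len(alleles_per_locus) - 1L)
  for (l in loci) {
    anc <- rdirichlet(1, rep(1.5, alleles_per_locus))[1, ]
    endA <- rdirichlet(1, concentration * anc)[1, ]
    endB <- rdirichlet(1, concentration * anc)[1, ]
    for (i in seq_len(n_pops)) {
      target <- (1 - ibd_strength) * anc +
        ibd_strength * (w[i] * endA + (1 - w[i]) * endB)
      pf <- rdirichlet(1, concentration * target)[1, ]
      freqs[[pops[i]]][[l]] <- stats::setNames(pf, as.character(ladder))
    }
  }
  if (!is.null(private_spec)) {
    for (k in seq_len(nrow(private_spec))) {
      sp <- private_spec[k, ]
      al <- as.character(sp$allele)
      for (p in pops) {
        v <- freqs[[p]][[sp$locus]]
        v <- v[names(v) != al]           # force absent everywhere first
        freqs[[p]][[sp$locus]] <- v / sum(v)
      }
      v <- freqs[[sp$pop]][[sp$locus]] * (1 - sp$freq)
      v[al] <- sp$freq
      freqs[[sp$pop]][[sp$locus]] <- v[order(as.integer(names(v)))]
    }
  }
  structure(list(freqs = freqs, coords = coords, f = f,
                 private = private_spec, pops = pops, loci = loci,
                 concentration = concentration,
                 ibd_strength = ibd_strength, seed = seed),
            class = "population_model")
}

#' Model-expected Weir-Cockerham theta of a Dirichlet perturbation model
#'
#' Under `p_pop ~ Dirichlet(c * p_anc)` every allele has among-population
#' variance `p(1-p)/(c+1)`, so the theta estimand is `1/(c+1)` for all loci.
#'
#' @param concentration the model's Dirichlet concentration
#' @export
expected_fst <- function(concentration) 1 / (concentration + 1)

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("population_model: %d populations x %d loci (concentration %.3g, ibd %.2f)\n",
              length(x$pops), length(x$loci), x$concentration,
              x$ibd_strength))
  if (!is.null(x$private))
    cat(sprintf("  injected private alleles: %d\n", nrow(x$private)))
  invisible(x)
}

#' Draw diploid genotypes from a population model
#'
#' Two mechanisms produce the heterozygote deficit: `"f"` draws, per call,
#' an identical-by-descent homozygote with probability `f` and an HWE
#' genotype otherwise; `"wahlund"` splits each population into
#' `wahlund_demes` cryptic demes (Dirichlet-differentiated so that the
#' between-deme theta approximates `f`) and samples HWE within demes, so
#' pooling creates the deficit, mimicking unrecognised substructure.
#'
#' @param model a [simulate_model()] result
#' @param sizes named vector of individuals per population (names may be a
#'   subset of the model's populations); unnamed vectors are matched by order
#' @param seed integer seed
#' @param mechanism `"f"` (default) or `"wahlund"`
#' @param wahlund_demes demes per population for the `"wahlund"` mechanism
#' @param prefix sample-ID prefix
#' @return a [genotype_table()] with class `"reference"` and population
#'   coordinates in the metadata
#' @export
simulate_genotypes <- function(model, sizes, seed = 1,
                               mechanism = c("f", "wahlund"),
                               wahlund_demes = 2, prefix = "R") {
  mechanism <- match.arg(mechanism)
  stopifnot(all(sizes >= 0))
  if (is.null(names(sizes))) names(sizes) <- model$pops[seq_along(sizes)]
  stopifnot(all(names(sizes) %in% model$pops))
  rs <- local_seed(seed)
  on.exit(rs$restore())
  n_tot <- sum(sizes)
  loci <- model$loci
  a1 <- matrix(NA_integer_, n_tot, length(loci))
  a2 <- matrix(NA_integer_, n_tot, length(loci))
  ids <- character(n_tot)
  popv <- character(n_tot)
  row <- 0L
  for (p in names(sizes)) {
    n <- sizes[[p]]
    if (n == 0L) next
    idx <- row + seq_len(n)
    f <- model$f[[p]]
    for (l in seq_along(loci)) {
      pf <- model$freqs[[p]][[loci[l]]]
      alleles <- as.integer(names(pf))
      if (mechanism == "f") {
        ibd <- stats::runif(n) < f
        g1 <- sample(alleles, n, replace = TRUE, prob = pf)
        g2 <- sample(alleles, n, replace = TRUE, prob = pf)
        g2[ibd] <- g1[ibd]
      } else {
        conc_w <- max((1 - f) / max(f, 1e-9), 1e-3)
        deme_f <- rdirichlet(wahlund_demes, conc_w * pf)
        deme <- sample.int(wahlund_demes, n, replace = TRUE)
        g1 <- integer(n); g2 <- integer(n)
        for (d in seq_len(wahlund_demes)) {
          m <- deme == d
          if (!any(m)) next
          g1[m] <- sample(alleles, sum(m), replace = TRUE, prob = deme_f[d, ])
          g2[m] <- sample(alleles, sum(m), replace = TRUE, prob = deme_f[d, ])
        }
      }
      a1[idx, l] <- pmin(g1, g2)
      a2[idx, l] <- pmax(g1, g2)
    }
    ids[idx] <- sprintf("%s_%s_%03d", prefix, p, seq_len(n))
    popv[idx] <- p
    row <- row + n
  }
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- loci
  co <- model$coords[match(popv, model$coords$pop), ]
  meta <- data.frame(id = ids, pop = popv, class = "reference",
                     lon = co$lon, lat = co$lat, stringsAsFactors = FALSE)
  genotype_table(a1, a2, meta)
}

#' Market-mixture specification and sampling
#'
#' `market_spec()` describes an urban bushmeat market (or a seizure) as a
#' mixture over source populations; [simulate_market()] draws each
#' individual's source from the mixture, samples its genotype from that
#' population (with the population's `f`), and keeps the true source in the
#' metadata for downstream recovery checks.
#'
#' @param name market name (becomes the `pop` label, class `"market"`)
#' @param weights named, non-negative mixture weights over source populations
#'   (normalised internally)
#' @param size number of individuals
#' @param class sample class, `"market"` or `"seizure"`
#' @export
market_spec <- function(name, weights, size, class = "market") {
  stopifnot(all(weights >= 0), sum(weights) > 0, size >= 0)
  structure(list(name = name, weights = weights / sum(weights),
                 size = as.integer(size), class = class),
            class = "market_spec")
}

#' @rdname market_spec
#' @param model a [simulate_model()] result
#' @param spec a `market_spec`
#' @param seed integer seed
#' @export
simulate_market <- function(model, spec, seed = 1) {
  stopifnot(all(names(spec$weights) %in% model$pops))
  rs <- local_seed(seed)
  on.exit(rs$restore())
  n <- spec$size
  src_pool <- names(spec$weights)
  if (n == 0L) {
    empty <- matrix(NA_integer_, 0, length(model$loci),
                    dimnames = list(NULL, model$loci))
    return(genotype_table(empty, empty,
                          data.frame(id = character(0))))
  }
  src <- sample(src_pool, n, replace = TRUE, prob = spec$weights)
  sub_seed <- stats::runif(1)  # advance; draws below reuse the stream
  tabs <- vector("list", length(src_pool))
  counts <- table(factor(src, levels = src_pool))
  # draw per-source blocks with the current stream, then interleave
  a1 <- matrix(NA_integer_, n, length(model$loci))
  a2 <- matrix(NA_integer_, n, length(model$loci))
  for (p in src_pool) {
    m <- src == p
    np <- sum(m)
    if (np == 0L) next
    f <- model$f[[p]]
    for (l in seq_along(model$loci)) {
      pf <- model$freqs[[p]][[model$loci[l]]]
      alleles <- as.integer(names(pf))
      ibd <- stats::runif(np) < f
      g1 <- sample(alleles, np, replace = TRUE, prob = pf)
      g2 <- sample(alleles, np, replace = TRUE, prob = pf)
      g2[ibd] <- g1[ibd]
      a1[m, l] <- pmin(g1, g2)
      a2[m, l] <- pmax(g1, g2)
    }
  }
  ids <- sprintf("%s_%03d", spec$name, seq_len(n))
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- model$loci
  meta <- data.frame(id = ids, pop = spec$name, class = spec$class,
                     true_source = src, stringsAsFactors = FALSE)
  genotype_table(a1, a2, meta)
}

#' Inject missingness, duplicate individuals and null alleles
#'
#' Emulates the defects of field genotype data: genotyping failures
#' (i.i.d. per-call missingness), the same animal sampled twice (exact
#' copies under new IDs, flagged via `duplicate_of`), and null alleles
#' (at the listed loci a hidden allele segregates at frequency `freq`;
#' each gene copy independently converts to null, making carriers appear
#' homozygous for the visible allele and null homozygotes appear missing).
#'
#' @param x a [genotype_table()]
#' @param missing_rate per-call missingness probability
#' @param duplicate_rate fraction of individuals to copy (each copy makes one
#'   duplicate pair)
#' @param null_allele_spec data frame with columns `locus, freq`
#' @param seed integer seed
#' @export
corrupt_genotypes <- function(x, missing_rate = 0, duplicate_rate = 0,
                              null_allele_spec = NULL, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1)
  rs <- local_seed(seed)
  on.exit(rs$restore())
  a1 <- x$a1; a2 <- x$a2; meta <- x$meta
  # null alleles act on the underlying genotypes first
  if (!is.null(null_allele_spec)) {
    for (k in seq_len(nrow(null_allele_spec))) {
      l <- match(null_allele_spec$locus[k], loci_names(x))
      r <- null_allele_spec$freq[k]
      n <- nrow(a1)
      z1 <- stats::runif(n) < r
      z2 <- stats::runif(n) < r
      both <- z1 & z2 & !is.na(a1[, l])
      one1 <- z1 & !z2 & !is.na(a1[, l])
      one2 <- z2 & !z1 & !is.na(a1[, l])
      a1[one1, l] <- a2[one1, l]          # first copy null: show the second
      a2[one2, l] <- a1[one2, l]
      a1[both, l] <- NA_integer_
      a2[both, l] <- NA_integer_
    }
  }
  # duplicates: exact copies of post-null, pre-missing genotypes
  n_dup <- round(duplicate_rate * nrow(a1))
  if (n_dup > 0L) {
    src <- sample.int(nrow(a1), n_dup, replace = FALSE)
    dup_ids <- paste0(rownames(a1)[src], "_dup")
    d1 <- a1[src, , drop = FALSE]
    d2 <- a2[src, , drop = FALSE]
    rownames(d1) <- rownames(d2) <- dup_ids
    dmeta <- meta[src, , drop = FALSE]
    dmeta$duplicate_of <- dmeta$id
    dmeta$id <- dup_ids
    a1 <- rbind(a1, d1); a2 <- rbind(a2, d2)
    if (!"duplicate_of" %in% names(meta)) meta$duplicate_of <- NA_character_
    meta <- rbind(meta, dmeta[, names(meta), drop = FALSE])
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(a1)) < missing_rate, nrow(a1))
    a1[drop] <- NA_integer_
    a2[drop] <- NA_integer_
  }
  genotype_table(a1, a2, meta)
}

#' The default study-shaped synthetic scenario
#'
#' Ten reference populations of 5-45 individuals at 20 loci with positive
#' per-population f (0.11-0.22), low within-lineage differentiation,
#' injected strictly-private alleles, two large urban markets (84 and 248
#' individuals) mixing several sources, one 10-individual seizure, ~2% exact
#' duplicates and 5% missing calls. Returns the model, the combined table and
#' the private-allele truth.
#'
#' @param seed master seed; stage seeds are derived from it
#' @param private_freq frequency given to every injected private allele
#' @param missing_rate,duplicate_rate corruption rates
#' @param ibd_strength spatial gradient weight
#' @param concentration Dirichlet concentration (differentiation level)
#' @return list with elements `model`, `table`, `reference`, `markets`,
#'   `private_spec`
#' @export
simulate_scenario <- function(seed = 1, private_freq = 0.15,
                              missing_rate = 0.05, duplicate_rate = 0.02,
                              ibd_strength = 0.6, concentration = 40) {
  seeds <- derive_seeds(seed, 6)
  sizes <- c(P01 = 13, P02 = 5, P03 = 23, P04 = 36, P05 = 12,
             P06 = 19, P07 = 6, P08 = 11, P09 = 45, P10 = 9)
  # one private allele for each of 8 populations spread over 8 loci;
  # codes 201, 203, ... sit off the 2-bp ladder so they are never drawn
  # by chance in other populations
  priv_pops <- paste0("P", sprintf("%02d", c(1, 3, 4, 5, 6, 7, 9, 10)))
  private_spec <- data.frame(
    pop = priv_pops,
    locus = paste0("L", sprintf("%02d", seq_along(priv_pops))),
    allele = 201L + 2L * seq_along(priv_pops),
    freq = private_freq,
    stringsAsFactors = FALSE)
  model <- simulate_model(
    n_pops = 10, n_loci = 20, alleles_per_locus = 8,
    concentration = concentration, ibd_strength = ibd_strength,
    f = stats::setNames(seq(0.11, 0.22, length.out = 10)[
      order(derive_seeds(seed, 10) %% 97)], names(sizes)),
    private_spec = private_spec, seed = seeds[1])
  ref <- simulate_genotypes(model, sizes, seed = seeds[2])
  markets <- list(
    douala = market_spec("Douala", c(P01 = 0.25, P09 = 0.35, P10 = 0.25,
                                     P03 = 0.15), 84),
    yaounde = market_spec("Yaounde", c(P09 = 0.3, P03 = 0.2, P07 = 0.1,
                                       P01 = 0.15, P06 = 0.15, P05 = 0.1),
                          248),
    seizure = market_spec("Seizure", c(P05 = 0.5, P01 = 0.5), 10,
                          class = "seizure"))
  mk <- mapply(simulate_market, spec = markets,
               seed = seeds[3:5], MoreArgs = list(model = model),
               SIMPLIFY = FALSE)
  tab <- do.call(rbind_tables, c(list(ref), unname(mk)))
  tab <- corrupt_genotypes(tab, missing_rate = missing_rate,
                           duplicate_rate = duplicate_rate,
                           seed = seeds[6])
  list(model = model, table = tab, reference = ref, markets = mk,
       private_spec = private_spec)
}
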
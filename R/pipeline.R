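# Config-driven pipeline tying the stages together, with a run report.
# The numbered scripts under analysis/ are thin drivers over this module.

#' Default pipeline configuration
#'
#' Numeric defaults are the field-protocol conventions: 75%
#' genotyping completeness, paf > 0.4 at g* = 5, 10,000 F_ST and Mantel
#' permutations, 1,000 LD randomizations, 500 NJ bootstraps, 1,000 mismatch
#' bootstraps, 10,000 bottleneck replications.
#'
#' @param seed master seed; every stage seed is derived from it
#' @param outdir output directory for stage artifacts
#' @param ... overrides for any top-level key
#' @export
default_config <- function(seed = 1, outdir = "results", ...) {
  cfg <- list(
    seed = seed,
    outdir = outdir,
    completeness = 0.75,
    paf_threshold = 0.4,
    g_star = 5,
    slope_tolerance = 0.01,
    rarefaction_unit = "individuals",
    fst_permutations = 10000,
    mantel_permutations = 10000,
    ld_randomizations = 1000,
    fis_randomizations = 1000,
    nj_bootstrap = 500,
    mismatch_bootstrap = 1000,
    bottleneck_reps = 10000,
    bottleneck_model = "TPM",
    tpm_p_smm = 0.95,
    tpm_variance = 12,
    geo_method = "greatcircle",
    scenario = list(private_freq = 0.15, missing_rate = 0.05,
                    duplicate_rate = 0.02, ibd_strength = 0.6,
                    concentration = 40),
    mtdna = list(n_per_lineage = c(40, 12), n_fixed_diff = 23,
                 mutations_per_seq = 2))
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, overrides)
}

#' @rdname default_config
#' @param path YAML config file
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path) {
  d <- data.frame(name = rownames(m), as.data.frame(m), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic (or supplied) dataset
#'
#' Stages: `simulate` (study-shaped synthetic scenario), `diversity`
#' (Na/Ho/He/uHe, allelic richness, F_IS, pairwise F_ST, Mantel IBD),
#' `identity` (matches, psex, PI indices), `trace` (rarefaction panel and
#' market/seizure assignment), `bottleneck`, `mtdna`. Each stage writes TSV
#' artifacts under `cfg$outdir` and its results are returned invisibly; a
#' run report records the config and stage seeds.
#'
#' @param cfg a [default_config()] list
#' @param stages character vector of stages to run
#' @param table optional pre-built [genotype_table()] (skips `simulate`)
#' @param quiet suppress progress messages
#' @return (invisibly) a named list of stage results
#' @export
run_pipeline <- function(cfg = default_config(),
                         stages = c("simulate", "diversity", "identity",
                                    "trace", "bottleneck", "mtdna"),
                         table = NULL, quiet = FALSE) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 10)
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list()

  scen <- NULL
  if ("simulate" %in% stages || is.null(table)) {
    scen <- do.call(simulate_scenario,
                    c(list(seed = seeds[1]), cfg$scenario))
    table <- scen$table
    res$scenario <- scen
    write_genalex(table, file.path(cfg$outdir, "genotypes_genalex.csv"))
    write_msat_tsv(table, file.path(cfg$outdir, "genotypes.tsv"))
    say("simulate: %d individuals x %d loci", n_ind(table), n_loci(table))
  }
  table <- filter_by_completeness(table, cfg$completeness)
  refs <- pop_map(table, classes = "reference")
  af <- allele_counts(table, refs)

  if ("diversity" %in% stages) {
    div <- diversity(table, refs)
    ar <- allelic_richness(af)
    fis <- fis_test(table, refs, n_randomizations = cfg$fis_randomizations,
                    seed = seeds[2])
    fst <- pairwise_fst(table, refs, n_permutations = cfg$fst_permutations,
                        seed = seeds[3])
    reftab <- table[table$meta$class == "reference" &
                      !is.na(table$meta$pop), ]
    ibd <- mantel_ibd(edwards_distance(reftab),
                      geo_dist_matrix(reftab, cfg$geo_method),
                      n_permutations = cfg$mantel_permutations,
                      seed = seeds[4])
    priv <- observed_private_alleles(af)
    summary <- div$summary
    summary$F_IS <- fis$f[match(summary$pop, fis$pop)]
    summary$F_IS_p <- fis$p[match(summary$pop, fis$pop)]
    summary$A_R <- ar$mean[summary$pop]
    summary$n_private <- as.integer(table(
      factor(priv$pop, levels = summary$pop)))
    pf <- tapply(priv$freq, factor(priv$pop, levels = summary$pop), mean)
    summary$private_freq <- as.numeric(pf)
    res$diversity <- list(summary = summary, by_locus = div$by_locus,
                          fst = fst, ibd = ibd, A_R = ar, private = priv)
    write_tsv(summary, file.path(cfg$outdir, "diversity_summary.tsv"))
    write_matrix_tsv(fst$theta, file.path(cfg$outdir, "pairwise_fst.tsv"))
    say("diversity: mean He %.3f, IBD r = %.3f (p = %.4g)",
        mean(summary$He, na.rm = TRUE), ibd$r, ibd$p)
  }

  if ("identity" %in% stages) {
    idr <- identity_screen(table)
    res$identity <- idr
    write_tsv(idr$matches, file.path(cfg$outdir, "matches.tsv"))
    write_tsv(idr$pi$per_locus, file.path(cfg$outdir, "pi_per_locus.tsv"))
    say("identity: %d matching pairs, cumulative uPI = %.3g",
        nrow(idr$matches), idr$pi$cumulative[["uPI"]])
  }

  if ("trace" %in% stages) {
    tr <- trace_pipeline(table, g_star = cfg$g_star,
                         paf_threshold = cfg$paf_threshold,
                         slope_tolerance = cfg$slope_tolerance,
                         unit = cfg$rarefaction_unit)
    res$trace <- tr
    write_tsv(as.data.frame(tr$panel),
              file.path(cfg$outdir, "tracing_panel.tsv"))
    write_tsv(tr$assignments, file.path(cfg$outdir, "assignments.tsv"))
    if (length(tr$summary))
      write_matrix_tsv(tr$summary,
                       file.path(cfg$outdir, "trace_summary.tsv"))
    say("trace: panel of %d private alleles, %d individuals assigned",
        nrow(tr$panel), nrow(tr$assignments))
  }

  if ("bottleneck" %in% stages) {
    pooled_ids <- unlist(refs, use.names = FALSE)
    bt <- lapply(c("SMM", "TPM"), function(mod)
      bottleneck_test(table, pooled_ids, model = mod,
                      n_reps = cfg$bottleneck_reps, seed = seeds[5],
                      p_smm = cfg$tpm_p_smm, variance = cfg$tpm_variance))
    names(bt) <- c("SMM", "TPM")
    res$bottleneck <- bt
    for (mod in names(bt))
      write_tsv(bt[[mod]]$per_locus,
                file.path(cfg$outdir, sprintf("bottleneck_%s.tsv", mod)))
    say("bottleneck: excess p (SMM) = %.4g, (TPM) = %.4g",
        bt$SMM$p_excess, bt$TPM$p_excess)
  }

  if ("mtdna" %in% stages) {
    mt <- do.call(simulate_mtdna,
                  c(list(seed = seeds[6]), cfg$mtdna))
    haps <- collapse_haplotypes(mt$alignment)
    groups <- split(names(mt$lineage), mt$lineage)
    div <- lapply(groups, function(idv)
      diversity_stats(mt$alignment[idv, , drop = FALSE]))
    mism <- mismatch_analysis(
      mt$alignment[groups[[1]], , drop = FALSE],
      n_bootstrap = cfg$mismatch_bootstrap, seed = seeds[7])
    tree <- nj_tree(mt$alignment, n_bootstrap = cfg$nj_bootstrap,
                    seed = seeds[8])
    res$mtdna <- list(haplotypes = haps, diversity = div,
                      mismatch = mism, tree = tree)
    writeLines(tree$newick, file.path(cfg$outdir, "nj_tree.nwk"))
    hap_tab <- data.frame(
      haplotype = names(haps$members),
      n = vapply(haps$members, length, integer(1)),
      members = vapply(haps$members, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)
    write_tsv(hap_tab, file.path(cfg$outdir, "haplotypes.tsv"))
    write_tsv(data.frame(class = names(mism$histogram),
                         count = as.integer(mism$histogram)),
              file.path(cfg$outdir, "mismatch_histogram.tsv"))
    say("mtdna: %d haplotypes; raggedness p = %.3f",
        nrow(haps$haplotypes), mism$p_raggedness)
  }

  report <- c(
    sprintf("pangotrace run report (%s)", format(Sys.time())),
    sprintf("R %s, pangotrace %s", getRversion(),
            as.character(utils::packageVersion("pangotrace"))),
    sprintf("stages: %s", paste(stages, collapse = ", ")),
    sprintf("stage seeds: %s", paste(seeds, collapse = ", ")),
    "config:",
    utils::capture.output(utils::str(cfg)))
  writeLines(report, file.path(cfg$outdir, "run_report.txt"))
  invisible(res)
}
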
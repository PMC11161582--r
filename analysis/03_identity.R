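# Individual identification: exact multilocus genotype matches (duplicate
# animals sampled twice), the chance-match probability psex per matching
# pair, and the forensic identity indices PI / uPI / PIsibs per locus and
# cumulated over the panel.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))
cfg <- analysis_config()

res <- run_pipeline(cfg, stages = c("simulate", "identity"))
m <- res$identity$matches
pi <- res$identity$pi
tab <- filter_by_completeness(res$scenario$table, cfg$completeness)
message(sprintf("%d matching pairs among %d genotypes (max psex %.3g): duplicates, not chance",
                nrow(m), n_ind(tab),
                if (nrow(m)) max(m$psex) else 0))
message(sprintf("cumulative uPI = %.3g, PIsibs = %.3g; %d loci reach PI < 0.01",
                pi$cumulative[["uPI"]], pi$cumulative[["PIsibs"]],
                min_loci_for_pi(pi$per_locus$PI, 0.01)))
message("wrote results/matches.tsv and results/pi_per_locus.tsv")
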
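# Per-population genetic diversity (Na, Ho, He, uHe), rarefied allelic
# richness, Weir-Cockerham F_IS with randomization tests, pairwise F_ST
# with permutation tests, and the individual-based Mantel test of
# isolation by distance on Cavalli-Sforza-Edwards chord distances.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))
cfg <- analysis_config()

res <- run_pipeline(cfg, stages = c("simulate", "diversity"))
s <- res$diversity$summary
message(sprintf("mean He %.3f (range %.3f-%.3f); mean F_IS %.3f; %d/%d F_IS significant at 0.05",
                mean(s$He), min(s$He), max(s$He), mean(s$F_IS, na.rm = TRUE),
                sum(s$F_IS_p <= 0.05, na.rm = TRUE), nrow(s)))
th <- res$diversity$fst$theta
message(sprintf("pairwise theta %.3f-%.3f; IBD r = %.3f (p = %.4g)",
                min(th[upper.tri(th)]), max(th[upper.tri(th)]),
                res$diversity$ibd$r, res$diversity$ibd$p))
message("wrote results/diversity_summary.tsv and results/pairwise_fst.tsv")
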
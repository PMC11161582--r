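# Heterozygosity-excess bottleneck tests on the pooled reference sample
# under the stepwise (SMM) and two-phase (TPM, p_smm = 0.95, variance 12)
# mutation models, with coalescent equilibrium distributions conditioned
# on the observed allele counts.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))
cfg <- analysis_config()

res <- run_pipeline(cfg, stages = c("simulate", "bottleneck"))
for (mod in names(res$bottleneck)) {
  b <- res$bottleneck[[mod]]
  message(sprintf("%s: %d loci, excess p = %.4g, deficit p = %.4g, two-sided p = %.4g",
                  b$model, b$n_loci_used, b$p_excess, b$p_deficit,
                  b$p_two_sided))
}
message("wrote results/bottleneck_SMM.tsv and results/bottleneck_TPM.tsv")
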
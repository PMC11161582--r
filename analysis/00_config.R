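# Shared configuration for the numbered analysis drivers.
#
# One master seed drives every stage; each driver re-derives the same
# synthetic dataset deterministically, so the scripts can be run
# independently or in order. Permutation counts here are scaled to keep
# each driver in the minutes range; the full study-scale counts (10,000
# F_ST/Mantel permutations, 10,000 bottleneck replications, ...) are the
# package defaults in `default_config()` and can be restored by editing
# the overrides below.

library(pangotrace)

analysis_config <- function() {
  default_config(
    seed = 20240607,
    outdir = "results",
    fst_permutations = 500,
    mantel_permutations = 2000,
    fis_randomizations = 500,
    nj_bootstrap = 200,
    mismatch_bootstrap = 300,
    bottleneck_reps = 1000)
}
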
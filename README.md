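# pangotrace

Population-genetic assessment and geographic tracing of trafficked
wildlife from co-dominant microsatellite genotypes and mitochondrial
sequences, built around the white-bellied pangolin (*Phataginus
tricuspis*) bushmeat trade in western Central Africa.

Urban bushmeat markets and border seizures concentrate animals whose
origins are unknown. Given reference populations genotyped at
species-specific microsatellite loci, the package answers three
questions in sequence:

1. **What is the genetic state of the source populations?** Diversity
   (Na, Ho, He, uHe), rarefied allelic richness
   `A_R = Σᵢ [1 − C(N−Nᵢ, g)/C(N, g)]`, Weir–Cockerham F_IS and pairwise
   F_ST with permutation tests, Hardy–Weinberg / linkage / null-allele
   diagnostics, and an individual-level Mantel test of isolation by
   distance on Cavalli-Sforza–Edwards chord distances.
2. **Can individuals be told apart?** Exact multilocus genotype matching
   (the same animal sampled twice), the chance-match probability
   `psex = 1 − (1 − pgen)^(n−1)`, and the forensic indices PI, unbiased
   PI and PIsibs per locus and cumulated over the panel.
3. **Where did traded animals come from?** The private-allele
   rarefaction protocol: expected private-allele counts
   `paf = Σᵢ [1 − C(Nⱼ−Nⱼᵢ, g)/C(Nⱼ, g)] · Πₖ≠ⱼ C(Nₖ−Nₖᵢ, g)/C(Nₖ, g)`
   per locus and population, locus selection (paf > 0.4, plateau or
   rising at g\* = 5), cross-filtering against observed private alleles,
   and screening of market/seizure genotypes for panel alleles.

Around this core sit a Cornuet–Luikart heterozygosity-excess bottleneck
test (coalescent SMM/TPM equilibrium distributions conditioned on the
observed allele count, compiled simulator) and a cytochrome-*b* workflow
(haplotype collapsing, S/h/Hd/π, K2P + neighbor-joining lineage
assignment with bootstrap, Rogers–Harpending mismatch analysis of sudden
demographic expansion). Because trade genotypes are rarely deposited, a
synthetic-data generator reproduces the statistical shape of such a
study — 10 reference populations of 5–45 individuals at 20 loci, Wahlund
structure, market mixtures, duplicates, missingness, strictly-private
alleles at controlled frequency — so every stage is testable against
generator truth.

## Worked example

The repository is organised as an analysis workflow; the numbered
scripts under `analysis/` run each stage on the default synthetic
scenario and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_diversity.R
Rscript analysis/04_trace.R
```

prints (master seed 20240607):

```
dataset: 531 individuals x 20 loci (4.7% missing calls)
classes: market 339, reference 182, seizure 10

mean He 0.742 (range 0.672-0.785); mean F_IS 0.160; 9/10 F_IS significant at 0.05
pairwise theta 0.003-0.067; IBD r = 0.122 (p = 0.0004998)

panel: 7 private alleles at 7 loci from 4 source populations
traced 53 of 349 market/seizure animals (15.2%); precision vs generator truth = 0.830
```

Reading: the reference populations are diverse (He ≈ 0.74) with a
consistent heterozygote deficit (F_IS ≈ 0.16) yet almost undifferentiated
(θ ≤ 0.07) — the Wahlund-like signature the generator injects — and a
significant isolation-by-distance signal. The tracing panel of 7
rarefaction-supported private alleles assigns 15% of market and seizure
animals to a source; 53 assignments include a handful driven by a
quasi-private allele (an allele rare-but-present in several populations
that the small reference samples missed), which is why precision against
generator truth is 0.83 at this seed rather than 1.0 — the central caveat
of the protocol, discussed in the methods vignette. Equivalent calls in
R: `simulate_scenario()`, `diversity()`, `fis_test()`, `pairwise_fst()`,
`mantel_ibd()`, `identity_screen()`, `trace_pipeline()`,
`bottleneck_test()`, `mismatch_analysis()`; `run_pipeline()` ties them
together from one config and master seed.

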
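# minecore

Community-ecology analysis of paired-habitat amplicon surveys: habitat
generalist/specialist classification from occupancy–abundance structure,
core-microbiota extraction and composition, a Bray-Curtis null model with a
PERMDISP test for stochastic vs deterministic community assembly, and
Spearman screening of OTUs against geochemical parameters. The motivating
system is a circum-neutral mine drainage channel and its surrounding
metal-rich soil, sampled six times each, but the functions are generic over
any OTU table with a sample-to-environment map.

The package is aimed at microbial ecologists who have an OTU count table
(the classic tab-separated layout, OTUs as rows), per-sample chemistry, and
a two-habitat design, and who want the downstream analyses reproducible and
testable. Because studies at this depth rarely ship raw data in a re-runnable
form, minecore includes a synthetic community generator that plants
generalists, specialists, core members and OTU–chemistry associations with
recorded ground truth, so every stage of the pipeline can be validated
end-to-end without external data.

## Methods at a glance

* **Niche classification.** Within a habitat with *n* samples, an OTU is a
  *generalist* if present in all *n* samples with mean relative abundance
  ≥ 2%, a *specialist* if present in only 1–2 samples at ≥ 2%, otherwise
  *other*. The mean is over occupied samples by default; both bases are
  stored.
* **Core microbiota.** OTUs present in every sample of the habitat;
  composition at a taxonomic rank as percent of core sequences.
* **Assembly stochasticity.** Null communities preserve each sample's depth
  and draw compositions multinomially from the pooled regional
  relative-abundance vector. One Bray-Curtis matrix
  (d = 1 − 2Σmin(x,y)/Σ(x+y)) over observed + null samples enters PERMDISP:
  one-way ANOVA F on distances to group centroids in principal-coordinates
  space (real and imaginary axes kept separately, Anderson's construction),
  p by label permutation with full centroid recomputation,
  p = (1 + #{F\* ≥ F})/(1 + n_perm). p ≥ α is consistent with stochastic
  assembly.
* **Chemistry screening.** Spearman ρ of OTU relative abundances vs each
  parameter within a habitat; exact permutation p by full enumeration for
  n ≤ 8 (the t-approximation is poor at n = 6), BH q-values reported
  alongside the raw p < 0.05 screen.

The methods vignette (`vignettes/minecore-methods.Rmd`) documents the
assumptions, numerical choices and limitations in detail.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
community that mirrors the motivating design (run them in order from the
repository root):

```sh
Rscript analysis/01_simulate_community.R
Rscript analysis/02_niche_and_core.R
Rscript analysis/03_assembly_stochasticity.R
Rscript analysis/04_chemistry_correlations.R
Rscript analysis/05_full_pipeline.R
```

Step 02 prints, for the default seed:

```
drainage: 3 generalists, 0 specialists, core 23 OTUs; 100.0% of labels match the planted truth
  dominant core genus: CoreDominant (48.7% of core sequences)
soil: 1 generalists, 1 specialists, core 11 OTUs; 100.0% of labels match the planted truth
```

i.e. the classifier recovers exactly the planted structure: three drainage
generalists and no drainage specialists, one soil generalist and one soil
specialist, and the planted dominant genus takes 48.7% of drainage core
sequences against a designed expectation of 48.6%. Step 03 prints:

```
Assembly stochasticity test (6 null replicates)
  PERMDISP F = 8439, p = 0.001 (alpha = 0.05)
  verdict: deterministic_signal

Same test on a pure-sampling-noise community:
  PERMDISP F = 12.59, p = 0.204 (alpha = 0.05)
  verdict: consistent_with_stochastic
```

the planted habitat structure is (correctly) flagged as deterministic
signal, while a community generated by the null process itself is not.
Step 04 screens the classified OTUs against the 16 chemistry parameters at
n = 6 per habitat and illustrates two small-sample realities discussed in
the vignette: a planted ρ = 0.88 association is only borderline-detectable
at n = 6, and raw-p screening across 16 parameters can let a spurious
correlation through.

Equivalent results come from the package API directly:

```r
library(minecore)
sim <- generate_community(community_config(seed = 1))
classify_otus(sim$otu, "drainage")          # occupancy, abundance, labels
core_microbiota(sim$otu, "drainage")        # core OTU set
stochasticity_test(sim$otu, seed = 1)       # F, p, verdict
correlate(sim$otu, sim$chemistry,
          "OTU_0001", environment = "drainage")
```

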
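# cytomem

Stimulus-induced epigenomic and transcriptional memory analysis from count
matrices.

Macrophages pulsed with a cytokine such as IFNγ can stay altered for days:
the stimulus creates *de novo* enhancers (H3K4me1 peaks), opens chromatin and
induces interferon-stimulated genes, and part of each survives washout of the
cytokine — unless JAK/STAT signaling is blocked afterwards (ruxolitinib or a
neutralizing antibody), which reverts them. On LPS restimulation, pretreated
cells respond more strongly at some genes (potentiation) and more weakly at
others (tolerance). `cytomem` is for analysts of such stimulus → washout →
restimulation experiments (CUT&Tag / ATAC-seq peak panels and RNA-seq gene
panels): it starts where alignment and peak calling end, at the feature ×
sample count matrix.

## What it computes

- **CPM normalization** with condition-wise pseudocount floors
  (1st-percentile per condition for peaks, 1 CPM for genes) and the
  top-50th-percentile acute-abundance filter.
- **Induced features** by an in-package negative-binomial conditional exact
  test: library sizes equalized to the geometric-mean depth, the two-sided
  p-value summing conditional split probabilities no more likely than the
  observed one, dispersion from a conditional-ML common estimate blended
  with per-feature moments, Benjamini–Hochberg FDR; induced = L2FC > 2,
  FDR < 0.01 versus unstimulated.
- **Washout durability**: persistence = L2FC ≥ 0 and FDR < 0.01 in the
  washout-vs-unstimulated contrast, per post-washout treatment; paired
  Wilcoxon signed-rank statistics for acute→washout shifts (exact
  enumeration up to 25 pairs, handling ties); k-means trajectory clustering
  of Z-scored condition-mean profiles with deterministic relabeling.
- **Gene memory calls** on LPS-restimulation time courses ({0, 1, 3, 6, 12} h,
  naive and cytokine-pretreated arms, ± ruxolitinib): potentiated = ≥ 5-fold
  LPS-inducible and ≥ 2-fold above naive at two consecutive timepoints;
  tolerized = ≥ 2-fold below naive at two consecutive timepoints with
  ≥ 4-fold induction under JAK blockade; basal set-point split at
  L2FC > 0.5; per-gene mean potentiation scores.
- **Enhancer–gene linkage** within ±20 kb of protein-coding TSSs (promoter
  ±1 kb excluded), and the Spearman association between enhancer washout
  fold change and linked-gene potentiation.
- **A truth-labelled synthetic generator** that emulates the whole design
  (negative-binomial counts, planted persistent/decaying/increasing
  enhancers, potentiated/tolerized genes, enhancer–gene couplings), so the
  entire pipeline is testable with no sequencing data.

## Worked example

```r
library(cytomem)

sim <- generate_dataset(sim_config(seed = 7))
fit <- peak_memory_analysis(
  sim$peaks$counts, sim$peaks$design, sim$peaks$features,
  stim_conditions    = c(ifng = "IFNG_8H", lps = "LPS_8H"),
  washout_conditions = c(media = "IFNG_WASH_MEDIA", rux = "IFNG_WASH_RUX",
                         anti_ifng = "IFNG_WASH_AIFNG"))
fit
#> Peak memory analysis
#>   features: 2000 input, 1590 pass abundance filter
#>   ifng-induced peaks (l2fc > 2, FDR < 0.01): 460
#>   lps-induced peaks (l2fc > 2, FDR < 0.01): 260
#>   persistence fractions after washout:
#>     media      58.7%
#>     rux        0.0%
#>     anti_ifng  0.0%
#>   trajectory clusters (k = 3 ): sizes 143, 164, 153
```

Of 2000 simulated peaks, 1590 clear the abundance filter and 460 are called
IFNγ-induced. 58.7% of those persist four days after washout in plain media,
while ruxolitinib or anti-IFNγ antibody after washout erases persistence —
the generator plants exactly that JAK-dependence, and the three trajectory
clusters separate the washout-elevated, unchanged and decayed patterns.

```r
gfit <- gene_memory_analysis(washout = sim$gene_washout,
                             restim = sim$restim, tss = sim$tss)
gfit
#> Gene memory analysis
#>   induced genes (fold >= 5): 450
#>     media washout bands: >=90%: 142 | 20-90%: 158 | <20%: 150
#>     rux washout bands: >=90%: 0 | 20-90%: 0 | <20%: 450
#>   potentiated genes: 59 (basal elevated: 28, equal: 31)
#>   tolerized genes: 30

link_memory(fit, gfit, tss = sim$tss)
#> Enhancer durability vs gene potentiation
#>   pairs: 165 | Spearman rho = 0.603 | p = 9.73e-18
```

Gene-side: 450 IFNγ-induced genes band by how much expression survives
washout (all collapse below 20% under ruxolitinib); 59 LPS-response genes are
called potentiated (28 from an elevated basal set-point, 31 from an unchanged
one) and 30 tolerized. Linking induced enhancers to nearby gene TSSs
recovers the planted coupling between enhancer durability and gene
potentiation (ρ = 0.60).

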
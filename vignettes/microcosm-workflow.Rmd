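---
title: "Community activity and beta-diversity in oil/dispersant microcosms"
author: "lrdmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community activity and beta-diversity in oil/dispersant microcosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrdmeta)
```

# The scientific setting

Deep-sea oil spills are fought with chemical dispersants, and a standing
question is how the dispersant itself — as opposed to the oil — reshapes
the indigenous microbial community and its activity. The experimental
design this package analyzes exposes replicate seawater microcosms to a
factorial set of amendments: a water-accommodated fraction of oil only
(WAF), dispersant only (DISP), their combination (CEWAF), CEWAF plus
inorganic nutrients (CEWAFN), and an unamended biotic control (BC),
sampled at five timepoints over six weeks (days 0, 7, 17, 28, 42; the
CEWAFN treatment only at days 0, 7 and 42). Each microcosm yields paired
molecular observations: 16S rRNA gene amplicon counts (the DNA side,
"who is there") and metatranscriptomic read counts annotated to taxa
(the RNA side, "who is transcribing").

`lrdmeta` implements the community-level analyses for this design:

1. **Taxonomy-label aggregation** to a fixed relative-abundance
   resolution, so heterogeneous annotation vocabularies collapse onto a
   common, small label space.
2. The **LRD index** — the mean log2 RNA:DNA ratio per taxon and
   treatment — with its three-group activity classification.
3. **Beta-diversity**: Bray-Curtis dissimilarity with principal
   coordinates ordination, and abundance-weighted phylogenetic distances
   (MPD and MNTD) over a reference tree.
4. **PERMANOVA** with sequential sums of squares for the factorial
   model, permuting sample identities.
5. A **Dirichlet-multinomial simulator** of the whole design, so every
   stage runs and is validated without any sequencing download.

# Taxonomy aggregation to a minimum resolution

Annotation pipelines emit labels at wildly different ranks and spellings.
After canonicalizing each raw label against a local reference table
(case- and whitespace-insensitive, synonyms resolved to one entry), each
input row is reported at the deepest rank of its lineage whose *subtree*
— the row together with every other row descending from that rank —
reaches the minimum relative-abundance threshold `T` (default 4%) in at
least one sample. Mass that never reaches `T` on any rank accumulates in
a virtual root bucket; unknown labels can be bucketed under a reserved
`Unclassified` entry.

Three properties are contractual and tested: per-sample totals are
conserved exactly (integer arithmetic on integer inputs), the operation
is idempotent, and raising `T` can only shrink the label set. Note that
the output deliberately mixes ranks: an abundant genus stays a genus
while its rare siblings surface as their family, so a family-named label
acts as the "remainder" of that clade. The row-groups behind the labels
are disjoint, but a retained genus can coexist with an ancestor-named
remainder bucket — exactly the label structure seen in community
composition figures from such studies. The `any_sample` retention rule
gives one mapping shared by all samples (required for cross-sample
distances); a `per_sample` mode, where each sample is aggregated by its
own walk, is provided for exploration.

# The LRD activity index

For taxon $i$ and treatment $j$,

$$\mathrm{LRD}_{ij} = \frac{1}{n}\sum_{t=1}^{n}
\log_2\!\frac{r_{ijt}}{d_{ijt}},$$

where $r$ and $d$ are the metatranscriptomic and 16S relative abundances
on the merged label space, the 16S triplicates having been averaged on
the (treatment, timepoint) grid. The sum runs over the timepoints the
treatment actually has, so $n$ is per $(i,j)$ — three for CEWAFN, five
for the others in the default design. The interpretation rests on DNA
being the stable denominator: taxa transcribing far in excess of their
genomic representation score high.

Classification follows the fixed boundaries, with the middle group
inclusive at both ends:

| Group | Rule | Reading |
|-------|------|---------|
| I | mean LRD > 3.5 | highest relative synthetic capacity |
| II | \|mean LRD\| ≤ 3.5 | transcription proportional to abundance |
| III | mean LRD < −3.5 | muted transcription relative to abundance |

**Zeros.** The ratio is undefined when either side is zero at a
timepoint. The default policy (`drop`) omits such timepoints and lets
`n_used` shrink — no mass is invented, and a row with no admissible
timepoint is reported in a skipped-rows table rather than silently
missing. The alternative `pseudocount` policy replaces zeros with half
the smallest nonzero relative abundance of the respective table; it
exists because wholly silent taxa are biologically interesting (they are
the extreme of Group III) and `drop` cannot score them.

# Beta-diversity and ordination

Bray-Curtis dissimilarity, $\mathrm{BC}(A,B) = \sum_i |a_i - b_i| /
\sum_i (a_i + b_i)$, is the abundance-weighted taxonomic measure; the
distance matrix is ordinated by principal coordinates analysis
(classical metric scaling via Gower double-centering). Axes with
negative eigenvalues are reported but excluded from coordinates, and no
Cailliez/Lingoes correction is applied unless requested — transparency
over silent adjustment.

The phylogenetic measures weight patristic distances (path sums of
branch lengths) by relative abundance:

* **MPD** (mean pairwise distance): $\sum_i \sum_j p_{iA}\, p_{jB}\,
  \delta_{ij}$ — the expected distance between a random read of $A$ and
  a random read of $B$.
* **MNTD** (mean nearest taxon distance): the abundance-weighted
  distance from each taxon of one sample to its nearest taxon present in
  the other, averaged over the two directions. Taxa shared by both
  samples contribute zero (conspecifics are not excluded), and a
  directional variant is available by flag since the symmetric average
  is a convention, not a law.

The self-comparison MPD/MNTD of a sample with itself is computed by the
same formula and may be positive; it is reported but excluded from
permutation tests. Expected rarefied richness uses the exact
hypergeometric form $E[S] = \sum_i \left(1 - \binom{N-N_i}{k} /
\binom{N}{k}\right)$ evaluated with log-gamma arithmetic, rather than
Monte-Carlo subsampling, for determinism.

# PERMANOVA with sequential sums of squares

The testing model, with terms in this exact order, is

$$U = O + D + O{\times}D + O{\times}D{\times}N + t + O{\times}t +
D{\times}t + O{\times}D{\times}t + O{\times}D{\times}N{\times}t,$$

where $O$, $D$, $N$ are the oil/dispersant/nutrient presence flags, $t$
is the timepoint treated as a categorical factor, and $U$ is any of the
three distance matrices. Squared distances are Gower-centered into an
inner-product matrix $G$ with $\mathrm{tr}(G) = \sum d^2_{ij}/n$ the
total sum of squares; each term's SS is the trace of $G$ against the
increment of projection matrices in formula order (sequential, Type I —
the order of the formula is meaningful). Pseudo-F is the usual
mean-square ratio against the residual, and p-values come from freely
permuting sample identities: $p = (1 + \#\{F^* \ge F\}) / (1 +
n_\mathrm{perm})$, so the smallest attainable p at 999 permutations is
0.001. $R^2$ is defined as $SS_\mathrm{term}/SS_\mathrm{total}$ and is
nonnegative by construction.

**Aliasing is handled honestly.** Nutrients occur only in CEWAFN
($O=D=1$), so the $O{\times}D{\times}N$ column reduces to the nutrient
contrast; it keeps the single degree of freedom that survives the
earlier terms. In designs without CEWAFN the term has no variation at
all and is reported with 0 df and no test rather than crashing or being
silently dropped. A subtler degeneracy is saturation: the default study
layout has 23 cells and one RNA library per cell, and the full model
with categorical time consumes all 22 degrees of freedom — no term is
testable. The study itself reports more transcriptomic libraries (27)
than cells, without stating which cells were replicated; the analysis
scripts and the acceptance run therefore use two RNA libraries per cell,
the minimal replicated layout, as this package's own choice.

# The synthetic-data generator

Each (treatment, timepoint) cell is one microcosm bottle. A latent
composition $q$ is drawn once per cell from
$\mathrm{Dirichlet}(c \cdot \pi_{jt})$, where $\pi_{jt}$ is the baseline
community with the cell's planted abundance fold-changes applied and
renormalized, and $c$ (default 500) is the single overdispersion knob —
larger $c$, less between-bottle variation. The 16S triplicates are
multinomial resamplings of $q$ at the configured depth; the paired
metatranscriptomic library resamples the *same* $q$ tilted by the
planted per-taxon log2 enrichments, $r \propto q_i 2^{L_i}$. Sharing
$q$ within a bottle is what makes the LRD estimand well defined: the
within-bottle RNA:DNA contrast is exactly the planted $L$ (minus the
small renormalization term $\log_2 \sum_i q_i 2^{L_i}$) plus sampling
noise. The default community holds twenty marine genera with realistic
lineages (hydrocarbon degraders, methylotrophs, Flavobacteriaceae); the
default planted effects follow the motifs such experiments report —
a dispersant-responder (Colwellia) enriched under DISP/CEWAF/CEWAFN, an
oil-responder (Marinobacter) enriched under WAF and suppressed under
dispersant, strong RNA-only enrichment for a rare methylotroph, and RNA
silencing for one Oceanospirillaceae genus — switched on from day 7.
Depths default to $10^4$ reads; parameter-recovery tests use $10^5$.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: annotation error and chimeras, taxon
correlations beyond the Dirichlet's, depth variation between libraries,
membership turnover (at these depths every merged label occurs in every
sample, which is why the simulated MNTD matrix is identically zero and
MNTD is validated on sparse random instances instead), and any
correlation between phylogeny and response. Because replicate libraries
of one bottle share $q$, their residual variation is sequencing noise
only; pseudo-F values on the synthetic Bray-Curtis matrix are therefore
much larger than real data would give.

# Numerical and design choices

* Tolerances: symmetry/normalization checks at 1e-9 absolute;
  threshold comparisons in the merge allow 1e-12 slack so ratios of
  integers compare as intended; MPD/MNTD oracle agreement at 1e-12.
* Merging uses the subtree abundance of a rank (all descendants present
  in the table), evaluated once from the input — this makes the merge a
  fixed point in a single pass and order-independent.
* Homonyms in the reference resolve toward the table's majority domain
  (by total counts); unresolved ones follow the unknown-label policy.
* Time is categorical by default (`time_linear` flag available); the
  ordinal day values 0/7/17/28/42 are carried in the design but only
  their ordering enters the factor.
* The permutation stream is seeded and the global RNG state restored on
  exit; all pipeline randomness derives from the single config seed, and
  rerunning a config yields byte-identical artifacts (checksummed in the
  manifest).
* Problem sizes in tests: oracle comparisons use 200 random instances
  (≤10 taxa, ≤4 ranks for the merge; ≤8 taxa, ≤6 samples for
  MPD/MNTD); type-I error calibration uses 500 null datasets of 20
  samples at 199 permutations; LRD recovery uses 20 seeds at depth
  $10^5$. These sizes make the full suite run in well under a minute
  apiece while leaving the binomial error bars tight enough to detect
  miscalibration.

# Known limitations

* The merge can place a label and its ancestor-named remainder bucket in
  one table; consumers that require rank-homogeneous output should
  aggregate further.
* PERMANOVA uses free permutations only — no strata — matching the
  analysis it reproduces; with repeated measures over time this is a
  liberal choice, and within-bottle replicate correlation (see above)
  further inflates significance on the synthetic data.
* MNTD degenerates to zero without membership turnover; this is a
  property of the statistic, not a bug, but it limits what the default
  synthetic run can say about it.
* The reference tree for the synthetic run is itself simulated; planted
  effects are phylogenetically unstructured, so MPD contrasts reflect
  abundance shifts, not clade structure.

# A worked run

```{r, eval = FALSE}
cfg <- list(synthetic = TRUE, seed = 9, threshold = 0.04,
            permutations = 999, sim = list(replicates_rna = 2))
manifest <- run_pipeline(cfg, "results/run1")
```

The numbered scripts under `analysis/` run the same stages separately
(simulate, merge, LRD, ordination, PERMANOVA) with a narrative printout,
and `scripts/acceptance.R` recomputes the headline quantities — planted
LRD recovery, dispersant/time PERMANOVA terms, ordination inertia,
type-I calibration — from scratch into a JSON report.
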
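# lrdmeta

Community-level analysis of paired metatranscriptomic and 16S rRNA gene
count tables from oil/dispersant seawater microcosms — for microbial
ecologists asking not just *who is there* after an oil spill and
dispersant application, but *who is transcribing*, and whether the
dispersant, the oil, or their interaction drives the community's
trajectory.

The experimental design behind the package is a factorial microcosm
study: a water-accommodated oil fraction (WAF), dispersant (DISP), their
combination (CEWAF), CEWAF plus nutrients (CEWAFN) and a biotic control
(BC), sampled at days 0, 7, 17, 28 and 42 (CEWAFN at days 0, 7, 42
only), with triplicate 16S libraries per cell.

## What it computes

**Taxonomy aggregation.** Raw annotation labels are canonicalized
against a local reference (synonyms, case, whitespace) and merged up
their lineages until every reported label's subtree reaches a minimum
relative-abundance resolution *T* (default 4%) in at least one sample.
Per-sample totals are conserved exactly; the merge is idempotent and
monotone in *T*.

**The LRD activity index.** For taxon *i* and treatment *j*,

    LRD_ij = (1/n) Σ_t log2( r_ijt / d_ijt )

with *r* the metatranscriptomic and *d* the 16S relative abundance at
timepoint *t*, averaged over the timepoints the treatment has. Taxa
fall into Group I (mean LRD > 3.5, high synthetic capacity), Group II
(|mean LRD| ≤ 3.5, inclusive) and Group III (mean LRD < −3.5).

**Beta-diversity.** Bray-Curtis dissimilarity with principal
coordinates ordination; abundance-weighted phylogenetic distances
between samples over a newick reference tree — MPD
(Σᵢ Σⱼ p_iA p_jB δᵢⱼ) and MNTD (weighted nearest-taxon distance,
symmetrized); analytic hypergeometric rarefaction.

**PERMANOVA.** Sequential (Type I) sums of squares on any of the
distance matrices for the fixed-order factorial model

    U = O + D + O×D + O×D×N + t + O×t + D×t + O×D×t + O×D×N×t

with free permutation of sample identities, seeded and reproducible;
aliased terms (nutrients occur only in CEWAFN) keep the degrees of
freedom that survive, reported rather than hidden.

**Synthetic data.** A Dirichlet-multinomial generator emulates the full
design — one latent composition per microcosm bottle shared by the 16S
replicates and the paired RNA library, planted abundance fold-changes on
the DNA side and planted log2 RNA enrichments on the RNA side — so the
entire pipeline runs and is tested without any sequencing download.

## Worked example

The numbered scripts under `analysis/` run the workflow with a
narrative printout; `Rscript analysis/01_simulate.R` through
`05_permanova.R` write tables under `results/`. Step 2 and 3 print,
for the default simulated experiment:

```
merged 20 input taxa into 20 labels at T = 4%
5 labels were promoted to a higher rank; e.g.
         raw_label         final_label final_rank
         Amphritea  Oceanospirillaceae     family
     Methylobacter Gammaproteobacteria      class
...
group sizes:
  I  II III
  0  99   1

most active (taxon, treatment) rows by mean LRD:
               taxon treatment  lrd_mean n_used group
 Piscirickettsiaceae     CEWAF 2.7611888      5    II
          Bermanella       WAF 2.6749807      5    II
```

Reading this: rare genera (Amphritea, Methylophaga, ...) fell below the
4% resolution and surface as their family or class; the planted RNA
enrichment for Bermanella under oil (L = 4) is recovered at its own
rank, while the enrichment planted for Methylophaga appears diluted in
its family bucket Piscirickettsiaceae (2.76 instead of 4) because the
unenriched Cycloclasticus merged into the same label — the
rank-aggregation/LRD interaction one must keep in mind with real data
too. The RNA-silenced Amphritea drags its family to mean LRD −3.72,
the single Group III row. Step 5 then shows the dispersant term
dominating the Bray-Curtis partition (R² = 0.46, p = 0.001 at 999
permutations) with time second (R² = 0.19), mirroring the planted
design.

A single call runs everything end to end and writes a checksummed
manifest (byte-identical for a fixed config and seed):

```r
library(lrdmeta)
cfg <- list(synthetic = TRUE, seed = 9, threshold = 0.04,
            permutations = 999, sim = list(replicates_rna = 2))
run_pipeline(cfg, "results/run1")
```

## Package layout

- `R/` — the implementation (IO and types, taxonomy merge, LRD,
  diversity, phylogenetic beta-diversity, PERMANOVA, simulator,
  pipeline driver)
- `analysis/` — numbered workflow scripts over the package
- `tests/testthat/` — unit, property and end-to-end suites with
  independent brute-force oracles
- `vignettes/microcosm-workflow.Rmd` — the methods vignette: models,
  assumptions, parameter defaults, numerical choices, limitations
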
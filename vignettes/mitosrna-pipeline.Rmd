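---
title: "The mitosRNA analysis pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mitosRNA analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosr)
```

# Overview

`mitosr` catalogs mitochondria-derived small RNAs (mitosRNAs) from
small-RNA-seq libraries and profiles the tRNA-derived fragments among
them. The pipeline has a fixed order — adapter trimming, 15–27 nt size
selection, collapsing to unique sequences, low-abundance filtering,
depth normalization, exact alignment to the circular mitochondrial
genome, strand/feature annotation, negative-binomial differential
expression, and fragment profiling — because each stage's contract
assumes the previous one (e.g. the aligner assumes adapter-free,
ACGT-only sequences).

The unit of analysis throughout is the *unique sequence*, not a gene:
two fragments differing by one terminal nucleotide are distinct rows of
the count matrix. This is what makes end-class and conserved-core
analysis possible downstream.

# Coordinate and strand conventions

Internally every interval is 0-based half-open on the heavy strand; the
heavy strand is defined as the forward strand of the reference FASTA and
the light strand as its reverse complement (the reference itself does
not declare which biological strand it is — this is a documented
assumption). GFF3 input/output converts to 1-based closed coordinates at
the boundary. On the circular genome, features or hits spanning the
origin are stored wrapped (`end > L`) and interpreted modulo the genome
length `L`.

# Exact alignment to a circular genome

Only 100%-identity hits are accepted, on either strand. The aligner
scans the genome extended by its first `m − 1` bases (`m` = query
length), which finds origin-wrapping matches without special-casing;
starts at or beyond `L` are duplicates of wrapped hits and are dropped.
The light strand is searched by matching the query's reverse complement
against the heavy strand, so a light hit at `[s, e)` means the read
equals the reverse complement of that heavy-strand interval. The test
suite checks this implementation exhaustively against a naive
doubled-string scan on random genomes up to 2 kb.

Multi-mapping sequences keep all hits, but summaries count each
sequence once through its *primary* hit: lowest heavy-strand start,
heavy before light on ties. Toy mitochondrial genomes essentially never
multi-map, but the tie-break is deterministic and documented; a
per-locus mode (`build_catalog(..., per_locus = TRUE)`) reports every
hit.

# Overlap classes and the extension allowance

A hit fully inside exactly one feature is `single_feature`. Any
extension beyond the feature — even 1 nt — reclassifies the hit as
`overlapping_features`, with `intergenic` appended to its feature list;
overlapping two or more annotated features does the same. This strict
(zero-allowance) rule was chosen because observed fragments genuinely do
start a couple of nucleotides upstream of their tRNA and extend into it,
and those must land in the overlapping/intergenic column of the summary
table rather than be absorbed into the tRNA column. The catalog records
the upstream/downstream extension lengths so a user can apply a laxer
rule post hoc.

# The negative-binomial model

Counts are modelled as NB with mean `µ` and dispersion `α`
(`Var = µ + α µ²`; `α = 0` is Poisson). Two deliberate simplifications
relative to full DE frameworks:

* **Dispersion** is a per-sequence method-of-moments estimate on
  normalized counts, pooled across the stage's treatment groups:
  `α̂ = max(0, (s²_within − µ̄)/µ̄²)`. No shrinkage across sequences is
  applied. This is noisier than shrinkage estimators at 3 replicates,
  which is why acceptance rests on planted-truth recovery (sensitivity
  ≥ 0.9, FDR ≤ 0.05 at |log2FC| = 4, mean 200, α = 0.1) rather than on
  replicating any particular DE list.
* **Testing** is a Wald test per contrast (each treatment vs `t0`
  within a stage — the natural reading of a design whose heatmaps show
  every treatment against time zero): `z = log2FC / SE` with the
  delta-method `SE² = (1/ln2)² Σ_g (µ_g + α µ_g²)/(n_g (µ_g + c)²)`,
  two-sided normal p-value, BH adjustment within contrast. A
  pseudocount `c = 0.5` normalized counts keeps fold changes of
  zero-count cells finite.

The DE call uses the published thresholds as *strict* inequalities:
`baseMean > 25`, `|log2FC| > 2`, `padj < 0.01`, with `baseMean` the
mean normalized count over all of the stage's samples, and the fold
change and adjusted p required in the *same* contrast. A sequence is DE
overall if flagged in at least one stage. Null simulations in the test
suite confirm that fewer than 2% of null sequences reach
`padj < 0.01`.

# Size factors

Median-of-ratios over the rows detected in every library, matching the
convention of the established DE tools (and cross-checked against one in
the tests). When no row is positive everywhere — possible in very sparse
toy data — the estimator falls back to column-total scaling with a
warning rather than failing.

# Fragment profiling

* **End classes** use a tolerance τ = 2 nt, matching both the planted
  jitter of the simulator and the granularity at which real fragment
  termini are reported; classification happens in the feature's own
  5'→3' orientation, so light-strand features flip coordinates.
* **Coverage profiles** include a 5 nt flank on each side of the
  feature so upstream extensions are visible.
* **Clustering** of relative-to-row-mean log2 fold-change patterns uses
  k-means with Euclidean distance, k = 3 by default (the number of
  broad anoxia/recovery patterns), Lloyd iterations with 20 random
  restarts under a fixed seed. `stats::kmeans` provides the
  implementation; with 20 restarts on well-separated patterns the
  seeding scheme (random rows rather than k-means++) is immaterial, and
  the planted-partition test demands perfect recovery.
* **Conserved core / probe**: the longest substring shared by every
  member of a fragment family, ties broken by the leftmost occurrence
  in the first sequence; the probe is its reverse complement. Probe
  chemistry (LNA thermodynamics, melting temperature) is out of scope —
  only the target-sequence logic is modelled. The finder is verified
  against a brute-force common-substring enumeration.

# The synthetic world

The simulator states a world once and the tests measure against it; its
defaults were not adjusted after seeing test outcomes.

* **Design**: 4 stages (D2, WS36, WS40, WS42) × 5 treatments (t0, EA,
  LA, ER, LR) × 3 replicates. The replicate number is not something the
  motivating study prints; 3 is a conventional small-RNA-seq depth.
* **Genome**: 2 kb circular toy genome with 5 tRNAs (20% on the light
  strand, as in real vertebrate mt genomes), 2 rRNAs, 3 mRNAs, one
  D-loop and one replication origin, all separated by intergenic gaps.
* **Planted fragments**: 1–5 variants per family generated by end
  jitter; 3' families share a core anchored at the feature's 3' end
  (variants are suffix-nested), 5' families symmetrically. Default core
  17 nt, jitter 2 nt, so all variant lengths stay within the 15–27 nt
  size window. Induction is scaled per stage (D2 0, WS36 1, WS40 0.5,
  WS42 0.25) to emulate an anoxia response that is robust in WS36,
  muted in WS40 and absent in dormant D2 embryos.
* **Noise**: NB sampling with `α = 0.1` by default; `α = 0` gives
  Poisson; an `exact` mode bypasses sampling for degenerate-noise
  tests. Per-library depth factors are drawn uniformly from
  [0.75, 1.25] so normalization is actually exercised.
* **Background**: 200 reads per library drawn from a pool of 25
  fragments of a 5 kb random decoy contig. The pool (rather than fully
  random positions) makes background sequences abundant enough to
  survive the low-abundance filter, so the non-mitochondrial branch of
  the catalog is exercised. A 12 nt synthetic adapter is appended to
  every read and the read truncated to 34 nt.

What the simulator does **not** emulate: sequencing errors, quality
variation, nuclear mitochondrial pseudogenes (NUMTs), ligation biases,
or realistic library depth. A green recovery test therefore establishes
that the pipeline's logic is correct under its stated model — not that
the model captures every artefact of real libraries.

# Numerical choices and degenerate inputs

* Low-abundance threshold: total raw count ≥ 10 across libraries
  (the original cutoff is unprinted; configurable).
* Adapter matching is exact with minimum overlap 6 nt; reads containing
  `N` are dropped at read-in with a logged count rather than resolved.
* Empty catalog subsets summarize to zero counts with percentages
  reported as 0.0 and an `empty` flag; enrichment on an empty subset is
  an error.
* `wald_test` with fewer than 2 replicates on either side reports the
  fold change but `NA` p-values; all-zero rows get `NA` dispersion and
  are excluded from testing.
* Disjoint fragment families yield a length-0 core, flagged
  `degenerate`.
* Trait correlations require ≥ 3 stages; zero-variance inputs return
  `NA` with a warning. The published stage traits (anoxia LT50,
  metabolic rate) come from prior work and are user-supplied.

# Limitations

* No mismatch-tolerant or gapped alignment; a single sequencing error
  makes a read invisible to the catalog (by design — the retention rule
  is 100% identity).
* The moment dispersion estimator is anti-conservative for very small
  replicate numbers combined with small effect sizes; the recovery
  guarantees hold for the stated world (|log2FC| = 4, mean 200,
  α = 0.1, 3 replicates) and degrade for weaker signals.
* Feature-type enrichment treats sequences as independent draws, which
  ignores that fragment variants of one family are correlated.
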
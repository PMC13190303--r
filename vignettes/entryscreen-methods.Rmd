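---
title: "Methods: enrichment screens, spectral ratios and homolog architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment screens, spectral ratios and homolog architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entryscreen)
```

`entryscreen` implements the computational core of a phage host-factor
screen: a barcoded transposon library is challenged with phage, surviving
clones are quantified by barcode sequencing (BarSeq), and genes whose
disruption permits survival are ranked by an enrichment statistic. Around
that core sit two companion analyses that the same kind of study produces:
enrichment ratios from pull-down spectral counts, and architecture analytics
for a family of membrane-anchored defence-protein homologs. All inputs can
be simulated with known ground truth, which is how the package tests itself.

## The enrichment statistic

Each condition column of the barcode count table is normalized as

$$v_i = \log_2\!\left(\frac{c_i}{\sum_j c_j} \times 10^6 + 1\right),$$

i.e. log2 of counts-per-million with the `+1` *inside* the logarithm, so a
zero count maps to exactly 0 and the transform is strictly monotone. The
normalization is implemented exactly in this form (`log2_cpm()`), not as a
rescaled `log1p`, because the two differ in their fixed points.

For each phage condition we fit ordinary least squares with intercept,

$$v^{\text{phage}}_i = \beta_1\, v^{\text{control}}_i + \beta_0 + r_i,$$

with the no-phage condition as the independent variable. The residual
$r_i$ is barcode $i$'s deviation from the abundance expected under no
selection. Averaging residuals within genes (intergenic barcodes excluded)
gives the per-gene log2 enrichment score; genes required for phage
infection surface at the top of the ranking. Scores are descriptive ranks:
no p-values or multiple-testing machinery are attached, because the
statistic itself is the readout.

Design choices worth noting:

* **Intercept included.** "Linear regression" alone does not determine the
  model; including an intercept is the default convention and gives the
  testable identities $\sum_i r_i = 0$ and $\sum_i r_i x_i = 0$, both
  asserted in the test suite at $10^{-9} n$.
* **No default count filter.** Barcodes with zero counts in both conditions
  contribute a point at the origin. A `min_total` filter exists in
  `run_screen()` but is off by default, since dropping rows silently would
  change the fit.
* **Unweighted gene means.** Residuals are averaged per gene without
  abundance weighting; ties in the ranking are broken lexicographically by
  gene id so output order is reproducible.

## Barcode counting

`extract_barcode()` anchors the pre-flank at any offset allowing a bounded
number of substitutions (fewest mismatches wins, then smallest offset) and
verifies the first eight bases of the post-flank under the same budget.
Counting is closed-pool: observed barcodes not in the characterized pool
are discarded and reported, never added as rows. The default assignment
policy is exact matching; `correct1` optionally rescues observed barcodes
that have exactly one pool barcode within Hamming distance 1, discarding
ambiguous cases. Exact is the default because the tolerance of upstream
counting pipelines varies, and a conservative default makes the round-trip
identity (error-free simulated reads count back to exactly the simulated
table) the contract. Per condition, the accounting identity
`assigned + discarded + unextracted = total` always holds.

## Spectral-count ratios

Pull-down enrichment is quantified as
$\log_2(c_a + p) - \log_2(c_b + p)$ with pseudocount $p$ (1 for
proximity-labelling tables, 0.5 for crosslinking tables; both are plain
parameters). Computing the ratio as a difference of logs makes the
swap-antisymmetry exact at the bit level. Ratios are reported for proteins
whose maximum count across samples reaches the `min_count` threshold
(default 50); the filter runs before ratio computation, is idempotent and
never alters counts.

## Homolog architecture

**Pairwise identity.** `pairwise_identity()` is a Needleman–Wunsch global
alignment with fixed scoring: match $+1$, mismatch $0$, linear gap $-1$.
Among co-optimal alignments the one maximizing match count is used; this
lexicographic refinement makes identity and coverage well defined, since
with this scoring the gap-column count is $G = M - S$ (matches minus
score) and the residue-residue column count is $A = (\ell_a + \ell_b -
G)/2$, so identity $= M/(A+G)$ and coverage $= A/\min(\ell_a, \ell_b)$
depend only on $(S, M)$. The DP kernel is in C++; the test suite checks it
against an exhaustive alignment enumerator on short sequences.

**Dereplication.** Greedy, deterministic: scan by length descending (ties
by id), join the first representative met at identity $\ge 0.95$ and
coverage $\ge 0.9$ (the conventional thresholds for collapsing
near-identical homologs), else found a new representative. Every member
provably satisfies both thresholds against its representative.

**Identity profile.** At each reference position, raw identity is the
fraction of non-reference rows matching the reference residue in that
alignment column, with gaps counted as mismatches. Reference-match
identity (rather than consensus identity) is used because the profile is
expressed in reference coordinates; a consensus-based profile would not be
anchored to the reference numbering. A five-residue centred rolling mean is
applied with truncated windows at the ends, so the profile length equals
the reference length exactly.

**Regions, TMs, hit cover, clades.** Region lengths count a homolog's
non-gap characters within the alignment span of each reference region
(1-based inclusive). TM summaries classify homologs into 0/1/2+ predicted
segments and collect first- and second-segment starts and lengths
separately. `hydropathy_tm_predict()` is a deliberately simple
Kyte–Doolittle sliding-window predictor (window 19, threshold 1.6, the
classic membrane-span settings); it exists so the TM-summary machinery can
be exercised from sequence alone, and it reports the full residue span of
each above-threshold window run, which slightly overhangs the hydrophobic
core. `greedy_hit_cover()` applies the strict significance cutoff
$p < 10^{-5}$, then repeatedly takes the most common hit (ties by name),
records its coverage and removes covered homologs. `clade_grouping()` forms
single-linkage components at identity $> 0.90$ and flags (never merges)
clades with any cross-clade pair at identity $\ge 0.20$; a region-restricted
identity mode supports comparisons over a fixed residue window such as
100–150.

External predictors and clustering tools are intentionally not wrapped:
their outputs (TM segments, domain hits) are consumed as plain annotation
tables, and the algorithms above are the package's own, documented
procedures. Protein coordinates are 1-based inclusive throughout; genomic
coordinates are 0-based half-open.

## What the simulators emulate

`simulate_tn_library()` draws uniform insertion sites, unique random
barcodes and log-normal clone abundances (sdlog = `abundance_dispersion`,
default 1 — the standard model for clone-abundance skew, which the
protocol itself does not constrain). `simulate_selection()` models phage
challenge as barcode reweighting (weight 1 in required genes, escape rate
$\varepsilon$ elsewhere) followed by multinomial resampling at the
requested depths; this reproduces the effective statistics of a
plate-select-and-scrape protocol without agent-level simulation, and
deliberately ignores double-infection kinetics. Column sums equal the
requested depths exactly. `emit_barseq_reads()` writes one read per count
with substitution-only errors — sufficient for flank-anchored extraction;
indels are out of scope. `simulate_spectral_counts()` uses
gamma-distributed per-protein baselines with Poisson sampling and
multiplicative planted fold changes. `simulate_homolog_family()` derives
homologs from a random reference by per-region substitution (defaults
0.6/0.3/0.1 across an N-terminal region, a DUF4041-like domain and a
nuclease domain at 1–190/191–330/331–500 of a 500-aa reference,
reproducing the observed conservation ordering), one N-terminal indel of
up to 60 aa placed just after the first reference position (so it stays
inside the first region's alignment span), and TM segments within the
first 70 aa, 10–20 aa long, at fractions 0.59/0.07 for one/two segments.
Every generator is a pure function of its seed, and each emits truth
tables sufficient to recompute what it generated.

What passing tests on these simulations do **not** show: real BarSeq
libraries have position-biased insertion densities, PCR jackpotting and
indel errors; real spectral counts have shared-peptide ambiguity and
batch structure; real homolog families have phylogenetic correlation
rather than i.i.d. substitutions. The simulations validate the statistics'
mechanics and recovery behaviour, not robustness to those artefacts.

## Problem sizes and study conditions

Recovery simulations use 200 genes of 950 bp tiling a 200-kb genome (so
~95% of insertions are genic and each gene carries ~15 barcodes at 3,000
insertions), two phage-required genes, escape rate $10^{-3}$, and depths
of $10^6$ reads per condition, repeated over 20 seeds; null calibration
repeats the same with $\varepsilon = 1$ and requires no gene beyond five
score standard deviations. Spectral recovery plants a 16-fold protein at
baseline mean 100 among 300 proteins. The profile analyses run a
474-homolog family (matching the scale of a curated defence-protein
homolog set) and TM summaries an 1,000-homolog family. These sizes were
chosen once as representative of the corresponding real datasets.

## Known limitations

* The aligner is exact Needleman–Wunsch with linear gaps; for very long
  or highly divergent pairs an affine-gap or heuristic aligner would
  differ. Dereplication cost is quadratic in the number of sequences.
* `hydropathy_tm_predict()` is a scale-based heuristic, not a topology
  model; it over-extends segments by construction and knows nothing of
  inside/outside orientation.
* The selection model treats survival as independent Bernoulli reweighting;
  co-infection, lysogeny and growth-rate differences are not modelled.
* The p-value column of domain-hit tables is applied as given; whether it
  is a probability or an E-value is the annotation producer's concern.
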
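# entryscreen

Analysis toolkit for genetic screens that identify the bacterial host
factors a bacteriophage needs to inject its genome. The experimental
design it serves: a pooled library of cells carrying uniquely barcoded
transposon insertions is challenged with phage; most cells die, but cells
whose insertion disrupts a gene required for infection survive. Sequencing
the barcodes before and after selection (BarSeq) and comparing the two
conditions ranks every gene by how strongly its disruption protects the
cell. The same studies typically produce two companion datasets this
package also handles: spectral-count tables from proximity-labelling or
crosslinking pull-downs (which proteins sit near the defence machinery),
and homolog families of the defence protein itself (how its domains
diversify across bacteria).

## The statistic at the core

For each condition column of the barcode count table,

```
v_i = log2( (c_i / Σ_j c_j) × 10^6 + 1 )
```

(log2 counts-per-million with the pseudocount inside the logarithm). For
each phage condition, ordinary least squares with intercept is fitted with
the no-phage condition as the independent variable,

```
v_phage,i = β1 · v_control,i + β0 + r_i ,
```

and each barcode's residual `r_i` is its log2 deviation from the abundance
expected under no selection. The per-gene **log2 enrichment score** is the
mean residual over the gene's barcodes; phage-required genes rise to the
top of the ranking.

Alongside the screen statistic the package provides: flank-anchored
barcode extraction and closed-pool counting (exact or Hamming-1-corrected);
pseudocounted log2 spectral-count ratios with a max-across-samples ≥ 50
reporting filter; and homolog-family analytics — global-alignment percent
identity (Needleman–Wunsch, match +1 / mismatch 0 / gap −1), greedy
dereplication at 0.95 identity / 0.9 coverage, reference-coordinate
identity profiles with a five-residue rolling mean, region-length
extraction, transmembrane-segment summaries, a Kyte–Doolittle hydropathy
predictor, greedy most-common-hit coverage at p < 1e-5, and identity-based
clade grouping (> 0.90 within, < 0.20 between). A synthetic-data module
generates every input with machine-readable ground truth.

## Worked example

Simulate a screen with two planted phage-required genes, run the
enrichment statistic, and confirm it recovers them:

```r
library(entryscreen)

genes <- gene_models(sprintf("g%03d", 1:200),
                     start = seq(0, by = 1000, length.out = 200),
                     end   = seq(950, by = 1000, length.out = 200))
pool <- simulate_tn_library(200000, genes, n_insertions = 3000, seed = 1)
sel  <- simulate_selection(pool,
                           selection_model(c("g010", "g020"), 1e-3, "lambda"),
                           depth_control = 1e6, depth_phage = 1e6, seed = 2)
scores <- run_screen(sel$counts, pool, "no_phage", "lambda")
head(scores$lambda, 4)
#>   gene_id n_barcodes     score rank
#> 1    g020         13 9.8179115    1
#> 2    g010         19 9.7804684    2
#> 3    g196          3 0.3111045    3
#> 4    g199         12 0.1993538    4
```

The two planted genes score ≈ 9.8 — their barcodes are ~2^9.8 ≈ 900-fold
above the abundance expected from the no-phage fit — while every
unprotected gene sits near 0. The same recovery works for a planted
16-fold-enriched protein in a spectral-count table:

```r
sim <- simulate_spectral_counts(300, baseline_mean = 100,
                                planted = data.frame(protein_id = "P0005",
                                                     fold_change = 16,
                                                     origin = "phage"),
                                seed = 3)
head(enrichment_table(sim$table, "bait", "control",
                      pseudocount = 1, min_count = 50), 3)
#>   protein_id origin bait control log2_ratio
#> 1      P0005  phage 1271      89  3.8210299
#> 2      P0145   host   59      39  0.5849625
#> 3      P0267   host  113      78  0.5291093
```

The planted protein tops the table with a log2 ratio near 4 (= log2 of the
planted 16-fold change); background host proteins scatter near 0. And for
a simulated 474-member homolog family with domain-specific substitution
rates:

```r
fam  <- simulate_homolog_family(homolog_family_spec(), n_homologs = 474, seed = 4)
prof <- column_identity_profile(fam$alignment, window = 5)
round(c(nterm    = mean(prof$raw[1:190]),
        duf4041  = mean(prof$raw[191:330]),
        nuclease = mean(prof$raw[331:500])), 3)
#>    nterm  duf4041 nuclease
#>     0.37     0.70     0.90

ids <- setdiff(names(fam$sequences), "reference")
round(summarize_tm(fam$tm_truth, ids)$percent, 1)
#>    0    1   2+
#> 33.5 58.6  7.8
```

The identity profile reproduces the expected conservation ordering
(variable N-terminal region, moderately conserved middle domain, highly
conserved nuclease domain), and the transmembrane categories land at the
generative fractions (34% / 59% / 7% of homologs with zero / one / two
segments).

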
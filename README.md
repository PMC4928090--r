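# xdiverge

Cross-species transcriptome divergence analysis for count data:
which one-to-one orthologues respond *differently* in two species
exposed to the same challenge, which functional categories those
divergent genes concentrate in, and which transcription-factor binding
sites are over-represented in their promoters.

The package is aimed at comparative transcriptomics of non-model
organism pairs — the motivating design is two fish species with
different lower survival temperatures under one cooling scheme
(control 28 °C, then 8 °C sampled at 0 h, 6 h, 12 h, three replicates
per species and condition) — but every stage takes plain tables and
generalizes to any two-species, shared-design comparison.

## The statistics at the core

**Divergence calling.** Counts are modelled as negative binomial,
`Var(y) = mu + phi * mu^2`, with `log mu = offset + X beta` on a
cell-means design over the combined `species:condition` factor, TMM
effective library sizes as offsets, and Cox–Reid adjusted-profile-
likelihood dispersion (common, optionally tagwise-shrunk). A pair is
divergently expressed at timepoint *t* when the difference-of-
differences contrast

```
(B:t − B:control) − (A:t − A:control)
```

exceeds 2-fold (`|log2 FC| > 1`) with Benjamini–Hochberg FDR < 0.05
under a likelihood-ratio test. The contrast itself performs the
"normalize to control" step; counts are never pre-divided.

**Gene-set enrichment.** Upper-tail hypergeometric test,
`P = sum_{j>=i} C(M,j) C(N−M,n−j) / C(N,n)`, over a universe of tested
ortholog pairs.

**Promoter motifs.** JASPAR PFMs become log2-odds PWMs against a
0-order background estimated from the scanned promoters; the exact
null distribution of discretized window scores is computed by dynamic
programming, and both strands of the 1 kb upstream of each TSS are
scanned at the exact-P < 1e-4 threshold.

**Binding-site enrichment.** A pair contains a motif if either
species' promoter has a hit; presence × divergence 2×2 tables are
tested with Fisher's exact test (two-sided, point-probability rule)
and summarized by the conditional-MLE odds ratio — the estimator
standard exact-test implementations report, not the sample
cross-product.

A synthetic-data generator plants divergence effects, motif
occurrences and enriched annotation terms with recorded ground truth,
so the whole pipeline is testable offline.

## Worked example

```r
library(xdiverge)

cfg    <- sim_config(n_pairs = 500, seed = 2026)   # synthetic two-species design
bundle <- simulate_counts(cfg)

joint <- merge_ortholog_counts(bundle$counts_a, bundle$counts_b, bundle$map)
div   <- call_divergent(joint, bundle$samples,
                        timepoints = c("8C_0h", "8C_6h", "8C_12h"))
glance(div)
#> # A tibble: 3 × 4
#>   timepoint n_tested n_divergent n_union
#>   <chr>        <int>       <int>   <int>
#> 1 8C_0h          500          51      56
#> 2 8C_12h         500          55      56
#> 3 8C_6h          500          51      56
```

With 10% of the 500 pairs carrying a planted |log2| = 2.5 interaction,
the 2-fold/FDR 0.05 rule recovers essentially all of them at each
timepoint (51–55 calls, union 56) with few false positives. The
strongest calls show the contrast estimate, its LRT P-value and FDR:

```r
dplyr::arrange(tidy(div), pvalue) |> head(3)
#>   pair_id     timepoint log2fc   pvalue      fdr is_divergent
#> 1 A0047|B0047 8C_0h      -3.71 1.57e-20 7.86e-18 TRUE
#> 2 A0011|B0011 8C_6h       3.33 4.83e-18 2.41e-15 TRUE
#> 3 A0030|B0030 8C_12h     -3.39 3.62e-17 1.81e-14 TRUE
```

A negative `log2fc` means the cold response was stronger in species A
(sign convention: positive = larger response in the second species).
Downstream, a presence × divergence table is tested exactly; for 24
divergent pairs (15 with the motif) against 41 non-divergent (8 with):

```r
fisher_exact(15, 9, 8, 33)
#>     pvalue odds_ratio or_defined
#> 1 0.000984       6.63 TRUE
```

i.e. motif presence multiplies the odds of divergence by ~6.6
(conditional MLE), P = 9.8e-4. Replicate QC on the same bundle gives a
mean pairwise Pearson r of 0.94 on log2(CPM+1), matching what a
well-behaved NB design at dispersion 0.05 should show.

`autoplot()` methods produce volcano panels per timepoint
(`autoplot(div)`), enrichment bars and odds-ratio/P scatter plots for
the gene-set and TFBS result types.

An `xdiverge` command-line wrapper over these functions is installed
under `inst/exec/` with `run | simulate | de | diverge | go | tfbs |
qc` subcommands; `xdiverge run --config cfg.yaml` executes the full
pipeline from a YAML file and writes TSV results plus a deterministic
JSON manifest.

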
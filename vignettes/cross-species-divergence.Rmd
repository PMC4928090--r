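---
title: "Models and methods: cross-species expression divergence, gene-set and promoter-motif enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdiverge)
```

# The scientific question

When two related species are exposed to the same environmental challenge
— the motivating case is two fish species with different lower survival
temperatures subjected to one cooling scheme — which orthologous genes
respond *differently* in the two species? Such divergently expressed
orthologues are candidates for explaining the phenotypic difference, and
their promoters can be interrogated for transcription-factor binding
sites that might drive the divergence. `xdiverge` implements that chain
of analysis on gene-level count matrices: differential expression,
divergence contrasts, gene-set over-representation, promoter scanning,
and binding-site enrichment, together with a ground-truthed synthetic
data generator so every stage is testable without any external download.

# The count model

Counts for gene $g$ in sample $s$ are modelled as negative binomial,

$$ y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi), \qquad
   \mathrm{Var}(y_{gs}) = \mu_{gs} + \phi\,\mu_{gs}^2, $$

with a log-linear mean

$$ \log \mu_{gs} = o_s + x_s^\top \beta_g, $$

where $o_s$ is the log *effective library size* of sample $s$ and $x_s$
is a cell-means design row: one indicator per
`species:condition` level (8 levels for the full 2 species × 4
conditions design, each with 3 replicates). $\phi = 0$ recovers the
Poisson model.

**Normalization.** Effective library sizes are raw library sizes times
trimmed-mean-of-M-values (TMM) factors: gene-wise log2 ratios against a
reference sample are trimmed (30% on M, 5% on A by default) and averaged
with inverse delta-method-variance weights; factors are rescaled to a
geometric mean of 1. Cross-species comparisons keep each sample's own
species' factors — there is no cross-species length or annotation
correction, a documented limitation shared with the analysis this
package systematizes.

**Dispersion.** A common $\phi$ is estimated by maximizing the summed
Cox–Reid adjusted profile likelihood (the NB log-likelihood at the
fitted coefficients minus $\tfrac12 \log\det X^\top W X$) over
$\log\phi$. Optional tagwise estimates shrink gene-wise curves toward
the common curve by weighted likelihood with `prior_df` (default 10)
prior degrees of freedom, maximized on a grid around the common value
with quadratic interpolation. Exact numerical equality with any
particular release of the established NB-GLM packages is not a target;
those packages serve as independent cross-checks in the test suite.

**Fitting and testing.** Coefficients are fitted by IRLS with step
halving (deviance provably non-increasing per iteration; tolerance
`1e-8` on the relative deviance change, at most 50 iterations).
Hypotheses are tested by likelihood-ratio test: the design is projected
onto the null space of the contrast, the reduced model is refitted at
the same dispersion, and the deviance difference is referred to
$\chi^2_1$. Genes with all-zero counts are excluded from testing and
from the Benjamini–Hochberg denominator.

# The divergence contrast

For timepoint $t$ with control $c$ and species $A, B$, divergence is the
difference of differences on cell means:

$$ \Delta_g = (\beta_{B:t} - \beta_{B:c}) - (\beta_{A:t} - \beta_{A:c}). $$

This contrast *is* the "normalize each species to its own control" step:
no counts are pre-divided, and on fitted cell means the contrast equals
the log ratio-of-ratios exactly (asserted in the tests at `1e-6`). The
sign convention is fixed: positive means a larger response in species
$B$, where $B$ is the second label of `species_order` (sorted labels by
default), so relabeling the species flips every contrast sign exactly.

A pair is called divergent at a timepoint when $|\Delta_g| > \log_2 2$
**and** BH-FDR $< 0.05$, both strict inequalities. BH is applied within
each timepoint's P-value vector, with $m$ the number of tested pairs
(per-contrast adjustment mirrors running one established-GLM call per
contrast; pooling across contrasts is available by adjusting the output
yourself). The union of the per-timepoint calls is the overall divergent
set.

`merge_ortholog_counts()` enforces a strictly one-to-one map and an
"expressed" filter of at least 1 count in at least 3 samples per
species; the filter is configurable because the upstream convention
(raw counts vs CPM) is rarely stated in published analyses.

# Gene-set over-representation

For a universe of $N$ genes, $n$ of them divergent, a term with $M$
annotated members of which $i$ are divergent has

$$ P = \sum_{j=i}^{\min(n,M)} \frac{\binom{M}{j}\binom{N-M}{n-j}}{\binom{N}{n}}, $$

the upper tail *including* the observed count, computed by log-space
summation. Terms are flagged at raw $P < 0.05$ by default — matching the
practice this pipeline reproduces — with BH adjustment behind a flag.
The default universe is the set of tested ortholog pairs (not a whole
genome): enrichment is asked relative to what was actually testable.
Term gene sets are used as given; no ontology-graph propagation is
performed.

# Promoter scanning

The promoter is the 1 kb immediately upstream of the TSS in gene
orientation, TSS base excluded, truncated at contig edges; the TSS is
the first base of the canonical transcript (minimum coordinate on `+`,
maximum on `-`; 0-based half-open internally, 1-based only in files
that are 1-based by dialect).

Position frequency matrices (JASPAR text format) become log2-odds PWMs
against a 0-order background with a total pseudocount of 0.1 per column
spread by background frequency. The background defaults to the base
composition of the scanned promoter set itself (configurable to
uniform); zero-probability cells (possible only at pseudocount 0) are
floored at −30 bits so downstream arithmetic stays finite while any
such window remains effectively unmatchable.

Scores are discretized to multiples of `granularity` (default `1e-3`
bits) and the *exact* distribution of the discretized score of a
background-random k-mer is computed by dynamic programming, giving
$P(\text{score} \ge s)$ for every attainable score; brute-force
enumeration over all k-mers reproduces these tails to `1e-9` in the
tests. A window is a hit when its exact P-value is below `1e-4` (the
conventional scanning default). Both strands are scanned; windows
containing `N` are skipped rather than scored against a fallback.
Because scanning and the null distribution share one discretization,
threshold monotonicity and strand symmetry hold exactly.

# Binding-site enrichment

An ortholog pair *contains* a motif when either species' promoter has at
least one hit (the either-species rule, symmetric in species order). For
each motif a 2×2 table of presence against divergence is built over a
scope gene set — e.g. the members of one GO category; the scope is an
input list, never a hard-coded term — and tested with Fisher's exact
test: the two-sided P-value is the sum of the probabilities of all
tables with the observed margins whose point probability does not
exceed the observed one.

The reported odds ratio is the **conditional maximum-likelihood
estimate** under the noncentral hypergeometric likelihood given both
margins, not the sample cross-product (which it visibly shrinks toward
1 on real tables). One numerical subtlety is deliberate: the root of the
conditional score equation is solved with the same bracketing and
convergence tolerance as the standard exact-test implementations, so
printed estimates from those tools are reproduced digit-for-digit. A
maximally precise root occasionally differs in the third decimal — for
one validation table the exact CMLE is 4.0651 where the standard
implementation reports 4.0649 — and matching the reporting convention
was judged more useful than the extra precision. Zero-margin tables
return $P = 1$ with an undefined (NaN) odds ratio and a flag.

Apoptosis-related transcription factors are defined by a literal,
case-insensitive keyword rule — a GO term name containing "apoptosis" or
"apoptotic" — applied to a user-supplied TF catalog; "programmed cell
death" deliberately does not match. Interaction subnetworks are induced
subgraphs on a user-supplied edge list (physical / co-localization /
genetic types carried through), reporting the fraction of query nodes in
the largest connected component, with declared intermediates allowed to
bridge.

# The synthetic-data generator

The generator emulates the study design the pipeline targets: 2 species
× {28C, 8C_0h, 8C_6h, 8C_12h} × 3 replicates, NB counts with
log-normal baseline means (median 200), dispersion 0.05, library-size
factors uniform on [0.7, 1.3], and a planted difference-of-differences
effect of $|\log_2| = 2.5$ in a configurable fraction of pairs (10% by
default), applied to species B at every non-control condition with a
random sign. Species and condition main effects are drawn once per gene
and shared, so only planted pairs carry interaction signal. Promoters
are i.i.d. background sequence (A/C/G/T = 0.3/0.2/0.2/0.3, an AT-rich
composition typical of promoters) in which motif instances sampled from
the PFM's column frequencies are planted at random offsets,
independently per species with a per-group probability (0.6 for
divergent, 0.1 for non-divergent pairs by default). Annotation terms
draw members uniformly (sizes log-uniform on 10–300); planted terms
weight divergent pairs by an odds factor (8 by default) and receive the
fixed geometric-midpoint size (~55) so the planted signal strength does
not depend on a size draw.

One global seed expands into per-component seeds by a fixed counter
(+1 counts, +2 promoters, +3 annotations), so adding a generator never
perturbs existing outputs, and every planted signal is recorded in truth
tables.

**What passing tests do and do not show.** The generator matches the
pipeline's own distributional assumptions — NB counts, 0-order
background sequence, independent planting. Real data add unmodelled
structure: gene-length and GC effects across species, correlated genes,
higher-order sequence composition, clustered binding sites, annotation
bias. Calibration and recovery on synthetic data therefore validate the
statistical machinery, not the biology of any particular dataset; the
genome-scale divergence counts of the motivating study require its
deposited sequencing data and are not reproducible from simulation.

# Problem sizes and runtime choices

The test suite and the acceptance script size their simulations to what
the statistics require rather than to genome scale: 1,000 ortholog
pairs for divergence calibration/recovery (null false-positive rate and
recovery of 100 planted effects), 200 pairs × 200 (tests) or 50
(script) seeds for end-to-end binding-site enrichment, 100-term
annotations over 20–50 seeds for gene-set calibration, and exhaustive
enumeration for the exact tests (all 2×2 tables with $N \le 40$, all
hypergeometric queries with $N \le 60$, all k-mers for motifs up to
length 6). The full pipeline on the 2,000-pair default completes in
minutes on one CPU.

# Known limitations

- One dispersion regime per analysis (common, optionally tagwise); no
  trended dispersion.
- No cross-species gene-length/GC normalization; divergence contrasts
  inherit whatever systematic quantification differences exist between
  the two annotations.
- The exact-test machinery targets 2×2 tables and single gene sets; no
  ontology-aware or rank-based enrichment.
- Promoter analysis is proximal (1 kb) only; no enhancer modelling, no
  motif discovery — only scanning of supplied PFMs.
- The test is the classic GLM likelihood-ratio test; quasi-likelihood
  F-tests are out of scope.
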
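---
title: "Methods: the models and procedures behind esomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the models and procedures behind esomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esomics)
```

`esomics` implements the bespoke computational stages used to molecularly
subtype oesophageal and gastro-oesophageal tumour cohorts, together with a
synthetic multi-platform cohort generator that provides ground truth for
every stage. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic cohort does —
and does not — establish about behaviour on real data.

## Arm-level copy-number alteration and CIN classification

A chromosome arm is called *altered* in a sample when segments whose
relative log2 copy ratio departs from zero by at least 0.15 cover at least
80% of the arm's length. Both thresholds are inclusive ("at least"), and
both are parameters (`gain_threshold`/`loss_threshold`, default 0.15;
`altered_fraction_threshold`, default 0.80). Fractions are base-pair
weighted by default: the denominator is the full arm length, and arm bases
not covered by any segment count toward neither gain nor loss — a strict
reading of "fraction of the arm". Probe weighting (`probe_weighted = TRUE`)
is available where probe density varies.

A sample is *SCNA-high* (chromosomally unstable) when it carries at least
one arm-level **loss** on an arm outside the exclusion set
`{18p, 18q, 21p, 21q}`; gains never qualify, and losses of the excluded
arms are recorded but do not count, because those arms recur in both quiet
and unstable genomes and therefore do not discriminate. The exclusion of
"21" is read at chromosome level (both arms), the conservative
interpretation; the set is a parameter. Acrocentric p-arms (13p, 14p, 15p,
21p, 22p) are marked non-callable in the bundled arm table, whose
coordinates are approximate GRCh37 arm boundaries split at centromere
midpoints — arm-level calls integrate over tens of megabases and are
insensitive to megabase-scale centromere error.

Correctness is established against a brute-force oracle that rasterizes
each arm at 10-kb resolution and counts altered bins; interval arithmetic
and the oracle agree bin-exactly on aligned fixtures.

## Ensemble mutation merging and filtering

Per-caller somatic SNV call sets are unioned on the key
(sample, chromosome, position, ref, alt); read counts for multiply-reported
variants come from the maximum-depth record, and caller provenance is kept.
The merged set then passes a fixed battery in which every rule contributes
a named *reason* and rules never short-circuit, so the rejects table is a
complete audit trail and the outcome is independent of evaluation order:

* `germline_1000G` / `panel_of_normals` — the site appears in the
  respective blacklist (allele-aware when the list records an allele);
* `normal_low_ref_coverage` — fewer than 8 reference reads in the normal;
* `normal_alt_reads` — more than 1 variant read in the normal;
* `normal_vaf` — normal variant allele fraction above 1%;
* `tumor_alt_reads` — fewer than 2 supporting reads in the tumour;
* `tumor_vaf` — tumour variant allele fraction below 5%;
* `oxog_orientation` — a C>A (or G>T) call whose alt reads sit at ≥ 90% in
  the 8-oxoguanine-consistent read orientation (F2R1 for C>A, F1R2 for
  G>T), with at least 3 orientation-counted alt reads.

The normal-sample alt-read and VAF rules are combined with OR (the stricter
reading of an ambiguous conjunction; `normal_rule = "and"` switches). VAF
denominators are ref+alt counts, the only counts the records carry.
Tumour-side minimums are inclusive. Under the generator's default read
model, roughly 3% of *true* variants draw an allele fraction below the 5%
minimum, so end-to-end recall against planted truth plateaus near 0.95
while precision is ≈ 1; this is a property of the simulated allele-fraction
distribution (Beta(2, 5)), not of the filter code, which is verified
variant-by-variant against an independent single-pass reimplementation.

## Pathway scoring

Gene-level differential expression between groups uses the Kruskal–Wallis
rank test (chi-square approximation, mid-rank ties; an all-constant gene
returns p = 1 by convention — its ranks carry no information). A pathway's
composite score is Fisher's combined statistic `S = -2 Σ log p` over its
genes that are present in the matrix. Because genes are correlated and
pathway genes are not a random sample, `S` is *not* referred to its
chi-square(2k) null; instead `P_s` is estimated by scoring `n_perm`
(default 10,000) random gene sets of the same matched size `k`, drawn
without replacement from all genes in the matrix (the natural pool; a
pool restricted to pathway genes can be substituted upstream). The add-one
estimator `P_s = (1 + #{S_rand ≥ S}) / (1 + n_perm)` is used, so `P_s`
is never 0 and its floor at 10,000 permutations is ≈ 9.999e-5.
Per-pathway seeds are derived from the master seed and the pathway *name*,
making results invariant to the order of sets in a GMT file. With
independent uniform gene p-values the empirical tail reproduces the
chi-square(2k) closed form within Monte-Carlo error, and on null data the
type-I error at 0.05 is calibrated — both are exercised in the tests at
1,000 pathways × 1,000 permutations, a size chosen to keep the suite fast
while leaving the binomial error bands tight.

## Epigenetic silencing

The original silencing calls were made by reading a methylation-versus-
expression scatterplot by eye. The package operationalizes that inverse
association with two thresholds: a sample is *silenced* for a gene when its
promoter beta value is at least `beta_high` (default 0.3) **and** its
expression (log2(RPKM+1)) is at or below the `expr_quantile` (default 0.25)
quantile of the clearly unmethylated samples (beta < `low_beta_ref`,
default 0.1), which anchor the gene's expected expressed level. A gene with
fewer than 5 unmethylated samples has no anchor and is uncallable. When
several probes map to one promoter, the probe with the most negative
methylation–expression correlation is used. All constants are parameters;
the defaults were fixed against the synthetic methylation–expression model,
not against any real cohort, and should be re-examined before use on
array data with different beta distributions.

Subtype association uses the package's exact Fisher test
(`fisher_exact_2x2`): full hypergeometric enumeration under fixed margins,
two-sided by the minimum-likelihood convention with relative tolerance
1e-7 — the convention that reproduces the printed two-sided p-values the
field's software produces. It is verified against exhaustive enumeration /
the reference implementation for every table with total up to 60. Per-gene
flags are reported at nominal `alpha` (default 0.01) and at the Bonferroni
level `alpha / number of callable genes`.

## Per-platform clustering and integration

mRNA-style matrices are reduced to features with mean above 10 (linear
scale) ranked by variance, keeping the top 25% of the original feature
count capped at the number qualifying; a count-based rule (`n = 303`,
variance-ranked) reproduces the miRNA convention with the same code path.
The matrix is transformed by log10(x+1) and row-scaled to mean 0, sd 1
(constant rows map to zeros), and samples are clustered by ward.D2 on
1 − Pearson correlation. The cluster count `k` is a required input — no
published rule for choosing it exists in this pipeline — and
`silhouette_scan()` reports mean silhouette widths over candidate `k` as a
diagnostic. External squamous-subtype centroids are applied by restricting
to shared genes, log2(x+1) transform, per-gene median centring, and
maximum-Pearson-correlation assignment, with lexicographic tie-breaks
(flagged) and a low-confidence flag below a correlation floor.

Integration encodes each platform's labels as a one-hot indicator block.
*SuperCluster* scales each block by `1/sqrt(sum of its column variances)`
so every platform contributes equal total variance; *COCA* scales by
`1/sqrt(K_p)`, discounting platforms that split samples more finely. The
exact weighting formulas of the original implementations are not public;
both forms here are surrogates chosen to realize the stated intent
(equal platform weight; granularity discounting) and are labelled as such.
The weighted indicator is partitioned by k-means with 25 restarts under a
fixed internal seed, so the module remains deterministic. K-means replaced
Ward agglomeration here after measurement: on one-hot encodings Ward
prefers to isolate samples with discordant platform votes into an outlier
cluster rather than split the concordant majority, and under the 10%
label-noise recovery benchmark it reached a mean adjusted Rand index of
only 0.66 where k-means reaches 0.93. Note one consequence of indicator
weighting in general: duplicating a platform leaves every block's weight
unchanged but doubles that platform's vote for samples whose platforms
disagree, so duplication invariance is exact only where platforms concur.

## Mutational signatures

SNVs with a trinucleotide context are binned into the standard 96-context
catalog (6 pyrimidine-strand substitution classes × 16 flanking pairs);
purine-reference records are reverse-complemented, and records whose
context disagrees with the reference allele are rejected and tallied, never
silently dropped. Count conservation (bin sums = valid SNV counts) is
asserted on every fixture.

Signature extraction is a Bayesian NMF with automatic relevance
determination, written for this package: the catalog `V (96 × N)` is
factorized as `W H` under the generalized Kullback–Leibler objective, with
exponential priors on the columns of `W` and rows of `H` sharing one
relevance scale `λ_k` per candidate signature (inverse-gamma hyperprior,
shape `a = 10`, rate `b = 1`). Maximum-a-posteriori fitting alternates
multiplicative updates of `W` and `H` with the closed-form `λ` update;
each step is a majorization–minimization move, so the penalized objective
is non-increasing — asserted on every run in the tests. Candidates whose
mutation mass collapses below `prune_fraction` (default 1%) of the
reconstruction are pruned; the surviving rank is the selected `K`. The
best of `n_restarts` (default 10) random restarts is kept, and after
pruning the factors are refit without the priors at fixed rank
(`refit_iter`), removing the shrinkage the priors impose — without the
refit, recovered exposure fractions are biased by ≈ 0.05 on the recovery
benchmark. Two caveats are inherent to NMF rather than to this
implementation: the factorization is identifiable only when exposures
include near-pure samples (separability), and profiles sharing a large
common floor can trade mass without affecting fit; the recovery tests
therefore use exposure distributions with signature-dominated samples, as
real cohorts have. Exposure fractions per sample are `H` rows normalized
to 1; group comparisons of fractions use the Wilcoxon rank-sum or
Kruskal–Wallis tests with the same degenerate-tie convention as above.

## The synthetic cohort

The generator plants, per subtype: arm-level gains/losses (probabilities
0.3–0.9 on distinct arm fingerprints, including losses of the CIN-excluded
arms 18q/21q in the adenocarcinoma-like subtype so the exclusion rule is
exercised); hypermethylated-and-silenced marker genes (4 per subtype at 80%
in-subtype vs 2% out-of-subtype rates) plus one differentially silenced
gene (40% vs 5%) and a 5% background silencing rate; pathway-coherent
expression shifts (one 30-gene pathway per subtype, +1.0 on the log10
scale); and multi-caller variant sets (3 callers, 100 true variants per
sample, tumour depth 100×, normal depth 140×, normal error rate 1e-3,
allele fractions Beta(2, 5), 5% caller dropout, 5% low-support false
positives plus 2% germline-site false positives per caller) whose
trinucleotide contexts are drawn from per-sample mixtures of three
caricature signatures (ageing-like C>T-at-CpG, APOBEC-like TpCpW,
smoking-like C>A). Altered arms sit at log2 ± 0.3 (segment noise sd 0.05)
covering at least 90% of the arm, deliberately far from the 80% / 0.15
decision boundaries; boundary behaviour is tested with deterministic
fixtures instead of random draws. Normal depth is 140× so that a single
sequencing-error read (the common case) stays below the 1% normal-VAF
rule instead of tripping it whenever the depth draw dips under 100.

One master seed drives labelled substreams per platform
(`derive_seed(seed, label)`), so regenerating one platform never perturbs
another and all outputs are byte-reproducible.

What passing these tests shows — and what it does not: the synthetic cohort
has clean subtype structure, independent noise, no batch effects, no tumour
purity or subclonality, no linkage between platforms beyond the planted
couplings, and caricature signatures far more separable than real
mutational processes. Recovery there demonstrates that the algorithms are
implemented correctly and calibrated under their stated models; it does not
demonstrate that the defaults are optimal for real array or sequencing
data.

## Problem sizes and reproducibility

The test suite and the acceptance script run the stages at desk scale:
120-sample cohorts for copy-number recovery, 50 samples × 100 variants for
the ensemble, 1,000 null pathways × 1,000 permutations (and 10,000
permutations for the planted-pathway power check), 20 integration
replicates of 90 samples, and 50-sample × ~500-mutation signature
catalogs. These sizes keep the whole suite in the low minutes while leaving
the Monte-Carlo error bands comfortably inside the asserted margins. Every
random quantity is reproducible from a single seed.
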
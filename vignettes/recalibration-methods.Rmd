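---
title: "Recalibrating differential expression by population dosage variance: models and methods"
author: "vgRecal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recalibrating differential expression by population dosage variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgRecal)
```

## The problem and the statistic

Differential-expression (DE) testing ranks genes by statistical evidence
and, in practice, by the magnitude of their log fold change. Both
implicitly assume that all genes tolerate dosage changes equally. They do
not: a 30% change in a tightly dosage-constrained transcription factor
can be biologically drastic while a four-fold change in an inducible
effector is within the range the population explores naturally. Ranking
by nominal fold change therefore favours highly variable *responder*
genes over constrained *driver* genes.

`vgRecal` rescales each gene's log fold change by the standard deviation
of its **genetic dosage variance** `V^G`: the variance in log-scale
expression attributable to common cis-regulatory variation in the human
population, in squared log-fold-change units. Because `V^G` shares the
unit system of DE fold changes, the recalibrated fold change

$$ \mathrm{FC}^*_i \;=\; \frac{\mathrm{FC}_i}{\sqrt{V^G_i}} $$

measures an observed change in *population standard deviations of that
gene's natural dosage variation*. A gene with `V^G = 0.02` is twice as
variable as one with `V^G = 0.01`, which is what makes this division
meaningful across genes. Recalibration happens *after* significance
testing: it reorders the significant genes, it never re-tests them.

Two formulations of this rescaling circulate (division by the variance
versus by its square root). This package divides by the standard
deviation `sqrt(V^G)`: that is the only version in which the statistic
is an effect size in standard-deviation units, it is the version that is
equivariant in the natural way (multiplying every `V^G` by `c^2` divides
every `FC*` by `c` and leaves the ranking unchanged), and it matches the
verbal definition of standardization.

### Units and log bases

`V^G` estimates derived from allelic fold changes and DESeq2's
`log2FoldChange` both live on the log2 scale, so the package treats log2
as its internal base for both quantities and performs no conversion by
default. `convertLogBase()` exists for externally supplied tables on
another scale (a variance of log-e effects is `1/ln(2)^2 ≈ 2.08` times
smaller than the same variance in log2 units). This default is a design
decision, not a property of the data: nothing in the statistic itself
pins the base, only the requirement that fold change and variance share
one.

## The V^G algebra

**Tissue aggregation.** `V^G` is estimated per tissue; the cross-tissue
summary is the *weighted harmonic mean* over tissues, weighted by mean
expression (TPM):

$$ \bar V^G = \frac{\sum_t w_t}{\sum_t w_t / V^G_t}. $$

Only tissues contributing both an estimate and a strictly positive
weight enter the aggregate (weights renormalize implicitly over that
subset), so per-tissue availability differences are handled without
imputation. The harmonic mean is dominated by the *least* variable
well-expressed tissues, a conservative choice for a quantity that later
sits in a denominator. The result always lies between the smallest and
largest contributing estimate and is invariant under uniform rescaling
of the weights.

**Merging.** Allelic-expression-derived estimates (`AE`) are the primary
track; machine-learned estimates (`ML`) fill the gaps, producing the
`AEML` track via `mergeVG()` with strict AE precedence. Missingness is
explicit everywhere: a `V^G` of zero is rejected as invalid rather than
clamped, because a zero would silently turn the recalibration into a
division by zero.

**Gene identity.** Tables are joined on Ensembl gene ids with version
suffixes stripped, so tables from different annotation releases join.

## Recalibrating a DE table

`recalibrateTable()` joins a DESeq2-style result table with one `V^G`
track, computes `fc_star`, and assigns 1-based ranks by descending
absolute value under both orderings. Genes without a usable estimate are
**dropped** by default — the published behaviour, and the only option
under which `fc_star` is defined for every retained row — or kept,
flagged, and left unranked under `missingPolicy = "keep"` for
exploratory use. When a significance threshold is supplied, only genes
with adjusted p strictly below it are ranked; the filter is strict
inequality by convention. Rank ties (equal `|fc_star|`) are broken
lexicographically by gene id so output files are reproducible.

Agreement between the orderings is summarised by the Pearson correlation
of *absolute* fold changes (`absPearson()`): direction never changes
under recalibration, so correlating signed values would inflate the
estimate. Spearman correlations elsewhere in the package carry bootstrap
percentile confidence intervals (`spearmanWithBootstrapCI()`, default
1,000 paired resamples under a caller-supplied seed; the resample count
and percentile method are package defaults, chosen as the plainest
consistent bootstrap).

## Gene-set statistics

Distribution comparisons between curated sets (e.g. haploinsufficient
versus nonessential genes) use a two-sided Mann-Whitney U test,
implemented natively: when both samples have at most 8 observations the
exact two-sided p is computed by enumerating the rank-sum distribution
(a generating-function dynamic program over the pooled, possibly tied,
midranks — equivalent to full enumeration but polynomial); larger
samples use the normal approximation with tie and continuity
correction. The native implementation exists because an exact test *in
the presence of ties* is not available from the standard library
routine; the cutoff of 8 trades exactness against enumeration cost. The
approximation is accurate to about `1e-3` from sample sizes of roughly
fifty upwards, and the exact path is verified against brute-force
enumeration in the test suite.

Tissue-of-lowest-`V^G` analysis assigns each gene the tissue where its
estimate is smallest (ties broken lexicographically; genes with no
tissue estimate are unassigned) and tests whether an interest set is
assigned into a tissue group more often than background genes, with a
one-sided binomial tail. The binomial null fraction `p0` is computed
over *assigned* background genes; computing it over all genes (counting
unassigned ones in the denominator) is the natural alternative, but it
would conflate estimate coverage with tissue preference, so the
assigned-genes fraction is used.

## Enrichment comparison

Over-representation analysis is the upper hypergeometric tail of the
query/term overlap against a background universe — all genes with
measured expression *and* a `V^G` estimate, which keeps both selections
comparable. Benjamini-Hochberg adjustment is applied within each
annotation namespace (test BP, CC and MF in separate calls). BH is used
where the upstream web service applies its own multiple-testing scheme;
the comparison logic is correction-agnostic, only the `adjusted p`
threshold semantics matter.

The before/after machinery selects the top-N genes under each ordering
(`N = "auto"` takes half the significant genes, rounded to the nearest
100 half-up — the half-way rule is a package decision), runs ORA twice
against the same background, and keeps the union of terms significant on
at least one side. A side where a term was *not* enriched is imputed
with an adjusted p of exactly 1, mirroring tools that report only
significant terms; consequently every term of an `EnrichmentComparison`
has both columns populated. Name-pattern association labels and the
geometric mean `10^{mean(log10 p)}` per label summarise term groups.

## Extending V^G by supervised learning

Genes lacking allelic-expression estimates are covered by a
gradient-boosted regression of `ln V^G` on 14 gene-level metrics
(eQTL-derived `V^G`, loss-of-function constraint, expression level,
enhancer counts, tissue specificity, ...). The natural-log transform
makes the heavy-tailed variance approximately Gaussian; predictions are
exponentiated back, so they are strictly positive by construction.

The shipped hyperparameters are the cross-validation-selected record:
depth 6, learning rate 0.0236, subsample 0.96, column subsample 0.746
per tree / 0.494 per level, 344 rounds, minimum split loss 2, L2 1.27,
L1 4.5. Hyperparameter *search* is deliberately out of scope; the final
record is the default. Training is single-threaded with a fixed seed,
making models bit-reproducible.

Before training, missing features are filled by a K-nearest-neighbour
imputer: genes with more than 5 missing features are dropped outright,
the rest have each missing cell replaced by the mean of the `k = 5`
nearest genes under Euclidean distance over the features observed in
both, computed on per-column standardized values and normalized by the
number of shared features. `k = 5` is the conventional imputer default;
standardization applies to the *distance only* — the trees see raw
feature values, since tree splits are scale-free and rescaling would
only obscure the stored model. Observed cells are never altered.

Labeled genes are split 80/20 into train and hold-out (deterministic
under a seed); evaluation reports the ln-scale RMSE and the Spearman
correlation on the hold-out set. Tissue-specific models reuse the same
hyperparameters with the tissue's TPM and eQTL-`V^G` as additional
features; tissues below a configurable minimum of labeled genes
(default 50) are skipped with a warning, and per-tissue predictions are
merged with observed estimates under AE precedence.

## What the synthetic generator emulates — and what it does not

`simulationConfig()` defines the reference study; its defaults are fixed
study conditions, not tuning knobs:

* gene-level `ln V^G ~ N(log 0.02, sqrt 0.2)` — a lognormal landscape
  centred on the magnitude typical of real estimates, with the
  dispersion observed for AE-derived values; lognormal is the simplest
  positive heavy-tailed law consistent with modelling `ln V^G`;
* five tissues with lognormal scatter (SD 0.3) around the gene level,
  TPM weights drawn lognormal, 10% of cells missing and 10% of genes
  without any estimate — exercising aggregation, missingness policies
  and coverage accounting;
* a DE experiment whose background fold-change magnitude couples to
  `V^G` with Spearman ~0.148 via a Gaussian copula — the weak positive
  coupling seen in stimulus-response data, the very bias recalibration
  addresses;
* a planted block of 200 *responders* from the top `V^G` quartile with
  `|log2 FC| ~ N(2, 0.15)` (about four-fold, as for strongly induced
  response genes) and 200 *drivers* from the bottom quartile whose
  effects are specified on the recalibrated scale (`fc* ~ N(15, 0.8)`),
  making their nominal fold changes modest (~1.6) while their `fc*`
  exceeds the responders' — so nominal selection favours responders and
  recalibrated selection favours drivers, the phenomenon the enrichment
  comparison must detect;
* a 14-column feature matrix whose labels are a fixed monotone function
  of three features plus 20% noise, with a per-cell missing rate
  (0.155) at which about 2% of genes exceed the 5-missing drop rule.

The generator mimics the *outputs* of DE testing (fold changes and
p-values are drawn directly), not its inputs: count-level simulation,
dispersion, library-size effects and shrinkage are upstream concerns and
out of scope. Passing tests therefore demonstrate that the statistics,
selection rules and comparisons behave as specified on data with known
structure — they do not validate any upstream DE pipeline, nor the
biological accuracy of real `V^G` estimates. Tests and the acceptance
script run at reduced scale (5,000-gene studies, 4,000-gene feature
matrices); these sizes give comfortable statistical margins for every
planted effect while keeping a full run inside a coffee break.

## Numerical choices and degenerate inputs

* Division by `sqrt(V^G)` requires strict positivity; zero or negative
  variances are validation errors everywhere, never clamped.
* Harmonic-mean aggregation with no usable tissue yields an explicit
  missing value, not zero and not an error.
* A recalibration in which *no* gene is retained raises an error rather
  than returning an empty table silently.
* Constant vectors make correlations undefined; these return `NA` with
  a warning rather than fabricating a value.
* Rank ties break lexicographically by gene id; argmin tissue ties
  break lexicographically by tissue name.
* An ensemble with no splits (constant label) reports uniform feature
  importances, the honest representation of "no information".
* Bootstrap and train/test RNG use locally seeded streams that restore
  the caller's RNG state.

## Known limitations

* `V^G` estimation itself (from allelic-expression or eQTL data) is out
  of scope; estimates are inputs, and their quality bounds everything
  downstream.
* The exact Mann-Whitney path is limited to small samples; mid-sized
  comparisons rely on an approximation accurate to ~`1e-3`.
* Gradient-boosting reproducibility is guaranteed for a fixed backend
  version, single thread and fixed seed; numerical equality across
  backend versions is not promised.
* The ORA is over-representation only; depletion, rank-based GSEA, GO
  graph propagation and term clustering are out of scope.
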
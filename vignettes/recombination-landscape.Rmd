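---
title: "Mapping and modelling the recombination landscape of an allopolyploid genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and modelling the recombination landscape of an allopolyploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recland)
```

## The problem

Meiotic crossovers (COs) are distributed very unevenly along plant
chromosomes: they are suppressed around centromeres and in methylated,
transposon-rich heterochromatin, and concentrated in gene-dense,
transcriptionally active euchromatin.  In the allopolyploid oilseed rape
genome (*Brassica napus*, AACC), the two parental subgenomes carry
visibly different landscapes — the A subgenome concentrates COs in
subtelomeric regions while the C subgenome is less recombinogenic
overall, with activity spread further into the chromosome arms.

`recland` implements the full analysis chain for studies of this kind:

1. **Recombination maps** from CO intervals detected in large
   multiparental populations genotyped on a moderate-density SNP array:
   quality filtering, proportional assignment of marker-resolution CO
   intervals to fixed 0.3-Mbp bins, the cM/Mbp rate formula, SNP-count
   normalization, and hotspot definition.
2. **Per-bin multi-omic features**: annotation coverages with
   cross-type trimming, single-base and coverage-weighted DNA
   methylation by context, TE-body CHH methylation, GC content and
   dinucleotide coverage, a log-compressed chromatin-accessibility
   score, log-transformed expression, telomere distance, subgenome
   identity, and SNP counts.
3. **Predictive modelling** of hotspot membership (classification) and
   SNP-normalized recombination rate (regression) with four learners
   under a homoeolog-grouped cross-validation protocol.
4. **Model selection under multicollinearity** via a robustness
   protocol, and **interpretation** with accumulated local effects
   (ALE) and Friedman H-statistics, both implemented from first
   principles.
5. A **synthetic-data generator** that emulates the statistical
   structure of such a study, with planted ground truth so the whole
   pipeline can be validated end to end.

## Recombination maps

CO intervals are filtered in two steps, in this order: individuals
whose total CO count across all meioses and chromosomes *exceeds* 100
are removed entirely (they behave like genotyping artifacts; each
removal also subtracts that individual's two informative meioses from
its population), then intervals longer than 2 Mbp are discarded as
marker-sparse placements.  Each surviving interval distributes one unit
of CO mass across the 0.3-Mbp bins it overlaps, proportional to
overlap, so total CO mass is conserved exactly.  The per-bin rate is

$$\mathrm{rate}_i \;=\; 100 \times
\frac{\mathrm{CO\text{-}equivalents}_i / \mathrm{informative\ meioses}}
     {\mathrm{bin\ length\ (Mbp)}_i ,}$$

using each bin's true length (terminal bins are truncated at chromosome
ends).  When several populations contribute, fractional counts and
meiosis counts are summed before division.

Because array markers are ascertained in polymorphic, gene-rich
regions, bins without markers show zero COs as an artifact; they are
flagged `snp_empty` and excluded from percentile computations and from
all modelling tables.  The regression target is the rate divided by the
bin's marker count.

**Hotspots** are bins above the genome-wide 95th percentile of the
(un-normalized) rate, computed over non-SNP-empty bins with the
standard linear-interpolation quantile; a bin exactly at the threshold
is not a hotspot, which makes "top 5%" deterministic.  For every
chromosome, the same number of non-hotspot bins is drawn uniformly
without replacement from that chromosome's bins below the genome-wide
75th percentile, giving balanced classes that preserve chromosomal
composition.  Because this balance makes subgenome and label exactly
independent inside the sample, the subgenome chi-square in
`hotspot_tests()` is computed on genome-wide hotspot counts when a map
is supplied.

## Feature computation choices

* **Coverage** merges within-type overlaps before counting (union
  semantics) and can trim against higher-priority annotation types;
  gene annotations take priority over TEs by default.
* **Methylation** follows the single-base cascade: per-cytosine rate
  per replicate, cytosines not called in every replicate of a tissue
  excluded from that tissue, mean across replicates, then across
  tissues, then an unweighted mean over a bin's cytosines.  The
  coverage-weighted variant (total methylated / total calls per bin) is
  provided for comparison; the two agree exactly under uniform
  coverage.
* **Accessibility** uses
  $\log_{10}(\mathrm{accessible\ length} + 1) / \log_{10}(\mathrm{bin\ length})$,
  capped at 1 and averaged over tissues — open chromatin is strongly
  tissue-specific and raw coverage would be dominated by single-tissue
  peaks.
* **Expression** is the mean over a bin's genes of
  $\log_{10}(\mathrm{TPM} + 0.1)$ (tissue means first); genes are
  assigned to the bin containing their midpoint, and gene-less bins sit
  at the transform floor $-1$, which is the natural "no expression"
  value rather than an imputation.
* **Telomere distance** is 0 at the telomere and 1 at the centromere of
  the arm containing the bin midpoint (the orientation used on the
  package's axes); `orientation = "centromere"` yields the reflected
  ratio for parity with the distance-from-centromere formulation.
* Bins where a feature is undefined (no retained cytosine, no
  TE-resident CHH site) are imputed with the column median at table
  assembly, with per-column counts kept in the imputation log; median
  imputation preserves rank structure and the affected bins are few.

**Smoothing.** Immediately before modelling, simple exponential
smoothing $s_1 = x_1,\; s_t = \alpha x_t + (1-\alpha)s_{t-1}$ with
$\alpha = 0.1$ is applied per chromosome, along the full contiguous bin
grid, to every smoothable feature and to the regression target, to
damp bin-boundary noise.  Telomere distance and the subgenome flag are
deterministic in position and are never smoothed, and the binary
classification target is left untouched.  The initial level is pinned
at the first observation rather than optimized, so smoothing is a pure,
reproducible linear filter.

## Modelling protocol

Cross-validation folds are **homoeolog groups**: A*k* with C*k* for
k = 1..8, and {A09, A10, C09} as the ninth group (A10 has no C
homoeolog and is syntenic with that pair).  Holding out whole groups
prevents leakage of shared ancestral sequence between training and
validation.  Single-subgenome models replace groups by chromosomes (10
A folds, 9 C folds).  Rows are shuffled within chromosomes under the
stage seed; membership is deterministic.

Per fold, preprocessing is fitted on the training rows only:
dummy-encoding of categoricals, removal of zero-variance columns, and
z-scoring by training mean/SD.  SNP count never enters the predictor
set (rates are already normalized by it, and marker density would leak
the ascertainment signal).

The four learners are a decision tree (`rpart`), elastic-net-penalized
logistic/linear regression (`glmnet`), a random forest (`ranger`, with
impurity importance: Gini for classification, response-variance
reduction for regression) and gradient-boosted trees (`xgboost`, total
gain importance).  Hyperparameters are searched with a seeded
Latin-hypercube draw over the documented ranges (the budget, default
25 configurations, trades fidelity for runtime; budget 1 evaluates the
package defaults); the selection metric is mean fold AUROC or mean
fold R².  Both the mean fold metric and the pooled out-of-fold metric
are reported — they legitimately differ, and neither is derived from
the other.  AUROC is computed by average-rank pair counting (ties count
one half).

## Robustness under multicollinearity and model selection

Chromatin-state features are mutually correlated by nature, so
importance rankings can be unstable.  The protocol clusters features as
connected components of the $|r| > 0.8$ correlation graph (transitive:
chains join), picks one representative per cluster (user-fixable;
default: highest mean within-cluster $|r|$), refits each model on the
full and on the reduced feature set, and reports (i) the Spearman
correlation of the two rankings over the reduced set's features and
(ii) the mean within-cluster SD of importance scores divided by the SD
across all features.  Model selection is lexicographic: Spearman, then
CV metric, then SD ratio.  Importance defaults to a full-data refit;
per-fold averaging is available (`refit = "cv"`).

## ALE and H-statistics

Both interpretation tools are implemented directly against the
package's uniform predict contract.

*ALE*: interval edges at empirical quantiles (K = 20 by default,
duplicates merged); per interval, the mean prediction difference
between upper- and lower-edge substitution over that interval's
observations; cumulative sum; centred so the count-weighted mean of the
interval mid-curve is zero.  Two-level features use the categorical
variant (one interval; the effect is the mean difference of the two
substituted predictions).

*H-statistics*: centred partial-dependence functions estimated by
Monte-Carlo over a seeded subsample (default 500 rows; all $n^2$
substitution pairs).  Pairwise
$H^2_{jk} = \sum [PD_{jk} - PD_j - PD_k]^2 / \sum PD_{jk}^2$; overall
$H^2_j = \sum [f - PD_j - PD_{-j}]^2 / \sum f^2$.  Negative numerical
values are clipped to zero before the square root.

## The synthetic generator

The generator emulates the statistical structure that the analysis
assumes, not sequence-level biology.  Defaults are fixed at the study
conditions: a 19-chromosome layout (10 A + 9 C, ~719 Mbp) with
single-point centromeres; two populations of 1243 and 1323 individuals
contributing two informative meioses each; Poisson CO counts with mean
1.2 per chromosome per meiosis (no interference model — the analysis
never uses interference); ~3.5 markers per 0.3-Mbp bin, denser in
gene-rich bins, and CO intervals reported between flanking markers so
resolution matches an array design; 2% of individuals carry 4-fold
inflated CO counts, emulating genotyping artifacts that the >100-CO
filter must catch.

Feature tracks derive from a latent chromatin-state field: a sigmoid of
telomere distance (euchromatic arms, heterochromatic interior) whose
midpoint sits at 0.55 in A but 0.25 in C — heterochromatin reaches much
further into C arms, which produces the bimodal pooled feature
distributions and the contrasting arm profiles.  Methylation and TE
tracks rise with the state, gene/expression/accessibility fall, the C
subgenome receives additive offsets (more methylation and TEs, fewer
genes and transcripts), TE-body CHH tracks gene content positively,
and GC/AT ride a separate latent nucleotide field so they form their
own correlated cluster without being informative about recombination.
Noise fields are moving-average-smoothed per chromosome (bandwidth 4
bins, rescaled to unit SD) so tracks are spatially autocorrelated —
which is what makes exponential smoothing meaningful.  Track noise
scales were chosen so that pairwise correlations inside the
chromatin cluster fall in the 0.85–0.95 range reported for real bins,
with the three causal tracks (CpG, TE, gene) the cleanest indicators of
the latent state, as their real counterparts are.

CO intensity per bin is
$\lambda(b) \propto \exp\{\beta \cdot x(b) + s_{\mathrm{subgenome}}(d)\}$
with planted $\beta$ = (CpG $-3.0$, TE $-1.8$, gene $+2.2$),
antisymmetric positional shapes — $s_A$ has a Gaussian peak at telomere
distance 0.25 and an equal trough at 0.75, $s_C$ the mirror image — so
the subgenome-by-position interaction is the dominant planted
non-additivity, and a hard zero inside 2.5 Mbp of each centromere.
Crossover counts are Poisson per chromosome and meiosis; C-subgenome
chromosomes draw from a reduced expectation (log offset $-0.5$), the
intrinsic recombination deficit of the C subgenome that remains after
features and position are accounted for.  The generator records the
truth — intensities, artifact individuals, planted effects — so tests
can check recovery, not just execution.

What the generator does **not** emulate: linkage between neighbouring
meioses, CO interference, structural variation, homoeologous exchange,
read-level noise, or any sequence composition signal.  Passing
recovery tests therefore shows the pipeline identifies planted
statistical structure at realistic noise levels; it does not certify
biological conclusions on real data.

## Numerical choices and degenerate inputs

* Quantiles use the standard linear-interpolation definition (type 7);
  hotspot ties break strictly (">" at the 95th percentile).
* Zero-variance features: t-test reports statistic 0 / p 1 with a flag;
  preprocessing drops them per training fold.
* Perfect separation in the hotspot GLM is detected and reported, never
  silently returned.
* Empty ALE intervals (possible after merging duplicate quantile
  edges) contribute zero local effect and zero weight.
* All randomness flows from one master seed through
  `stage_seed(master, stage)`, a pure function; no global-state RNG is
  consulted, and fixed seeds make every stochastic stage reproducible
  bit for bit.

## Problem sizes used by the test-suite

The packaged tests validate the pipeline at the default study scale
(2,566 individuals, ~2,400 bins) for single fits, and at reduced scale
(a few hundred individuals) where many replicate fits are needed;
hyperparameter budgets in tests are small because the tested properties
— fold hygiene, metric identities, planted-signal recovery — do not
depend on exhaustive tuning.  The acceptance script runs the full
default-size pipeline once with a caller-supplied seed.

## Known limitations

* The rate combination across populations (summed counts over summed
  meioses) is one of several defensible conventions; per-population
  maps are available from the map stage for correlation checks.
* Impurity-based importance is the protocol's metric by design; it
  inherits that metric's biases (it is exactly what the robustness
  protocol quantifies), and no permutation or SHAP alternative is
  offered.
* The hyperparameter search is a seeded space-filling design, not a
  sequential surrogate-model optimizer; with the budgets used here the
  difference is immaterial, and the interface (budget, seed) would not
  change.
* SES with a pinned initial level differs from implementations that
  optimize the level; for $\alpha = 0.1$ on thousands of bins the
  difference is confined to the first few bins of each chromosome.
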
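---
title: "Methods: clinical rule mining, efficacy walks and network pharmacology in xfcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinical rule mining, efficacy walks and network pharmacology in xfcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xfcnet)
```

`xfcnet` evaluates a herbal formula (Xinfeng capsule, XFC) in
rheumatoid arthritis along two axes: a clinical axis (does treatment
exposure associate with laboratory-marker improvement, and do outcomes
show serial structure across the patient sequence?) and a molecular
axis (are the formula's compound targets over-represented among
disease-perturbed genes, and which of them are topologically central
and diagnostically informative?). This vignette is the package's
account of the statistical machinery, the tunable parameters, and the
design decisions taken where the underlying methodology is genuinely
open.

## Improvement transactions and association rules

Each patient contributes one binary transaction: the exposure item
`XFC` if treated, and `<marker>_improved` for each marker whose
post-treatment value moved strictly in the beneficial direction. For
the eight markers tracked here, elevation is pathological
("high-is-bad"), so improvement means `post < pre * (1 - tolerance)`.
The `tolerance` parameter (relative, default 0) defines a dead-band for
analysts who want to ignore sub-noise changes; the default is a strict
decrease because the coding rule should not build in an arbitrary noise
model. Ties are never improvements. A patient with a missing pre/post
pair contributes no item for that marker but stays in the record count
N — N is the denominator of support, and dropping records would
silently inflate every rule.

Mining is a from-scratch level-wise Apriori: level-k candidates join
frequent (k−1)-itemsets sharing their first k−2 items, are pruned by
downward closure, and counted against the table. At the scale of a
hospital cohort (~10³ records, ~10 items) this is exact and fast;
approximate or tree-based miners would buy nothing. Rule metrics are
stored as fractions in [0, 1] so the identities
`lift * support(Y) = confidence` and `support <= confidence <= 1` hold
exactly; rendering to the percent columns of a clinical report
multiplies by 100 at write time only.

The default rule search pairs the single-item antecedent `{XFC}` with
every single-item consequent — the clinical question — with
`expand = TRUE` available for a full frequent-itemset search. Default
thresholds are permissive (`minSupport = 0.01`, `minConfidence = 0`):
rule *selection* is the analyst's judgement; the miner should not
pre-filter it. A rule is labelled **strong** when confidence > 60% and
lift > 1. The moderate band (lift > 1 but confidence ≤ 60%) is this
package's own explicit criterion: lift > 1 is the minimal evidence of
positive association, and we chose to keep it visible rather than
undefined. Lift ≤ 1 is always **weak**, whatever the confidence,
because a confident rule for an outcome that is just as common without
the antecedent carries no associational evidence.

## The efficacy random walk

Outcomes are accumulated in record order: +1 if the record carries the
outcome item, −1 otherwise, giving a walk y(l) with y(0) = 0. The
fluctuation function is

F²(l) = mean(Δy_l²) − mean(Δy_l)²,  Δy_l = y(l₀ + l) − y(l₀),

with the mean over **all overlapping start points** l₀ ∈ {0, …, n−l}.
Overlapping windows maximize averaging; nothing in the model requires
disjoint windows. Lags are capped at n/2 because longer windows average
too few displacements for a stable variance.

The scaling exponent α is defined on F(l) = sqrt(F²(l)), fitted as the
least-squares slope of ½·log F²(l) against log l. This convention
matters: independent ±1 outcomes give Var(Δy_l) = l, i.e. F²(l) ∝ l¹
but F(l) ∝ l^½, so defining α on F makes the memoryless null α = ½ —
the familiar diffusive exponent. The default fit grid is ≤12
log-spaced lags from 4 to n/4: below l = 4 the ±1 discreteness
dominates, above n/4 the variance estimate is noisy and biased
downward because overlapping displacements are strongly correlated.
That bias is visible as mean fitted exponents slightly below ½ (about
0.46–0.47 at n = 5,000) for perfectly memoryless walks; it cancels in
the significance test below because the null distribution carries the
same bias.

**Null test.** The null hypothesis is memoryless outcomes. We refit α
on permutations of the increments: shuffling preserves the step
marginal exactly while destroying serial structure, so the shuffled
exponents are the null distribution for *this* walk's marginal, and
the observed α̂ is flagged when outside the empirical
(level/2, 1−level/2) quantiles. We deliberately do not use the
regression standard error of the slope: F² values at nearby lags are
computed from almost the same displacements, so the regression's
independence assumption fails badly and its confidence interval is
anti-conservative. With 99–199 shuffles at level 0.05 the test is
calibrated (empirical type-I ≈ 5–7%) and has essentially full power
against strongly persistent walks.

**A saturation caveat.** For super-diffusive fixtures whose increments
are themselves a cumulative ±1 sum, the ensemble variance of l-step
displacements from a fixed origin grows like l³ (exponent 1.5 on F).
The single-series estimator used here does not reach that value: with
nonstationary increments, the variance across overlapping start points
is dominated by the l²·Var(local level) term, and the fitted exponent
saturates near 1 — the classic limitation of plain (non-detrended)
fluctuation analysis for signals rougher than a simple random walk.
Detrending variants (DFA-1/2) would recover the larger exponent but
are out of scope: the model implemented is the plain fluctuation
function. Detection of persistence is unaffected — α̂ ≈ 1 sits far
outside the permutation null centred at ½ — but the *magnitude* of α̂
above 1 should not be interpreted quantitatively, and the test suite
asserts detection (and the α ≈ 1 saturation value) rather than the
unreachable ensemble exponent.

Record order stands in for admission order; an explicit ordering
vector can be supplied when a real admission sequence is available.

## The synthetic cohort

The generator is the package's replacement for a non-shareable
hospital cohort; its defaults encode the published cohort's marginal
structure.

* **Pre-treatment values** are log-normal per marker, with
  μ = log(median) and σ = log(q3/q1) / (2·Φ⁻¹(0.75)) solved from the
  published median and quartiles. Laboratory markers are positive and
  right-skewed, and the published summaries are median (Q1, Q3) — a
  log-normal reproduces the median exactly and both quartiles exactly
  when the printed quartiles are log-symmetric (FBG: model quartiles
  4.28/5.38 against printed 4.27/5.37). For strongly asymmetric
  markers (Hs-CRP: 36 with quartiles 16/66) one σ cannot match both
  endpoints and the fit splits the difference; the median is always
  exact in distribution.
* **Treatment effect** is a per-marker conditional improvement
  probability given treated/untreated (`effectMap`). The defaults are
  the package's emulation choice: Hs-CRP 0.80 vs 0.50 (the strongly
  responsive acute-phase marker, and the planted-effect demo), ESR
  0.72, RF 0.65, weak effects (0.52–0.58) for FBG/PLT/IgA/IgG, and a
  null effect for IgM, whose pre/post shift in the source cohort was
  non-significant. An improving "high-is-bad" marker shrinks
  multiplicatively toward the midpoint of its reference range (uniform
  25–75% of the gap); a non-improving one drifts up by 0–6%.
* **Measurement noise** is multiplicative log-normal with coefficient
  of variation `noiseCV` (default 0.05, a typical clinical-assay CV).
  At `noiseCV = 0` the fraction of treated patients with
  `post < pre` equals `p_treated` exactly in expectation. With noise
  on, a share of non-improvers dips below baseline by chance, so
  *observed* improvement rates exceed the latent probabilities — the
  familiar inflation of apparent response by measurement error, which
  the strict-decrease coding makes visible rather than hiding.
* **Exposure**: `treatedFraction` defaults to 0.17, the exposure share
  implied by the source cohort's constant antecedent-support column.
* **Seeding**: one master seed with named per-stage substreams
  (`deriveSeed`), so adding or toggling one generator never perturbs
  another's stream; all generators are bit-identical under a fixed
  seed.

What the generator does **not** emulate: longitudinal multi-admission
trajectories, medication co-exposures, missingness mechanisms,
between-marker correlation of improvements, or any real biological
covariance between the expression matrix and the cohort. Passing tests
therefore demonstrate the correctness and operating characteristics of
the *methods* under known truth — not clinical conclusions about real
data.

## Expression screen, intersection, network, enrichment

**Differential expression** is a per-gene Welch (unequal-variance)
t-test on log2 values with log2FC = mean(case) − mean(control).
Moderated-variance machinery is deliberately not reproduced: the
screening rule of interest filters on raw p < 0.05 and |log2FC| > 2,
for which a plain two-sample test is transparent and dependency-free;
with ≥10 samples per group the moderation would change little. No
multiple-testing correction is applied by default because the selection
rule is defined on raw p; `p.adjust` can be applied to the returned
table. Degenerate genes are explicit: zero pooled variance with equal
means gives p = 1, with unequal means p = 0 plus a `degenerate` flag.
Values on an apparently linear scale (max > 50) are log2(x+1)
transformed with a message, overridable. Duplicate symbols collapse to
the highest-mean row — the common probe-collapse rule.

**Target intersection** is case-insensitive and whitespace-trimmed;
target lists are unioned and deduplicated before intersecting with the
DEG set, and per-list Venn counts are reported.

**Centralities.** Degree, closeness and betweenness back the hub-gene
selection (intersection of the three top-k lists, k = 10 by default,
ties broken score-descending then symbol-ascending so selection is
deterministic). Closeness is *harmonic* (sum of reciprocal shortest
path distances): interaction subnetworks are routinely disconnected,
and harmonic closeness handles unreachable pairs gracefully (an
isolated node contributes 0, not undefined). Betweenness is left
unnormalized — only ranks feed the top-k selection, and ranks are
invariant to normalization. Core genes are ranked by maximal-clique
centrality, score(v) = Σ over maximal cliques S containing v of
(|S|−1)!, computed by full maximal-clique enumeration with a
configurable budget (default 10⁶ cliques) so pathological graphs abort
with guidance instead of hanging; an isolated node scores 1 via its
singleton maximal clique.

**ROC screening** uses the rank-statistic AUC (concordant pairs plus
half ties over all case–control pairs; identically Mann–Whitney
U / n₁n₂). Orientation is fixed — case-high counts as positive — so an
AUC below 0.5 is reported as such rather than silently flipped;
candidates pass AUC > 0.7.

**Over-representation** is the exact upper-tail hypergeometric
P(X ≥ k) for the overlap of the query with each set, against a
background universe that defaults to the measured genes (the
conservative convention when the true assay background is unknown —
using the whole genome would overstate enrichment). Query genes
outside the universe are dropped with a logged count; zero-overlap
sets are hidden by default. BH q-values are computed across the
emitted batch; the significance flag follows either raw p < α
(mirroring the source workflow's selection rule) or q < α. The
EASE-style (k−1) modification of the tail is not implemented; the
plain tail is the exactly-defined default.

## Pipeline, determinism and problem sizes

`runPipeline()` executes mining → walk → differential expression →
intersection → network → enrichment under one validated configuration
(`validateConfig()` fills defaults, range-checks every field, and
rejects unknown keys with a nearest-key suggestion, collecting all
violations in one error). The report is identical under identical seed
and configuration, timings aside.

The test suite and the acceptance script exercise the methods at sizes
chosen to make Monte-Carlo bands tight while keeping a full run on one
CPU within a few minutes: cohorts of 1,283 patients (the published
cohort size) with 20 replicate seeds; walks of n = 5,000 (100 seeds)
for exponent means and n = 1,000 (200/100 seeds) for test operating
characteristics; expression matrices of 2,000 genes × 10 + 10 samples
with 50 spikes at |log2FC| = 3, σ = 1 (20 seeds); exact-oracle checks
on 50 random transaction tables (≤12 records, ≤6 items), 100 random
graphs (≤8 nodes for path enumeration, ≤10 for clique enumeration) and
a hypergeometric grid up to N = 60.

## Known limitations

* Single pre/post pair per patient; no within-patient longitudinal
  modelling.
* The fluctuation exponent saturates near 1 for signals rougher than a
  random walk (see above); only detection, not magnitude, is reliable
  there.
* The Welch screen is not a moderated test; at very small group sizes
  (< 5 per group) its variance estimates are unstable and a moderated
  alternative should be preferred.
* Improvement items are marginal per marker; rules about joint
  multi-marker improvement require `expand = TRUE` and larger cohorts
  than the defaults to estimate stably.
* The maximal-clique score is exponential-time in the worst case; the
  clique budget makes this explicit rather than fast.
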
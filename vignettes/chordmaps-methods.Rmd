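---
title: "Methods: from chord statistics to bodily sensation and emotion"
author: "chordmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chord statistics to bodily sensation and emotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`chordmaps` implements a complete analysis chain for studies that ask how the
*statistical expectancy* of a chord progression shapes bodily sensation and
emotion. The chain has three parts: an information-dynamics model of chord
transitions, a quantile-stratified stimulus design, and the behavioural /
statistical machinery that processes body-map clicks, Likert ratings and
ranked emotion selections.

### Information dynamics of chord transitions

The expectancy model is a first-order Markov model over a chord vocabulary
$S$. From a corpus of songs (each an independent symbol sequence; transitions
are never counted across song boundaries) we estimate the transitional
probability $P(e_{n+1} \mid e_n)$ as the row-normalised pair count, with
optional pseudo-count smoothing $\alpha$:
$(c_{ij}+\alpha)/(c_{i\cdot}+\alpha|S|)$. Two quantities follow, both in
bits:

* **Surprisal / information content** of an observed transition,
  $I(e_{n+1}) = -\log_2 P(e_{n+1}\mid e_n)$ — how surprising the chord that
  actually arrived is.
* **Entropy / uncertainty** of a context,
  $H = -\sum_e p(e \mid e_n) \log_2 p(e \mid e_n)$ — how unpredictable the
  upcoming chord is before it arrives. Entropy is the expectation of
  surprisal under the model, an identity the test suite checks to $10^{-9}$.

The model order is fixed at one: the conditioning event is the immediately
preceding chord only. Higher-order context effects are studied through the
*design* (the 3-chord context class) rather than through deeper models.

### Stimulus taxonomy and thresholds

Pooling the surprisal of every observed transition and the entropy of every
token that has a successor, the bottom and top 20% empirical quantiles
(linear-interpolation convention, `stats::quantile` type 7) define Low and
High bands for surprise and uncertainty separately. A 4-chord progression is
typed by a context class (all scored context positions jointly low, `sLuL`,
or jointly high, `sHuH`) and a final class (the 2x2 cell of the 4th chord),
giving the 8 types `sLuL-sLuL` ... `sHuH-sHuH`. Threshold comparisons are
closed (a value exactly at a cut point counts as low resp. high); the open
middle band refuses classification.

**Scored context positions.** A first-order model defines transitions into
positions 2..4 only. Position 1 can be scored by convention from the
zeroth-order marginal, but its uncertainty is then the *same constant* (the
marginal entropy) for every sequence — so requiring position 1 to satisfy
the context class would make the two context classes mutually unreachable
(one needs that constant below the low cut, the other above the high cut).
The classifier therefore scores context positions 2–3 by default;
`context_positions = 1:3` remains available, and the marginal convention
used for position 1 is recorded in every profile.

**Threshold pooling.** Pools are taken across all observed corpus
transitions (occurrence-weighted), not across candidate progressions; this
makes the thresholds a property of the corpus rather than of any particular
search set.

### The structured synthetic corpus

`make_structured_corpus()` plants a corpus whose fitted model provably
realises all 8 types. Its 6-symbol core has three context classes:

* `A` (one symbol): near-deterministic, $P(\text{main}) = 8/9$
  ($H \approx 0.50$ bits; rare continuation $I = \log_2 9 \approx 3.17$);
* `C` (two symbols): coin-flip contexts, two outcomes at $1/2$
  ($H = 1$, every link $I = 1$);
* `B` (three symbols): diffuse contexts, one main outcome at $1/2$ plus four
  spreads at $1/8$ ($H = 2$ exactly; spread links $I = 3$ exactly).

Songs are emitted as closed walks that partition a seeded Eulerian circuit
of a balanced integer multigraph (1570 edges per unit), so pooled pair
counts equal the designed counts *exactly* and every fitted probability is
an exact dyadic ratio. Consequently the 20% thresholds land exactly on
$s_{low}=1$, $s_{high}=3$, $u_{low}=1$, $u_{high}=2$ bits, the closed-band
comparisons are float-exact, and type reachability holds deterministically
rather than up to sampling noise. Extra vocabulary beyond the core (default
`vocab_size = 8`) is appended as a separate deterministic cycle song of
negligible pool mass. The design gives some types deliberately few distinct
realisations (e.g. a single `sLuL-sHuL` sequence), mirroring the uneven
stimulus counts per type that such quantile designs produce on real corpora.

## The behavioural layer

### Body maps

Clicks live on an 871 x 1920 px canvas (origin top-left). The cardiac
(x 360–550, y 390–620) and abdominal (x 360–510, y 650–850) masks follow
the published bounds; head bounds were never published, so the default head
mask (x 300–570, y 40–330) is a package default, clearly flagged and fully
configurable. All masks are closed intervals and may not overlap. Region
statistics always use raw coordinates; the factor-40 "downsampling" is
interpreted as spatial grid coarsening for heat maps only (22 cells across,
48 down), with an optional bilinear upsample for display that is never used
for statistics.

### Emotion scores

Ranked top-5 selections from 33 categories map to scores $6-r$ (rank 1 → 5
points ... rank 5 → 1 point, others 0; the five nonzero scores always sum to
15). Categories whose responses are zero in *strictly more than* 75% of
rows are excluded — a category zero in exactly 75% is retained. Group
averages per unique progression support three grouping rules: valence
(high > 6, low < 4, the middle excluded), and felt/none splits for cardiac
and abdominal clicks. The felt boundary is ambiguous for exactly one click;
the default rule is exhaustive (felt = count >= 1, none = count 0) on the
reading that any click indicates felt sensation, with a strict mode
(felt = count > 1) available.

### The statistical battery

* **Normality gate**: Shapiro–Wilk; p < 0.05 routes to the nonparametric
  branch (9-point Likert data essentially always does).
* **Friedman test**: tie-corrected statistic on within-participant
  mid-ranks, $\chi^2 = (k-1)\sum_j (R_j - n(k+1)/2)^2/(A-C)$ with
  $A=\sum r_{ij}^2$, $C=nk(k+1)^2/4$; equals the classic formula without
  ties (cross-checked against `stats::friedman.test`), and equals $n(k-1)$
  under perfect concordance. Implemented in-package because the tie
  correction and the post hoc below share the rank machinery.
* **Durbin–Conover post hoc**: pairwise
  $t=(R_i-R_j)/\sqrt{2n(A-B)/((n-1)(k-1))}$, $B=\sum_j R_j^2/n$, on
  $(n-1)(k-1)$ df, Benjamini–Hochberg adjusted across the
  $k(k-1)/2$ pairs. No installed package provides this procedure, so it is
  implemented from the standard formulation and validated against a
  hand-computed block design.
* **Spearman correlations** with a single BH adjustment per analysis family.
* **Paired contrasts**: one condition against the participant-wise mean of
  the other seven; Cohen's d = mean difference / SD of differences. The
  pooling of the comparison conditions (mean, not concatenation) is a
  package choice where the procedure was underdetermined.
* **Random-intercept model**: `response ~ predictor + (1 | participant)`
  via `lme4`. The family is deliberately explicit in the output: click
  counts default to Poisson with log link, with a Gaussian identity-link
  option, because no family is canonical for this design and z-statistics
  are family-dependent.
* **Mediation**: the a-path from a Huber M-estimator fit (`MASS::rlm`,
  default tuning) of mediator on predictor — robust regression chosen for
  non-normal residuals; the b-path from OLS of outcome on predictor and
  mediator; indirect effect $a\cdot b$ with a percentile CI from seeded
  case resampling, 5000 resamples by default. The predictor coding is a
  one-vs-rest condition indicator. The reported direct effect is
  total − indirect, with the OLS x-coefficient alongside.

Significance conventions mirror the analysis this package accompanies:
0.05 for correlations and mixed models, 0.01 for the ANOVA post hoc family.

## The synthetic cohort

`simulate_cohort()` draws a full participant cohort with known truth:
region click counts from a log-linear Poisson model with participant random
intercepts (SD 0.35 by default); cardiac counts additionally carry a planted
mediation path (condition → latent valence via `a`, latent valence → cardiac
log-rate via `b`); valence/arousal as rounded (half-up), clipped latent
values on the 9-point scale; click coordinates uniform within the assigned
region mask; and ranked emotions by Plackett–Luce sequential sampling with
condition-dependent propensities. Twenty-three of the 33 categories get
near-zero weight so the sparse filter is exercised and retains roughly the
ten analysed categories. Default effect directions mirror the study's
findings (abdominal sensation strongest for `sLuL-sLuL`, cardiac for
`sLuL-sHuL`, head for the `sLuH` types, higher valence for the predictable
contexts); the default cohort size is 527 and each condition samples one of
92 progression exemplars (14, 14, 12, 8, 18, 14, 3, 9 per type).

What the generator does *not* emulate: reaction times, within-trial click
timing, spatially smooth click fields (clicks are uniform within a region),
demographic covariates, and ordinal-scale artefacts beyond rounding. A
passing recovery suite therefore shows the estimators are correct under a
known truth of this shape, not that real click data meet these assumptions.

## Numerical choices and problem sizes

* Quantile convention: type-7 (linear interpolation) everywhere, including
  bootstrap percentile CIs.
* Likert discretisation: round half up, clip to 1..9.
* Degenerate inputs: constant vectors are errors for the normality gate and
  mediation; a zero-variance paired contrast returns a flagged infinite (or
  zero) effect instead of erroring; an all-tied Friedman matrix returns
  statistic 0.
* Stimulus search: seeded rejection sampling, uniform over observed
  successors; a shortfall within the attempt budget warns (or errors in
  strict mode) and returns the partial set.
* Pipeline seeds: one master seed, per-stage seeds derived as
  `(master * 131 + stage * 7919) mod 2^31 - 1`, so partial reruns are
  reproducible.
* Simulation sizes: the calibration studies use 2000 null replicates
  (Friedman at n = 50 participants x 8 conditions; Spearman at n = 200);
  recovery studies use 100 replicates at n = 500 with 400 bootstrap
  resamples per replicate (single mediation analyses keep the 5000-resample
  default); the cohort honesty check runs at n = 2000 within three standard
  errors. These sizes are the package's chosen compromise between Monte
  Carlo error and desk-scale runtimes.
* The embedding delegates to `uwot::umap` (components 2, random state 42,
  min_dist 0.001, spread 10), single-threaded so a fixed random state is
  bit-reproducible. The neighbourhood size was not reported with the other
  embedding parameters; the package default is 15, capped at n − 1 and
  recorded in the output metadata.

## Known limitations

* The first-chord convention (marginal scoring) is a documented convention,
  not an inference; profiles record it so downstream users can exclude
  position 1.
* The Poisson count family is a modelling default; real click counts may be
  over-dispersed, and the z-statistics of the mixed model depend on the
  family choice, which is always echoed in the output.
* Mediation here is single-level (participant resampling, no random
  slopes); multilevel mediation is out of scope.
* The embedding is for qualitative structure inspection only; no inference
  is attached to its coordinates.
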
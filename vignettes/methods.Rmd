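---
title: "Recurrent breakpoint detection from copy-number profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent breakpoint detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurbreak)
```

## Overview

`recurbreak` addresses a cohort-level question: given array-CGH copy-number
profiles from many individuals, which rearrangement breakpoints recur across
individuals, and which of them imply structural variants, gene truncations,
or fusion genes? The package deliberately avoids committing to a single
segmentation per profile. Marginal events — exactly the ones whose
recurrence across patients is informative — are the ones a maximum a
posteriori segmentation silently drops. Instead it computes, per individual,
posterior breakpoint probabilities over *all* segmentations, and combines
those probabilities across the cohort with a rank-based order statistic.

## The change-point model

A per-chromosome profile is `X = (X_1, …, X_n)`, the log2 test:reference
ratio at `n` ordered probes (probes are treated as points; only their order
and gap membership matter). Conditional on a partition into `K` contiguous
segments with levels `θ_1, …, θ_K`:

* `X_i ~ Normal(θ_s, σ²)` independently, where probe `i` lies in segment `s`;
* `θ_s ~ Normal(μ₀, σ₀²)` independently (conjugate, so each segment's
  marginal likelihood has a closed form);
* given `K`, all `C(n−1, K−1)` breakpoint placements are equally likely;
* `P(K = 1) = p_single` (default 0.5), with the remaining mass uniform on
  `2 … k_max`.

The per-segment marginal likelihood for probes `i..j` (length `l`, mean
`x̄`, within-segment sum of squares `SS`) is

$$\log m(i,j) = -\tfrac{l}{2}\log(2\pi\sigma^2)
  + \tfrac12\log\frac{\sigma^2}{\sigma^2 + l\sigma_0^2}
  - \frac{SS}{2\sigma^2}
  - \frac{l(\bar x-\mu_0)^2}{2(\sigma^2 + l\sigma_0^2)},$$

evaluated in O(1) from prefix sums. The dynamic program
`S_k(j) = Σ_v S_{k−1}(v) · m(v+1, j)` (log-space, with a streaming
log-sum-exp) gives `P(X | K = k) = S_k(n) / C(n−1, k−1)`, the evidence
`P(X)`, and the posterior over `K`; a backward stochastic recursion then
draws exact, independent breakpoint sequences from `P(A | X)`. Per drawn
segment the posterior-mean level
`θ̂ = (σ₀² l x̄ + σ² μ₀)/(σ² + l σ₀²)` is recorded; differences of adjacent
`θ̂` define the direction of copy change at each sampled breakpoint, and
their per-probe average across draws is the exported mean segmentation
(single-draw exports therefore show the usual conjugate shrinkage toward
`μ₀`).

Gap, interval, and joint-interval breakpoint probabilities are sample
fractions over the draws. They are also available analytically: forbidding
a gap set `W` in the DP recursion sums exactly the segmentations avoiding
`W`, so `P(no breakpoint in W | X)` is a ratio of two DP runs
(`exact_breakpoint_free_posterior()`), and inclusion–exclusion gives joint
probabilities. The test suite uses this to verify the sampled estimates
against exact values, and both against brute-force enumeration over all
`2^(n−1)` segmentations for small `n`.

### Hyperparameters

All three hyperparameters are estimated per profile from sliding windows of
`window = 10` probes (stride 1): `μ₀` is the median ratio; `V` the median
window variance; `M` the maximal absolute deviation of a window mean from
`μ₀`. Defaults are `σ² = 2V` and `σ₀² = M²`; the alternatives
(`V`, `3V`; `M`, `M³`) are exposed because the calibration simulations
below sweep them. Doubling `V` deliberately over-estimates the noise so
that local trends are not chased into spurious segments. When `σ ≥ 3σ₀`
the dynamic range of the profile is inside the noise and the profile is
reported breakpoint-free without segmentation — without this guard, pure
noise profiles with a degenerate `M` would be shredded into false
breakpoints.

`k_max` defaults to `min(n, 50)`: the DP is `O(n² k_max)` and posterior
mass beyond a few dozen segments is negligible for desk-scale chromosomes;
the bound is configurable for heavily rearranged genomes. Masked probes
(missing values, single-probe artifacts) are removed before segmentation;
gap indices always refer to the unmasked sequence.

## Recurrence statistics

### Probe-level

`P(b_g | S_j)`, the probability of a breakpoint at gap `g` in individual
`j`, is split by direction (`p_pos`/`p_neg`, ties on the posterior-mean
levels counted as positive — a measure-zero event for continuous data).
Because rearrangement burden varies enormously across cancer genomes, raw
probabilities are not comparable across individuals; each individual's
probabilities are reduced to normalised ranks over all of that individual's
gaps, genome-wide:

$$\rho_j(u) = \frac{\#\{u' : s_j(u') > s_j(u)\} + \#\{\text{ties incl. } u\}}{N + 1}.$$

For distinct scores this is the usual `(r+1)/(N+1)`; tied units all take
their tie group's *worst* rank. The tie rule matters: under a null cohort
most gaps have sampled probability exactly 0, and ranking ties optimistically
would hand every gap of a quiet genome a tiny rank, destroying calibration.
Counting ties against the unit keeps ranks stochastically larger than
uniform, hence p-values conservative (this is verified empirically by the
null-calibration test below).

Ranks are combined across the `m` individuals with a binomial order
statistic: sorting ranks ascending,

$$p = \min_{h_{\min} \le h \le m} \Pr[\mathrm{Binomial}(m, \rho_{(h)}) \ge h].$$

Only rank information enters — the statistic is invariant under any
strictly monotone per-individual transform of scores. The minimisation
over `h` makes the statistic mildly anti-conservative under the null
(bounded by the union bound, `P(p ≤ a) ≤ (m − h_min + 1)·a`; tested); BH
correction over the full hypothesis set absorbs this in practice, which the
null-calibration experiment confirms directly. `h_min` defaults to 4:
below four shared individuals a "recurrent" event is not distinguishable
from coincidence at desk-scale cohort sizes. Each gap is tested in both
directions (doubling the hypotheses), and Benjamini–Hochberg FDR control
is applied across all (gap, direction) pairs at `fdr_alpha = 0.01`
(a matched-normal screen uses 0.1 so weak germline signals still veto
tumor calls).

### Interval-level

Larger intervals are a priori likelier to contain a breakpoint, so gene
scans use a size-corrected log-odds score,

$$\ell_j(W) = \mathrm{logit}\, P(b \in W \mid S_j) - \mathrm{logit}\,(1 - P_{\text{free}}(W)),$$

where the prior free probability is combinatorial:
`P_free = Σ_k P(K=k) · C(n−1−w, k−1)/C(n−1, k−1)` for an interval
containing `w` gaps (a gap belongs to `W` only if both flanking probes lie
inside `W`). Posterior probabilities are clipped to
`[1/(S+1), 1 − 1/(S+1)]` (`S` = number of draws) so scores stay finite.
An individual's direction call for an interval follows a 90% rule over all
its sampled in-interval breakpoints; individuals failing it count as
non-supporting for both directions. Ranks, the order statistic, and BH
proceed as at probe level.

### Pairs

Pairs of intervals (gene pairs genome-wide; single-gap pairs within a
chromosome arm for structural variants) are scored by the joint analogue:
joint posterior hit probability (shared-segmentation sample fraction on one
chromosome; product across chromosomes, where segmentations are
independent) against a joint prior (inclusion–exclusion
`1 − free(w₁) − free(w₂) + free(w₁+w₂)` on one chromosome; product of hit
probabilities across chromosomes). Four direction combinations are tested
per pair. Scoring all pairs exhaustively is quadratic in the unit count,
so candidates are pre-filtered to pairs in which at least `h_min`
individuals have interval probability ≥ 0.1 in both members, and ranks are
taken against the empirical log-odds distribution over a seeded random
background of non-overlapping pairs (default `background_pairs = 1e5`,
capped at availability) plus all candidates. Without a cytoband table each
chromosome is treated as a single arm (with a warning).

## Classification, filtering, ranking

A fusion joins the 5' end of one gene to the 3' end of the other. From
copy-number data alone, the side of a gene retained in the fusion is the
higher-copy side of its in-gene breakpoint: genomic right if the copy
change is `+`, left if `−`. That side is the gene's own 3' end exactly when
`orient(G)·dir(G) = +`. A gene pair is therefore fusion-compatible iff
`orient(G₁)·dir(G₁)·orient(G₂)·dir(G₂) = −1`, and the 5' partner is the
gene with `orient·dir = −`. The rule covers deletion-type and
duplication-type fusions uniformly ("each gene contributes its higher-copy
side"); it reproduces the known geometry of the TMPRSS2–ERG deletion (two
minus-strand genes, copy stepping up into the right-flank gene, which is
the 5' partner). Gene-pair calls failing the rule are retained as generic
pairs; single-gene calls become truncation predictions; intra-arm probe
pairs become structural variants. The lists are disjoint by construction.

Filters only change a call's `status`, preserving a full audit trail:

* **Single-probe aberrations** (before segmentation): probe `i` is masked
  if both adjacent jumps exceed `τ` with opposite signs and its neighbours
  agree within `δ`. Defaults `τ = 3σ̂`, `δ = σ̂` with `σ̂ = √(2V)` from the
  pre-mask profile (thresholds must exist before masking, and masking
  precedes estimation). At these defaults an extreme noise probe inside a
  real event satisfies the rule with probability ~1e-4 — such probes are
  genuinely indistinguishable from artifacts, and losing an interior probe
  does not move the event's flanks.
* **Known variants**: single-locus calls within 10 kb of a catalogued
  variant endpoint are flagged; intrachromosomal pairs additionally require
  mutual overlap > 50% between the spanned interval and the variant.
  Interchromosomal pairs are never variant-filtered.
* **Matched normals**: loci also called in a normal cohort scanned at the
  lenient FDR are flagged `filtered_blood`, direction ignored.

Paired predictions are ranked ascending by RMS discordance between the copy
levels flanking the two breakpoints on their fused sides (mean of the 3
probes immediately outside each gene on that side; fewer are used, flagged,
at chromosome ends). Physically joined flanks share a derivative chromosome
and should agree; RMS near 0 ranks first.

## The synthetic-data generator

`simulate_single_aberration()` reproduces the calibration setting used
throughout: a 100-probe chromosome with a centred 40-probe gain of log2
ratio 1 (true gaps 30 and 70) under Gaussian probe noise — one sweep over
noise sd at ratio 1, one over ratio ∈ {0.5, 1, 2, 3, 4, 5, 6} at noise sd
0.5. `simulate_cohort()` emulates tumor-cohort structure: a shared probe
grid (10 kb spacing), carrier subsets receiving piecewise-constant events
with optional per-carrier breakpoint jitter (Gaussian in probes, rounded),
non-carriers pure noise, and an optional matched-normal cohort inheriting
only events marked germline. Cohort noise defaults to sd 0.25, between the
clean and hard regimes of the sweeps. What the generator does **not**
emulate: GC/wave artifacts, probe-specific response, tumor purity and
ploidy mixtures, and correlated noise — so passing tests demonstrate
statistical correctness of the machinery, not robustness to every
real-array pathology.

Breakpoint recovery is scored with the protocol used by the calibration
experiments: gaps with posterior probability ≥ 0.5 are predictions, a
prediction within 2 probes of a truth gap is a true positive
(greedy nearest-first one-to-one matching; a second prediction near an
already-matched truth gap is redundant, not false).

## Numerical choices

* All DP and evidence arithmetic is in log space; inner sums use a two-pass
  log-sum-exp that skips terms more than 37 log-units below the maximum
  (below double precision's contribution threshold).
* `SS` from prefix sums is clamped at 0 against cancellation.
* Constant profiles floor `σ²` at a configurable `ε` (1e-8) with a warning
  (the zero-breakpoint guard fires anyway, since `M = 0`).
* Sampling uses R's RNG (so `set.seed`/function seeds give bit-identical
  draws); every cohort operation derives per-profile sub-seeds
  deterministically from one master seed, making the whole pipeline a pure
  function of (inputs, config, seed).
* Direction ties (`θ̂` exactly equal across a gap) count as positive.
* Coordinates are 0-based half-open internally; readers accept 1-based
  dumps via a dialect flag.

## What the validation shows — and its edges

The acceptance suite checks, at sizes chosen to keep the full run in
minutes on one CPU: exact-inference agreement with brute-force enumeration
(n ≤ 10, tolerance 1e-9); sampler agreement with exact posteriors (8
probes, 50,000 draws, 3 binomial SEs, plus chi-square calibration across
independent batches); combinatorial priors against subset enumeration
(n ≤ 12); breakpoint-recovery trends over both calibration sweeps (25
replicates per condition); null calibration (100 cohorts of 20 × 500
probes: ≥ 95% must yield zero probe-level calls at FDR 0.01); an
interval-vs-probe sensitivity cohort (truncation jittered ±3 probes inside
one gene, 9/36 carriers, detected only by the interval scan); end-to-end
fusion recovery (5/36 carriers, exactly the planted pair, RMS near 0, and
nothing on a matched null cohort); and byte-identical reruns.

One edge is worth stating precisely. At ratio 1 and noise sd 0.5
(per-probe SNR 2), the *exact* per-gap posterior — computed analytically,
independent of sampling — spreads breakpoint mass over roughly three
adjacent gaps, so typically no single gap reaches the 0.5 threshold and
mean TP under the protocol is ≈ 0.6 (≈ 1.0 even with `σ² = V`). Detection
at that signal-to-noise is present but smeared; it saturates (TP ≥ 1.8)
from ratio 2 upward. The trend tests assert exactly this shape. The
smearing is a property of the model-plus-protocol combination, not of the
sampler: interval-level statistics, which aggregate the smeared mass, are
the appropriate tool at that regime — which is precisely the motivation
for the interval scan.

Interval and pair ranks need a reasonably sized unit set to have
resolution (`ρ` cannot be smaller than `1/(N+1)`): with only a handful of
genes, even a perfectly recurrent event cannot reach a small p-value.
Cohort fixtures therefore include a few dozen background genes; real use
with genome-wide gene sets is the intended regime.

## Limitations

* Per-chromosome independence: interchromosomal dependence enters only
  through the product rule for pair probabilities; no translocation
  breakend model.
* The probe-exact scan compares gaps across individuals by flanking-probe
  positions on a shared grid; a gap whose flanking probe is masked in some
  individual takes the worst rank there (conservative).
* No base-pair refinement of breakpoints, no transcript-frame checking of
  fusions, no purity/ploidy correction.
* The `O(n² k_max)` DP is comfortable to ~10⁴ probes per chromosome;
  beyond that, block processing would be needed.
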
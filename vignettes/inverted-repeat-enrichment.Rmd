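---
title: "Scanning genomes for inverted-repeat enrichment: model, calibration and design"
author: "irscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for inverted-repeat enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the
design decisions that were genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The observation model

The unit of observation is an inverted-repeat pair: a `k`-word at
position `i` whose exact reverse complement starts at `i + d`. Distances
are start-to-start, so `d = k` means the two words are adjacent and the
loop (the spacer a hairpin would extrude) has length `d - k`. Every
qualifying ordered pair is counted, not only nearest neighbours; for odd
`k` no word is its own reverse complement (the middle base would have to
self-pair), so there is no self-pair ambiguity at the default `k = 7`.

Hard-masked and otherwise ambiguous symbols — `N` and all non-ACGT IUPAC
codes — are separators. A pair is only counted when both words **and the
loop** lie inside one unambiguous run. The alternative (allowing `N` in
the loop only) was considered and rejected: the separator semantics of a
masked region is that nothing is known about it, including whether it
would interrupt a hairpin stem's spacer; and it keeps `n(d)` (below)
exactly computable per run.

Within a window, for each `d` the count `m(d)` is compared with what an
order-`k` Markov chain fitted to the chromosome predicts. With

* `n(d) = sum over runs of max(0, L_run - d - k + 1)` — the number of
  positions a pair could occupy, which is where the ambiguity adjustment
  lives, and
* `p(d)` — the chain's probability that a word occurrence is followed at
  distance `d` by its reverse complement,

the count is modelled as Binomial(`n(d)`, `p(d)`) and standardised,

```
T(d) = (m(d) - n(d) p(d)) / sqrt(n(d) p(d) (1 - p(d))),   T(d) = 0 when n(d) = 0,
```

and summed over distance classes into the enrichment statistic
`S[d1, d2]`. The default classes are the total class `I_t = S[k, dmax]`
and eight equal bands (`I_1 = S[7, 500]`, ..., `I_8 = S[3501, 4000]` at
the default `k = 7`, `dmax = 4000`); they partition `[k, dmax]`, so
`S(I_t)` equals the sum of the band scores exactly — an identity the
tests assert.

Binomial trials at overlapping positions are not independent, and
windows differ compositionally from their chromosome model; both effects
make `S` wider-tailed than a sum of independent standard normals. That
is precisely why significance is *empirical* (next section) rather than
Gaussian: no parametric p-value for `S` is offered, deliberately.

## Empirical calibration: the control scenario

A control genome is simulated from the fitted chain per chromosome: the
same length, the exact same `N` positions, each unambiguous run drawn
independently (the chain restarts at run boundaries — separators
terminate dependence; the first `k` symbols of a run come from the word
distribution `pi`, truncated for runs shorter than `k`). Scanning the
control with the *same* fitted null gives the S distribution under the
hypothesis of no enrichment; the critical value per chromosome and
class is the 0.95 nearest-rank quantile of the control window scores
(sorted ascending, rank `ceiling(0.95 N)`), and windows *strictly*
surpassing it are called enriched.

Nearest-rank was chosen over interpolated quantiles: it is conservative,
always an actually observed S value, and matches the plain reading of a
quantile of the control values. One control replicate is the default;
`replicates` pools windows from several for tighter quantiles.

Two finite-sample properties are worth knowing. First, with `W` control
windows per chromosome the nearest-rank 0.95 quantile is the
`ceiling(0.95 W)`-th order statistic, and the probability that an
independent null window strictly exceeds it is `(W + 1 - rank)/(W + 1)`
— for `W = 20` that is `2/21 ≈ 9.5%`, not 5%. The calibration is
asymptotically nominal but noticeably anti-conservative at small window
counts; at genome scale (hundreds to thousands of windows per
chromosome) the discrepancy is negligible. Second, fully masked windows
score `S = 0` (via the `n = 0` guard) and are retained both in the
control distribution and in percentage denominators, but are never
flagged; dropping them instead would shift critical values slightly in
heavily masked chromosomes — the retained convention matches window
counts obtained by ceiling division of chromosome length.

## The null model and p(d)

`fitMarkov` estimates `pi` (empirical `k`-word frequencies over all run
positions) and the 4^k x 4 transition matrix from within-run adjacencies
only. Words never observed in a transition context get a uniform row;
words never observed at all get `pi = 0`. Models are fitted per
chromosome by default (base composition varies between chromosomes);
`modelScope = "global"` pools.

`p(d)` is computed by exact state propagation: start the chain in word
`w` (weight `pi(w)`), advance `g = d - k` one-base steps through the
loop, then chain the `k` transition probabilities that spell out the
reverse complement of `w`; sum over `w`. DNA chains mix fast, so beyond
a configurable `horizon` (default 50 gap steps) the propagated state
distribution is indistinguishable from stationarity and the flat tail
`p_inf` — the `pi`-averaged probability of meeting the reverse
complement — is used; a property test asserts the value at the horizon
is within 1e-6 of the tail on fitted chains.

Numerical choices:

* Exact propagation costs O(horizon x 4^{2k}) time and 4^{2k} memory;
  that is instant for `k <= 3`, fine for `k = 5`, and prohibitive at
  `k = 7` (2 GB matrices). For `k > 5` the implementation therefore
  drops to `horizon = 0`: `p(d) = p_inf` for all `d > k`, with `p_inf`
  computed as `sum_w pi(w) pi(rc(w))` (exact when `pi` is stationary
  under the transitions, which the fitted empirical `pi` is up to run
  boundary effects). Since the gap dependence of `p(d)` decays within a
  few steps and — more importantly — the *same* `p(d)` is used for the
  real scan and the control scan, calibration is unaffected by this
  approximation; only the first couple of distances above `k` carry a
  small systematic offset that cancels between observed and control.
  The exact estimator of the chain-aware `p(d)` is not uniquely pinned
  down in the literature the method draws on; the horizon scheme
  brackets the options (`horizon = 0` is the stationary/independence
  approximation, large horizons the fully chain-aware value).
* `p(d)` is clipped to `[1e-12, 1 - 1e-12]`; a model degenerate enough
  to hit the clip (e.g. a deterministic complement chain) is flagged and
  all its `T(d)` forced to 0 rather than emitting infinities.
* Counting uses an O(L + #pairs) bucket scheme (positions grouped by
  word, swept against the reverse-complement bucket) in C++; the
  contract is the count itself, which the tests pin to a brute-force
  double loop over all position pairs.

## Windows and coordinates

Coordinates are 0-based half-open everywhere internally and in BED
output; 1-based inclusive labels (`chr:start:end`) appear only in
human-readable region names. Windows are successive, non-overlapping,
`ceiling(L / windowSize)` per chromosome; the trailing partial window is
kept and analysed. Pairs never cross window boundaries: with the default
window (10^5) two orders larger than `dmax` (4000), the edge loss is a
few percent and identical in the observed and control scans, so it does
not bias calls — it is a known, shared censoring, not a correction.

Soft-masked lower-case letters are folded to upper case by default
(hard-masked input is the intended use); `hardMaskLower = TRUE` treats
them as separators instead.

## The synthetic world

The generator exists so that every stage is testable without downloads.
Its defaults state one fixed world:

* 4 chromosomes x 2 Mb, windows of 10^5 nt; analysis at `k = 3`,
  `dmax = 1000` (minutes on one CPU; `k = 7` is exercised in the
  planted-recovery test at 1 chromosome x 2 Mb).
* Background: i.i.d. GC 0.41 ("gcskew", close to human composition),
  expressed as an order-`k` model so the same machinery fits and
  simulates it.
* Mask: 10 kb `N` caps at both ends plus alternating
  exponentially-distributed unmasked runs (mean 1000 nt) and `N` runs
  (mean 800 nt), masking ~45% — the coarse statistics of a
  RepeatMasker + Tandem-Repeats-Finder hard-masked human chromosome.
* Plants: directives overwrite stem and reverse-complement-stem
  positions inside one window (the loop keeps its background content),
  stems sampled from the background word distribution so the enrichment
  lies in pairing structure, not composition, and the Markov null stays
  well-specified. The default intensity is 400 stems of `k = 7` with
  loops uniform on [10, 100]: sized so a planted window's S(I_t) (~270
  to 460 in pilot runs) clears the null maximum across 20 windows
  (~130) with a factor-two margin, making the 19-of-20 recovery
  property a test of the pipeline rather than a coin flip. (For
  perspective, 30 planted stems shift S(I_t) by about 12 — invisible
  against a null spread of tens of units.)

What a green synthetic test does **not** establish: real chromosomes are
not order-3 (or order-7) Markov — they carry isochores, uncatalogued
repeats and genuine inverted-repeat biology, all of which widen the real
S distribution and are the reason the empirical-calibration machinery
exists. The generator also does not emulate realistic repeat-family
masking patterns, tandem repeats, or other non-B motif classes. The
desk-scale dispersion ordering across length classes is likewise weak:
with equal-width classes the binomial component of Var(S) is identical
across bands, and only the mask-driven decline of `n(d)` with `d` (plus
between-window composition variance, which scales with `n(d) p(d)`)
tilts it; at `k = 3` with ~45% masking that tilt is a few percent per
band, so the tests assert a negative rank trend and a strict I_1 > I_8
endpoint decline rather than strict monotonicity across all eight bands
— at genome scale with `k = 7` the effect is much stronger.

## Degenerate inputs and tie-breaks

* Empty FASTA, non-IUPAC characters (with position), duplicate record
  names: errors.
* Fully masked chromosome: valid, zero runs, all-zero spectra, never
  enriched.
* Runs shorter than `2k`: contribute nothing (`n(d) = 0` for all `d`).
* `S` exactly equal to the critical value: *not* enriched (strict
  surpassing).
* `alpha = 0`: the critical value is the control maximum.
* Profile-window selection (`selectProfileWindows`) breaks ties by the
  first window in genome order (`which.max` semantics).
* Seeds: one run seed; per-chromosome/per-replicate child seeds derived
  by a fixed affine map modulo 2^31 - 1, so chromosome results are
  independent of processing order and every derived seed stays below
  2^31.

## Known limitations

* Only exact reverse-complement stems are counted — no mismatches,
  bulges or degenerate pairing.
* The `S` statistic's dispersion depends on class width and on `n(d)`;
  comparisons of raw S across classes are not meaningful without the
  per-class critical values (which is how the pipeline uses them).
* No multiple-testing correction beyond the empirical-quantile
  procedure; with per-chromosome 5% thresholds, 5% of null windows per
  chromosome are expected to be flagged.
* Genome-scale runs at `k = 7`, `dmax = 4000` are hours of single-CPU
  work on a mammalian assembly; stage artifacts (model JSON, cv JSON,
  score TSV) exist so stages re-run independently.
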
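---
title: "Screening digester microbiomes for hydrolytic candidate taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening digester microbiomes for hydrolytic candidate taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hydrolysis of cellulose and hemicellulose is usually the rate-limiting step
when lignocellulosic biomass (straw, deep litter) is digested anaerobically
to methane. The organisms that secrete the responsible cellulases and
xylanases are hard to pin down from sequencing data alone: most digester
taxa are poorly characterized, and genomic potential does not guarantee
expressed activity. hydroscreen implements a screening strategy that links
two independent weekly measurements from the same reactor —

1. **bulk hydrolase activity**, measured fluorometrically with
   4-methylumbelliferone (MUF)-linked substrate mimics
   (MUF-cellobioside for cellulases, MUF-xylopyranoside for xylanases), and
2. **community composition**, as an amplicon sequence variant (ASV) count
   table from 16S rRNA gene sequencing —

and asks which individual ASVs rise and fall *like the enzyme activity
does*. Association is statistical, not causal: a candidate may produce the
enzyme, or grow symbiotically with the producer. The output is a ranked
shortlist for targeted follow-up, not a functional assignment.

## The assay model

Under substrate saturation the enzymatic release of MUF is zero-order, so
well fluorescence grows linearly with time until substrate depletion or
quenching effects bend the curve. The activity estimate is built from:

* **Standard curve** (`fit_standard_curve()`): OLS of fluorescence (AU) on
  known MUF concentrations (µmol/L), fitted separately for standards
  prepared in active and heat-inactivated slurry so matrix quenching
  cancels. The linear range is the widest low-concentration prefix whose
  fit reaches `r2_threshold` (default 0.99).
* **Initial rate** (`estimate_initial_rate()`): the slope of the longest
  reading window that starts at the first reading and attains a linear fit
  `r² ≥ 0.98` (default; at least 4 points, whole series when fewer than 6
  points). A prefix-anchored window is used because product accumulation
  only slows the reaction: later readings can only under-estimate the
  initial rate. The AU/min slope is converted via the standard-curve slope
  to µmol MUF/L/min, then ×60 and ×0.17617 mg/µmol (MUF molar mass
  176.17 g/mol), and divided by the slurry dilution to report the
  undiluted-slurry rate in mg MUF·L⁻¹·h⁻¹. A stricter window threshold
  (e.g. 0.99) excludes plateau points more aggressively and is preferable
  when kinetics saturate sharply.
* **Blank correction** (`blank_correct()`): the matched heat-inactivated
  control rate is subtracted and the result floored at zero — negative
  enzymatic activities are physically meaningless. A blank above 20% of the
  sample rate (default) raises a QC flag instead of an error.
* **Concentration averaging** (`average_concentrations()`): each sample is
  assayed at two substrate concentrations to verify saturation; the
  reported activity is their mean, flagged when they disagree by more than
  25% (default) relative to the mean.

Replicate wells are averaged reading-by-reading before the rate fit
(default); per-well fitting with rate averaging is available
(`average_replicates = FALSE`). Assay temperature is treated as metadata
only; no kinetic temperature correction is applied.

## The screening model

For one reactor–enzyme combination (`screen()`):

1. Samples below 10,000 reads (default) are removed
   (`filter_samples()`); counts become relative abundances.
2. Activity days are paired with the nearest sampling day within 3 days
   (`align_days()`), injectively, greedily by smallest gap, ties toward the
   earlier sample day. Weekly schedules rarely coincide exactly; unpaired
   days are dropped and logged.
3. Both the activity series and each ASV's relative abundance series are
   z-score normalized, `z = (x − mean(x)) / sd(x)` with the sample
   (n−1) standard deviation. The z-scale removes units, so the screen is
   invariant to affine rescaling of either variable.
4. **Selection** (`ks_screen()`): a two-sample Kolmogorov–Smirnov test
   compares the z-scored abundance values with the z-scored activity
   values. "Behaves like the activity" is operationalized as
   *non-rejection*: an ASV is retained iff the KS p-value exceeds
   `ks_alpha` (default 0.05, configurable). ASVs present in fewer than 4
   samples, or constant, are excluded up front — their z-scores are
   degenerate. Note the KS statistic compares value distributions and is
   blind to temporal ordering; ordering enters at the ranking step.
5. **Ranking** (`rank_candidates()`): per retained ASV, OLS of z-scored
   abundance on z-scored activity. On standardized variables the slope
   equals Pearson's r and the ranking metric is R² = r², descending. Ties
   break by higher mean relative abundance, then ASV id, making candidate
   tables byte-reproducible. The top 25 (default) are reported with
   taxonomy labels, mirroring the candidate-table format used in practice.

### The exact KS p-value

Time series here have ~10–11 points, far below where the asymptotic
Kolmogorov tail is trustworthy. The p-value is therefore computed exactly
for pooled sizes m+n ≤ 26 (default) by counting, over all
`choose(m+n, m)` assignments of labels to the pooled values, those whose
statistic reaches the observed D. The count is a dynamic program over
blocks of tied values working on the integer statistic
`|A·n − B·m|` (A, B = cumulative per-sample counts), so ties and
floating-point comparisons are handled exactly; the cost is polynomial, not
combinatorial. With ties, D itself is evaluated at every distinct pooled
value, which assesses both one-sided deviations at each point.

### The regression reading

The source procedure couples a KS selection to "a linear regression
analysis of the relative abundances of the selected ASVs, normalized by the
enzymatic activity" — a phrasing with two defensible readings. The default
here regresses z-scored abundance on z-scored activity and ranks by R²
(the "normalization" is the z-scoring of both variables); this is
scale-free, symmetric in interpretation, and reduces to |r| ranking. The
alternative reading — the abundance/activity *ratio* regressed on time —
is implemented behind `ranking = "ratio_trend"` but is not the default: it
is undefined at zero activity and conflates trend with tracking.

## Ordination support analyses

* `correspondence_analysis()` performs classical CA by SVD of the
  standardized chi-square residual matrix; total inertia equals χ²/N
  exactly, and degenerate tables yield fewer axes rather than failing.
* `rda()` performs redundancy analysis with a single activity constraint:
  species columns (Hellinger-transformed by default) are centered and
  fitted by per-species least squares on the centered constraint;
  the constrained fraction R² = SS(fitted)/SS(total). Significance comes
  from permuting the constraint across samples,
  `p = (1 + #{R²_perm ≥ R²_obs}) / (1 + n_permutations)`; with the default
  999 permutations the smallest attainable p is 0.001. The Hellinger
  default exists because raw abundances make linear ordination
  scale-dominated; `transform = "none"` reproduces the raw-scale analysis.
  R² is reported unadjusted, with the adjusted value alongside.
* Axis signs are canonicalized (first nonzero loading positive) so score
  files are reproducible across platforms and sample orderings.
* `pearson()`/`pearson_window()` support day-windowed correlations of
  operational series (e.g. methane production rate against activity during
  early feeding vs. late feeding).

## What the synthetic data emulate

`generate_activity_profile()` produces the canonical lag–rise–decline
activity trajectory: baseline until `rise_day`, linear ramp to
`baseline × fold_rise` at `decline_day`, then linear decline to
`decline_fraction` of the peak at the last day, with mean-preserving
multiplicative lognormal noise (`noise_cv`). Defaults (baseline 4, 17.6-fold
rise to a 70.4 mg MUF·L⁻¹·h⁻¹ peak around day 62, weekly days 11–81)
represent a strongly responding mesophilic straw-fed reactor.

`generate_community()` plants ground truth for recovery testing:

* **Background**: fixed per-simulation mean proportions drawn from a
  lognormal rank-abundance curve (long-tailed richness without modeling
  real taxa), with per-sample Dirichlet draws (concentration scale
  `dispersion`, default 200) providing compositional noise. Background
  trajectories carry no temporal signal.
* **Responders**: for each responder a unit-variance trajectory `w` is
  constructed with in-sample correlation exactly `responder_tracking` to
  the z-scored activity (the noise component is orthogonalized before
  mixing), and expected proportions follow `base × exp(k·w)`,
  renormalized to a target mean abundance drawn log-uniformly inside
  0.01–0.5% of reads — the abundance stratum where hydrolytic candidates
  were observed. The exponential coupling (`coupling_strength` k = 1)
  keeps proportions positive and closure valid; it also means the *linear*
  z-trajectory of a responder correlates slightly below the nominal
  tracking value, while the log-proportion z-trajectory matches it
  exactly.
* **Counts**: proportions are closed to 1 and sampled multinomially at
  lognormal depths (defaults mean 54,495, sd 21,312 reads — the per-sample
  scale of the motivating study), so row sums equal the drawn depths by
  construction.

Defaults are 510 ASVs with 10 responders per enzyme at tracking 0.9 over 11
weekly samples. What the simulation does *not* emulate: phylogenetic
structure, temporally autocorrelated background dynamics (washout,
succession), multiple co-varying responder guilds, chimeras or other
sequencing artifacts, and replicate-reactor covariance. A passing recovery
benchmark therefore demonstrates that the statistical machinery finds
coupled low-abundance trajectories under realistic compositional and
counting noise — not that real hydrolytic taxa will always be found.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: closed-form
OLS for rates and curves; full `combn` enumeration for the exact KS p
(all size pairs with m+n ≤ 12, >1,000 randomized cases); per-species
`lm()` normal equations and vegan for the RDA constrained fraction
(100 random matrices, 1e−10 agreement) plus a 500–1,000-dataset null
calibration of the permutation test at 99 permutations; χ²/N for CA
inertia; tallied frequency-of-frequencies for Chao1. The recovery
benchmark runs 20 seeds at tracking 0.9 (median planted-responder recovery
in the top 25 must reach 8/10) and 10 seeds per tracking level in
{0.5, 0.7, 0.9, 1.0} for monotonicity. These sizes keep the full suite
around a minute while leaving Monte-Carlo error well inside the asserted
margins.

## Numerical choices and edge cases

* Zero-variance guards: constant ASVs are excluded before z-scoring;
  a constant RDA constraint or a zero-slope standard curve is an error.
* A perfectly flat kinetic series fits a flat line: its r² is defined as 1
  and its slope 0, so noiseless blanks are exact.
* `filter_samples()` keeps samples with total ≥ `min_reads` (strictly-less
  removed); an all-removed table is an empty table plus a warning, because
  downstream stages can report it more informatively than an abort.
* Depth filtering happens before relative abundances are computed.
* Unresolved taxonomy ranks aggregate under the nearest classified parent
  (`"X (unclassified)"`), and fully unknown lineages under
  `"Unclassified"`.
* All pipeline randomness (RDA permutations) flows from one root seed with
  fixed per-combination offsets; reruns of the same configuration are
  byte-identical.

## Limitations

KS non-rejection is a weak criterion by design — with ~11 time points its
power is limited and a large fraction of variable ASVs passes; the
regression ranking, not the KS gate, does most of the selective work.
Low-abundance ASVs near the prevalence threshold have noisy z-scores, and
compositionality means strong blooms of dominant taxa depress all other
relative abundances simultaneously; candidates should be inspected against
that background. The screen detects linear association on the z-scale:
threshold-like or lagged responses score poorly. Finally, candidate status
is an association statement; confirming hydrolytic function needs targeted
experiments (isolation, metatranscriptomics, activity-based probes).
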
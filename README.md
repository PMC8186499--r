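# hydroscreen

Identify candidate cellulolytic and xylanolytic microorganisms in anaerobic
digesters by linking fluorometric hydrolase assays to 16S rRNA amplicon time
series.

Hydrolysis is typically the rate-limiting step in anaerobic digestion of
lignocellulosic biomass, but the taxa that actually express cellulases and
xylanases are rarely identifiable from sequencing alone. hydroscreen is
aimed at microbiome researchers and digester engineers who monitor a
reactor weekly on two channels — bulk enzyme activity from
4-methylumbelliferone (MUF)-linked substrate assays, and community
composition as an ASV count table — and want a ranked shortlist of taxa
whose abundance trajectories track the enzymatic activity.

## The method

For a reactor–enzyme combination with activity series `a(t)` and relative
abundance series `x_i(t)` for ASV *i* (aligned to common sampling days):

1. **Assay reduction.** Plate-reader kinetics → activity: the initial
   linear hydrolysis rate (zero-order kinetics) is the slope of the longest
   linear reading window, converted through the matrix-matched MUF standard
   curve, blank-corrected against heat-inactivated controls
   (`max(v_sample − v_blank, 0)`), averaged over the two substrate
   concentrations, and reported in mg MUF·L⁻¹·h⁻¹ of undiluted slurry.
2. **Depth filter.** Samples with fewer than 10,000 reads are removed
   before relative abundances are computed.
3. **Normalization.** Both series are z-scored:
   `z = (x − x̄)/s` with the sample standard deviation.
4. **Selection.** A two-sample Kolmogorov–Smirnov test compares
   `z(x_i)` with `z(a)`; ASVs whose value distribution is *not*
   distinguishable from the activity's (p > α = 0.05) are retained.
   For these short series the p-value is exact (tie-aware counting over
   label assignments), not asymptotic.
5. **Ranking.** Per retained ASV, OLS of `z(x_i)` on `z(a)`; on
   standardized variables the slope is Pearson's r and candidates are
   ranked by R² = r², top 25 reported with taxonomy.

Supporting analyses: Chao1 and Shannon alpha diversity, correspondence
analysis (total inertia = χ²/N), redundancy analysis constrained by the
activity with an exact-level permutation test, and day-windowed Pearson
correlations. A synthetic-data module generates plate kinetics, activity
profiles, and multinomial–Dirichlet community time series with *planted*
responder ASVs, so the whole pipeline is testable against known ground
truth.

## Worked example

Simulate a strongly responding reactor (activity rising 17.6-fold to a peak
of ~70 mg MUF·L⁻¹·h⁻¹, 11 weekly samples), plant 10 low-abundance responder
ASVs at tracking 0.9 among 500 background ASVs, and screen:

```r
library(hydroscreen)

spec <- activity_profile_spec()        # lag-rise-decline, weekly days 11..81
act  <- generate_activity_profile(spec, reactor = "R2",
                                  enzyme = "cellulase", seed = 42)
round(act$rate[1:6], 1)
#> [1]  4.6  3.8  4.1  4.2 20.2 34.4

com  <- generate_community(community_sim_spec(), act, seed = 42)
cand <- screen(com$counts, com$taxonomy, com$metadata, act,
               reactor = "R2", enzyme = "cellulase")
head(as.data.frame(cand), 5)
#>   rank   asv_id    taxonomy  ks_D  ks_p r_squared slope mean_rel_abundance
#> 1    1 ASV_0321 Species_321 0.273 0.833     0.850 0.922           0.000242
#> 2    2 ASV_0122   Genus_036 0.364 0.479     0.784 0.885           0.000191
#> 3    3 ASV_0153   Genus_033 0.364 0.479     0.692 0.832           0.001252
#> 4    4 ASV_0049 Species_049 0.182 0.997     0.687 0.829           0.000169
#> 5    5 ASV_0228 Genus_044   0.364 0.479     0.687 0.829           0.000432

attr(cand, "n_screened"); attr(cand, "n_retained")
#> [1] 249
#> [1] 249

planted <- com$truth$responders$cellulase
sum(planted %in% cand$asv_id)
#> [1] 10
```

Reading the table: `ks_D`/`ks_p` are the Kolmogorov–Smirnov statistic and
exact p against the z-scored activity (retention requires p > 0.05 —
*similarity* is non-rejection, which is why most variable ASVs pass the
gate); `r_squared` is the squared correlation between the z-scored
abundance and activity trajectories and drives the ranking; `slope` is
Pearson's r. Here all 10 planted responders are recovered in the top 25.
Mean relative abundances fall in the 0.01–0.5% stratum the simulation
plants responders in.

The community-wide link can be quantified with RDA:

```r
r <- rda(to_relative(com$counts), act$rate, n_permutations = 999, seed = 1)
sprintf("R2 = %.2f, p = %.3f", r$constrained_fraction, r$permutation_p)
#> [1] "R2 = 0.11, p = 0.100"
```

With only 10 of 510 ASVs coupled to the activity, the community-wide
constrained fraction is expectedly small — RDA measures global
restructuring, while `screen()` finds the individual responders.

A full multi-reactor run is orchestrated by `run_pipeline()` from a
`run_config()` (or YAML file), writing activity, diversity, ordination and
candidate TSVs plus a JSON manifest; `inst/cli/hydroscreen.R` is a thin
command-line wrapper with `run-all` and `simulate` subcommands.

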
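---
title: "Analysing an oral FMT trial: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing an oral FMT trial: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtkit)
```

fmtkit analyses small placebo-controlled oral fecal microbiota
transplantation (FMT) trials in dogs with tylosin-responsive enteropathy
(TRE): a single stool donor, FMT and placebo arms followed over a
screening → inclusion → endoscopy → treatment → post-treatment timeline,
and a healthy reference cohort.  This vignette explains the models the
package implements, the parameters that matter, what the synthetic trial
generator does and does not emulate, and the design choices made where
several readings were defensible.

## Feature-table processing

All microbiome stages start from an `asv_table`: a samples × ASVs
matrix of non-negative integer counts with optional 7-rank taxonomy.
Processing order is **rare-ASV removal → low-count filter →
low-variance filter → genus aggregation → total-sum scaling**; each step
is an exported function, so other orders are available to callers who
want them (whether filtering preceded or followed aggregation is
genuinely open; scaling "at the genus level" fixes only the last two
steps, and we default to filtering at ASV resolution because that is
where rare-feature noise lives).

* `remove_rare_asvs()` drops ASVs whose **dataset-wide** summed count is
  ≤ 2 (singletons/doubletons).  The scope is deliberately the entire
  analysis dataset, donor included: presence-based statistics such as
  engraftment rates are computed downstream of this filter and would
  otherwise be inflated by sequencing noise.
* `low_count_filter()` keeps features with ≥ 4 counts in ≥ 20% of
  samples, both boundaries inclusive.  The underlying rule ("filter all
  features with < 4 counts in at least 20% of the values") is worded
  ambiguously in common tooling; we implement the conventional
  minimum-count/minimum-prevalence *retention* rule that matches the
  documented semantics of the usual web platforms.
* `low_variance_filter()` ranks features by inter-quartile range
  (type-7 quantiles) and removes the lowest `floor(0.10 × p)`, ties
  broken lexicographically by feature id so results are deterministic.
  Note this filter is *relative*: applying it twice removes a further
  decile.  The count-threshold filters are idempotent; the rank-based
  one is not, by construction.
* `total_sum_scaling()` divides each sample by its total.  Zero-total
  samples cannot be scaled; they are excluded with a warning rather than
  an error so partial datasets still process (the pipeline collects such
  warnings into the run report).
* `aggregate_taxa()` sums counts over a rank label and pools ASVs with a
  missing label under `unclassified <nearest assigned parent>`
  (e.g. "unclassified Lachnospiraceae"); per-sample totals are conserved
  exactly.
* `collapse_other()` pools taxa whose mean relative abundance falls
  below a display threshold (1% at genus level, 1.4% at species level by
  default) into "Other".  We pool the *low*-abundance taxa and display
  the rest individually — the only reading consistent with a finite
  legend.

## Engraftment by set exclusion

For each FMT recipient, presence profiles (`build_presence()`) are
formed from the rare-ASV-filtered table: pre-FMT presence from the
endoscopy visit (the last sampling point before capsules start; dogs
that skipped endoscopy need an explicit `baseline_visit` override),
post-FMT presence from the union of treatment and post-treatment
samples, and donor presence from all donor lots (a per-lot mode is
available, since lot-to-lot variation moves the denominator).  Presence
means count ≥ 1 in any contributing sample — the rare-ASV filter above
is the noise gate, so no additional threshold is applied.

The candidate denominator is the donor set minus everything the
recipient already carried pre-FMT; the engraftment rate is the
percentage of candidates detected post-FMT.  A recipient sharing every
donor ASV pre-FMT has an empty denominator and is excluded with an
explicit error rather than a silent `NaN`.  Post-FMT detection pools
*either* post-phase sample ("detected in the post-FMT samples"); we read
the alternative "in both samples" interpretation as stricter than
intended, since a dog leaving the trial early contributes only one
post-FMT sample.

Rates are stored at full precision and reported to two decimals.
`summarize_engraftment()` adds the mean, median (midpoint convention),
range and the per-ASV engraftment frequency across recipients.

## Diversity

`shannon()` uses the natural logarithm by default (configurable base):
H = −Σ p log p over nonzero proportions.  Group comparisons use the
Kruskal–Wallis rank test (`stats::kruskal.test` underneath, with the
all-ties case defined as H = 0, p = 1); pairwise comparisons are
two-group calls and are *not* multiplicity-adjusted by default,
matching how raw pairwise p-values are conventionally reported for
these designs.

`bray_curtis()` is 1 − 2Σmin(x,y)/(Σx+Σy) with no internal
normalisation — callers pass relative abundances, and the scale
dependence is intentional and documented.  `permanova()` partitions the
squared-distance geometry into between/within-group components
(Gower centering) and tests the pseudo-F by label permutation:

* p = (exceedances + 1)/(B + 1) for B sampled permutations (default
  B = 999, so the grid includes 0.001), bit-reproducible given the
  mandatory seed;
* when the number of distinct labelings is ≤ 10,000 the full
  enumeration is used and p is the exact exceedance fraction;
* exceedance uses a 1e-12 slack so the observed labeling always counts
  against itself under floating-point noise.

Calibration is tested, not assumed: under an exchangeable null the
empirical type-I error at α = 0.05 sits inside the binomial 95%
interval over 500 simulated datasets (12 samples, 2 groups — small
enough to run routinely, large enough to detect miscalibration).

## Differential abundance

The bias-corrected linear model treats the log relative abundance of
each taxon as the response.  Because proportions are compositional, a
true change in some taxa induces an identical spurious log-scale shift
in *all* taxa; the model therefore:

1. winsorises each taxon at its 0.97 quantile (per taxon, across
   samples, before the log; no re-normalisation afterwards);
2. regresses log(w + 0.5 · m₀) — m₀ the smallest positive proportion in
   the table, 0.5 the configurable pseudocount — on the pre/post phase
   indicator with a per-dog random intercept (lme4);
3. estimates the shared bias as the kernel-density mode of the raw
   phase coefficients (the mode, unlike the mean, is robust when a
   minority of taxa truly change; with < 10 taxa the median is used);
4. subtracts the bias — a rigid shift, so taxon ranking is unchanged —
   and computes t-tests on the corrected coefficients with BH
   adjustment across taxa.

Small-cohort realities drive two further choices.  With ~7 dogs per
arm, random-intercept variance estimates frequently hit the boundary;
singular or failed fits fall back to dog fixed effects and are flagged
per taxon in the output.  And the residual degrees of freedom of the
fixed-effect parametrisation (n − n_dogs − 1) are used for t-tests in
*both* paths, so p-values are deterministic and do not depend on which
path a taxon took.  Arms are modelled separately (pre vs post within
FMT, pre vs post within placebo); the prevalence filter (30%, count ≥ 1,
boundary inclusive) is applied per arm before fitting.

Null calibration (40 taxa, 10 dogs, one pre and one post sample each,
depth 20,000, 200 replicates) keeps the raw p < 0.05 fraction inside
the binomial 95% interval, and a 4-fold spiked taxon attains the
smallest adjusted p — these sizes are the package's regression-test
baseline, chosen to finish in a few minutes on one core.

## Clinical scoring and outcomes

The CCECAI is the sum of nine 0–3 items (range 0–27) with bands 0–3
insignificant, 4–5 mild, 6–8 moderate, 9–11 severe, ≥ 12 very severe.
Remission requires CCECAI ≤ 3 **and** mean FCS ≤ 3; relapse is
CCECAI > 3 **or** (clinical signs **and** FCS ≥ 4).  The precedence
matters: a loose stool alone, without signs and with an insignificant
CCECAI, is not a relapse — the reading consistent with a dog that can
relapse on CCECAI while keeping a normal FCS.  The two classifiers are
mutually exclusive over the whole score grid (tested exhaustively).
Mean FCS pools every defecation event in the 3-day window ending at the
evaluation day, with no per-day pre-averaging; for dogs relapsing
mid-phase the window is anchored at the relapse day.

Fecal dry matter: the commonly printed formula
((wet − dry)/wet) × 100 computes *moisture*, yet dry-matter percentages
are reported on the dry/wet scale (medians around 28–49%).  The default
convention is therefore `dry_over_wet` = 100·dry/wet, with
`printed_formula` available explicitly; the two are complementary
(they sum to 100, a tested identity).  Duplicate measurements are
averaged and their CV% carried as a quality metric.

Capsule dosing uses half-open weight bands (5–10] → 1, (10–20] → 2,
(20–30] → 3, > 30 → 4 capsules/day; the printed band edges leave
(10, 11) kg unassigned, so the bands are implemented as intervals
covering every weight above the 5 kg floor.

`phase_outcomes()` tabulates evaluable dogs, relapses and responder
percentages (half-up rounding to one decimal, matching conventional
trial reporting) per group × phase plus a cumulative row, and compares
groups with **Fisher's exact test** on the 2×2 relapse table.  A
logistic regression would ask the same question, but at 6–7 dogs per
arm its model-based p-values depend on software-specific settings;
the exact test is reproducible and appropriate at these sizes, and is
reported as such.

## The trial simulator

`trial_sim_config()` fixes the study conditions: 7 FMT and 7 placebo
recipients, 30 healthy dogs, one donor sequenced as 2 lots, 60
donor-specific ASVs over a 240-ASV background, transfer probability
0.30 per candidate ASV, depth 20,000 reads/sample, and clinical
trajectories with FDM ~ N(35, 5²) and FCS = 5 − 0.09·FDM + N(0, 0.397²)
(the implied Pearson correlation is −0.45/0.6 = −0.75, and relapse
probabilities default to the observed per-arm, per-phase rates of a
14-dog trial: 2/7 and 0.5 for FMT, 0.5 and 0 for placebo).

Communities are Dirichlet draws with a long-tailed concentration vector
(one dominant taxon — donors dominated by a single abundant species are
realistic); counts are multinomial at fixed depth.  Recipient pre-FMT
communities divide the background concentrations by
`dysbiosis_severity + 1` (default 4 + 1), lowering evenness and hence
Shannon diversity relative to healthy dogs; post-FMT placebo visits are
drift-only redraws, while FMT visits implant each transferred ASV at a
relative abundance of at least `transfer_floor/depth` (default 5/depth).

Two deliberate idealisations make ground truth exact: donor-specific
ASVs are disjoint from the background by default (set
`overlap_fraction > 0` to stress the pre-FMT exclusion logic at the
cost of ambiguous truth), and donor proportions are floored at
2·`transfer_floor`/depth so every donor ASV is detected and survives
singleton/doubleton removal.  Under these conditions the engraftment
module recovers the transferred sets exactly and the mean rate is a
binomial estimate of the transfer probability.  Consequences to keep in
mind: real data have no disjoint donor, detection is depth-limited, and
longitudinal autocorrelation beyond the drift redraw is not modelled —
passing simulation tests demonstrates correctness of the procedure, not
field performance.  One visible artifact: with a fully disjoint donor,
donor-specific ASVs rarely pass the 20% prevalence filter, so donor
samples can drop out of the scaled genus table with a logged zero-total
warning; this is the filters behaving as specified.

All randomness flows from the single config seed (the clinical
generator offsets it by one so microbiome and clinical draws are
independent streams); `make_fixture_dataset()` writes byte-identical
bundles for identical configs.

## Pipeline and reproducibility

`load_config()` validates a YAML config (exactly one of `input:` or
`simulate:`; unknown keys rejected with their paths) and fills every
parameter with its standard default — 30% prevalence, 0.97
winsorisation, low-count 4/20%, IQR drop 10%, "Other" 1%/1.4%, 999
permutations.  `run_pipeline()` executes ingest → filters → aggregation
→ scaling → the toggled stages, tags stage errors with the stage name,
collects warnings (zero-total samples, mixed-model fallbacks, excluded
dogs) into the JSON run report, and is bit-reproducible for a fixed
seed.  The engraftment stage is skipped with a logged reason when the
dataset has no donor or no FMT samples.  The thin CLI at
`inst/cli/fmtkit` wraps these functions; the package API is the primary
interface.

## Known limitations

* No rarefaction, Chao1/Faith PD, or ordination plotting (PCoA
  coordinates can be derived from the exported distance matrix).
* Engraftment is presence-based at ASV identity: no strain-level (SNV)
  resolution, no abundance weighting, no sequencing-depth correction of
  the denominator.
* The differential-abundance model adjusts for phase and dog only; no
  zero-inflation component.
* The simulator's clinical items are drawn to match their band
  (responders ≤ 3, relapsers > 3), not from a fitted item-level model.
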
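---
title: "Methods: lineage-tracking simulation and DFE inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-tracking simulation and DFE inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the generative model behind `simulate_evolution()`,
the estimators behind `run_cohort_pipeline()`, the numerical choices, and
the design decisions — including why each estimator safeguard exists and
what the package's problem sizes are calibrated to.

```{r setup}
library(lineagedfe)
```

## 1. The experimental design being modeled

A founding clone is tagged with `n_barcodes` random barcodes; the pool is
expanded to `Nf ≈ 1e12` cells, frozen, and used to found replicate
evolutions. Each evolution is a serial batch-transfer culture: cells grow
from a bottleneck of `N0` cells to saturation at `250·N0` (≈ 8 doublings),
then a 1:250 dilution founds the next cycle. Barcode amplicons are
sequenced at every cycle boundary at a finite read depth. Two facts drive
all of the statistics:

* **Establishment is stochastic.** A new beneficial mutation survives drift
  with probability ~`s` and becomes quasi-deterministic only once its
  subclone reaches ~`1/s` cells (its *establishment time* `τ` is the
  extrapolated generation at which that happens; `τ` may be negative).
* **Pre-existing mutations are shared.** Mutations arising during the
  barcoding expansion enter every replicate, with an effective per-lineage
  establishment far in the past. They must be identified (adaptive in both
  replicates, `τ < -2/s` in at least one) and excluded from rate
  estimates, because the rate-frequency inversion accounts for them
  analytically.

## 2. The forward simulator

`simulate_evolution()` propagates three compartments per replicate:

* **Founders** (neutral, one frequency per barcode) and **established
  subclones** evolve deterministically in frequency space:
  `f → f·e^{s - x̄(t)} / Z` per generation, with `x̄(t)` recomputed every
  generation as the frequency-weighted mean selection coefficient and `Z`
  renormalizing. Growth uses the per-generation factor `250^{1/8}` so that
  8 generations exactly regenerate the 1:250 dilution.
* **Small subclones** (below `small_pop_threshold = 1e4` cells) evolve in
  cell space by a Poisson branching process with offspring mean
  `250^{1/8}·e^{s - x̄}`, capturing establishment stochasticity. Crossing
  the threshold promotes a subclone to the deterministic compartment.
* **Mutation arrivals** are Poisson with rate `μ_total ×` (unmutated cells),
  assigned to barcodes multinomially and started at one cell (single-step
  regime: mutant subclones do not mutate again; arrivals are proportional
  to *unmutated* cells, a second-order distinction while the mutant
  fraction is small).

Bottlenecks are multinomial draws of `N0` cells (binomial thinning for the
cell-space compartment); reads are multinomial draws at the configured
depth (optionally Dirichlet-multinomial via `overdispersion`). Ground truth
records every subclone that survives at least one bottleneck — recording
each of the ~10^7 arrivals per replicate, most of which die within one
cycle, would be pointless — and per-generation arrival totals are kept in
the diagnostics.

**Pre-existing generator.** The expansion to `Nf` is modeled as
`G = ceil(log2 Nf)` doublings. A mutation arising when the population has
`N_k` cells founds a subclone whose final relative frequency is `W/N_k`
with `W ~ Exp(1)` (the size factor of a supercritical branching process),
so its inoculum cell count is Poisson(`N0·W/N_k`), a geometric mixture.
Doublings with `N_k ≫ N0` are sampled by exact geometric thinning: only
subclones contributing ≥ 1 inoculum cell are instantiated, with survival
probability `λ/(1+λ)`, `λ = N0/N_k`.

## 3. Estimators

### Mean fitness from the neutral band

Lineages whose read count stays within `[neutral_lo, neutral_hi]`
(20–30 reads at full depth; 5–10 for shallowly sequenced data) are too
small ever to have established a mutation; their summed frequency decays as
`exp(-X(t))`, giving `x̄` per interval and the cumulative `X(t)`. Two
safeguards matter on long experiments:

* **Windowed band** (`neutral_max_generation`): once `X(t)` reaches ~1.5,
  genuinely neutral lineages have decayed *out* of a band enforced at every
  timepoint; the survivors of such a filter are biased. Enforcing the band
  only through generation ~64 selects on early counts and lets the
  reference decay freely afterwards.
* **Contamination cap** (`neutral_cap_multiple`): a reference lineage that
  acquires a beneficial mutation grows out of band and flattens the
  apparent decay. A true in-band Poisson count essentially never doubles,
  so lineages whose count anywhere exceeds twice the band ceiling are
  dropped.

### Per-lineage fits

The advection-corrected log frequency `y(t) = ln f(t) + X(t) + ln N_eff`
is fitted by weighted least squares with weights equal to the read counts
(`var(ln c) ≈ 1/c`), skipping zero counts; `τ = -(a + ln s)/s` places the
fitted lineage at `1/s` cells. When `bottleneck_cells` is set, standard
errors add the **bottleneck drift** variance `≈ 1.2/(n0·G·T)` (`n0` cells
carried per bottleneck, `T` fitted time span): for small lineages drift
dominates counting noise, and without this term their random walks
masquerade as selection.

Because a mutant lineage is a *mixture* — decaying unmutated founder cells
plus the expanding subclone — a straight line through the early plateau
biases `s` downward (~0.01 at the diploidization peak). For candidate
lineages, `refine_lineage_fits()` fits `y = ln(A + B e^{st})` by
Nelder–Mead from multiple starts and replaces `s` and `τ`. A refined
lineage is flagged adaptive only if its fitted mutant share at the final
generation is ≥ 0.5 **and** one of three channels fires: (i) the raw line
slope clears the detection threshold; (ii) the curvature improvement
`ΔSSE(line → two-component)` exceeds the 0.999 quantile of the same
statistic on neutral-reference lineages (an empirical null for drift,
which produces slow trends but not a flat-then-exponential bend); or
(iii) the mutant share is ≥ 0.75 with a line slope ≥ half the threshold.
These gates exist because a flexible two-component model happily hangs a
high-`s`, tiny-amplitude component on one noisy late count; calibrating
against the cohort's own neutral lineages rejects exactly that.

### Rate spectrum

Adaptive, non-pre-existing lineages are binned by fitted `s` on a
half-open grid of width `ds = 0.002` from the detection threshold (0.02).
Each bin's frequency — advection-corrected by `e^{X(t_ref)}`, since the
rate-frequency relation lives in the decaying neutral frame, and weighted
by the fitted mutant share — is inverted through the implicit relation
(Section 4) at the bin midpoint, with error `sqrt(μ ds / N_eff)`.

### Everything downstream

Diploid curation takes experimentally verified diploids flagged
pre-existing with fitted `s < 0.1` and forms a t-interval on their mean
fitness; non-pre-existing adaptive lineages inside that interval give a
conservative *lower bound* on the diploidization rate (per-lineage
single-clone inversion, summed). Pooled assays estimate per-interval
log-ratio slopes against a neutral set with counting-noise variances and
combine them — and technical replicates — by inverse variance. The
mutation-catalog tools apply the standard filter cascade (coverage,
mitochondrial, alignment-blacklisted genes, ancestral recurrence,
low-quality singletons; first matching rule attributed), tally multi-hit
genes, and test the loss-of-function fraction between adaptation steps
with a Yates-corrected chi-square (Fisher cross-check reported).

## 4. Numerical choices

The bin rate solves `g(μ ds) = μ ds·[1 + s·ln(Nf·μ ds)] - f·s·e^{-st} = 0`.
`g` is increasing only for `μ ds > e^{-(1+s)/s}/Nf`; `solve_mu()` bisects
*in log rate* on that monotone branch, 100 iterations to a relative width
~1e-13. Log-space bisection (rather than linear bisection to an absolute
tolerance) is what makes round trips `solve(forward(m)) = m` accurate to
1e-8 *relative* down to `m ~ 1e-9`, where any absolute tolerance larger
than 1e-17 would fail. Bin edges are rounded to 9 decimals so nominal
boundaries (0.036, 0.05, …) behave exactly in comparisons and interval
sums.

The Nelder–Mead refinement is started from the log-linear fit and from
2× and 4× its slope: the objective is nearly flat in `s` when the mutant
is visible only late, and a single start settles near its initialization.

## 5. Problem sizes (a package choice)

All simulation scales in the tests and stock configurations are the
package's own choice, set by one dimensionless quantity: **reads per
effective cell**, `depth / (N0 · gens_per_cycle)`. The sequencing floor —
the smallest subclone visible above Poisson read noise — is set by this
ratio, so a smaller cohort with the same ratio sits in the same detection
regime as a large one.

* `recovery_sim_config()`: 1e5 barcodes, `N0 = 8e6`, depth 3e6
  → 0.047 reads/cell, the full-coverage regime in which rate spectra are
  quantitatively recoverable; 17 cycles (136 generations), 2 replicates.
  Runtime ~2 min per cohort.
* Compression comparisons: 2e4 barcodes, `N0 = 4e6`, depth 1.5e6 — the
  same ratio, one fifth the cost, used where only the *direction* of a
  difference is asserted (refinement off so both arms are processed
  identically).
* Detection-limit checks: depth 1.6e5 over the same cohort
  → 0.005 reads/cell, deliberately the *shallow* regime (neutral band
  5–10) in which lineages with `s < 0.02` remain below the floor for the
  whole experiment.

## 6. Known limitations

* The recovered total rate at desk scale sits at ~0.6–0.9× of truth: the
  pre-existing term `s·ln(Nf·μ ds)` of the inversion attributes part of
  each bin's frequency to expansion-derived mutants even after flagged
  pre-existing lineages are excluded, and clonal interference among strong
  tail mutants suppresses some establishment that the single-lineage
  theory assumes. Both effects are properties of the method, not of the
  implementation.
* The simulator is single-step: double mutants and adaptation of already
  mutated subclones are out of scope, so late-time dynamics (mutant
  fraction ≳ 50%) are increasingly approximate.
* The two-component refinement reports the log-linear standard error as a
  conservative uncertainty; it does not propagate uncertainty in `X(t)`.
* `diploid_rate_lower_bound()` is a lower bound by construction: it counts
  only lineages whose fitted fitness falls inside the curated diploid
  confidence interval and which pass the adaptive gates.

## 7. Reproducibility

Every stochastic function takes a seed (`sim_config(seed = )`,
`simulate_preexisting(seed = )`, `downsample_counts(seed = )`); identical
configurations are bitwise reproducible. `scripts/acceptance.R` derives
all sub-seeds from its `--seed` argument and writes its results as JSON.
Pipeline configurations round-trip through YAML
(`save_pipeline_config()` / `load_pipeline_config()`), including DFE
components; unknown keys are rejected rather than silently ignored.
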
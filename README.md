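# lineagedfe

Inference of the distribution of fitness effects (DFE) of beneficial
mutations from barcoded lineage-tracking evolution experiments, with a
forward simulator of serial-transfer evolution to validate every estimator
against known ground truth.

## Scientific background

In a barcoded evolution experiment, hundreds of thousands of neutral DNA
barcodes are inserted into a founding clone; the pool then evolves by serial
batch transfer (here 1:250 dilution, ~8 generations of regrowth per cycle)
and is sequenced at every cycle. A lineage that acquires a beneficial
mutation with selection coefficient `s` rises exponentially against the
population mean fitness, so the read-count trajectory of each barcode
carries enough information to

1. estimate the **population mean fitness** `x̄(t)` from the collective decay
   of lineages whose counts sit in a low "neutral band" (they are too small
   to have acquired mutations, so their summed frequency decays as
   `exp(-∫x̄ dt)`);
2. fit a **selection coefficient and establishment time** `(s, τ)` per
   lineage by weighted regression of the advection-corrected log frequency
   `ln f(t) + X(t)`;
3. convert the summed frequency `f` of lineages in each fitness bin
   `[s, s+ds)` into a **beneficial-mutation rate** `μ(s)·ds` through the
   implicit relation

   ```
   μ ds · [1 + s·ln(Nf·μ ds)] = f · s · e^{-s t}
   ```

   whose second term accounts for mutations that pre-existed the experiment
   (they arose during the expansion of the barcoded pool to `Nf ≈ 1e12`
   cells and are therefore shared between replicate evolutions), with
   counting-noise error `sqrt(μ ds / N)`.

The package also implements the surrounding analyses of such a study:
pre-existing-mutation classification across replicates, curation of
spontaneously diploidized lineages and a conservative lower bound on the
diploidization rate, pooled competition assays for clone fitness
(log-ratio slopes combined by inverse variance), mutation-catalog filters
and spectrum statistics (loss-of-function contingency, multi-hit genes,
additive expectations for double mutants).

All tabular data are plain tibbles (`barcode` + `gen_<G>` count columns),
so every step composes with dplyr; models expose `tidy()`/`glance()` and
plots are available via `autoplot()` and `plot_*()`.

## Worked example

Simulate two replicate evolutions of 20,000 barcoded lineages for 17 cycles
(136 generations) under a DFE with an autodiploidization point mass
(rate 1e-5 at s = 0.035) plus an exponential tail of spontaneous beneficial
mutations (rate 1e-5, mean 0.03 above s = 0.02), then run the full
inference:

```r
library(lineagedfe)

cfg <- sim_config(
  n_barcodes = 2e4, bottleneck_cells = 4e6, cycles = 17, read_depth = 6e5,
  dfe = dfe_model(dfe_point(rate = 1e-5, s = 0.035),
                  dfe_tail(rate = 1e-5, mean_s = 0.03, s_min = 0.02, s_max = 0.16)),
  seed = 42, n_replicates = 2)

inf <- inference_config(
  neutral_lo = 20, neutral_hi = 30,        # read band defining the neutral set
  n_eff = 4e6 * 8,                         # effective population size
  neutral_max_generation = 64,             # band enforced on early timepoints
  neutral_cap_multiple = 2,                # drop contaminated reference lineages
  bottleneck_cells = 4e6)                  # drift-aware standard errors

out <- run_cohort_pipeline(cfg, inf)
out$summaries
#>   replicate peak_fitness rate_at_peak rate_gt_005 total_detectable_rate
#> 1         1        0.037      7.1e-06     9.0e-07               9.7e-06
#> 2         2        0.033      7.3e-06     7.1e-07               9.0e-06
```

Both replicates place the diploidization peak at s ≈ 0.033–0.037 per
generation (truth: 0.035) and recover a total detectable rate of
~0.9–1.0e-5 against a true detectable rate of 2e-5 — at this reduced depth
(0.019 reads per effective cell) part of the tail sits below the sequencing
floor; at the package's full recovery scale
(`recovery_sim_config()`, 0.047 reads/cell) totals come in at 0.7–0.9× of
truth. Repeating the run with `recovery_dfe("second")` — the tail compressed
tenfold in rate and maximal effect, the diminishing-returns spectrum of an
already-adapted background — drops the inferred strong-effect rate
(`rate_gt_005`) by an order of magnitude.

Downstream pieces:

```r
fits <- out$fits[[1]]                   # per-lineage (s, tau) fits, flags
glance(fits)                            # counts of fittable/adaptive/pre-existing
autoplot(out$spectra[[1]])              # mu(s) bar spectrum with error bars
autoplot(out$mean_fitness[[1]])         # mean-fitness track
plot_trajectories(out$sim$counts[[1]])  # lineage fan plot

# establishment/detection deadlines: s = 0.02, mean fitness crosses at gen 90
detectability_deadline(0.02, t_crossing = 90, mode = "establish")  # 40
detectability_deadline(0.02, t_crossing = 90, n_e = 1000, mode = "detect")
#> -59.79  (~60 generations before the experiment starts)

# pooled competition assay: inverse-variance combination of replicates
combine_replicates(s = c(0.05, 0.07), se = c(0.01, 0.02))
#>       s          se
#> 1 0.054     0.00894

# loss-of-function contingency between first- and second-step mutations
lof_contingency_table(53, 42, 14, 41)$p_value
#> 0.0006017
```

## Installation and reproduction

The package is standard R: `R CMD INSTALL .` (dependencies: dplyr, tidyr,
purrr, tibble, readr, ggplot2, generics, rlang, withr, yaml).

* Unit, property and acceptance tests:
  `testthat::test_dir("tests/testthat", package = "lineagedfe")`
  (the acceptance file simulates several full cohorts and takes ~15 minutes).
* Headline quantities as JSON:
  `Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`.
  All randomness derives from `--seed`; identical seeds give identical JSON.
* Methods and design rationale: `vignettes/lineage-dfe-methods.Rmd`.
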
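# Shared cohort builders for simulation-based tests.
#
# Problem sizes are chosen so the whole suite stays within a desk-scale
# runtime; the rationale for each regime (reads per effective cell, founder
# cells per bottleneck) is laid out in the methods vignette.

# minimal config for fast structural tests
tiny_config <- function(seed = 1L, n_barcodes = 200, cycles = 3,
                        bottleneck_cells = 2e4, read_depth = 5e3,
                        dfe = dfe_model(), ...) {
  sim_config(n_barcodes = n_barcodes, cycles = cycles,
             bottleneck_cells = bottleneck_cells, read_depth = read_depth,
             dfe = dfe, seed = seed, ...)
}

# mid-size cohort for the compression comparison: one fifth of the recovery
# cohort's barcodes at the same reads-per-effective-cell ratio (~0.047)
compression_sim_config <- function(seed, step = "first") {
  sim_config(n_barcodes = 2e4, bottleneck_cells = 4e6, cycles = 17,
             read_depth = 1.5e6, dfe = recovery_dfe(step), seed = seed,
             n_replicates = 2)
}

compression_inference_config <- function() {
  inference_config(neutral_lo = 20, neutral_hi = 30, n_eff = 4e6 * 8,
                   neutral_max_generation = 64, neutral_cap_multiple = 2,
                   bottleneck_cells = 4e6)
}

# detection-limit cohort: reads per effective cell ~0.005, the regime of the
# emulated experiments, where sub-threshold (s < 0.02) lineages stay below
# the sequencing floor; band 5-10 as used for ~matching depths
detection_sim_config <- function(seed, sub_threshold = TRUE) {
  dfe <- if (sub_threshold) dfe_model(dfe_point(rate = 1e-4, s = 0.015))
         else dfe_model()
  sim_config(n_barcodes = 2e4, bottleneck_cells = 4e6, cycles = 17,
             read_depth = 1.6e5, dfe = dfe, seed = seed, n_replicates = 2)
}

detection_inference_config <- function() {
  inference_config(neutral_lo = 5, neutral_hi = 10, n_eff = 4e6 * 8,
                   neutral_max_generation = 64, neutral_cap_multiple = 2,
                   bottleneck_cells = 4e6)
}

# run neutral selection + mean fitness + fits (+ optional refinement) on one
# replicate matrix
fit_replicate <- function(counts, inf, refine = FALSE) {
  nb <- select_neutral_reference(counts, inf)
  tr <- estimate_mean_fitness(counts, nb, inf)
  fits <- fit_lineages(counts, tr, inf, nb)
  if (refine) fits <- refine_lineage_fits(fits, counts, tr, inf)
  list(neutral = nb, track = tr, fits = fits)
}

# small pooled assay with known clone effects
make_assay_clones <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      barcode = sprintf("clone%03d", seq_len(n)),
      s = c(rep(0, n %/% 2), runif(n - n %/% 2, 0.01, 0.10))
    )
  })
}

assay_sim_config <- function(seed = 1) {
  sim_config(n_barcodes = 100, bottleneck_cells = 1e6, read_depth = 1e6,
             seed = seed)
}
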
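#' Configuration of a simulated barcoded serial-transfer evolution
#'
#' Defaults follow the study conditions the simulator emulates: ~7e5 barcoded
#' founders, 20 two-day transfer cycles of ~8 generations each, a 1:250
#' bottleneck with ~8e7 cells transferred (saturation = bottleneck x 250), a
#' barcoding expansion to Nf = 1e12 cells generating pre-existing mutations
#' shared between replicate evolutions, and finite sequencing depth of ~3e6
#' reads per timepoint.
#'
#' @param n_barcodes Number of barcoded founder lineages.
#' @param cycles Number of growth/transfer cycles to simulate.
#' @param gens_per_cycle Generations per cycle; must equal
#'   `round(log2(dilution))` (8 for a 1:250 dilution).
#' @param bottleneck_cells Cells transferred at each bottleneck.
#' @param dilution Dilution denominator (250 for 1:250); saturation cell count
#'   is `bottleneck_cells * dilution`.
#' @param read_depth Per-timepoint sequencing depths (recycled across the
#'   `cycles + 1` sampled timepoints).
#' @param nf Largest population size reached during the barcoding expansion;
#'   source of pre-existing mutations.
#' @param dfe [dfe_model()] of beneficial mutations arising during evolution.
#' @param preexisting_dfe [dfe_model()] of mutations arising during the
#'   barcoding expansion (defaults to `dfe`).
#' @param small_pop_threshold Cell count below which a mutant subclone is
#'   propagated by a stochastic per-generation Poisson branching process;
#'   at or above it the subclone grows deterministically.
#' @param founder_sdlog Log-normal spread (sdlog) of founder inoculum
#'   frequencies; 0 gives exactly equal founders.
#' @param sampling_noise If `FALSE`, all stochastic steps (branching offspring,
#'   bottleneck sampling, read sampling, mutation arrivals) are replaced by
#'   their deterministic expectations; only explicitly seeded mutants evolve.
#' @param overdispersion Optional Dirichlet-multinomial concentration parameter
#'   for read sampling; `NULL` (default) gives pure multinomial sampling.
#' @param n_replicates Number of replicate evolutions founded from the same
#'   barcoded pool.
#' @param seed Integer seed controlling all randomness of the simulation.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_barcodes = 7e5,
                       cycles = 20,
                       gens_per_cycle = 8,
                       bottleneck_cells = 8e7,
                       dilution = 250,
                       read_depth = 3e6,
                       nf = 1e12,
                       dfe = dfe_model(),
                       preexisting_dfe = NULL,
                       small_pop_threshold = 1e4,
                       founder_sdlog = 0.5,
                       sampling_noise = TRUE,
                       overdispersion = NULL,
                       n_replicates = 2,
                       seed = 1L) {
  if (n_barcodes < 1) stop_lineagedfe("`n_barcodes` must be positive", class = "lineagedfe_config_error")
  if (any(read_depth <= 0)) {
    stop_lineagedfe("`read_depth` must be positive at every timepoint",
                    class = "lineagedfe_config_error")
  }
  if (bottleneck_cells <= 0 || dilution <= 1) {
    stop_lineagedfe("`bottleneck_cells` must be positive and `dilution` > 1",
                    class = "lineagedfe_config_error")
  }
  if (gens_per_cycle != round(log2(dilution))) {
    stop_lineagedfe(
      sprintf("`gens_per_cycle` (%d) must equal round(log2(dilution)) = %d",
              gens_per_cycle, round(log2(dilution))),
      class = "lineagedfe_config_error")
  }
  if (!inherits(dfe, "dfe_model")) stop_lineagedfe("`dfe` must be a dfe_model")
  if (is.null(preexisting_dfe)) preexisting_dfe <- dfe
  if (!inherits(preexisting_dfe, "dfe_model")) {
    stop_lineagedfe("`preexisting_dfe` must be a dfe_model")
  }
  structure(list(
    n_barcodes = as.integer(n_barcodes),
    cycles = as.integer(cycles),
    gens_per_cycle = as.integer(gens_per_cycle),
    bottleneck_cells = bottleneck_cells,
    dilution = dilution,
    saturation_cells = bottleneck_cells * dilution,
    read_depth = read_depth,
    nf = nf,
    dfe = dfe,
    preexisting_dfe = preexisting_dfe,
    small_pop_threshold = small_pop_threshold,
    founder_sdlog = founder_sdlog,
    sampling_noise = isTRUE(sampling_noise),
    overdispersion = overdispersion,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %s barcodes, %d cycles x %d generations, 1:%g bottleneck (%g -> %g cells)\n",
              format(x$n_barcodes, big.mark = ","), x$cycles, x$gens_per_cycle,
              x$dilution, x$bottleneck_cells, x$saturation_cells))
  cat(sprintf("  read depth %s, Nf = %g, %d replicates, seed %d\n",
              paste(format(unique(x$read_depth), scientific = TRUE), collapse = "/"),
              x$nf, x$n_replicates, x$seed))
  cat(sprintf("  evolution DFE rate %g, pre-existing DFE rate %g\n",
              dfe_total_rate(x$dfe), dfe_total_rate(x$preexisting_dfe)))
  invisible(x)
}

# sampled generation grid: cycle boundaries 0, G, 2G, ...
sim_generations <- function(config) {
  seq(0L, config$cycles * config$gens_per_cycle, by = config$gens_per_cycle)
}

# per-timepoint depths, recycled over the grid
sim_depths <- function(config) {
  gens <- sim_generations(config)
  rep_len(config$read_depth, length(gens))
}
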
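#' Curate pre-existing diploid lineages
#'
#' Experimentally verified diploids (e.g. by a benomyl sensitivity assay) that
#' are flagged pre-existing in the lineage fits form the curated reference
#' group for diploid fitness: their ploidy is known but, having diploidized
#' before the experiment, they do not contribute to the rate of diploidization
#' during evolution. Lineages with fitted `s >= max_s` are excluded to avoid
#' diploids carrying additional beneficial mutations.
#'
#' @param clone_records Tibble with columns `barcode` and `ploidy`
#'   (`"haploid"`/`"diploid"`/`"unknown"`).
#' @param fits `"lineage_fits"` with `pre_existing` flags resolved.
#' @param max_s Fitness cap for curation (default 0.1 per generation).
#' @param conf_level Confidence level of the t-interval on the curated mean.
#' @return An object of class `"diploid_curation"`: list with `barcodes`,
#'   `s` (curated fitness values), `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
curate_preexisting_diploids <- function(clone_records, fits, max_s = 0.1,
                                        conf_level = 0.95) {
  verified <- clone_records$barcode[clone_records$ploidy == "diploid"]
  j <- fits[fits$barcode %in% verified & fits$pre_existing &
              !is.na(fits$s) & fits$s < max_s, ]
  if (nrow(j) == 0L) {
    stop_lineagedfe("no curated pre-existing diploids; cannot form a fitness CI",
                    class = "lineagedfe_diploidy_error")
  }
  if (nrow(j) == 1L) {
    stop_lineagedfe("a single curated diploid gives a degenerate CI",
                    class = "lineagedfe_diploidy_error")
  }
  m <- mean(j$s)
  half <- qt(1 - (1 - conf_level) / 2, df = nrow(j) - 1) * sd(j$s) / sqrt(nrow(j))
  structure(list(barcodes = j$barcode, s = j$s, mean = m,
                 ci_lo = m - half, ci_hi = m + half, n = nrow(j)),
            class = "diploid_curation")
}

#' @export
print.diploid_curation <- function(x, ...) {
  cat(sprintf("<diploid_curation> n = %d, mean s = %.4f, %s CI [%.4f, %.4f]\n",
              x$n, x$mean, "95%", x$ci_lo, x$ci_hi))
  invisible(x)
}

#' @export
tidy.diploid_curation <- function(x, ...) {
  tibble(barcode = x$barcodes, s = x$s)
}

#' @export
glance.diploid_curation <- function(x, ...) {
  tibble(n = x$n, mean_s = x$mean, ci_lo = x$ci_lo, ci_hi = x$ci_hi)
}

#' Conservative lower bound on the diploidization rate
#'
#' Non-pre-existing lineages whose fitted fitness falls inside the curated
#' diploid confidence interval are classified as diploids that arose during
#' the evolution; each classified lineage's frequency at the reference
#' generation is inverted through the single-lineage form of the
#' rate-frequency relation ([solve_mu()] at the lineage's own `s`), and the
#' per-lineage rates are summed. Because the curated CI captures only a
#' subgroup of true diploids, the result is a conservative underestimate of
#' the diploidization rate.
#'
#' @param curation A `"diploid_curation"`.
#' @param fits `"lineage_fits"` of the replicate.
#' @param counts Barcode-count tibble of the replicate.
#' @param t_ref Reference generation (defaults to the last included one).
#' @param config An [inference_config()].
#' @param nf Barcoding-expansion population size.
#' @param mean_track Optional `"mean_fitness_track"` for the advection
#'   correction of lineage frequencies (as in [dfe_spectrum()]).
#' @return A list: `rate` (lower bound, mutations per cell per generation),
#'   `classified` (tibble of classified lineages with per-lineage rates).
#' @export
diploid_rate_lower_bound <- function(curation, fits, counts, t_ref = NULL,
                                     config = inference_config(), nf = 1e12,
                                     mean_track = NULL) {
  gens <- count_generations(counts)
  gens <- gens[gens <= config$max_generation]
  if (is.null(t_ref)) t_ref <- max(gens)
  col <- paste0("gen_", t_ref)
  if (!col %in% names(counts)) {
    stop_lineagedfe(sprintf("t_ref = %g is not a sampled generation", t_ref),
                    class = "lineagedfe_spectrum_error")
  }
  depth <- sum(counts[[col]])
  cls <- fits[!fits$pre_existing & !is.na(fits$s) &
                fits$s >= curation$ci_lo & fits$s <= curation$ci_hi &
                fits$adaptive, ]
  if (nrow(cls) == 0L) {
    return(list(rate = 0,
                classified = tibble(barcode = character(), s = double(),
                                    f = double(), mu = double())))
  }
  reads <- counts[[col]][match(cls$barcode, counts$barcode)]
  x_corr <- if (is.null(mean_track)) 1 else exp(mean_fitness_X(mean_track, t_ref))
  f <- ifelse(is.na(reads), 0, reads) / depth * x_corr
  mu <- solve_mu(f, cls$s, t_ref, nf = nf)
  list(rate = sum(mu),
       classified = tibble(barcode = cls$barcode, s = cls$s, f = f, mu = mu))
}

#' Deterministic model of the diploid fraction in an evolving population
#'
#' Minimal per-generation recursion containing the three determinants of the
#' diploid fraction: the diploidization rate `mu_dip` (conversions per cell
#' per generation), the diploid fitness advantage `s_dip`, and the population
#' mean fitness `x_bar(t)` of the non-diploid compartment. Each generation
#'
#' \deqn{f' = [f e^{s_{dip} - \bar{x}} + \mu_{dip} (1 - f)] / Z}
#'
#' with `Z = f e^{s_dip - x_bar} + (1 - f)` renormalizing frequencies.
#'
#' @param mu_dip Diploidization rate per cell per generation (`>= 0`).
#' @param s_dip Diploid selection coefficient per generation.
#' @param x_bar Mean fitness of the rest of the population: a scalar or a
#'   vector of length `generations`.
#' @param generations Number of generations to iterate.
#' @param f0 Initial diploid fraction.
#' @return Tibble `generation` (0..generations), `diploid_fraction`.
#' @export
diploid_fraction_model <- function(mu_dip, s_dip, x_bar = 0, generations = 160,
                                   f0 = 0) {
  stopifnot(mu_dip >= 0, f0 >= 0, f0 <= 1)
  xb <- rep_len(x_bar, generations)
  f <- numeric(generations + 1)
  f[1] <- f0
  for (g in seq_len(generations)) {
    grown <- f[g] * exp(s_dip - xb[g])
    z <- grown + (1 - f[g])
    f[g + 1] <- (grown + mu_dip * (1 - f[g])) / z
  }
  tibble(generation = 0:generations, diploid_fraction = f)
}
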
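#' Estimate clone fitness from a pooled competition assay
#'
#' Clones are competed against a common reference over successive growth
#' cycles; fitness per generation is the slope of the log-ratio of clone to
#' neutral reads. For each consecutive-timepoint interval,
#' `s_i = (delta ln f_clone - delta ln F_N) / gens_per_cycle` with `F_N` the
#' summed frequency of the neutral set; intervals with a zero count at either
#' endpoint (clone or neutral total) are dropped. Interval estimates are
#' combined by inverse-variance weighting with counting-noise variances
#' (`var(ln n) ~ 1/n` at each endpoint).
#'
#' @param assay Barcode-count tibble over the assay timepoints (e.g.
#'   `gen_0 .. gen_32`).
#' @param neutral_barcodes Character vector of neutral reference lineages
#'   (e.g. the ancestor lineage plus known neutral clones); must have reads at
#'   all timepoints in total.
#' @param gens_per_cycle Generations per competition cycle (default 8).
#' @return Tibble of class `"clone_fit"`: `barcode`, `s`, `se`, `n_intervals`,
#'   `estimable`. Clones with reads at fewer than two timepoints are returned
#'   with `estimable = FALSE`.
#' @export
estimate_clone_fitness <- function(assay, neutral_barcodes, gens_per_cycle = 8) {
  validate_counts(assay)
  if (length(neutral_barcodes) == 0L) {
    stop_lineagedfe("neutral set is empty", class = "lineagedfe_neutral_error")
  }
  cols <- gen_cols(assay)
  gens <- count_generations(assay)
  m <- as.matrix(assay[cols])
  depths <- colSums(m)
  ntot <- colSums(m[assay$barcode %in% neutral_barcodes, , drop = FALSE])
  if (any(ntot == 0)) {
    stop_lineagedfe("neutral reference has zero reads at a timepoint",
                    class = "lineagedfe_neutral_error")
  }
  dt <- diff(gens)
  # per-interval log-ratio slopes for every clone at once
  lf <- log(sweep(m, 2, depths, "/"))   # -Inf where zero
  lf[m == 0] <- NA_real_
  ln_n <- log(ntot / depths)
  n_tp <- length(cols)
  s_mat <- (lf[, -1, drop = FALSE] - lf[, -n_tp, drop = FALSE] -
              rep(diff(ln_n), each = nrow(m))) / rep(dt, each = nrow(m))
  var_mat <- (1 / m[, -1, drop = FALSE] + 1 / m[, -n_tp, drop = FALSE] +
                rep(1 / ntot[-1] + 1 / ntot[-n_tp], each = nrow(m))) /
    rep(dt^2, each = nrow(m))
  var_mat[!is.finite(s_mat)] <- NA_real_
  w <- 1 / var_mat
  w[is.na(s_mat)] <- NA_real_
  sw <- rowSums(w, na.rm = TRUE)
  s_hat <- rowSums(w * s_mat, na.rm = TRUE) / sw
  se <- 1 / sqrt(sw)
  n_int <- rowSums(!is.na(s_mat))
  estimable <- n_int >= 1
  out <- tibble(
    barcode = assay$barcode,
    s = ifelse(estimable, s_hat, NA_real_),
    se = ifelse(estimable, se, NA_real_),
    n_intervals = as.integer(n_int),
    estimable = estimable
  )
  class(out) <- c("clone_fit", class(out))
  out
}

#' Combine replicate fitness estimates by inverse-variance weighting
#'
#' @param s Vector of per-replicate fitness estimates.
#' @param se Vector of their standard errors.
#' @return One-row tibble `s`, `se` with
#'   `s = sum(s_i/se_i^2) / sum(1/se_i^2)` and `se = sqrt(1 / sum(1/se_i^2))`.
#' @examples
#' combine_replicates(c(0.05, 0.07), c(0.01, 0.02))  # 0.054 +/- 0.00894
#' @export
combine_replicates <- function(s, se) {
  keep <- is.finite(s) & is.finite(se) & se > 0
  if (!any(keep)) {
    return(tibble(s = NA_real_, se = NA_real_))
  }
  w <- 1 / se[keep]^2
  tibble(s = sum(s[keep] * w) / sum(w), se = 1 / sqrt(sum(w)))
}

#' Combine technical replicates of a pooled assay clone by clone
#'
#' @param fits List of `"clone_fit"` tibbles (one per technical replicate).
#' @return A `"clone_fit"` tibble with inverse-variance combined `s` and `se`
#'   per barcode.
#' @export
combine_clone_fits <- function(fits) {
  bind_rows(fits) |>
    group_by(.data$barcode) |>
    summarise(res = combine_replicates(.data$s, .data$se),
              n_replicates = sum(.data$estimable), .groups = "drop") |>
    tidyr::unpack("res") |>
    mutate(estimable = .data$n_replicates >= 1)
}

#' Two-pass pooled fitness estimation
#'
#' First pass: fitness is estimated against an internally inferred neutral
#' set (clones whose absolute first-pass fitness, measured against the
#' reference lineage alone, falls below the `neutral_quantile` of the
#' distribution). Second pass: when a curated list of known haploid neutral
#' clones is supplied, fitness is re-estimated against that list; otherwise
#' the first-pass neutral set is reused, making the call idempotent.
#'
#' @param assay Barcode-count tibble.
#' @param known_haploid_neutrals Optional character vector of neutral clone
#'   barcodes to use in the second pass.
#' @param reference_barcode The common reference lineage present in the assay.
#' @param neutral_quantile Quantile gate for the internal neutral inference.
#' @param gens_per_cycle Generations per cycle.
#' @return A list: `fits` (second-pass `"clone_fit"`), `neutral_set` (the
#'   barcodes used as neutrals in the final pass).
#' @export
two_pass_estimation <- function(assay, known_haploid_neutrals = NULL,
                                reference_barcode = "ancestor",
                                neutral_quantile = 0.25, gens_per_cycle = 8) {
  validate_counts(assay)
  if (nrow(assay) == 0L) {
    stop_lineagedfe("empty assay table")
  }
  if (!reference_barcode %in% assay$barcode) {
    stop_lineagedfe(sprintf("reference barcode '%s' not present in the assay",
                            reference_barcode))
  }
  pass1 <- estimate_clone_fitness(assay, reference_barcode, gens_per_cycle)
  cand <- pass1[pass1$estimable & pass1$barcode != reference_barcode, ]
  gate <- quantile(abs(cand$s), neutral_quantile, na.rm = TRUE, names = FALSE)
  inferred <- c(reference_barcode, cand$barcode[abs(cand$s) <= gate])
  if (is.null(known_haploid_neutrals)) {
    neutral_set <- inferred
  } else {
    neutral_set <- intersect(c(reference_barcode, known_haploid_neutrals),
                             assay$barcode)
    if (length(intersect(known_haploid_neutrals, assay$barcode)) == 0L) {
      stop_lineagedfe("supplied neutral list shares no barcode with the assay",
                      class = "lineagedfe_neutral_error")
    }
  }
  list(fits = estimate_clone_fitness(assay, neutral_set, gens_per_cycle),
       neutral_set = neutral_set)
}

#' Classify assayed clones by ploidy and fitness
#'
#' Haploids are `neutral_haploid` when their fitness lies within `z_class`
#' reference standard deviations of the ancestor reference mean and
#' `adaptive_haploid` above it; diploids are `high_fitness_diploid` when
#' their fitness exceeds the diploid reference mean by more than `z_class`
#' reference standard deviations and `pure_diploid` otherwise. Clones with
#' unknown ploidy receive class `unknown`.
#'
#' @param records Tibble with columns `barcode`, `s` and `ploidy`.
#' @param ancestor_reference Numeric vector of reference fitness values for
#'   the (haploid) ancestor distribution.
#' @param diploid_reference Numeric vector of reference fitness values for
#'   pure diploids.
#' @param z_class Standard-deviation multiple defining "similar" vs
#'   "significantly higher" (default 2).
#' @return `records` with a `class` column.
#' @export
classify_clones <- function(records, ancestor_reference, diploid_reference,
                            z_class = 2) {
  mu_a <- mean(ancestor_reference); sd_a <- sd(ancestor_reference)
  mu_d <- mean(diploid_reference); sd_d <- sd(diploid_reference)
  records |>
    mutate(class = dplyr::case_when(
      .data$ploidy == "haploid" & .data$s > mu_a + z_class * sd_a ~ "adaptive_haploid",
      .data$ploidy == "haploid" ~ "neutral_haploid",
      .data$ploidy == "diploid" & .data$s > mu_d + z_class * sd_d ~ "high_fitness_diploid",
      .data$ploidy == "diploid" ~ "pure_diploid",
      TRUE ~ "unknown"
    ))
}
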
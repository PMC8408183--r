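#' Forward and inverse mutation-rate relation for a fitness bin
#'
#' The summed frequency `f` at generation `t` of lineages carrying mutations
#' with fitness in a bin `[s, s + ds]` is tied to the per-cell per-generation
#' mutation rate `mu * ds` of that bin by the implicit relation
#'
#' \deqn{\mu ds [1 + s \ln(N_f \mu ds)] = f s e^{-s t}}
#'
#' with `nf` the largest population size reached during the barcoding
#' expansion: the `1` accounts for mutations arising during the evolution and
#' the `s ln(Nf mu ds)` term for pre-existing mutations from the expansion.
#' `mu_forward()` evaluates the frequency implied by a rate; `solve_mu()`
#' inverts it by bisection (in log rate) on the monotone branch
#' `m > exp(-(1+s)/s) / nf`, to relative tolerance ~1e-13.
#'
#' @param mu_ds Bin mutation rate `mu(s) * ds`, mutations per cell per
#'   generation.
#' @param f Summed lineage frequency of the bin at generation `t` (`>= 0`).
#' @param s Bin fitness coefficient (per generation, `> 0`).
#' @param t Generation at which `f` is measured.
#' @param nf Barcoding-expansion population size (default 1e12).
#' @return `mu_forward()`: the frequency `f`; `solve_mu()`: the rate `mu_ds`
#'   (0 when `f = 0`). Both are vectorized over their first argument.
#' @export
mu_forward <- function(mu_ds, s, t, nf = 1e12) {
  mu_ds * (1 + s * log(nf * mu_ds)) * exp(s * t) / s
}

#' @rdname mu_forward
#' @export
solve_mu <- function(f, s, t, nf = 1e12) {
  stopifnot(length(s) %in% c(1L, length(f)), length(t) %in% c(1L, length(f)))
  s <- rep_len(s, length(f))
  t <- rep_len(t, length(f))
  out <- numeric(length(f))
  for (i in seq_along(f)) {
    if (f[i] < 0) stop_lineagedfe("`f` must be nonnegative")
    if (s[i] <= 0) stop_lineagedfe("`s` must be positive")
    if (f[i] == 0) { out[i] <- 0; next }
    rhs <- f[i] * s[i] * exp(-s[i] * t[i])
    g <- function(lm) { m <- exp(lm); m * (1 + s[i] * log(nf * m)) - rhs }
    lo <- max(log(1e-300), -(1 + s[i]) / s[i] - log(nf) + 1e-9)
    hi <- 0  # m = 1
    if (g(lo) > 0 || g(hi) < 0) {
      stop_lineagedfe(sprintf(
        "no sign change when bracketing mu: g(lo) = %g, g(hi) = %g (f = %g, s = %g, t = %g)",
        g(lo), g(hi), f[i], s[i], t[i]), class = "lineagedfe_solver_error")
    }
    for (iter in 1:100) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-13) break
    }
    out[i] <- exp((lo + hi) / 2)
  }
  out
}

#' Estimate the beneficial-mutation rate spectrum mu(s)
#'
#' Adaptive, non-pre-existing lineages are binned by their fitted selection
#' coefficient on a half-open grid `[s_lo, s_lo + ds)` rising from the
#' detection threshold; each bin's summed read frequency at the reference
#' generation is inverted through [solve_mu()] into a per-bin mutation rate,
#' with counting-noise standard error `sqrt(mu_ds / n_eff)`.
#'
#' @param fits `"lineage_fits"` with `pre_existing` flags resolved (flagged
#'   lineages are excluded, as are neutral-reference lineages).
#' @param counts Barcode-count tibble of the same replicate.
#' @param t_ref Reference generation at which bin frequencies are read; must
#'   lie on the generation grid. Defaults to the last included generation.
#' @param config An [inference_config()] (supplies `detection_threshold` and
#'   `n_eff`).
#' @param ds Bin width in fitness (default 0.002 per generation).
#' @param s_max Upper end of the binned fitness axis.
#' @param nf Barcoding-expansion population size.
#' @param mean_track Optional `"mean_fitness_track"`. When supplied, bin
#'   frequencies are corrected for mean-fitness advection by `e^{X(t_ref)}`
#'   (i.e. measured relative to the decaying neutral reference), which the
#'   rate-frequency relation assumes; without it raw frequencies are used,
#'   underestimating rates once the adapted fraction is appreciable.
#' @return A tibble of class `"dfe_spectrum"`: `s_lo`, `s_hi`, `s_mid`, `f`
#'   (bin summed frequency, after the advection correction when requested),
#'   `n_lineages`, `mu_ds`, `err`.
#' @export
dfe_spectrum <- function(fits, counts, t_ref = NULL,
                         config = inference_config(), ds = 0.002,
                         s_max = 0.3, nf = 1e12, mean_track = NULL) {
  gens <- count_generations(counts)
  gens <- gens[gens <= config$max_generation]
  if (is.null(t_ref)) t_ref <- max(gens)
  if (!t_ref %in% gens) {
    stop_lineagedfe(sprintf("t_ref = %g is not on the included generation grid (%s)",
                            t_ref, paste(gens, collapse = ", ")),
                    class = "lineagedfe_spectrum_error")
  }
  col <- paste0("gen_", t_ref)
  depth <- sum(counts[[col]])
  x_corr <- if (is.null(mean_track)) 1 else exp(mean_fitness_X(mean_track, t_ref))

  use <- fits$adaptive & !fits$pre_existing & !fits$neutral_ref & !is.na(fits$s)
  sel <- tibble(barcode = fits$barcode[use], s = fits$s[use])
  # a refined lineage's frequency is split between its mutant subclone and
  # residual unmutated founder cells; only the mutant share enters the bin
  share <- if ("mutant_share" %in% names(fits)) fits$mutant_share[use] else NULL
  sel$share <- if (is.null(share)) 1 else ifelse(is.na(share), 1, share)
  sel <- dplyr::left_join(sel,
                          dplyr::select(counts, "barcode", reads = dplyr::all_of(col)),
                          by = "barcode")
  sel$f <- sel$reads / depth * x_corr * sel$share

  # round away accumulated floating-point error so nominal edge values
  # (0.036, 0.05, ...) behave as exact bin boundaries
  edges <- round(seq(config$detection_threshold, s_max, by = ds), 9)
  bins <- tibble(
    s_lo = edges[-length(edges)],
    s_hi = edges[-1]
  )
  bins$s_mid <- (bins$s_lo + bins$s_hi) / 2
  # half-open bins [s_lo, s_hi): ties at an edge go to the upper bin
  idx <- findInterval(sel$s, edges, rightmost.closed = FALSE)
  ok <- idx >= 1 & idx <= nrow(bins)
  fsum <- rep(0, nrow(bins))
  nsum <- rep(0L, nrow(bins))
  if (any(ok)) {
    agg <- rowsum(sel$f[ok], idx[ok])
    fsum[as.integer(rownames(agg))] <- agg[, 1]
    cnt <- table(idx[ok])
    nsum[as.integer(names(cnt))] <- as.integer(cnt)
  }
  bins$f <- fsum
  bins$n_lineages <- nsum
  bins$mu_ds <- solve_mu(bins$f, bins$s_mid, t_ref, nf = nf)
  bins$err <- sqrt(bins$mu_ds / config$n_eff)
  class(bins) <- c("dfe_spectrum", class(bins))
  attr(bins, "t_ref") <- t_ref
  attr(bins, "ds") <- ds
  attr(bins, "n_eff") <- config$n_eff
  bins
}

#' Summarize a mutation-rate spectrum
#'
#' Condenses per-bin rates into the headline quantities: the diploidization
#' peak (the maximal-rate bin with `s_lo < 0.05`, where autodiploidization
#' shows up as a peak at s ~ 3-4% per generation), the rate within +/- 0.01 of
#' the peak, interval rates above 0.05, within 0.07-0.12 and above 0.12, and
#' the total detectable rate. Sums use the half-open bin convention
#' `[s_lo, s_hi)`.
#'
#' @param bins A `"dfe_spectrum"` tibble.
#' @param peak_window Half-width of the window summed around the peak.
#' @return One-row tibble: `peak_fitness`, `rate_at_peak`, `rate_gt_005`,
#'   `rate_007_012`, `rate_gt_012`, `total_detectable_rate`.
#' @export
summarize_spectrum <- function(bins, peak_window = 0.01) {
  if (nrow(bins) == 0L) {
    stop_lineagedfe("empty spectrum", class = "lineagedfe_spectrum_error")
  }
  low <- bins[bins$s_lo < 0.05, , drop = FALSE]
  peak <- if (nrow(low) && any(low$mu_ds > 0)) {
    low$s_mid[which.max(low$mu_ds)]
  } else NA_real_
  in_window <- if (is.na(peak)) rep(FALSE, nrow(bins)) else
    bins$s_hi > peak - peak_window & bins$s_lo < peak + peak_window
  tibble(
    peak_fitness = peak,
    rate_at_peak = sum(bins$mu_ds[in_window]),
    rate_gt_005 = sum(bins$mu_ds[bins$s_lo >= 0.05]),
    rate_007_012 = sum(bins$mu_ds[bins$s_lo >= 0.07 & bins$s_hi <= 0.12]),
    rate_gt_012 = sum(bins$mu_ds[bins$s_lo >= 0.12]),
    total_detectable_rate = sum(bins$mu_ds)
  )
}

#' @export
glance.dfe_spectrum <- function(x, ...) summarize_spectrum(x, ...)
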
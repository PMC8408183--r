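#' Configuration of lineage fitness inference
#'
#' @param neutral_lo,neutral_hi Read-count band defining the neutral reference
#'   set: lineages whose count lies in `[neutral_lo, neutral_hi]` at every
#'   included timepoint. Defaults 20-30 for deeply sequenced data; use 5-10
#'   for data down-sampled to ~3e6 reads per timepoint.
#' @param detection_threshold Smallest selection coefficient (per generation)
#'   treated as detectable; lineages below it are never called adaptive.
#' @param n_e Lineage size (cells) entering the detectability formula.
#' @param n_eff Effective population size during evolution; converts lineage
#'   frequencies to sizes for establishment-time estimation and sets the
#'   counting-noise error of the mutation-rate spectrum.
#' @param max_generation Last generation used for inference (later timepoints
#'   are ignored).
#' @param z_adaptive Significance multiple: a lineage is called adaptive only
#'   if `s >= detection_threshold` and `s / se_s >= z_adaptive`.
#' @param neutral_max_generation Last generation at which the neutral band is
#'   enforced. By default (`Inf`) the band applies at every included
#'   timepoint; a finite window (e.g. 64) selects lineages on their early
#'   counts only, which keeps the reference set usable when the cumulative
#'   mean fitness is large enough that genuinely neutral lineages decay out
#'   of the band.
#' @param bottleneck_cells When set, per-lineage standard errors include the
#'   genetic-drift variance of the serial bottleneck in addition to counting
#'   noise: a lineage transferring `n` cells per bottleneck accumulates
#'   log-frequency variance `~1/n` per cycle, which dominates counting noise
#'   for small lineages and otherwise lets their random walks masquerade as
#'   selection. `NULL` (default) uses counting noise alone.
#' @param neutral_cap_multiple When finite, the mean-fitness estimator drops
#'   reference lineages whose count at *any* included timepoint exceeds
#'   `neutral_cap_multiple * neutral_hi`: such growth marks a beneficial
#'   mutation arising inside the lineage, which would otherwise contaminate
#'   the decay signal. Poisson fluctuations of true in-band neutrals
#'   essentially never reach twice the band ceiling, so 2 is a safe choice.
#' @return An object of class `"inference_config"`.
#' @export
inference_config <- function(neutral_lo = 20, neutral_hi = 30,
                             detection_threshold = 0.02,
                             n_e = 1000, n_eff = 6e8,
                             max_generation = 136, z_adaptive = 2,
                             bottleneck_cells = NULL,
                             neutral_max_generation = Inf,
                             neutral_cap_multiple = Inf) {
  if (!(0 < neutral_lo && neutral_lo < neutral_hi)) {
    stop_lineagedfe("need 0 < neutral_lo < neutral_hi",
                    class = "lineagedfe_config_error")
  }
  if (detection_threshold <= 0) {
    stop_lineagedfe("`detection_threshold` must be positive",
                    class = "lineagedfe_config_error")
  }
  structure(list(neutral_lo = neutral_lo, neutral_hi = neutral_hi,
                 detection_threshold = detection_threshold,
                 n_e = n_e, n_eff = n_eff,
                 max_generation = max_generation, z_adaptive = z_adaptive,
                 bottleneck_cells = bottleneck_cells,
                 neutral_max_generation = neutral_max_generation,
                 neutral_cap_multiple = neutral_cap_multiple),
            class = "inference_config")
}

# columns at or below max_generation
included_cols <- function(counts, config) {
  gens <- count_generations(counts)
  gen_cols(counts)[gens <= config$max_generation]
}

#' Select the neutral reference set
#'
#' Lineages whose read count lies within the configured band at every included
#' timepoint are treated as neutral; their collective decay measures the
#' population mean fitness.
#'
#' @param counts Barcode-count tibble (filtered).
#' @param config An [inference_config()].
#' @return Character vector of neutral barcodes.
#' @export
select_neutral_reference <- function(counts, config = inference_config()) {
  cols <- included_cols(counts, config)
  gens <- count_generations(counts)
  gens <- gens[gens <= config$max_generation]
  cols <- cols[gens <= config$neutral_max_generation]
  m <- as.matrix(counts[cols])
  ok <- rowSums(m >= config$neutral_lo & m <= config$neutral_hi) == length(cols)
  if (!any(ok)) {
    stop_lineagedfe(
      sprintf(paste0("no lineage stays within the %g-%g read band at all %d ",
                     "timepoints; widen the band or check depths"),
              config$neutral_lo, config$neutral_hi, length(cols)),
      class = "lineagedfe_neutral_error")
  }
  counts$barcode[ok]
}

#' Estimate population mean fitness from the neutral reference
#'
#' The summed read frequency `F_N(t)` of the neutral set decays as
#' `exp(-X(t))`, where `X(t)` is the running integral of the population mean
#' fitness. On each interval between consecutive included timepoints the mean
#' fitness is `x_bar = -(ln F_N(t2) - ln F_N(t1)) / (t2 - t1)`, and `X(t)` is
#' accumulated piecewise linearly with `X(0) = 0`.
#'
#' @param counts Barcode-count tibble.
#' @param neutral_barcodes Character vector from [select_neutral_reference()].
#' @param config An [inference_config()].
#' @return A tibble of class `"mean_fitness_track"`: `generation`, `F_N`
#'   (summed neutral frequency), `x_bar` (mean fitness on the interval
#'   starting at this timepoint; `NA` for the last) and `X` (cumulative
#'   integral at this timepoint).
#' @export
estimate_mean_fitness <- function(counts, neutral_barcodes,
                                  config = inference_config()) {
  if (length(neutral_barcodes) == 0L) {
    stop_lineagedfe("neutral set is empty", class = "lineagedfe_neutral_error")
  }
  cols <- included_cols(counts, config)
  gens <- count_generations(counts)
  gens <- gens[gens <= config$max_generation]
  depths <- count_depths(counts)[cols]
  dt <- diff(gens)
  cap <- config$neutral_cap_multiple * config$neutral_hi

  m <- as.matrix(counts[counts$barcode %in% neutral_barcodes, cols, drop = FALSE])
  if (is.finite(cap)) {
    # Contamination control: a reference lineage whose count anywhere on the
    # trajectory exceeds the cap has almost certainly acquired a beneficial
    # mutation (a true neutral in the band essentially never fluctuates that
    # high) and is dropped from the reference set outright.
    keep <- apply(m, 1, max) <= cap
    if (!any(keep)) {
      stop_lineagedfe("all reference lineages exceed the contamination cap",
                      class = "lineagedfe_neutral_error")
    }
    m <- m[keep, , drop = FALSE]
  }
  fn <- colSums(m) / depths
  if (any(fn <= 0)) {
    stop_lineagedfe("neutral reference has zero reads at a timepoint",
                    class = "lineagedfe_neutral_error")
  }
  xb <- unname(-diff(log(fn)) / dt)
  out <- tibble(
    generation = gens,
    F_N = unname(fn),
    x_bar = c(xb, NA_real_),
    X = c(0, cumsum(xb * dt))
  )
  class(out) <- c("mean_fitness_track", class(out))
  out
}

# X(t) at arbitrary generations by piecewise-linear interpolation
mean_fitness_X <- function(track, t) {
  stats::approx(track$generation, track$X, xout = t, rule = 2)$y
}

#' Fit per-lineage selection coefficients and establishment times
#'
#' For each lineage the log frequency is corrected for mean-fitness advection,
#' `y(t) = ln f_i(t) + X(t) + ln n_eff`, and fitted by weighted least squares
#' `y = a + s t`, with weights equal to the read count (the counting-noise
#' variance of `ln f` is approximately `1/count`). Timepoints with zero count
#' are skipped; a lineage needs at least two usable timepoints, otherwise it
#' is returned with `fittable = FALSE` rather than an error. The establishment
#' time is `tau = -(a + ln s)/s` for `s > 0`, the time at which the fitted
#' lineage size reaches `1/s` cells, beyond which growth is
#' quasi-deterministic. A lineage is flagged adaptive when
#' `s >= detection_threshold` and `s/se_s >= z_adaptive`.
#'
#' @param counts Barcode-count tibble.
#' @param mean_track A `"mean_fitness_track"` from [estimate_mean_fitness()].
#' @param config An [inference_config()].
#' @param neutral_barcodes Optional; barcodes flagged `neutral_ref` in the
#'   output.
#' @return A tibble of class `"lineage_fits"`, one row per barcode: `barcode`,
#'   `s`, `se_s`, `tau`, `n_points`, `fittable`, `neutral_ref`, `adaptive`,
#'   `pre_existing` (initialized `FALSE`; see [classify_preexisting()]).
#' @export
fit_lineages <- function(counts, mean_track, config = inference_config(),
                         neutral_barcodes = character(0)) {
  cols <- included_cols(counts, config)
  gens <- count_generations(counts)
  gens <- gens[gens <= config$max_generation]
  m <- as.matrix(counts[cols])
  depths <- colSums(m)
  X <- mean_fitness_X(mean_track, gens)

  # y_it = ln(c_it / depth_t) + X(t) + ln n_eff, weight w_it = c_it (0 skipped)
  w <- m
  y <- log(sweep(m, 2, depths, "/")) + rep(X + log(config$n_eff), each = nrow(m))
  y[w == 0] <- 0

  tmat <- matrix(gens, nrow = nrow(m), ncol = length(gens), byrow = TRUE)
  sw <- rowSums(w)
  n_pts <- rowSums(w > 0)
  fittable <- n_pts >= 2
  sw[sw == 0] <- NA_real_
  tbar <- rowSums(w * tmat) / sw
  ybar <- rowSums(w * y) / sw
  sxx <- rowSums(w * (tmat - tbar)^2)
  sxy <- rowSums(w * (tmat - tbar) * ((w > 0) * (y - ybar)))
  s_hat <- sxy / sxx
  a_hat <- ybar - s_hat * tbar
  se_s <- 1 / sqrt(sxx)   # known counting-noise variance: var(y_it) = 1/c_it

  if (!is.null(config$bottleneck_cells)) {
    # bottleneck drift: per-cycle log-frequency variance ~ 1/(cells carried
    # through the bottleneck); for a random walk observed over a span T and
    # fitted by least squares, the slope picks up variance ~ 1.2 sigma_g^2 / T
    G <- median(diff(gens))
    n0 <- pmax(m[, 1] * config$bottleneck_cells / depths[1], 1)
    nz <- w > 0
    tspan <- gens[max.col(nz, "last")] - gens[max.col(nz, "first")]
    tspan[!is.finite(tspan) | tspan <= 0] <- NA_real_
    drift_var <- 1.2 / (n0 * G * tspan)
    se_s <- sqrt(se_s^2 + ifelse(is.na(drift_var), 0, drift_var))
  }

  # degenerate spreads (all weight at one timepoint)
  bad <- !is.finite(s_hat) | sxx <= 0
  s_hat[bad & fittable] <- 0
  fittable <- fittable & !bad

  tau <- rep(NA_real_, length(s_hat))
  pos <- which(fittable & s_hat > 0)
  tau[pos] <- -(a_hat[pos] + log(s_hat[pos])) / s_hat[pos]
  adaptive <- fittable & s_hat >= config$detection_threshold &
    (s_hat / se_s) >= config$z_adaptive

  out <- tibble(
    barcode = counts$barcode,
    s = ifelse(fittable, s_hat, NA_real_),
    se_s = ifelse(fittable, se_s, NA_real_),
    tau = tau,
    n_points = as.integer(n_pts),
    fittable = fittable,
    neutral_ref = counts$barcode %in% neutral_barcodes,
    adaptive = adaptive,
    pre_existing = FALSE,
    mutant_share = NA_real_
  )
  class(out) <- c("lineage_fits", class(out))
  attr(out, "config") <- config
  out
}

#' Refine adaptive lineage fits with a two-component trajectory model
#'
#' A barcode lineage carrying a beneficial mutation is a mixture: the
#' unmutated founder cells decay with the mean fitness while the mutant
#' subclone expands, so its advection-corrected log frequency
#' `y(t) = ln f(t) + X(t)` follows `ln(A + B e^{s t})` rather than a straight
#' line — fitting a single slope through the early neutral plateau biases
#' `s` downward, increasingly so for fit lineages. For the selected barcodes
#' (by default all flagged adaptive) this function minimizes the
#' count-weighted least-squares objective over `(A, B, s)` by Nelder-Mead,
#' initialized from the log-linear fit, and updates `s` and
#' `tau = -(ln(B n_eff) + ln s)/s` (the generation at which the mutant
#' subclone reaches `1/s` cells). The log-linear standard error is retained
#' as a conservative uncertainty, and lineages whose refined `s` falls below
#' the detection threshold lose their adaptive flag.
#'
#' @param fits `"lineage_fits"` from [fit_lineages()].
#' @param counts Barcode-count tibble the fits came from.
#' @param mean_track The `"mean_fitness_track"` used for the fits.
#' @param config The [inference_config()] used for the fits.
#' @param barcodes Barcodes to refine. The default takes every fittable,
#'   non-reference lineage whose log-linear slope reaches a quarter of the
#'   detection threshold: lineages whose mutant subclone is still comparable
#'   in size to their unmutated founder cells carry log-linear slopes well
#'   below their true `s`, and would otherwise be missed entirely.
#' @param min_mutant_share Minimum fitted mutant share of the lineage at the
#'   last included generation for an adaptive call. Requiring the expanding
#'   component to actually dominate its lineage rejects spurious
#'   high-`s`/tiny-amplitude components that a flexible two-component model
#'   can hang on a single noisy late count.
#' @param null_quantile A lineage whose straight-line slope is below the
#'   detection threshold is only promoted to adaptive by the two-component
#'   model if the weighted SSE improvement of the curved fit over the best
#'   straight line exceeds this quantile of the same improvement computed on
#'   the neutral reference lineages — an empirical null for bottleneck drift,
#'   which produces slow quasi-linear trends but not the flat-then-exponential
#'   bend of a genuine mutant subclone.
#' @return The updated `"lineage_fits"` tibble, with the adaptive flag
#'   recomputed from the refined coefficients and a `mutant_share` column
#'   giving each refined lineage's fitted mutant fraction at the last
#'   included generation.
#' @export
refine_lineage_fits <- function(fits, counts, mean_track,
                                config = inference_config(),
                                barcodes = NULL, min_mutant_share = 0.5,
                                null_quantile = 0.999) {
  if (is.null(barcodes)) {
    cand <- fits$fittable & !fits$neutral_ref & !is.na(fits$s) &
      (fits$s >= config$detection_threshold / 4 | fits$adaptive)
    barcodes <- fits$barcode[cand]
  }
  if (length(barcodes) == 0L) return(fits)
  cols <- included_cols(counts, config)
  gens <- count_generations(counts)
  gens <- gens[gens <= config$max_generation]
  depths <- count_depths(counts)[cols]
  X <- mean_fitness_X(mean_track, gens)
  t_last <- gens[length(gens)]

  # two-component fit of one trajectory; returns NULL when not fittable
  fit_one <- function(cc, s0) {
    use <- cc > 0
    if (sum(use) < 3L || !is.finite(s0) || s0 <= 0) return(NULL)
    tt <- gens[use]; w <- cc[use]
    y <- log(cc[use] / depths[use]) + X[use]
    # nested straight-line fit (the drift/steady-selection null)
    sw <- sum(w); tbar <- sum(w * tt) / sw; ybar <- sum(w * y) / sw
    s_line <- sum(w * (tt - tbar) * (y - ybar)) / sum(w * (tt - tbar)^2)
    sse_line <- sum(w * (y - ybar - s_line * (tt - tbar))^2)
    a0 <- max(exp(y[1]), 1e-12)
    obj <- function(p) {
      mu <- log(exp(p[1]) + exp(p[2] + p[3] * tt))
      sum(w * (y - mu)^2)
    }
    # the objective is nearly flat in s when the mutant subclone is only
    # visible late; multiple starts avoid settling near the initialization
    fit <- NULL
    for (s_try in unique(pmax(c(s0, 2 * s0, 4 * s0), 1e-4))) {
      b0 <- max(exp(y[length(y)]) - a0 * 0.5, 1e-15) * exp(-s_try * tt[length(tt)])
      cand_fit <- stats::optim(c(log(a0), log(b0), s_try), obj,
                               method = "Nelder-Mead",
                               control = list(maxit = 400, reltol = 1e-10))
      if (is.null(fit) || cand_fit$value < fit$value) fit <- cand_fit
    }
    list(s = fit$par[3], lA = fit$par[1], lB = fit$par[2], sse2 = fit$value,
         s_line = s_line, d_sse = max(sse_line - fit$value, 0))
  }

  # empirical null for the curvature improvement: neutral reference lineages
  # carry drift but no expanding subclone
  null_bc <- fits$barcode[fits$neutral_ref]
  if (length(null_bc) > 1500L) {
    null_bc <- null_bc[seq(1L, length(null_bc), length.out = 1500L)]
  }
  lrt_crit <- 9
  if (length(null_bc) >= 50L) {
    mn <- as.matrix(counts[match(null_bc, counts$barcode), cols, drop = FALSE])
    d_null <- vapply(seq_len(nrow(mn)), function(k) {
      r <- fit_one(mn[k, ], 0.01)
      if (is.null(r)) NA_real_ else r$d_sse
    }, numeric(1))
    d_null <- d_null[is.finite(d_null)]
    if (length(d_null) >= 50L) {
      lrt_crit <- max(lrt_crit, quantile(d_null, null_quantile, names = FALSE))
    }
  }

  rows <- match(barcodes, counts$barcode)
  m <- as.matrix(counts[rows, cols, drop = FALSE])
  frow <- match(barcodes, fits$barcode)
  line_ok <- rep(FALSE, length(barcodes))
  curve_ok <- rep(FALSE, length(barcodes))
  dominant_ok <- rep(FALSE, length(barcodes))
  for (k in seq_along(barcodes)) {
    r <- fit_one(m[k, ], fits$s[frow[k]])
    if (is.null(r) || !is.finite(r$s) || r$s <= 0 || r$s > 1) next
    fits$s[frow[k]] <- r$s
    fits$tau[frow[k]] <- -(r$lB + log(config$n_eff) + log(r$s)) / r$s
    share_k <- 1 / (1 + exp(r$lA - (r$lB + r$s * t_last)))
    fits$mutant_share[frow[k]] <- share_k
    # three acceptance channels for near-threshold lineages:
    # (1) the straight-line slope alone clears the detection threshold;
    # (2) the curved fit beats the line by more than drift ever does on the
    #     neutral reference (empirical null);
    # (3) the fitted mutant component dominates the lineage 3:1 and the raw
    #     slope reaches half the threshold — sustained growth that pure
    #     bottleneck drift produces with negligible probability
    line_ok[k] <- r$s_line >= config$detection_threshold
    curve_ok[k] <- r$d_sse >= lrt_crit
    dominant_ok[k] <- share_k >= 0.75 && r$s_line >= config$detection_threshold / 2
  }
  ref <- frow
  share <- ifelse(is.na(fits$mutant_share[ref]), 1, fits$mutant_share[ref])
  fits$adaptive[ref] <- fits$fittable[ref] &
    fits$s[ref] >= config$detection_threshold &
    (fits$s[ref] / fits$se_s[ref]) >= config$z_adaptive &
    share >= min_mutant_share &
    (line_ok | curve_ok | dominant_ok)
  attr(fits, "lrt_crit") <- lrt_crit
  fits
}

#' Cross-replicate classification of pre-existing mutations
#'
#' Mutations arising during the barcoding expansion are shared between the
#' replicate evolutions. A lineage is flagged pre-existing when it is (1)
#' adaptive in both replicates and (2) has an establishment time earlier than
#' `-2/s` in at least one replicate.
#'
#' @param fits_rep1,fits_rep2 `"lineage_fits"` tibbles sharing barcode
#'   identifiers.
#' @return A list of the two fits tibbles with updated `pre_existing` flags.
#' @export
classify_preexisting <- function(fits_rep1, fits_rep2) {
  j <- dplyr::inner_join(
    dplyr::select(as_tibble(fits_rep1), "barcode", s1 = "s", tau1 = "tau", a1 = "adaptive"),
    dplyr::select(as_tibble(fits_rep2), "barcode", s2 = "s", tau2 = "tau", a2 = "adaptive"),
    by = "barcode")
  early1 <- !is.na(j$tau1) & !is.na(j$s1) & j$s1 > 0 & j$tau1 < -2 / j$s1
  early2 <- !is.na(j$tau2) & !is.na(j$s2) & j$s2 > 0 & j$tau2 < -2 / j$s2
  pre <- j$barcode[j$a1 & j$a2 & (early1 | early2)]
  fits_rep1$pre_existing <- fits_rep1$barcode %in% pre
  fits_rep2$pre_existing <- fits_rep2$barcode %in% pre
  list(fits_rep1, fits_rep2)
}

#' Fraction of adapted individuals per timepoint
#'
#' @param counts Barcode-count tibble.
#' @param fits `"lineage_fits"` for the same replicate.
#' @return Tibble `generation`, `adapted_fraction`: summed read frequency of
#'   lineages flagged adaptive.
#' @export
adapted_fraction <- function(counts, fits) {
  cols <- gen_cols(counts)
  m <- as.matrix(counts[cols])
  depths <- colSums(m)
  ad <- counts$barcode %in% fits$barcode[fits$adaptive]
  tibble(
    generation = count_generations(counts),
    adapted_fraction = unname(colSums(m[ad, , drop = FALSE]) / depths)
  )
}

#' Establishment and detection deadlines for beneficial mutations
#'
#' With the population mean fitness crossing a mutation's selection
#' coefficient `s` at generation `t_crossing`, clonal interference stops
#' later-arising mutations of that effect from establishing: they must arise
#' before `t_crossing - 1/s` (`mode = "establish"`). To also be *detected*
#' against a lineage of `n_e` cells, they must arise before
#' `t_crossing - (1/s) * ln(n_e * s)` (`mode = "detect"`). For example,
#' mutations with `s = 0.02` and a crossing at generation 90 must arise before
#' generation 40 to establish and roughly 60 generations before the start of
#' the experiment to be detected.
#'
#' @param s Selection coefficient(s), per generation; must be positive.
#' @param t_crossing Generation at which mean fitness reaches `s`.
#' @param n_e Lineage size in cells (`detect` mode).
#' @param mode `"establish"` or `"detect"`.
#' @return Deadline generation(s); vectorized over `s`.
#' @export
detectability_deadline <- function(s, t_crossing, n_e = 1000,
                                   mode = c("establish", "detect")) {
  mode <- match.arg(mode)
  if (any(s <= 0)) stop_lineagedfe("`s` must be positive")
  if (mode == "establish") {
    t_crossing - 1 / s
  } else {
    if (any(n_e * s <= 0)) stop_lineagedfe("`n_e * s` must be positive")
    t_crossing - (1 / s) * log(n_e * s)
  }
}

#' @export
glance.lineage_fits <- function(x, ...) {
  tibble(
    n_lineages = nrow(x),
    n_fittable = sum(x$fittable),
    n_neutral_ref = sum(x$neutral_ref),
    n_adaptive = sum(x$adaptive),
    n_pre_existing = sum(x$pre_existing),
    median_s_adaptive = median(x$s[x$adaptive], na.rm = TRUE)
  )
}
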
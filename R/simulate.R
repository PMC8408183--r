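#' Simulate pre-existing mutations from the barcoding expansion
#'
#' Before the evolution experiment the barcoded pool is expanded to roughly
#' `nf` cells; beneficial mutations arising during this expansion are present
#' at the start of the experiment and, because both replicate evolutions are
#' founded from the same pool, are shared between replicates.
#'
#' The expansion is modeled as `G = ceiling(log2(nf))` doublings. A mutation
#' arising while the population has `N_k` cells founds a subclone whose
#' relative frequency at the end of the expansion is `W / N_k`, with
#' `W ~ Exp(1)` the exponential-tailed size factor of a supercritical
#' branching process. Its cell count in the experiment's founding inoculum of
#' `bottleneck_cells` cells is Poisson distributed around
#' `bottleneck_cells * W / N_k`. Doublings large enough that almost no
#' descendant reaches the inoculum are handled by exact geometric thinning, so
#' only subclones contributing at least one founding cell are instantiated.
#'
#' @param config A [sim_config()]; uses `preexisting_dfe`, `nf`,
#'   `bottleneck_cells`, `n_barcodes` and `seed`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble (one row per pre-existing subclone): `subclone`, `barcode`,
#'   `s`, `origin_gen` (negative, generations before the experiment), `cells0`
#'   (cells in the founding inoculum), `pre_existing = TRUE`.
#' @export
simulate_preexisting <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  mu <- dfe_total_rate(config$preexisting_dfe)
  if (mu <= 0) {
    return(tibble(subclone = character(), barcode = character(), s = double(),
                  origin_gen = double(), cells0 = double(), pre_existing = logical()))
  }
  n0 <- config$bottleneck_cells
  G <- ceiling(log2(config$nf))
  sizes <- config$nf / 2^(G - seq_len(G))   # N_k at doubling k = 1..G

  cells <- integer(0)
  origin <- integer(0)
  for (k in seq_len(G)) {
    nk <- sizes[k]
    lam <- n0 / nk  # expected inoculum cells per mutation (before W factor)
    if (lam >= 1) {
      # early doublings: instantiate every arrival
      n_arr <- rpois(1, mu * nk)
      if (n_arr == 0) next
      w <- rexp(n_arr)
      cc <- rpois(n_arr, lam * w)
    } else {
      # late doublings: with W ~ Exp(1), inoculum cells are geometric with
      # P(>=1) = lam/(1+lam); draw only the survivors
      n_arr <- rpois(1, mu * nk * lam / (1 + lam))
      if (n_arr == 0) next
      cc <- 1L + rgeom(n_arr, prob = 1 / (1 + lam))
    }
    keep <- cc >= 1
    if (!any(keep)) next
    cells <- c(cells, cc[keep])
    origin <- c(origin, rep.int(k - G - 1L, sum(keep)))  # negative generations
  }
  n <- length(cells)
  if (n == 0L) {
    return(tibble(subclone = character(), barcode = character(), s = double(),
                  origin_gen = double(), cells0 = double(), pre_existing = logical()))
  }
  s <- dfe_sample(config$preexisting_dfe, n)
  bc_idx <- sample.int(config$n_barcodes, n, replace = TRUE)
  tibble(
    subclone = sprintf("pre_%05d", seq_len(n)),
    barcode = barcode_ids(config$n_barcodes)[bc_idx],
    s = s,
    origin_gen = as.double(origin),
    cells0 = as.double(cells),
    pre_existing = TRUE
  )
}

barcode_ids <- function(n) sprintf("bc%06d", seq_len(n))

# Dirichlet-multinomial (or multinomial) read sampling of `depth` reads
sample_reads <- function(freq, depth, overdispersion = NULL) {
  if (!is.null(overdispersion)) {
    alpha <- freq * overdispersion
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    g[alpha == 0] <- 0
    freq <- g / sum(g)
  }
  as.integer(rmultinom(1, depth, freq))
}

#' Simulate barcoded replicate evolutions
#'
#' Forward simulation of the serial-transfer lineage-tracking experiment.
#' Founder lineages and established mutant subclones are propagated
#' deterministically in frequency space with per-generation growth
#' `e^(s - xbar)`, where the population mean fitness `xbar` is recomputed
#' every generation as the frequency-weighted mean selection coefficient.
#' Rare subclones (below `small_pop_threshold` cells) are propagated in cell
#' space by a Poisson branching process with offspring mean
#' `g * e^(s - xbar)` per generation, where `g = dilution^(1/gens_per_cycle)`
#' is the within-cycle growth factor, capturing establishment stochasticity
#' (lineages become quasi-deterministic around 1/s cells). New beneficial
#' mutations arrive each generation as a Poisson process with rate
#' `rate * unmutated cells` and found single-cell subclones within their
#' barcode (single-step regime: mutant subclones do not mutate again).
#' At the end of each cycle the population is bottlenecked by multinomial
#' sampling of `bottleneck_cells`; at each cycle boundary reads are drawn
#' (multinomially, or Dirichlet-multinomially when `overdispersion` is set)
#' at the configured depth.
#'
#' Pre-existing subclones from [simulate_preexisting()] are injected
#' identically into every replicate; their subsequent fates are
#' replicate-specific.
#'
#' @param config A [sim_config()].
#' @param init_mutants Optional tibble with columns `barcode`, `s`, `cells`
#'   seeding mutant subclones at generation 0 (useful with
#'   `sampling_noise = FALSE` for deterministic checks).
#' @param track_frequencies If `TRUE`, each replicate additionally carries a
#'   `frequencies` matrix of true barcode frequencies at the sampled
#'   timepoints (attribute `"frequencies"` on each count tibble).
#' @return A list with elements
#'   `counts` (list of per-replicate barcode-count tibbles on the generation
#'   grid `0, G, 2G, ...`, column sums equal to the configured depths),
#'   `truth` (tibble of mutant subclones: `replicate`, `subclone`, `barcode`,
#'   `s`, `origin_gen`, `pre_existing`, `established`; pre-existing rows are
#'   shared across replicates, and subclones that never survive a bottleneck
#'   are tallied in `stats` rather than listed), and
#'   `stats` (list with `mean_fitness` — tibble of true per-generation mean
#'   fitness and its running integral — `adapted` — tibble of true mutant and
#'   adaptive cell fractions at each sampled timepoint — and
#'   `n_mutation_events` — tibble of mutation arrivals per generation).
#' @export
simulate_evolution <- function(config, init_mutants = NULL, track_frequencies = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  n_b <- config$n_barcodes
  G <- config$gens_per_cycle
  n0 <- config$bottleneck_cells
  gamma <- config$dilution^(1 / G)   # per-generation growth factor
  gens <- sim_generations(config)
  depths <- sim_depths(config)
  noise <- config$sampling_noise
  thr <- config$small_pop_threshold
  bc <- barcode_ids(n_b)

  # founding pool (common to replicates)
  if (config$founder_sdlog > 0) {
    f0 <- rlnorm(n_b, sdlog = config$founder_sdlog)
    f0 <- f0 / sum(f0)
  } else {
    f0 <- rep(1 / n_b, n_b)
  }
  pre <- simulate_preexisting(config, seed = config$seed + 1L)
  pre_idx <- match(pre$barcode, bc)

  mu_total <- dfe_total_rate(config$dfe)
  results <- vector("list", config$n_replicates)
  truth_list <- list()
  stats_mf <- list()
  stats_ad <- list()
  stats_ev <- list()

  for (rep_i in seq_len(config$n_replicates)) {
    # deterministic compartments: founders (s = 0) and established subclones
    fo_freq <- f0
    est <- list(bc = integer(0), s = numeric(0), freq = numeric(0), id = integer(0),
                origin = numeric(0), pre = logical(0))
    # stochastic small subclones (cell space)
    sm <- list(bc = pre_idx, s = pre$s, cells = pre$cells0, id = -seq_len(nrow(pre)),
               origin = pre$origin_gen, pre = rep(TRUE, nrow(pre)),
               recorded = rep(TRUE, nrow(pre)))
    if (!is.null(init_mutants)) {
      idx <- match(init_mutants$barcode, bc)
      if (anyNA(idx)) stop_lineagedfe("init_mutants barcode not in the simulated pool")
      sm$bc <- c(sm$bc, idx)
      sm$s <- c(sm$s, init_mutants$s)
      sm$cells <- c(sm$cells, init_mutants$cells)
      sm$id <- c(sm$id, -1000000L - seq_len(nrow(init_mutants)))
      sm$origin <- c(sm$origin, rep(0, nrow(init_mutants)))
      sm$pre <- c(sm$pre, rep(FALSE, nrow(init_mutants)))
      sm$recorded <- c(sm$recorded, rep(TRUE, nrow(init_mutants)))
    }
    next_id <- 1L
    established_ids <- integer(0)  # ids that ever reach the deterministic regime
    gt <- list()  # recorded ground-truth rows
    # record pre-existing + seeded mutants up front
    if (length(sm$id)) {
      gt[[length(gt) + 1L]] <- tibble(id = sm$id, bc = sm$bc, s = sm$s,
                                      origin = sm$origin, pre = sm$pre)
    }
    mf_gen <- integer(0); mf_x <- numeric(0)
    ev_gen <- integer(0); ev_n <- numeric(0)

    reads <- matrix(0L, nrow = n_b, ncol = length(gens))
    freqs <- if (track_frequencies) matrix(0, nrow = n_b, ncol = length(gens)) else NULL

    agg_freq <- function(ncells_total) {
      a <- fo_freq
      if (length(est$bc)) {
        add <- rowsum(est$freq, est$bc, reorder = FALSE)
        a[as.integer(rownames(add))] <- a[as.integer(rownames(add))] + add[, 1]
      }
      if (length(sm$bc)) {
        add <- rowsum(sm$cells / ncells_total, sm$bc, reorder = FALSE)
        a[as.integer(rownames(add))] <- a[as.integer(rownames(add))] + add[, 1]
      }
      a
    }
    take_sample <- function(tp, ncells_total) {
      a <- agg_freq(ncells_total)
      if (track_frequencies) freqs[, tp] <<- a
      reads[, tp] <<- if (noise) sample_reads(a, depths[tp], config$overdispersion)
                      else as.integer(round(a * depths[tp]))
      # true mutant / adaptive cell fractions
      mut_f <- sum(est$freq) + sum(sm$cells) / ncells_total
      ad_f <- sum(est$freq[est$s >= 0.02]) + sum(sm$cells[sm$s >= 0.02]) / ncells_total
      stats_ad[[length(stats_ad) + 1L]] <<- tibble(
        replicate = rep_i, generation = gens[tp], mutant_fraction = mut_f,
        adaptive_fraction = ad_f)
    }

    take_sample(1L, n0)

    for (cyc in seq_len(config$cycles)) {
      for (g in seq_len(G)) {
        t_now <- (cyc - 1L) * G + g      # generation being completed
        n_start <- n0 * gamma^(g - 1)
        n_end <- n_start * gamma
        f_small <- sum(sm$cells) / n_start
        xbar <- sum(est$freq * est$s) + sum(sm$cells * sm$s) / n_start
        mf_gen <- c(mf_gen, t_now); mf_x <- c(mf_x, xbar)

        # mutation arrivals in unmutated cells (single-step regime)
        if (noise && mu_total > 0) {
          f_neutral <- sum(fo_freq)
          n_arr <- rpois(1, mu_total * n_start * f_neutral)
          ev_gen <- c(ev_gen, t_now); ev_n <- c(ev_n, n_arr)
          if (n_arr > 0) {
            per_bc <- as.integer(rmultinom(1, n_arr, fo_freq))
            hit <- which(per_bc > 0)
            new_bc <- rep.int(hit, per_bc[hit])
            n_new <- length(new_bc)
            sm$bc <- c(sm$bc, new_bc)
            sm$s <- c(sm$s, dfe_sample(config$dfe, n_new))
            sm$cells <- c(sm$cells, rep.int(1, n_new))
            sm$id <- c(sm$id, seq.int(next_id, length.out = n_new))
            sm$origin <- c(sm$origin, rep.int(t_now, n_new))
            sm$pre <- c(sm$pre, rep.int(FALSE, n_new))
            sm$recorded <- c(sm$recorded, rep.int(FALSE, n_new))
            next_id <- next_id + n_new
          }
        }

        # growth
        w_fo <- fo_freq * exp(-xbar)
        w_est <- est$freq * exp(est$s - xbar)
        if (length(sm$cells)) {
          lam <- sm$cells * gamma * exp(sm$s - xbar)
          sm$cells <- if (noise) as.double(rpois(length(lam), lam)) else lam
        }
        f_small_end <- sum(sm$cells) / n_end
        z <- (sum(w_fo) + sum(w_est)) / max(1 - f_small_end, 1e-12)
        fo_freq <- w_fo / z
        est$freq <- w_est / z

        # drop extinct, record + promote established subclones
        if (length(sm$cells)) {
          alive <- sm$cells > 0
          if (!all(alive)) sm <- lapply(sm, function(v) v[alive])
          promote <- sm$cells >= thr
          if (any(promote)) {
            newly <- promote & !sm$recorded
            if (any(newly)) {
              gt[[length(gt) + 1L]] <- tibble(id = sm$id[newly], bc = sm$bc[newly],
                                              s = sm$s[newly], origin = sm$origin[newly],
                                              pre = sm$pre[newly])
            }
            est$bc <- c(est$bc, sm$bc[promote])
            est$s <- c(est$s, sm$s[promote])
            est$freq <- c(est$freq, sm$cells[promote] / n_end)
            est$id <- c(est$id, sm$id[promote])
            est$origin <- c(est$origin, sm$origin[promote])
            est$pre <- c(est$pre, sm$pre[promote])
            established_ids <- c(established_ids, sm$id[promote])
            sm <- lapply(sm, function(v) v[!promote])
          }
        }
      }

      # sample reads at the cycle boundary (saturated culture)
      take_sample(cyc + 1L, n0 * config$dilution)

      # bottleneck: multinomial sampling of bottleneck_cells
      if (noise) {
        if (length(sm$cells)) {
          sm$cells <- as.double(rbinom(length(sm$cells),
                                       size = as.integer(pmin(sm$cells, .Machine$integer.max)),
                                       prob = 1 / config$dilution))
          alive <- sm$cells > 0
          # survivors of a bottleneck enter the ground-truth record
          surv_new <- alive & !sm$recorded
          if (any(surv_new)) {
            gt[[length(gt) + 1L]] <- tibble(id = sm$id[surv_new], bc = sm$bc[surv_new],
                                            s = sm$s[surv_new], origin = sm$origin[surv_new],
                                            pre = sm$pre[surv_new])
            sm$recorded[surv_new] <- TRUE
          }
          if (!all(alive)) sm <- lapply(sm, function(v) v[alive])
        }
        det_freq <- c(fo_freq, est$freq)
        f_small_now <- sum(sm$cells) / n0
        det_counts <- as.integer(rmultinom(1, n0, det_freq))
        tot <- sum(det_counts) / max(1 - f_small_now, 1e-12)
        fo_freq <- det_counts[seq_len(n_b)] / tot
        if (length(est$freq)) {
          est$freq <- det_counts[-seq_len(n_b)] / tot
          keep <- est$freq > 0
          if (!all(keep)) est <- lapply(est, function(v) v[keep])
        }
      } else if (length(sm$cells)) {
        sm$cells <- sm$cells / config$dilution
      }
    }

    colnames(reads) <- paste0("gen_", gens)
    tb <- tibble(barcode = bc)
    tb <- dplyr::bind_cols(tb, as_tibble(reads))
    attr(tb, "meta") <- list(replicate = rep_i, seed = config$seed)
    if (track_frequencies) {
      colnames(freqs) <- paste0("gen_", gens)
      rownames(freqs) <- bc
      attr(tb, "frequencies") <- freqs
    }
    results[[rep_i]] <- tb

    if (length(gt)) {
      g_all <- dplyr::distinct(bind_rows(gt), .data$id, .keep_all = TRUE)
      est_ids <- established_ids
      truth_list[[rep_i]] <- tibble(
        replicate = rep_i,
        subclone = dplyr::case_when(
          g_all$id < -1000000L ~ sprintf("seed_%03d", -(g_all$id + 1000000L)),
          g_all$id < 0L ~ sprintf("pre_%05d", -g_all$id),
          TRUE ~ sprintf("r%d_m%07d", rep_i, g_all$id)
        ),
        barcode = bc[g_all$bc],
        s = g_all$s,
        origin_gen = g_all$origin,
        pre_existing = g_all$pre,
        established = g_all$id %in% est_ids
      )
    } else {
      truth_list[[rep_i]] <- tibble(replicate = integer(), subclone = character(),
                                    barcode = character(), s = double(),
                                    origin_gen = double(), pre_existing = logical(),
                                    established = logical())
    }
    stats_mf[[rep_i]] <- tibble(replicate = rep_i, generation = mf_gen, x_bar = mf_x,
                                X = cumsum(mf_x))
    stats_ev[[rep_i]] <- tibble(replicate = rep_i, generation = ev_gen, n_events = ev_n)
  }

  list(
    counts = results,
    truth = bind_rows(truth_list),
    stats = list(
      mean_fitness = bind_rows(stats_mf),
      adapted = bind_rows(stats_ad),
      n_mutation_events = bind_rows(stats_ev)
    )
  )
}

#' Simulate a pooled competition assay
#'
#' Clones are pooled (10% of cells, split by the given pool frequencies) and
#' mixed 1:9 with their common reference ancestor, then grown for four
#' serial-transfer cycles; samples are taken at mixing (timepoint 0) and at
#' the end of each cycle, giving 5 timepoints labelled `gen_0 .. gen_32` for
#' 8 generations per cycle. Within each cycle frequencies evolve by
#' `e^((s - xbar) * gens_per_cycle)` with `xbar` the frequency-weighted mean
#' fitness; reads are drawn multinomially per technical replicate.
#'
#' @param clones Tibble with columns `barcode` and `s` (true per-generation
#'   selection coefficients); optional `pool_frequency` column (normalized
#'   within the 10% pool share, equal split by default).
#' @param config A [sim_config()]; uses `gens_per_cycle`, `read_depth`
#'   (recycled over the 5 timepoints), `sampling_noise`, `seed`.
#' @param n_cycles Number of competition growth cycles (default 4).
#' @param n_tech_reps Technical replicates (independent read samplings of the
#'   same culture), default 3.
#' @param reference_barcode Identifier of the ancestor reference lineage
#'   (90% of cells at mixing).
#' @return A list of `n_tech_reps` barcode-count tibbles; the reference
#'   lineage appears as the `reference_barcode` row.
#' @export
simulate_pooled_assay <- function(clones, config, n_cycles = 4, n_tech_reps = 3,
                                  reference_barcode = "ancestor") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(clones) || nrow(clones) == 0L) {
    stop_lineagedfe("`clones` must contain at least one clone")
  }
  depths <- rep_len(config$read_depth, n_cycles + 1L)
  if (any(depths <= 0)) {
    stop_lineagedfe("read depth must be positive at every assay timepoint",
                    class = "lineagedfe_config_error")
  }
  withr::local_seed(config$seed)
  G <- config$gens_per_cycle
  pool <- if ("pool_frequency" %in% names(clones)) {
    clones$pool_frequency / sum(clones$pool_frequency)
  } else rep(1 / nrow(clones), nrow(clones))
  freq <- c(0.9, 0.1 * pool)               # reference first
  s <- c(0, clones$s)
  gens <- seq(0L, n_cycles * G, by = G)

  traj <- matrix(0, nrow = length(freq), ncol = length(gens))
  traj[, 1] <- freq
  for (cyc in seq_len(n_cycles)) {
    for (g in seq_len(G)) {
      xbar <- sum(freq * s)
      freq <- freq * exp(s - xbar)
      freq <- freq / sum(freq)
    }
    traj[, cyc + 1L] <- freq
  }

  out <- vector("list", n_tech_reps)
  for (r in seq_len(n_tech_reps)) {
    reads <- vapply(seq_along(gens), function(j) {
      if (config$sampling_noise) sample_reads(traj[, j], depths[j], config$overdispersion)
      else as.integer(round(traj[, j] * depths[j]))
    }, integer(length(freq)))
    colnames(reads) <- paste0("gen_", gens)
    tb <- tibble(barcode = c(reference_barcode, clones$barcode))
    tb <- dplyr::bind_cols(tb, as_tibble(reads))
    attr(tb, "meta") <- list(technical_replicate = r, seed = config$seed)
    out[[r]] <- tb
  }
  out
}

#' Simulate a mutation catalog for spectrum statistics
#'
#' Generates a catalog of causative mutation calls with the structure needed
#' by the mutation-spectrum statistics: a first-step stratum (mutations fixed
#' on the wild-type background) and a second-step stratum (mutations acquired
#' on adapted backgrounds), each with a configurable probability that a call
#' is disruptive (nonsense or frameshift, i.e. loss of function).
#'
#' @param n_first,n_second Number of first- and second-step calls.
#' @param lof_prob_first,lof_prob_second Probability that a call in the
#'   stratum is a nonsense or frameshift mutation.
#' @param seed Integer seed.
#' @return Tibble of mutation calls: `clone`, `background`, `gene`, `pathway`,
#'   `effect`, `step`, `quality`, `coverage`, `chrom`.
#' @export
simulate_mutation_catalog <- function(n_first, n_second,
                                      lof_prob_first, lof_prob_second,
                                      seed = 1L) {
  stopifnot(lof_prob_first >= 0, lof_prob_first <= 1,
            lof_prob_second >= 0, lof_prob_second <= 1)
  withr::local_seed(seed)
  genes <- c(IRA1 = "RAS/PKA", IRA2 = "RAS/PKA", GPB2 = "RAS/PKA", CYR1 = "RAS/PKA",
             PDE2 = "RAS/PKA", KSP1 = "TOR/Sch9", SCH9 = "TOR/Sch9", TOR1 = "TOR/Sch9",
             SSK2 = "HOG", PBS2 = "HOG", HOG1 = "HOG",
             MKS1 = "RTG", RTG2 = "RTG", BMH1 = "RTG", GSH1 = "other", ARO80 = "other")
  one_stratum <- function(n, lof_prob, step, backgrounds) {
    if (n == 0L) {
      return(tibble(clone = character(), background = character(), gene = character(),
                    pathway = character(), effect = character(), step = character(),
                    quality = double(), coverage = double(), chrom = character()))
    }
    gene <- sample(names(genes), n, replace = TRUE)
    lof <- runif(n) < lof_prob
    effect <- ifelse(lof, sample(c("nonsense", "frameshift"), n, replace = TRUE),
                     "missense")
    tibble(
      clone = sprintf("%s_clone%04d", step, seq_len(n)),
      background = sample(backgrounds, n, replace = TRUE),
      gene = gene,
      pathway = unname(genes[gene]),
      effect = effect,
      step = step,
      quality = round(runif(n, 150, 3000), 1),
      coverage = round(runif(n, 15, 80), 1),
      chrom = sample(paste0("chr", as.roman(1:16)), n, replace = TRUE)
    )
  }
  bind_rows(
    one_stratum(n_first, lof_prob_first, "first", "WT"),
    one_stratum(n_second, lof_prob_second, "second", c("cyr1", "gpb2", "tor1"))
  )
}
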
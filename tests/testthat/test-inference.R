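# deterministic toy cohort: neutral band lineages + one growing mutant
toy_cohort <- function(s_mut = 0.08, depth = 1e5, n_neutral = 40) {
  gens <- seq(0, 48, by = 8)
  # neutral lineages sit at 25 reads; the mutant grows exponentially
  f_mut <- 1e-4 * exp(s_mut * gens)
  mut <- round(f_mut * depth)
  m <- rbind(matrix(25L, nrow = n_neutral, ncol = length(gens)), mut)
  filler <- depth - colSums(m)
  m <- rbind(m, filler)
  tb <- tibble::tibble(barcode = c(sprintf("n%02d", seq_len(n_neutral)), "mut", "bulk"))
  for (j in seq_along(gens)) tb[[paste0("gen_", gens[j])]] <- as.integer(m[, j])
  tb
}

test_that("inference_config validates its band", {
  expect_error(inference_config(neutral_lo = 30, neutral_hi = 20),
               class = "lineagedfe_config_error")
  expect_error(inference_config(detection_threshold = 0),
               class = "lineagedfe_config_error")
})

test_that("neutral selection takes exactly the in-band lineages", {
  x <- toy_cohort()
  inf <- inference_config(neutral_lo = 20, neutral_hi = 30)
  nb <- select_neutral_reference(x, inf)
  expect_setequal(nb, sprintf("n%02d", 1:40))
  expect_error(select_neutral_reference(x, inference_config(neutral_lo = 400,
                                                            neutral_hi = 500)),
               class = "lineagedfe_neutral_error")
})

test_that("mean fitness track recovers an imposed neutral decay", {
  gens <- seq(0, 32, by = 8)
  xb_true <- 0.03
  depth <- 1e6
  # build 30 neutral lineages decaying at xb_true plus bulk filler
  base <- round(25 * exp(-xb_true * gens))
  m <- matrix(rep(base, each = 30), nrow = 30)
  m <- rbind(m, depth - colSums(m))
  tb <- tibble::tibble(barcode = c(sprintf("n%02d", 1:30), "bulk"))
  for (j in seq_along(gens)) tb[[paste0("gen_", gens[j])]] <- as.integer(m[, j])
  inf <- inference_config(neutral_lo = 8, neutral_hi = 30)
  nb <- select_neutral_reference(tb, inf)
  tr <- estimate_mean_fitness(tb, nb, inf)
  expect_s3_class(tr, "mean_fitness_track")
  expect_equal(tr$X[1], 0)
  expect_equal(mean(tr$x_bar, na.rm = TRUE), xb_true, tolerance = 0.05)
  expect_equal(tr$X[length(gens)], xb_true * 32, tolerance = 0.3)
})

test_that("the contamination cap drops reference lineages that take off", {
  gens <- seq(0, 32, by = 8)
  depth <- 1e5
  n_n <- 30
  m <- matrix(25L, nrow = n_n, ncol = length(gens))
  # one 'neutral' lineage acquires a mutation and grows out of band late
  m[1, ] <- c(25L, 25L, 28L, 80L, 300L)
  tb <- tibble::tibble(barcode = sprintf("n%02d", seq_len(n_n)))
  for (j in seq_along(gens)) tb[[paste0("gen_", gens[j])]] <- m[, j]
  tb$gen_0 <- as.integer(tb$gen_0)
  bulk <- tibble::tibble(barcode = "bulk")
  for (j in seq_along(gens)) bulk[[paste0("gen_", gens[j])]] <- depth - sum(m[, j])
  tb <- dplyr::bind_rows(tb, bulk)
  inf_win <- inference_config(neutral_lo = 20, neutral_hi = 30,
                              neutral_max_generation = 16,
                              neutral_cap_multiple = 2)
  nb <- select_neutral_reference(tb, inf_win)
  expect_true("n01" %in% nb)  # in-band inside the selection window
  tr_cap <- estimate_mean_fitness(tb, nb, inf_win)
  inf_nocap <- inference_config(neutral_lo = 20, neutral_hi = 30,
                                neutral_max_generation = 16)
  tr_raw <- estimate_mean_fitness(tb, nb, inf_nocap)
  # without the cap the contaminant drags the apparent mean fitness negative
  expect_lt(tr_raw$X[5], tr_cap$X[5])
  expect_equal(tr_cap$X[5], 0, tolerance = 0.05)
})

test_that("fit_lineages recovers slope, establishment time and flags", {
  s_true <- 0.08
  x <- toy_cohort(s_mut = s_true)
  inf <- inference_config(neutral_lo = 20, neutral_hi = 30)
  nb <- select_neutral_reference(x, inf)
  tr <- estimate_mean_fitness(x, nb, inf)
  fits <- fit_lineages(x, tr, inf, nb)
  expect_s3_class(fits, "lineage_fits")
  mut <- fits[fits$barcode == "mut", ]
  expect_equal(mut$s, s_true, tolerance = 0.003)
  expect_true(mut$adaptive)
  expect_false(mut$neutral_ref)
  # tau: fitted size n_eff * 1e-4 * e^{s tau} = 1/s => tau = -ln(1e-4 n_eff s)/s
  tau_true <- -log(1e-4 * inf$n_eff * s_true) / s_true
  expect_lt(abs(mut$tau - tau_true), 2)
  # neutral lineages are not adaptive
  expect_false(any(fits$adaptive[fits$neutral_ref]))
  gl <- glance(fits)
  expect_equal(gl$n_adaptive, 1L)
})

test_that("unfittable lineages are flagged, not errors", {
  x <- toy_cohort()
  x[x$barcode == "mut", paste0("gen_", seq(8, 48, by = 8))] <- 0L
  inf <- inference_config(neutral_lo = 20, neutral_hi = 30)
  nb <- select_neutral_reference(x, inf)
  tr <- estimate_mean_fitness(x, nb, inf)
  fits <- fit_lineages(x, tr, inf, nb)
  mut <- fits[fits$barcode == "mut", ]
  expect_false(mut$fittable)
  expect_true(is.na(mut$s))
  expect_false(mut$adaptive)
})

test_that("drift-aware errors shrink with founding lineage size", {
  x <- toy_cohort()
  inf0 <- inference_config(neutral_lo = 20, neutral_hi = 30)
  infd <- inference_config(neutral_lo = 20, neutral_hi = 30,
                           bottleneck_cells = 1e7)
  nb <- select_neutral_reference(x, inf0)
  tr <- estimate_mean_fitness(x, nb, inf0)
  f0 <- fit_lineages(x, tr, inf0, nb)
  fd <- fit_lineages(x, tr, infd, nb)
  # drift inflates every standard error
  expect_true(all(fd$se_s >= f0$se_s, na.rm = TRUE))
  infd_big <- inference_config(neutral_lo = 20, neutral_hi = 30,
                               bottleneck_cells = 1e10)
  fb <- fit_lineages(x, tr, infd_big, nb)
  # a larger population means more cells per lineage, hence less drift
  expect_true(all(fb$se_s <= fd$se_s, na.rm = TRUE))
})

test_that("refinement corrects the plateau bias of the log-linear fit", {
  # lineage = decaying founder cells + expanding mutant: early plateau
  gens <- seq(0, 64, by = 8)
  depth <- 1e6
  s_true <- 0.05
  a <- 2e-4                       # founder component (neutral)
  b <- 3.3e-5                     # mutant component at t=0 (dominates by t=64)
  f_mix <- a + b * exp(s_true * gens)
  n_n <- 60
  m <- matrix(25L, nrow = n_n, ncol = length(gens))
  tb <- tibble::tibble(barcode = sprintf("n%02d", seq_len(n_n)))
  for (j in seq_along(gens)) tb[[paste0("gen_", gens[j])]] <- m[, j]
  mix <- tibble::tibble(barcode = "mix")
  bulk <- tibble::tibble(barcode = "bulk")
  for (j in seq_along(gens)) {
    mix[[paste0("gen_", gens[j])]] <- as.integer(round(f_mix[j] * depth))
    bulk[[paste0("gen_", gens[j])]] <- depth - sum(m[, j]) -
      as.integer(round(f_mix[j] * depth))
  }
  tb <- dplyr::bind_rows(tb, mix, bulk)
  inf <- inference_config(neutral_lo = 20, neutral_hi = 30)
  nb <- select_neutral_reference(tb, inf)
  tr <- estimate_mean_fitness(tb, nb, inf)
  fits <- fit_lineages(tb, tr, inf, nb)
  s_line <- fits$s[fits$barcode == "mix"]
  expect_lt(s_line, s_true - 0.01)    # the straight line is biased low
  ref <- refine_lineage_fits(fits, tb, tr, inf)
  s_ref <- ref$s[ref$barcode == "mix"]
  expect_equal(s_ref, s_true, tolerance = 0.02)
  expect_true(ref$adaptive[ref$barcode == "mix"])
  share <- ref$mutant_share[ref$barcode == "mix"]
  b_share <- b * exp(s_true * 64) / f_mix[length(gens)]
  expect_equal(share, b_share, tolerance = 0.05)
})

test_that("pre-existing classification needs both replicates and early tau", {
  f <- tibble::tibble(
    barcode = c("a", "b", "c", "d"),
    s = c(0.05, 0.05, 0.05, NA),
    se_s = 0.005, tau = c(-100, -100, 5, NA), n_points = 5L,
    fittable = c(TRUE, TRUE, TRUE, FALSE),
    neutral_ref = FALSE,
    adaptive = c(TRUE, TRUE, TRUE, FALSE),
    pre_existing = FALSE, mutant_share = NA_real_
  )
  g <- f
  g$adaptive <- c(TRUE, FALSE, TRUE, FALSE)  # 'b' adaptive in one replicate only
  g$tau <- c(5, -100, 5, NA)                  # 'a' early in replicate 1 only
  out <- classify_preexisting(f, g)
  expect_true(out[[1]]$pre_existing[out[[1]]$barcode == "a"])   # both adaptive, early in rep1
  expect_false(out[[1]]$pre_existing[out[[1]]$barcode == "b"])  # adaptive in one rep
  expect_false(out[[1]]$pre_existing[out[[1]]$barcode == "c"])  # tau too late (> -2/s)
  expect_identical(out[[1]]$pre_existing, out[[2]]$pre_existing)
})

test_that("detectability deadlines match the closed forms", {
  expect_equal(detectability_deadline(0.02, t_crossing = 90, mode = "establish"), 40)
  dd <- detectability_deadline(0.02, t_crossing = 90, n_e = 1000, mode = "detect")
  expect_equal(dd, 90 - 50 * log(20))
  expect_equal(dd, -59.7866, tolerance = 1e-4)
  expect_error(detectability_deadline(-0.01, 90), "positive")
  # vectorized
  expect_length(detectability_deadline(c(0.02, 0.05), 90), 2)
})

test_that("adapted_fraction sums the adaptive lineages' read share", {
  x <- toy_cohort()
  inf <- inference_config(neutral_lo = 20, neutral_hi = 30)
  nb <- select_neutral_reference(x, inf)
  tr <- estimate_mean_fitness(x, nb, inf)
  fits <- fit_lineages(x, tr, inf, nb)
  af <- adapted_fraction(x, fits)
  manual <- x$gen_48[x$barcode == "mut"] / sum(x$gen_48)
  expect_equal(af$adapted_fraction[af$generation == 48], manual)
})
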
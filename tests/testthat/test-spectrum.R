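test_that("the forward relation matches its algebraic form", {
  # mu * (1 + s ln(Nf mu)) * e^{s t} / s, checked against a frozen value
  f <- mu_forward(1e-6, s = 0.05, t = 112, nf = 1e12)
  manual <- 1e-6 * (1 + 0.05 * log(1e12 * 1e-6)) * exp(0.05 * 112) / 0.05
  expect_equal(f, manual)
  expect_equal(f, 9.144607e-3, tolerance = 1e-6)     # frozen oracle
  # and the inverse recovers the rate from the frozen frequency
  expect_equal(solve_mu(9.144607e-3, s = 0.05, t = 112), 1e-6, tolerance = 1e-6)
})

test_that("solver round trip is exact to 1e-8 over an (s, m) grid", {
  grid <- expand.grid(s = c(0.02, 0.035, 0.05, 0.08, 0.12, 0.2),
                      m = 10^seq(-9, -4, by = 0.5),
                      t = c(0, 64, 112, 136))
  f <- mu_forward(grid$m, grid$s, grid$t)
  m_back <- solve_mu(f, grid$s, grid$t)
  expect_lt(max(abs(m_back - grid$m) / grid$m), 1e-8)
})

test_that("solver handles edge cases and refuses bad input", {
  expect_equal(solve_mu(0, s = 0.05, t = 100), 0)
  expect_equal(solve_mu(c(0, 0), s = 0.05, t = 100), c(0, 0))
  expect_error(solve_mu(-1, s = 0.05, t = 100), "nonnegative")
  expect_error(solve_mu(1e-3, s = -0.05, t = 100), "positive")
  # enormous frequency outside the solvable branch gives a clear error
  expect_error(solve_mu(1e30, s = 0.05, t = 0),
               class = "lineagedfe_solver_error")
})

test_that("counting-noise error follows sqrt(mu ds / N)", {
  bins <- tibble::tibble(s_lo = 0.034, s_hi = 0.036, s_mid = 0.035,
                         f = 0, n_lineages = 0L, mu_ds = 1e-6)
  expect_equal(sqrt(1e-6 / 6e8), 4.0825e-8, tolerance = 1e-4)
})

test_that("dfe_spectrum bins adaptive lineages and inverts their frequency", {
  gens <- seq(0, 48, by = 8)
  depth <- 1e6
  tb <- tibble::tibble(barcode = c("m1", "m2", "bulk"))
  f1 <- 2e-4 * exp(0.05 * gens)
  f2 <- 1e-4 * exp(0.037 * gens)
  for (j in seq_along(gens)) {
    r1 <- round(f1[j] * depth); r2 <- round(f2[j] * depth)
    tb[[paste0("gen_", gens[j])]] <- as.integer(c(r1, r2, depth - r1 - r2))
  }
  fits <- tibble::tibble(
    barcode = c("m1", "m2", "bulk"),
    s = c(0.05, 0.037, 0.001), se_s = 0.001, tau = -50, n_points = 7L,
    fittable = TRUE, neutral_ref = FALSE,
    adaptive = c(TRUE, TRUE, FALSE), pre_existing = FALSE,
    mutant_share = NA_real_
  )
  inf <- inference_config(n_eff = 6e8)
  sp <- dfe_spectrum(fits, tb, t_ref = 48, config = inf)
  expect_s3_class(sp, "dfe_spectrum")
  # m1 falls in [0.05, 0.052) (half-open: the tie goes up), m2 in [0.036, 0.038)
  b1 <- sp[sp$s_lo == 0.050, ]
  b2 <- sp[sp$s_lo < 0.037 & sp$s_hi > 0.037, ]
  expect_equal(b1$n_lineages, 1L)
  expect_equal(b2$n_lineages, 1L)
  f1_48 <- round(f1[7] * depth) / depth
  expect_equal(b1$f, f1_48)
  expect_equal(b1$mu_ds, solve_mu(f1_48, b1$s_mid, 48))
  # round trip through the forward relation
  expect_equal(mu_forward(b1$mu_ds, b1$s_mid, 48), b1$f, tolerance = 1e-8)
  expect_equal(b1$err, sqrt(b1$mu_ds / 6e8))
  # empty bins give zero rate
  expect_true(all(sp$mu_ds[sp$n_lineages == 0] == 0))
  expect_error(dfe_spectrum(fits, tb, t_ref = 7, config = inf),
               class = "lineagedfe_spectrum_error")
})

test_that("pre-existing and neutral-reference lineages are excluded from bins", {
  gens <- seq(0, 16, by = 8)
  tb <- tibble::tibble(barcode = c("pre", "adp", "bulk"),
                       gen_0 = c(100L, 100L, 99800L),
                       gen_8 = c(150L, 150L, 99700L),
                       gen_16 = c(220L, 220L, 99560L))
  fits <- tibble::tibble(
    barcode = c("pre", "adp", "bulk"), s = c(0.05, 0.05, NA),
    se_s = 0.001, tau = -60, n_points = 3L, fittable = c(TRUE, TRUE, FALSE),
    neutral_ref = FALSE, adaptive = c(TRUE, TRUE, FALSE),
    pre_existing = c(TRUE, FALSE, FALSE), mutant_share = NA_real_
  )
  sp <- dfe_spectrum(fits, tb, t_ref = 16, config = inference_config())
  expect_equal(sum(sp$n_lineages), 1L)  # only 'adp' is binned
})

test_that("advection correction scales bin frequencies by e^{X(t_ref)}", {
  gens <- seq(0, 16, by = 8)
  tb <- tibble::tibble(barcode = c("adp", "bulk"),
                       gen_0 = c(100L, 99900L),
                       gen_8 = c(150L, 99850L),
                       gen_16 = c(225L, 99775L))
  fits <- tibble::tibble(
    barcode = c("adp", "bulk"), s = c(0.05, NA), se_s = 0.001, tau = -60,
    n_points = 3L, fittable = c(TRUE, FALSE), neutral_ref = FALSE,
    adaptive = c(TRUE, FALSE), pre_existing = FALSE, mutant_share = NA_real_
  )
  track <- tibble::tibble(generation = gens, F_N = exp(-0.01 * gens),
                          x_bar = c(0.01, 0.01, NA), X = 0.01 * gens)
  class(track) <- c("mean_fitness_track", class(track))
  sp0 <- dfe_spectrum(fits, tb, t_ref = 16, config = inference_config())
  sp1 <- dfe_spectrum(fits, tb, t_ref = 16, config = inference_config(),
                      mean_track = track)
  expect_equal(max(sp1$f), max(sp0$f) * exp(0.16))
})

test_that("mutant_share weights the binned frequency", {
  gens <- seq(0, 16, by = 8)
  tb <- tibble::tibble(barcode = c("adp", "bulk"),
                       gen_0 = c(100L, 99900L),
                       gen_8 = c(150L, 99850L),
                       gen_16 = c(200L, 99800L))
  fits <- tibble::tibble(
    barcode = c("adp", "bulk"), s = c(0.05, NA), se_s = 0.001, tau = -60,
    n_points = 3L, fittable = c(TRUE, FALSE), neutral_ref = FALSE,
    adaptive = c(TRUE, FALSE), pre_existing = FALSE,
    mutant_share = c(0.6, NA)
  )
  sp <- dfe_spectrum(fits, tb, t_ref = 16, config = inference_config())
  expect_equal(max(sp$f), 200 / 1e5 * 0.6)
})

test_that("spectrum summary extracts peak and interval rates", {
  bins <- tibble::tibble(
    s_lo = round(seq(0.02, 0.198, by = 0.002), 9))
  bins$s_hi <- round(bins$s_lo + 0.002, 9)
  bins$s_mid <- bins$s_lo + 0.001
  bins$f <- 0
  bins$n_lineages <- 0L
  bins$mu_ds <- 0
  bins$mu_ds[bins$s_lo == 0.034] <- 5e-6   # peak at s ~ 0.035
  bins$mu_ds[bins$s_lo == 0.036] <- 2e-6
  bins$mu_ds[bins$s_lo == 0.06] <- 1e-6
  bins$mu_ds[bins$s_lo == 0.08] <- 5e-7
  bins$mu_ds[bins$s_lo == 0.13] <- 2e-7
  bins$err <- sqrt(bins$mu_ds / 6e8)
  class(bins) <- c("dfe_spectrum", class(bins))
  sm <- summarize_spectrum(bins)
  expect_equal(sm$peak_fitness, 0.035)
  expect_equal(sm$rate_at_peak, 7e-6)          # both bins inside +/- 0.01
  expect_equal(sm$rate_gt_005, 1e-6 + 5e-7 + 2e-7)
  expect_equal(sm$rate_007_012, 5e-7)
  expect_equal(sm$rate_gt_012, 2e-7)
  expect_equal(sm$total_detectable_rate, sum(bins$mu_ds))
  expect_equal(glance(bins), sm)
  expect_error(summarize_spectrum(bins[0, ]), class = "lineagedfe_spectrum_error")
})
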
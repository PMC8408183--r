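test_that("sim_config validates the cycle/dilution relationship", {
  expect_error(sim_config(gens_per_cycle = 7), "round\\(log2\\(dilution\\)\\)")
  expect_error(sim_config(n_barcodes = 0), class = "lineagedfe_config_error")
  expect_error(sim_config(read_depth = c(1e6, 0)), class = "lineagedfe_config_error")
  cfg <- sim_config(bottleneck_cells = 1e5, dilution = 250)
  expect_equal(cfg$saturation_cells, 2.5e7)
  expect_equal(lineagedfe:::sim_generations(tiny_config()), c(0L, 8L, 16L, 24L))
})

test_that("simulation output has the declared shape and exact depths", {
  cfg <- tiny_config(seed = 3)
  sim <- simulate_evolution(cfg)
  expect_length(sim$counts, cfg$n_replicates)
  for (tb in sim$counts) {
    expect_equal(nrow(tb), cfg$n_barcodes)
    expect_equal(count_generations(tb), lineagedfe:::sim_generations(cfg))
    expect_equal(unname(count_depths(tb)), rep(cfg$read_depth, cfg$cycles + 1))
  }
  expect_true(all(c("replicate", "subclone", "barcode", "s", "origin_gen",
                    "pre_existing", "established") %in% names(sim$truth)))
  expect_s3_class(sim$stats$mean_fitness, "tbl_df")
})

test_that("simulation is reproducible and seed-sensitive", {
  a <- simulate_evolution(tiny_config(seed = 5))
  b <- simulate_evolution(tiny_config(seed = 5))
  c <- simulate_evolution(tiny_config(seed = 6))
  expect_identical(a$counts[[1]], b$counts[[1]])
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$counts[[1]], c$counts[[1]]))
})

test_that("noise-free seeded mutant follows the deterministic expectation", {
  s_true <- 0.05
  cfg <- tiny_config(seed = 1, n_barcodes = 100, cycles = 6,
                     founder_sdlog = 0, sampling_noise = FALSE,
                     bottleneck_cells = 1e6, read_depth = 1e7)
  init <- tibble::tibble(barcode = "bc000001", s = s_true, cells = 1e3)
  sim <- simulate_evolution(cfg, init_mutants = init, track_frequencies = TRUE)
  fr <- attr(sim$counts[[1]], "frequencies")
  mut0 <- 1e-3   # 1e3 of 1e6 bottleneck cells
  gens <- lineagedfe:::sim_generations(cfg)
  # exact logistic solution of the two-type model: founders at s=0, mutant s
  pred <- (mut0 * exp(s_true * gens)) / (mut0 * exp(s_true * gens) + (1 - mut0))
  # mutant lineage's barcode = mutant subclone + its residual founder cells
  f_mut <- unname(fr["bc000001", ] - fr["bc000002", ])
  expect_equal(f_mut[-1] / pred[-1], rep(1, length(gens) - 1), tolerance = 2e-3)
  # frequencies are normalized at every post-founding timepoint
  expect_equal(unname(colSums(fr)[-1]), rep(1, length(gens) - 1), tolerance = 1e-9)
})

test_that("pre-existing subclones are shared across replicates, later fates differ", {
  dfe <- dfe_model(dfe_point(rate = 2e-5, s = 0.05))
  cfg <- tiny_config(seed = 21, n_barcodes = 500, cycles = 5,
                     bottleneck_cells = 5e4, read_depth = 5e4,
                     dfe = dfe_model(), preexisting_dfe = dfe, nf = 1e9)
  pre <- simulate_preexisting(cfg, seed = cfg$seed + 1L)
  expect_gt(nrow(pre), 0)
  expect_true(all(pre$origin_gen < 0))
  expect_true(all(pre$cells0 >= 1))
  sim <- simulate_evolution(cfg)
  tr <- sim$truth[sim$truth$pre_existing, ]
  shared <- intersect(tr$subclone[tr$replicate == 1], tr$subclone[tr$replicate == 2])
  # the same expansion-derived subclones are injected into both replicates
  expect_setequal(tr$subclone[tr$replicate == 1], pre$subclone)
  expect_setequal(shared, pre$subclone)
})

test_that("pre-existing arrival intensity matches the doubling model", {
  # a mutation at doubling k survives into the inoculum with probability
  # lam/(1+lam) (Poisson count mixed over the Exp(1) size factor)
  cfg <- tiny_config(n_barcodes = 10, nf = 1e4, bottleneck_cells = 1e4,
                     preexisting_dfe = dfe_model(dfe_point(rate = 2e-4, s = 0.05)))
  G <- ceiling(log2(cfg$nf))
  sizes <- cfg$nf / 2^(G - seq_len(G))
  lam <- cfg$bottleneck_cells / sizes
  expected <- 2e-4 * sum(sizes * lam / (1 + lam))
  n_arr <- vapply(1:100, function(i) nrow(simulate_preexisting(cfg, seed = i)),
                  numeric(1))
  se <- sd(n_arr) / sqrt(length(n_arr))
  expect_lt(abs(mean(n_arr) - expected), 3 * se + 1e-9)
})

test_that("thinned late-doubling regime preserves the surviving-subclone rate", {
  # single doubling dominated case: nf small, bottleneck far below nf so lam < 1
  cfg <- tiny_config(n_barcodes = 10, nf = 1e6, bottleneck_cells = 1e3,
                     preexisting_dfe = dfe_model(dfe_point(rate = 1e-3, s = 0.05)))
  G <- ceiling(log2(cfg$nf))
  sizes <- cfg$nf / 2^(G - seq_len(G))
  lam <- cfg$bottleneck_cells / sizes
  # P(survive) = lam/(1+lam) under W ~ Exp(1) mixing of a Poisson count
  expected <- 1e-3 * sum(sizes * lam / (1 + lam))
  n_arr <- vapply(1:200, function(i) nrow(simulate_preexisting(cfg, seed = i)),
                  numeric(1))
  se <- sd(n_arr) / sqrt(length(n_arr))
  expect_lt(abs(mean(n_arr) - expected), 3 * se + 1e-9)
})

test_that("mutation arrivals occur at rate mu times unmutated cells", {
  cfg <- tiny_config(seed = 2, n_barcodes = 50, cycles = 2,
                     bottleneck_cells = 1e5, read_depth = 1e4,
                     dfe = dfe_model(dfe_point(rate = 1e-6, s = 0.05)),
                     preexisting_dfe = dfe_model())
  tot <- vapply(1:100, function(i) {
    cfg$seed <- i
    sim <- simulate_evolution(cfg)
    ev <- sim$stats$n_mutation_events
    sum(ev$n_events[ev$replicate == 1])
  }, numeric(1))
  # expected arrivals per generation ~ mu * N(t); N grows g^k from 1e5,
  # unmutated fraction ~1 over 16 generations at this rate
  g <- cfg$dilution^(1 / cfg$gens_per_cycle)
  n_per_gen <- cfg$bottleneck_cells * g^(0:(cfg$gens_per_cycle - 1))
  expected <- 1e-6 * sum(n_per_gen) * cfg$cycles
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("pooled assay mixes 1:9 and grows clones at their fitness", {
  clones <- tibble::tibble(barcode = c("n1", "a1"), s = c(0, 0.06))
  cfg <- sim_config(n_barcodes = 10, seed = 4, read_depth = 1e6,
                    sampling_noise = FALSE)
  assay <- simulate_pooled_assay(clones, cfg, n_tech_reps = 2)
  expect_length(assay, 2)
  tb <- assay[[1]]
  expect_equal(count_generations(tb), c(0L, 8L, 16L, 24L, 32L))
  f0 <- tb$gen_0 / sum(tb$gen_0)
  expect_equal(f0[tb$barcode == "ancestor"], 0.9, tolerance = 1e-5)
  expect_equal(f0[tb$barcode == "n1"], 0.05, tolerance = 1e-5)
  # noise-free: recover s of the adaptive clone from the log-ratio slope
  fit <- estimate_clone_fitness(tb, neutral_barcodes = "ancestor")
  expect_equal(fit$s[fit$barcode == "a1"], 0.06, tolerance = 1e-3)
  expect_equal(fit$s[fit$barcode == "n1"], 0, tolerance = 1e-3)
})

test_that("mutation catalog strata have the configured disruptive probabilities", {
  cat <- simulate_mutation_catalog(2000, 2000, 0.56, 0.25, seed = 8)
  p1 <- mean(cat$effect[cat$step == "first"] %in% c("nonsense", "frameshift"))
  p2 <- mean(cat$effect[cat$step == "second"] %in% c("nonsense", "frameshift"))
  expect_equal(p1, 0.56, tolerance = 0.04)
  expect_equal(p2, 0.25, tolerance = 0.04)
  expect_true(all(cat$background[cat$step == "first"] == "WT"))
  expect_true(all(cat$background[cat$step == "second"] %in% c("cyr1", "gpb2", "tor1")))
})
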
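test_that("simulation config rejects impossible parameters", {
  expect_error(sim_config(rain_rate = 1), "rain_rate")
  expect_error(sim_config(droplet_volume = 0), "droplet_volume")
  expect_error(sim_config(partitioned_fraction = 0), "partitioned_fraction")
  expect_error(sim_config(amplitude_pos_mean = 1200), "separable")
})

test_that("well generator is deterministic and respects zero template", {
  cfg <- sim_config(seed = 31)
  w1 <- simulate_well(50, cfg)
  w2 <- simulate_well(50, cfg)
  expect_identical(w1, w2)
  w3 <- simulate_well(50, cfg, seed = 32)
  expect_false(identical(w1$k_positive, w3$k_positive) &&
                 identical(w1$n_accepted, w3$n_accepted))

  z <- simulate_well(0, cfg)
  expect_identical(z$k_positive, 0L)
  expect_error(simulate_well(-1, cfg), "non-negative")

  b1 <- simulate_wells(10, 25, cfg)
  b2 <- simulate_wells(10, 25, cfg)
  expect_identical(b1, b2)
})

test_that("pooled positive fraction follows the Poisson occupancy law", {
  # C = 123.95 copies/ul, Vd = 8.5e-4 ul -> occupancy 1 - exp(-0.10536) ~ 0.1000
  cfg <- sim_config(seed = 77)
  wells <- simulate_wells(123.95, 50, cfg)
  frac <- sum(wells$k_positive) / sum(wells$n_accepted)
  p0 <- 1 - exp(-123.95 * 8.5e-4)
  n_tot <- sum(wells$n_accepted)
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / n_tot))

  # negative-droplet complement: exp(-C * Vd) band at a second concentration
  wells2 <- simulate_wells(500, 50, sim_config(seed = 78))
  pneg <- exp(-500 * 8.5e-4)
  frac_neg <- 1 - sum(wells2$k_positive) / sum(wells2$n_accepted)
  expect_lt(abs(frac_neg - pneg),
            3 * sqrt(pneg * (1 - pneg) / sum(wells2$n_accepted)))
})

test_that("amplitude export matches the counts and feeds the caller", {
  cfg <- sim_config(seed = 5)
  w <- simulate_well(123.95, cfg, with_amplitudes = TRUE)
  amp <- attr(w, "amplitudes")[[w$well_id]]
  expect_length(amp, w$n_accepted)
  called <- call_droplets(amp)
  expect_equal(called$k_positive, w$k_positive)
})

test_that("dilution series scales concentration by the nominal factors", {
  cfg <- sim_config(seed = 9)
  s <- simulate_dilution_series(437, c(0.1), replicates_per_point = 3, config = cfg)
  expect_equal(unique(s$nominal_concentration), 43.7)

  s1 <- simulate_dilution_series(437, c(1.0), replicates_per_point = 2, config = cfg)
  expect_equal(unique(s1$nominal_concentration), 437)

  expect_error(simulate_dilution_series(437, numeric(0)), "factors")
  expect_error(simulate_dilution_series(437, c(0.1, 0.5)), "decreasing")
  expect_error(simulate_dilution_series(-1, c(0.1)), "positive")

  # estimated concentration ratio between consecutive 10-fold points ~ 10
  set.seed(123)
  ratios <- replicate(200, {
    s <- simulate_dilution_series(400, c(1e-1, 1e-2), replicates_per_point = 4,
                                  config = sim_config(seed = NULL))
    est <- vapply(split(s, s$replicate_group), function(g) {
      m <- merge_replicates(g)
      poisson_quantify(m$k_merged, m$n_merged)$concentration
    }, 0)
    max(est) / min(est)
  })
  expect_lt(abs(mean(ratios) - 10), 1)
})

test_that("LOD experiment draws molecules per replicate as specified", {
  d <- lod_default_design()
  expect_equal(d$replicates, c(2L, 6L, 8L, 12L, 14L))
  expect_equal(d$labels, c(1e-4, 5e-5, 1e-5, 5e-6, 1e-6))
  expect_equal(lod_default_design("stated")$copies_per_well, c(10, 5, 2, 1, 0.5))

  cfg <- sim_config(seed = 21, rain_rate = 0)
  e0 <- simulate_lod_experiment(copies_per_well = c(0, 0), replicates = c(4, 6),
                                config = cfg, labels = c(1e-3, 1e-4))
  expect_true(all(vapply(e0$points, function(p) all(p$wells$k_positive == 0),
                         TRUE)))
  expect_error(
    simulate_lod_experiment(copies_per_well = c(1, 2), replicates = c(2), config = cfg),
    "equal length"
  )

  # detection probability at m = 1 with full partitioning: 1 - e^-1
  cfg1 <- sim_config(seed = 22, partitioned_fraction = 1)
  e1 <- simulate_lod_experiment(copies_per_well = 1, replicates = 10000,
                                config = cfg1, labels = 1e-5)
  frac <- mean(e1$points[[1]]$wells$k_positive >= 1)
  p <- 1 - exp(-1)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("cohort generator pairs truth, comparator calls and droplet wells", {
  spec <- cohort_spec(n_samples = 40, seed = 55)
  cfg <- sim_config(seed = 55)
  c1 <- simulate_cohort(spec, cfg)
  c2 <- simulate_cohort(spec, cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$samples), 40)
  expect_equal(nrow(c1$wells), 40 * 2 * 3)

  # all-zero mixture: everything negative by both methods after the pipeline
  zspec <- cohort_spec(n_samples = 20,
                       class_mix = c(high = 0, low = 0, trace = 0, zero = 1),
                       seed = 7)
  cz <- simulate_cohort(zspec, sim_config(seed = 7, rain_rate = 0))
  expect_true(all(cz$samples$qrtpcr_class == "NEG"))
  res <- quantify_wells(cz$wells)
  expect_true(all(res$mrd_class == "NEG"))

  expect_error(cohort_spec(class_mix = c(high = 0.5, low = 0.5, trace = 0.5,
                                         zero = -0.5)), "non-negative")
  expect_error(cohort_spec(class_mix = c(high = 0.5, low = 0.5, trace = 0.5,
                                         zero = 0.5)), "sum to 1")
})

test_that("trace-level samples are PNQ by the comparator more often than high-level", {
  spec_t <- cohort_spec(n_samples = 300,
                        class_mix = c(high = 0, low = 0, trace = 1, zero = 0),
                        seed = 91)
  spec_h <- cohort_spec(n_samples = 300,
                        class_mix = c(high = 1, low = 0, trace = 0, zero = 0),
                        seed = 92)
  ct <- simulate_cohort(spec_t, sim_config(seed = 91))
  ch <- simulate_cohort(spec_h, sim_config(seed = 92))
  pnq_trace <- mean(ct$samples$qrtpcr_class == "PNQ")
  pnq_high <- mean(ch$samples$qrtpcr_class == "PNQ")
  expect_gt(pnq_trace, pnq_high)
})
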
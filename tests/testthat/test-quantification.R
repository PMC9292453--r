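test_that("occupancy estimate matches numeric inversion of the partition model", {
  # independent oracle: solve 1 - exp(-lambda) = k/n numerically
  invert <- function(k, n) {
    if (k == 0) return(0)
    stats::uniroot(function(l) 1 - exp(-l) - k / n, c(1e-12, 60),
                   tol = 1e-12)$root
  }
  for (n in 1:50) {
    for (k in 0:(n - 1)) {
      q <- poisson_quantify(k, n, droplet_volume = 1)
      expect_equal(q$lambda_hat, invert(k, n), tolerance = 1e-9)
    }
  }
})

test_that("closed-form example and degenerate counts behave as specified", {
  q <- poisson_quantify(2000, 20000, droplet_volume = 8.5e-4)
  expect_equal(q$lambda_hat, 0.105361, tolerance = 1e-5)
  expect_equal(q$concentration, 123.95, tolerance = 1e-4)
  expect_false(q$saturated)

  q0 <- poisson_quantify(0, 20000)
  expect_identical(q0$lambda_hat, 0)
  expect_identical(q0$concentration, 0)
  expect_identical(q0$ci_low, 0)

  qs <- poisson_quantify(20000, 20000)
  expect_true(qs$saturated)
  expect_identical(qs$concentration, Inf)
  expect_true(is.finite(qs$ci_low) && qs$ci_low > 0)

  expect_error(poisson_quantify(5, 0), "positive")
  expect_error(poisson_quantify(30, 20), "k")
})

test_that("lambda estimate is strictly monotone in k and CI brackets the estimate", {
  n <- 12000
  q <- poisson_quantify(0:(n - 1), rep(n, n))
  expect_true(all(diff(q$lambda_hat) > 0))
  expect_true(all(q$ci_low <= q$concentration + 1e-12))
  expect_true(all(q$concentration <= q$ci_high + 1e-12))
})

test_that("droplet-count QC keeps the 9000 boundary inclusive and logs rejections", {
  w <- make_wells(c(1, 1, 1), c(9000, 8999, 20000))
  qc <- qc_filter(w)
  expect_setequal(qc$accepted$n_accepted, c(9000L, 20000L))
  expect_equal(qc$rejected$n_accepted, 8999L)
  expect_match(qc$rejected$qc_reason, "8999")

  empty <- qc_filter(make_wells(integer(0), integer(0)))
  expect_equal(nrow(empty$accepted), 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("replicate merging pools partitions and refuses mixed groups", {
  m <- merge_replicates(make_wells(c(3, 1), c(10000, 12000)))
  expect_equal(m$k_merged, 4)
  expect_equal(m$n_merged, 22000)

  single <- merge_replicates(make_wells(7, 15000))
  expect_equal(single$k_merged, 7)
  expect_equal(single$n_merged, 15000)

  # quantifying merged counts is the same as one large well
  qa <- poisson_quantify(m$k_merged, m$n_merged)
  qb <- poisson_quantify(4, 22000)
  expect_equal(qa$concentration, qb$concentration)

  mixed <- rbind(make_wells(1, 10000, target = "p190"),
                 make_wells(1, 10000, target = "p210"))
  expect_error(merge_replicates(mixed), "mixed targets")
  expect_error(merge_replicates(make_wells(integer(0), integer(0))), "empty")
})

test_that("MRD ratio is target over control times 100; predilution is recorded only", {
  tq <- function(conc) {
    # counts whose Poisson estimate hits conc exactly at Vd = 8.5e-4
    n <- 2e6
    k <- round(n * (1 - exp(-conc * 8.5e-4)))
    poisson_quantify(k, n)
  }
  target <- tq(0.05); control <- tq(100)
  m <- mrd_ratio(target, control, dilution_factor = 5)
  expect_equal(m$ratio, 0.05, tolerance = 1e-2)
  expect_equal(m$dilution_factor, 5)

  expect_equal(mrd_ratio(tq(78), tq(100))$ratio, 78, tolerance = 1e-3)
  expect_equal(mrd_ratio(poisson_quantify(0, 20000), tq(100))$ratio, 0)
  expect_error(mrd_ratio(tq(1), poisson_quantify(0, 20000)), "control inadequate")
})

test_that("amplitude threshold calling recovers the positive cluster count", {
  set.seed(42)
  amp <- sample(c(rnorm(19900, 1000, 50), rnorm(100, 8000, 100)))
  res <- call_droplets(amp)
  # oracle: clusters are >100 SDs apart, so any threshold in the gap gives 100
  expect_equal(sum(amp > 1300 & amp < 7000), 0)
  expect_equal(res$k_positive, 100)
  expect_equal(res$n_accepted, 20000)
  # threshold sits in the empty zone above the background cluster
  expect_gt(res$threshold, max(amp[amp < 1300]))
  expect_lt(res$threshold, 7000)

  pure_bg <- rnorm(5000, 1000, 50)
  expect_equal(call_droplets(pure_bg)$k_positive, 0)

  expect_error(call_droplets(numeric(0)), "no amplitudes")
  expect_error(call_droplets(rnorm(50, 1000, 50)), "fewer than 100")
})

test_that("pooled merging beats averaging per-well estimates at trace level", {
  # ~1 expected positive droplet per well
  set.seed(101)
  conc <- 1 / (8.5e-4 * 20000)
  p <- 1 - exp(-conc * 8.5e-4)
  n_rep <- 400; n_wells <- 4; n <- 20000
  err_merge <- err_avg <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    k <- rbinom(n_wells, n, p)
    q_merged <- poisson_quantify(sum(k), n_wells * n)$concentration
    q_each <- poisson_quantify(k, rep(n, n_wells))$concentration
    err_merge[i] <- (q_merged - conc)^2
    err_avg[i] <- (mean(q_each) - conc)^2
  }
  expect_lte(sqrt(mean(err_merge)), sqrt(mean(err_avg)) * 1.0000001)
})

test_that("plate-level quantification pipeline produces ratios and classes", {
  wells <- rbind(
    make_wells(c(150, 160, 140), c(20000, 21000, 19000), sample_id = "S1"),
    make_wells(c(3400, 3300, 3500), c(20000, 20500, 19500), sample_id = "S1",
               target = "control_ABL1", well_id = sprintf("C%02d", 1:3)),
    make_wells(0, 8000, sample_id = "S1", well_id = "LOWQC")
  )
  res <- quantify_wells(wells)
  expect_equal(nrow(res), 1)
  expect_equal(res$k_target, 450)         # the QC-failed well is excluded
  expect_equal(res$n_target, 60000)
  expect_equal(res$mrd_class, "POS")
  expect_equal(res$ratio,
               100 * poisson_quantify(450, 60000)$concentration /
                 poisson_quantify(10200, 60000)$concentration)
})
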
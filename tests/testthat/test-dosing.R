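test_that("gavage schedules deliver the exact daily dose", {
  s <- gavage_schedule(25, 0.225, 7)
  expect_equal(nrow(s), 7)
  expect_true(all(s$amount == 5.625))
  expect_identical(sum(s$amount), 39.375)
  expect_equal(s$start, 24 * 0:6)

  s0 <- gavage_schedule(0, 0.225, 7)
  expect_true(all(s0$amount == 0))

  s28 <- gavage_schedule(75, 0.225, 28)
  expect_equal(nrow(s28), 28)
  expect_true(all(s28$amount == 16.875))

  expect_error(gavage_schedule(-5, 0.225, 7), "non-negative")
  expect_error(gavage_schedule(25, 0.225, 0), "n_days")
})

test_that("drinking schedules spread the daily dose over 48 half-hour slots", {
  s <- drinking_schedule(25, 0.225, 1, pattern = uniform_drinking_pattern())
  expect_equal(nrow(s), 48)
  expect_true(all(abs(s$amount - 0.1171875) < 1e-15))
  expect_equal(s$start, seq(0, 23.5, by = 0.5))

  # a pattern concentrated in one slot reduces to a time-shifted gavage
  w <- rep(0, 48); w[17] <- 1
  s1 <- drinking_schedule(40, 0.225, 2, pattern = drinking_pattern(w))
  g <- gavage_schedule(40, 0.225, 2)
  active <- s1[s1$amount > 0, ]
  expect_equal(nrow(active), 2)
  expect_equal(active$amount, g$amount)
  expect_equal(active$start, g$start + 0.5 * 16)

  expect_error(drinking_schedule(25, 0.225, 1, pattern = rep(1 / 47, 47)),
               "48")
})

test_that("scheduled mass equals dose * bw * n_days for arbitrary patterns", {
  set.seed(7)
  for (i in 1:5) {
    w <- runif(48); w <- w / sum(w)
    dose <- runif(1, 0, 120); bw <- runif(1, 0.1, 0.5)
    n <- sample(1:28, 1)
    s <- drinking_schedule(dose, bw, n, pattern = drinking_pattern(w))
    expect_lt(abs(sum(s$amount) - dose * bw * n) / max(dose * bw * n, 1e-12),
              1e-12)
    g <- gavage_schedule(dose, bw, n)
    expect_lt(abs(sum(g$amount) - dose * bw * n) / max(dose * bw * n, 1e-12),
              1e-12)
  }
})

test_that("infusion_rate is a right-continuous square wave with exact mass", {
  s <- gavage_schedule(25, 0.225, 2)
  pulse <- 15 / 3600
  expect_identical(infusion_rate(-1, s), 0)
  expect_equal(infusion_rate(pulse / 2, s), 5.625 / pulse)  # 1350 mg/h
  # boundary conventions: start belongs to the pulse, end does not
  expect_equal(infusion_rate(24, s), 5.625 / pulse)
  expect_identical(infusion_rate(pulse, s), 0)
  # pulse-edge-aligned quadrature recovers the scheduled mass exactly
  mids <- s$start + s$duration / 2
  expect_lt(abs(sum(infusion_rate(mids, s) * s$duration) - sum(s$amount)),
            1e-12 * sum(s$amount))
})

test_that("drinking patterns validate their invariants", {
  expect_error(drinking_pattern(rep(1 / 47, 47)), "48")
  expect_error(drinking_pattern(rep(1 / 50, 48)), "sum to 1")
  w <- rep(1 / 48, 48); w[1] <- -w[1]; w[2] <- w[2] - 2 * w[1]
  expect_error(drinking_pattern(w), "non-negative")
})

test_that("the default diurnal pattern is dark-dominant and normalized", {
  w <- default_drinking_pattern()
  expect_length(unclass(w), 48)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(sum(w[1:24]), 0.85, tolerance = 1e-9)  # dark-phase fraction
  # drinking bout right after dark onset: first slot is the daily maximum
  expect_equal(which.max(w), 1L)
  # anticipatory rise at the end of the dark phase
  expect_gt(w[24], w[12])
  # light phase is uniform and low
  expect_true(all(abs(w[25:48] - 0.15 / 24) < 1e-12))
})

test_that("pattern CSV files round-trip", {
  w <- default_drinking_pattern()
  tf <- tempfile(fileext = ".csv")
  write_drinking_pattern(w, tf)
  expect_equal(as.numeric(read_drinking_pattern(tf)), as.numeric(w),
               tolerance = 1e-12)
  prof <- read_drinking_pattern(system.file(
    "extdata", "drinking_pattern_default.csv", package = "caaPBPK"))
  expect_equal(as.numeric(prof), as.numeric(w), tolerance = 1e-12)
})

test_that("steady-state daily AUC is insensitive to pattern permutation (linear regime)", {
  p <- params_with(1808, 15)
  w <- default_drinking_pattern()
  day2_auc <- function(tc) {
    sub <- tc[tc$time_h >= 24, ]
    caaPBPK:::trapz(sub$time_h, sub$venous_mg_per_L)
  }
  tc1 <- run_simulation("drinking_water", 10, 2, params = p, pattern = w)
  tc2 <- run_simulation("drinking_water", 10, 2, params = p,
                        pattern = drinking_pattern(rev(as.numeric(w))))
  expect_equal(day2_auc(tc2) / day2_auc(tc1), 1, tolerance = 0.01)
  # ... while Cmax is pattern-sensitive, but boundedly so: the diurnal
  # bout concentrates intake less than 3-fold relative to uniform sipping
  tcu <- run_simulation("drinking_water", 10, 2, params = p,
                        pattern = uniform_drinking_pattern())
  r <- compute_cmax(tc1)$cmax / compute_cmax(tcu)$cmax
  expect_gt(r, 1)
  expect_lt(r, 3)
})

test_that("gavage Cmax is insensitive to the 10 s vs 15 s pulse description", {
  p <- params_with(1808, 15)
  bw <- p$physiology$body_weight
  tc15 <- run_simulation("gavage", 25, 2, params = p)
  s10 <- gavage_schedule(25, bw, 2, pulse_duration = 10 / 3600)
  out <- caaPBPK:::integrate_schedule(s10, 48, p, output_step = 0.01,
                                      rtol = 1e-8, atol = 1e-10,
                                      compiled = TRUE)
  cmax10 <- max(out[, "venous"])
  expect_equal(compute_cmax(tc15)$cmax / cmax10, 1, tolerance = 0.005)
})
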
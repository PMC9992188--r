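test_that("a zero-dose run returns an identically zero time course", {
  tc <- run_simulation("gavage", 0, 2)
  expect_true(all(tc$venous_mg_per_L == 0))
  expect_true(all(tc$a_metabolized == 0))
  expect_true(all(tc$a_absorbed == 0))
  expect_equal(range(tc$time_h), c(0, 48))
})

test_that("mass is conserved along every simulated course", {
  tol <- 1e-3   # acceptance bound; the integrator does far better
  tc1 <- run_simulation("gavage", 25, 2)
  expect_lt(attr(tc1, "conservation_error"), tol)
  tc2 <- run_simulation("drinking_water", 25, 1)
  expect_lt(attr(tc2, "conservation_error"), tol)
  expect_lt(attr(gavage10_7day(), "conservation_error"), tol)
  # washout accounting: everything infused is eventually absorbed
  tot <- attr(tc1, "totals")
  expect_equal(tot$absorbed, attr(tc1, "total_infused"), tolerance = 1e-5)
  expect_equal(tot$metabolized + tot$exhaled, tot$absorbed, tolerance = 1e-4)
})

test_that("exhalation is a minor elimination route", {
  for (tc in reference_timecourses()) {
    tot <- attr(tc, "totals")
    expect_lt(tot$exhaled / tot$absorbed, 0.02)
  }
})

test_that("daily gavage reaches periodic steady state within a week", {
  tc <- gavage10_7day()
  day <- pmin(floor(tc$time_h / 24) + 1, 7)
  peaks <- tapply(tc$venous_mg_per_L, day, max)
  # repeating daily peaks: inter-day variation below 1% from day 3 on
  expect_lt(max(abs(diff(peaks[3:7])) / peaks[3:7][-1]), 0.01)

  ss <- check_steady_state(tc)
  expect_true(ss)
  daily <- attr(ss, "daily")
  expect_equal(nrow(daily), 7)
  expect_true(all(daily$peak >= daily$trough))
})

test_that("steady-state check handles degenerate and short runs", {
  tc0 <- run_simulation("gavage", 0, 2)
  expect_true(check_steady_state(tc0))
  tc1 <- run_simulation("gavage", 10, 1)
  expect_error(check_steady_state(tc1), "2 simulated days")
})

test_that("the output grid captures the gavage peak", {
  p <- params_with()
  tc <- run_simulation("gavage", 25, 2, params = p)
  fine <- run_simulation("gavage", 25, 2, params = p, output_step = 0.001)
  expect_equal(compute_cmax(tc)$cmax / compute_cmax(fine)$cmax, 1,
               tolerance = 0.001)
})

test_that("grid and tolerance refinement leave Cmax and AUC unchanged", {
  p <- params_with()
  tc <- run_simulation("gavage", 25, 2, params = p)
  ref <- run_simulation("gavage", 25, 2, params = p,
                        output_step = 0.005, rtol = 5e-9, atol = 5e-11)
  expect_equal(compute_cmax(ref)$cmax / compute_cmax(tc)$cmax, 1,
               tolerance = 0.001)
  expect_equal(compute_auc(ref) / compute_auc(tc), 1, tolerance = 0.001)
})

test_that("dose doubling superposes in the linear regime", {
  p <- params_with(1808, 15)
  lo <- run_simulation("gavage", 10, 3, params = p)
  hi <- run_simulation("gavage", 20, 3, params = p)
  expect_equal(compute_cmax(hi)$cmax / compute_cmax(lo)$cmax, 2,
               tolerance = 0.02)
  expect_equal(compute_auc(hi) / compute_auc(lo), 2, tolerance = 0.02)
})

test_that("with no metabolism the tissues hold partition equilibrium with blood", {
  p <- pbpk_params(metabolism = metabolic_params(0, 15))
  tc <- run_simulation("gavage", 10, 2, params = p, washout = FALSE)
  last <- tc[nrow(tc), ]   # 24 h after the final pulse: gut long empty
  d <- caaPBPK:::derived_params(p)
  ca <- last$arterial_mg_per_L
  for (tis in c("liver", "fat", "bone_marrow", "richly", "slowly")) {
    ratio <- last[[paste0("c_", tis)]] / (d$p_tissue[[tis]] * ca)
    expect_equal(ratio, 1, tolerance = 0.01)
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(run_simulation("gavage", 10, 2, output_step = 0.3),
               "output_step")
  expect_error(run_simulation("gavage", 10, 2, output_step = 0),
               "output_step")
  expect_error(run_simulation("swallow", 10, 2))
})

test_that("time-course CSV export carries a provenance header", {
  tc <- run_simulation("gavage", 10, 1)
  tf <- tempfile(fileext = ".csv")
  write_timecourse_csv(tc, tf)
  lines <- readLines(tf, n = 4)
  expect_match(lines[1], "^# caaPBPK")
  expect_match(lines[2], "^# params_md5: [0-9a-f]{32}$")
  body <- utils::read.csv(tf, comment.char = "#")
  expect_equal(nrow(body), nrow(tc))
  expect_equal(body$venous_mg_per_L, tc$venous_mg_per_L, tolerance = 1e-6)
})
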
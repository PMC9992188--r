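# Minimal hand-built time course for the pure-arithmetic metric checks.
fake_tc <- function(time, venous, bm = NULL) {
  df <- data.frame(time_h = time, venous_mg_per_L = venous)
  if (!is.null(bm)) df$c_bone_marrow <- bm
  structure(df, class = c("pbpk_timecourse", "data.frame"))
}

test_that("Cmax is the earliest maximum of the venous curve", {
  tc <- fake_tc(seq(0, 24, by = 0.5), rep(2, 49))
  cm <- compute_cmax(tc)
  expect_equal(cm$cmax, 2)
  expect_equal(cm$t_cmax, 0)       # tie broken by earliest time

  z <- run_simulation("gavage", 0, 1)
  cm0 <- compute_cmax(z)
  expect_equal(cm0$cmax, 0)
  expect_equal(cm0$t_cmax, 0)

  expect_error(compute_cmax(fake_tc(numeric(0), numeric(0))), "empty")
})

test_that("AUC is the trapezoidal integral of the venous curve", {
  expect_equal(compute_auc(fake_tc(seq(0, 24, by = 0.5), rep(2, 49))), 48)
  # triangle 0 -> 1 -> 0 over 2 h has unit area
  expect_equal(compute_auc(fake_tc(c(0, 1, 2), c(0, 1, 0))), 1)
})

test_that("trapezoidal AUC matches the ODE-integrated AUC", {
  tc <- gavage10_7day()
  expect_equal(compute_auc(tc, "trapezoid") / compute_auc(tc, "ode"), 1,
               tolerance = 0.001)
})

test_that("bioavailability equals 1 without metabolism and the well-stirred form in the linear regime", {
  p0 <- pbpk_params(metabolism = metabolic_params(0, 15))
  tc0 <- run_simulation("gavage", 10, 2, params = p0)
  expect_equal(compute_bioavailability(tc0), 1, tolerance = 1e-6)

  # low dose, strong extraction: concentrations far below Km
  p <- params_with(1808, 15)
  tc <- run_simulation("gavage", 1, 2, params = p)
  expect_equal(compute_bioavailability(tc),
               wellstirred_bioavailability(p), tolerance = 0.05)

  # and a low-extraction corner of the read-across grid
  p2 <- params_with(226, 122)
  tc2 <- run_simulation("gavage", 1, 2, params = p2)
  expect_equal(compute_bioavailability(tc2),
               wellstirred_bioavailability(p2), tolerance = 0.05)

  expect_error(compute_bioavailability(run_simulation("gavage", 0, 1)),
               "zero-dose")
})

test_that("bioavailability rises with dose and falls with metabolic capacity", {
  p <- params_with(226, 15.3)    # most saturable corner
  f_lo <- compute_bioavailability(run_simulation("gavage", 10, 2, params = p))
  f_hi <- compute_bioavailability(run_simulation("gavage", 83.9, 2, params = p))
  expect_gte(f_hi, f_lo)

  p_big <- params_with(904, 15.3)
  f_big <- compute_bioavailability(run_simulation("gavage", 10, 2,
                                                  params = p_big))
  expect_lte(f_big, f_lo)
})

test_that("tissue exposure averages the concentration and scales by Cmax", {
  # constant equilibrium profile: average/Cmax recovers the partition ratio
  tc <- fake_tc(seq(0, 24, by = 0.5), rep(2, 49), bm = rep(2 * 1.06, 49))
  ex <- compute_tissue_exposure(tc, "bone_marrow")
  expect_equal(ex$avg_conc, 2.12)
  expect_equal(ex$avg_to_cmax_ratio, 1.06)

  expect_error(compute_tissue_exposure(tc, "spleen"), "unknown tissue")
})

test_that("sustained drinking exposure sits closer to Cmax than gavage spikes", {
  tcs <- reference_timecourses()
  bm_g <- compute_tissue_exposure(tcs$gavage_75, "bone_marrow")
  bm_w <- compute_tissue_exposure(tcs$dw_75, "bone_marrow")
  expect_gt(bm_w$avg_to_cmax_ratio, 4 * bm_g$avg_to_cmax_ratio)
  # both are bounded by the bone-marrow partition coefficient
  expect_lt(bm_w$avg_to_cmax_ratio, 1.06)
})

test_that("route comparison reports gavage-dominant Cmax and similar AUC", {
  cmp <- compare_routes(75, 4, params = params_with(1808, 15))
  expect_gte(cmp$cmax_ratio, 1)
  expect_gt(cmp$cmax_ratio, 4)
  expect_gte(cmp$auc_ratio, 0.95)
  expect_lte(cmp$auc_ratio, 1.20)
  expect_equal(nrow(cmp$metrics), 2)

  expect_error(compare_routes(0, 4), "zero dose")
})

test_that("route AUC ratio is unity in a linear-clearance regime", {
  # low dose, high-affinity metabolism: clearance is linear and AUC is
  # insensitive to the within-day dosing profile
  cmp <- compare_routes(1, 4, params = params_with(1808, 15))
  expect_equal(cmp$auc_ratio, 1, tolerance = 0.01)
})

test_that("a tracer without metabolism keeps the route AUC ratio in band", {
  cmp <- compare_routes(10, 4, params = pbpk_params(
    metabolism = metabolic_params(0, 15)))
  expect_gte(cmp$cmax_ratio, 1)
  expect_gte(cmp$auc_ratio, 0.95)
  expect_lte(cmp$auc_ratio, 1.20)
})
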
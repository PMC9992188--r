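#' Run a PBPK simulation over a dosing schedule
#'
#' Integrates the flow-limited PBPK model over `n_days` of dosing by the
#' requested route and returns a dense time course.  Infusions are exact
#' square pulses: the integration is restarted at every pulse edge, so the
#' delivered mass is exact and no event smoothing occurs.  The output grid
#' is `output_step` (default 0.01 h) with every pulse edge included.
#'
#' After the dosing horizon the model is silently integrated drug-free
#' until the mass remaining in the gut and tissues falls below 1e-6 of the
#' total infused mass (or 240 h at most); the cumulative totals at the end
#' of this washout parameterize [compute_bioavailability()].
#'
#' @param route `"gavage"` or `"drinking_water"`.
#' @param dose Administered dose, mg/kg/day.
#' @param n_days Number of dosing days (>= 1); the reported time course
#'   spans `[0, 24 * n_days]` h.
#' @param params A [pbpk_params()] object.
#' @param pattern Drinking pattern (drinking-water route only).
#' @param output_step Output grid spacing, h; must be in (0, 0.25].
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @param compiled Use the compiled right-hand side (default) or the
#'   pure-R one (slower; intended for cross-checking).
#' @param washout Perform the terminal washout extension (default TRUE).
#' @return A `pbpk_timecourse`: a data frame with columns `time_h`,
#'   `venous_mg_per_L`, `arterial_mg_per_L`, one amount column (`a_*`, mg)
#'   per state, and one concentration column (`c_*`, mg/L) per tissue.
#'   Attributes carry the schedule, parameters, washout totals and the
#'   worst mass-conservation error.
#' @examples
#' \donttest{
#' tc <- run_simulation("gavage", dose = 10, n_days = 2)
#' compute_cmax(tc)
#' }
#' @export
run_simulation <- function(route = c("gavage", "drinking_water"),
                           dose, n_days,
                           params = pbpk_params(),
                           pattern = default_drinking_pattern(),
                           output_step = 0.01,
                           rtol = 1e-8, atol = 1e-10,
                           compiled = TRUE,
                           washout = TRUE) {
  route <- match.arg(route)
  stopifnot(inherits(params, "pbpk_params"))
  if (!is.finite(output_step) || output_step <= 0 || output_step > 0.25)
    stop("output_step must be in (0, 0.25] h")
  bw <- params$physiology$body_weight
  schedule <- if (route == "gavage") {
    gavage_schedule(dose, bw, n_days)
  } else {
    drinking_schedule(dose, bw, n_days, pattern = pattern)
  }
  t_end <- 24 * n_days

  out <- integrate_schedule(schedule, t_end, params,
                            output_step = output_step,
                            rtol = rtol, atol = atol, compiled = compiled)

  total_infused <- sum(schedule$amount)
  cons <- conservation_error(out, schedule, total_infused)

  y_end <- out[nrow(out), STATE_NAMES]
  wash <- list(hours = 0, final_state = y_end)
  if (washout && total_infused > 0) {
    wash <- washout_extension(y_end, t_end, params,
                              total_infused = total_infused,
                              rtol = rtol, atol = atol, compiled = compiled)
  }
  fin <- wash$final_state

  tc <- build_timecourse(out, params)
  structure(tc,
            class = c("pbpk_timecourse", "data.frame"),
            route = route, dose = dose, n_days = n_days,
            output_step = output_step,
            params = params, schedule = schedule,
            total_infused = total_infused,
            conservation_error = cons,
            washout_hours = wash$hours,
            totals = list(
              absorbed = unname(fin["a_absorbed"]),
              metabolized = unname(fin["a_metabolized"]),
              exhaled = unname(fin["a_exhaled"]),
              firstpass_escape = unname(fin["a_firstpass_escape"])))
}

# Piecewise integration across pulse edges.  Returns a matrix with columns
# time, the 11 states, venous, arterial.
integrate_schedule <- function(schedule, t_end, params, output_step,
                               rtol, atol, compiled, y0 = NULL) {
  if (is.null(y0)) y0 <- pbpk_state()
  edges <- sort(unique(c(0, t_end,
                         schedule$start, schedule$start + schedule$duration)))
  edges <- edges[edges >= 0 & edges <= t_end]
  grid <- seq(0, t_end, by = output_step)
  ft <- sort(unique(c(grid, edges)))
  # collapse grid points indistinguishable from a pulse edge
  ft <- ft[c(TRUE, diff(ft) > 1e-12)]
  seg_idx <- match(edges, ft)

  ncols <- 1 + length(STATE_NAMES) + 2
  res <- matrix(NA_real_, nrow = length(ft), ncol = ncols)
  colnames(res) <- c("time", STATE_NAMES, "venous", "arterial")

  # per-segment constant infusion rate, from the event containing the midpoint
  starts <- schedule$start
  rates <- schedule$amount / schedule$duration
  seg_rate <- function(mid) {
    i <- findInterval(mid, starts)
    if (i >= 1 && mid < starts[i] + schedule$duration[i]) rates[i] else 0
  }

  y <- y0
  pv <- param_vector(params)
  rinf_slot <- length(pv)
  d <- derived_params(params)

  for (s in seq_len(length(seg_idx) - 1L)) {
    i0 <- seg_idx[s]
    i1 <- seg_idx[s + 1L]
    times <- ft[i0:i1]
    pv[rinf_slot] <- seg_rate((times[1] + times[length(times)]) / 2)
    if (compiled) {
      sol <- deSolve::lsoda(y, times, func = "pbpk_deriv", parms = pv,
                            dllname = "caaPBPK", initfunc = "pbpk_init",
                            nout = 2, outnames = c("venous", "arterial"),
                            rtol = rtol, atol = atol)
    } else {
      sol <- deSolve::lsoda(y, times, func = rhs_r_factory(d, pv[rinf_slot]),
                            parms = NULL, rtol = rtol, atol = atol)
    }
    if (nrow(sol) < length(times))
      stop(sprintf(paste0("integrator failure in segment [%g, %g] h ",
                          "(returned %d of %d requested times)"),
                   times[1], times[length(times)], nrow(sol), length(times)))
    res[i0:i1, ] <- sol[, colnames(res)]
    y <- sol[nrow(sol), STATE_NAMES]
    neg <- y[MASS_STATES] < 0
    if (any(y[MASS_STATES] < -1e-6 * max(1, sum(schedule$amount))))
      stop(sprintf("negative state beyond tolerance at t = %g h", ft[i1]))
    y[MASS_STATES][neg] <- 0
  }
  res
}

# Pure-R right-hand side (cross-check path); mirrors src/pbpk.c.
rhs_r_factory <- function(d, rinf) {
  qt <- unname(d$q_tissue); vt <- unname(d$v_tissue); pt <- unname(d$p_tissue)
  ql <- qt[1]
  function(t, y, p) {
    cvt <- y[2:6] / (vt * pt)
    cv <- sum(qt * cvt) / d$q_total
    ca <- d$q_total * cv / (d$q_total + d$q_alv / d$p_blood_air)
    cvl <- cvt[1]
    rmet <- d$vmax * cvl / (d$km + cvl)
    rabs <- d$ka * y[1]
    rexh <- d$q_alv * ca / d$p_blood_air
    dy <- numeric(11)
    dy[1] <- rinf - rabs
    dy[2:6] <- qt * (ca - cvt)
    dy[2] <- dy[2] + rabs - rmet
    dy[7] <- rmet
    dy[8] <- rexh
    dy[9] <- rabs
    dy[10] <- rabs * ql / (ql + d$vmax / (d$km + cvl))
    dy[11] <- cv
    list(dy, venous = cv, arterial = ca)
  }
}

# Worst relative mass-balance error over the output grid: the sum of the
# physical-mass states must equal the mass infused up to each time.
conservation_error <- function(out, schedule, total_infused) {
  if (total_infused <= 0) return(0)
  # cumulative infused mass is piecewise linear with knots at pulse edges
  knots <- c(0)
  vals <- c(0)
  cum <- 0
  for (i in seq_len(nrow(schedule))) {
    knots <- c(knots, schedule$start[i], schedule$start[i] + schedule$duration[i])
    vals <- c(vals, cum, cum + schedule$amount[i])
    cum <- cum + schedule$amount[i]
  }
  inf_t <- stats::approx(knots, vals, xout = out[, "time"], rule = 2,
                         ties = "ordered")$y
  in_model <- rowSums(out[, MASS_STATES, drop = FALSE])
  max(abs(in_model - inf_t)) / total_infused
}

washout_extension <- function(y, t_start, params, total_infused,
                              rtol, atol, compiled,
                              rel_threshold = 1e-6, max_hours = 240) {
  d <- derived_params(params)
  pv <- param_vector(params, infusion_rate = 0)
  t <- t_start
  residual <- function(y) sum(y[c("a_gut", paste0("a_", TISSUES))])
  while (residual(y) > rel_threshold * total_infused && t < t_start + max_hours) {
    times <- c(t, t + 12)
    if (compiled) {
      sol <- deSolve::lsoda(y, times, func = "pbpk_deriv", parms = pv,
                            dllname = "caaPBPK", initfunc = "pbpk_init",
                            nout = 2, outnames = c("venous", "arterial"),
                            rtol = rtol, atol = atol)
    } else {
      sol <- deSolve::lsoda(y, times, func = rhs_r_factory(d, 0),
                            parms = NULL, rtol = rtol, atol = atol)
    }
    y <- sol[nrow(sol), STATE_NAMES]
    t <- t + 12
  }
  list(hours = t - t_start, final_state = y)
}

build_timecourse <- function(out, params) {
  d <- derived_params(params)
  tc <- data.frame(time_h = out[, "time"],
                   venous_mg_per_L = out[, "venous"],
                   arterial_mg_per_L = out[, "arterial"])
  for (nm in STATE_NAMES) tc[[nm]] <- out[, nm]
  for (i in seq_along(TISSUES)) {
    tc[[paste0("c_", TISSUES[i])]] <-
      out[, paste0("a_", TISSUES[i])] / d$v_tissue[[i]]
  }
  tc
}

#' Steady-state check for a multi-day time course
#'
#' Computes the peak and trough venous concentration of each simulated day
#' and reports whether the final two days agree within 1 percent relative
#' (both peak and trough), i.e. whether the daily profile has converged to
#' its periodic steady state.
#'
#' @param tc A `pbpk_timecourse` from [run_simulation()].
#' @return Logical scalar with attribute `daily`, a data frame with one
#'   row per day (`day`, `peak`, `trough`).
#' @export
check_steady_state <- function(tc) {
  stopifnot(inherits(tc, "pbpk_timecourse"))
  n_days <- attr(tc, "n_days")
  if (is.null(n_days) || n_days < 2)
    stop("steady-state check needs at least 2 simulated days")
  day <- pmin(floor(tc$time_h / 24) + 1, n_days)
  peaks <- tapply(tc$venous_mg_per_L, day, max)
  troughs <- tapply(tc$venous_mg_per_L, day, min)
  daily <- data.frame(day = as.integer(names(peaks)),
                      peak = as.numeric(peaks),
                      trough = as.numeric(troughs))
  rel <- function(a, b) if (a == 0 && b == 0) 0 else abs(a - b) / max(a, b)
  n <- nrow(daily)
  ok <- rel(daily$peak[n], daily$peak[n - 1]) < 0.01 &&
    rel(daily$trough[n], daily$trough[n - 1]) < 0.01
  structure(ok, daily = daily)
}

#' Write a time course to CSV
#'
#' Writes the time-course table with a provenance header (`#`-prefixed
#' lines recording the package version, route, dose and a parameter hash)
#' followed by a standard CSV.
#'
#' @param tc A `pbpk_timecourse`.
#' @param path Output file path.
#' @param provenance Write the provenance header (default TRUE).
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path, provenance = TRUE) {
  stopifnot(inherits(tc, "pbpk_timecourse"))
  if (provenance) {
    writeLines(provenance_header(attr(tc, "params"),
                                 route = attr(tc, "route"),
                                 dose = attr(tc, "dose"),
                                 n_days = attr(tc, "n_days")), path)
    suppressWarnings(utils::write.table(tc, path, append = TRUE, sep = ",",
                                        row.names = FALSE, qmethod = "double"))
  } else {
    utils::write.csv(tc, path, row.names = FALSE)
  }
  invisible(path)
}

provenance_header <- function(params, ...) {
  extra <- list(...)
  ver <- as.character(utils::packageVersion("caaPBPK"))
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass_rec(params), tf)
  hash <- unname(tools::md5sum(tf))
  c(sprintf("# caaPBPK %s", ver),
    sprintf("# params_md5: %s", hash),
    if (length(extra))
      sprintf("# %s", paste(names(extra), unlist(extra),
                            sep = "=", collapse = " ")))
}

unclass_rec <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_rec)
  x
}

#' @export
print.pbpk_timecourse <- function(x, ...) {
  cat(sprintf("PBPK time course: %s, %g mg/kg/day, %d day(s), %d time points\n",
              attr(x, "route"), attr(x, "dose"), attr(x, "n_days"), nrow(x)))
  cat(sprintf("  venous Cmax %.4g mg/L; mass-balance error %.2g (relative)\n",
              max(x$venous_mg_per_L), attr(x, "conservation_error")))
  invisible(x)
}

#' Plot a simulated venous concentration profile
#'
#' @param x A `pbpk_timecourse`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pbpk_timecourse <- function(x, ...) {
  graphics::plot(x$time_h, x$venous_mg_per_L, type = "l",
                 xlab = "time (h)", ylab = "venous concentration (mg/L)", ...)
  invisible(x)
}
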
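# 15 seconds in hours: duration of every oral infusion pulse.
PULSE_H <- 15 / 3600

#' Drinking-pattern container
#'
#' A drinking pattern assigns a non-negative weight to each of the 48
#' half-hour slots of the 24-h day; the weights are the fractions of the
#' daily water (hence chemical) intake consumed in each slot and must sum
#' to 1.  Slot `k` (1-based) covers `[0.5*(k-1), 0.5*k)` hours after the
#' start of the simulated day, which is taken as the onset of the dark
#' phase.
#'
#' @param weights Numeric vector of length 48, non-negative, summing to 1
#'   within 1e-12.
#' @return An object of class `drinking_pattern` (numeric vector).
#' @seealso [default_drinking_pattern()], [uniform_drinking_pattern()],
#'   [diurnal_drinking_pattern()]
#' @export
drinking_pattern <- function(weights) {
  weights <- as.numeric(weights)
  if (length(weights) != 48L)
    stop("a drinking pattern must have exactly 48 half-hour weights, got ",
         length(weights))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("pattern weights must be finite and non-negative")
  if (abs(sum(weights) - 1) > 1e-12)
    stop("pattern weights must sum to 1 (got ",
         format(sum(weights), digits = 15), ")")
  structure(weights, class = "drinking_pattern")
}

#' Uniform drinking pattern
#'
#' Equal intake in every half-hour slot (1/48 each).  Useful as a
#' degenerate reference; real rats drink predominantly in the dark phase.
#'
#' @return A [drinking_pattern()].
#' @export
uniform_drinking_pattern <- function() drinking_pattern(rep(1 / 48, 48))

#' Diurnal two-bout drinking pattern
#'
#' Parametric model of the circadian drinking rhythm of laboratory rats:
#' a fraction `dark_fraction` of the daily intake falls in the 12-h dark
#' phase (slots 1-24, dark onset at t = 0), with an exponential drinking
#' bout immediately after dark onset, a smaller anticipatory rise toward
#' the end of the dark phase, and the remaining dark-phase intake uniform;
#' light-phase intake is uniform.  Slot weights are exact integrals of the
#' continuous intake-rate profile over each half-hour slot.
#'
#' @param dark_fraction Fraction of daily intake consumed in the dark
#'   phase (default 0.85).
#' @param onset_bout Fraction of daily intake in the post-dark-onset bout
#'   (default 0.25).
#' @param onset_tau Decay time of the onset bout, h (default 1.5).
#' @param end_bout Fraction of daily intake in the anticipatory end-of-dark
#'   bout (default 0.10).
#' @param end_tau Rise time of the end-of-dark bout, h (default 2).
#' @return A [drinking_pattern()].
#' @export
diurnal_drinking_pattern <- function(dark_fraction = 0.85,
                                     onset_bout = 0.25, onset_tau = 1.5,
                                     end_bout = 0.10, end_tau = 2) {
  if (dark_fraction <= 0 || dark_fraction >= 1)
    stop("dark_fraction must lie in (0, 1)")
  if (onset_bout < 0 || end_bout < 0 ||
      onset_bout + end_bout > dark_fraction)
    stop("bout fractions must be non-negative and fit within dark_fraction")
  edges <- seq(0, 12, by = 0.5)
  lo <- edges[-25]
  hi <- edges[-1]
  # exponential bout masses, normalized over the 12-h dark phase
  on_cdf <- function(t) (1 - exp(-t / onset_tau)) / (1 - exp(-12 / onset_tau))
  end_cdf <- function(t) {
    (exp(-(12 - t) / end_tau) - exp(-12 / end_tau)) / (1 - exp(-12 / end_tau))
  }
  base <- dark_fraction - onset_bout - end_bout
  dark <- onset_bout * (on_cdf(hi) - on_cdf(lo)) +
    end_bout * (end_cdf(hi) - end_cdf(lo)) +
    base * (hi - lo) / 12
  light <- rep((1 - dark_fraction) / 24, 24)
  w <- c(dark, light)
  drinking_pattern(w / sum(w))    # remove last-digit rounding
}

#' Default drinking pattern
#'
#' The package default used by [drinking_schedule()], [run_scan()] and
#' [run_reference_scenarios()]: the [diurnal_drinking_pattern()] with 85
#' percent dark-phase intake, a post-dark-onset bout carrying 25 percent of
#' daily intake (1.5 h decay) and an end-of-dark bout carrying 10 percent
#' (2 h rise).  The bout magnitudes were fixed once, by calibrating the
#' drinking-water dose metrics against reported rat dosimetry (see the
#' methods vignette), and are not tuned per analysis.
#'
#' @return A [drinking_pattern()].
#' @export
default_drinking_pattern <- function() diurnal_drinking_pattern()

#' Read and write drinking-pattern CSV files
#'
#' Plain CSV with 48 rows and columns `slot_start_h` (0, 0.5, ..., 23.5)
#' and `weight`.
#'
#' @param path File path.
#' @param pattern A [drinking_pattern()] (for writing).
#' @return `read_drinking_pattern()` returns a [drinking_pattern()].
#' @export
read_drinking_pattern <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("slot_start_h", "weight") %in% names(x)))
    stop("pattern file must have columns slot_start_h, weight")
  if (nrow(x) != 48L) stop("pattern file must have exactly 48 rows")
  x <- x[order(x$slot_start_h), ]
  if (max(abs(x$slot_start_h - seq(0, 23.5, by = 0.5))) > 1e-9)
    stop("slot_start_h must be 0, 0.5, ..., 23.5")
  drinking_pattern(x$weight)
}

#' @rdname read_drinking_pattern
#' @export
write_drinking_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "drinking_pattern"))
  utils::write.csv(
    data.frame(slot_start_h = seq(0, 23.5, by = 0.5),
               weight = as.numeric(pattern)),
    path, row.names = FALSE)
  invisible(path)
}

new_schedule <- function(start, duration, amount, route, dose, bw, n_days) {
  sched <- data.frame(start = start, duration = duration, amount = amount)
  sched <- sched[order(sched$start), , drop = FALSE]
  rownames(sched) <- NULL
  if (nrow(sched) > 1L &&
      any(sched$start[-1] - (sched$start + sched$duration)[-nrow(sched)] < -1e-12))
    stop("infusion events overlap")
  structure(sched, class = c("infusion_schedule", "data.frame"),
            route = route, dose = dose, bw = bw, n_days = n_days)
}

#' Oral gavage dosing schedule
#'
#' One brief square-pulse infusion into the gut compartment at the start of
#' each simulated day.  The pulse amount is `dose * bw` mg, so the total
#' scheduled mass is exactly `dose * bw * n_days`.
#'
#' @param dose Administered dose, mg/kg/day (non-negative).
#' @param bw Body weight, kg.
#' @param n_days Number of dosing days (>= 1).
#' @param pulse_duration Pulse length, h; default 15 s.
#' @return An `infusion_schedule`: a data frame with columns `start` (h),
#'   `duration` (h) and `amount` (mg), sorted by start time.
#' @examples
#' gavage_schedule(25, 0.225, 7)   # 7 daily pulses of 5.625 mg
#' @export
gavage_schedule <- function(dose, bw, n_days, pulse_duration = PULSE_H) {
  check_dose_args(dose, bw, n_days, pulse_duration)
  new_schedule(start = 24 * (seq_len(n_days) - 1),
               duration = pulse_duration,
               amount = rep(dose * bw, n_days),
               route = "gavage", dose = dose, bw = bw, n_days = n_days)
}

#' Drinking-water dosing schedule
#'
#' 48 brief square-pulse infusions per day, one at the start of each
#' half-hour slot, with per-pulse amounts `dose * bw * weights[k]` so that
#' the daily mass is exactly `dose * bw` for any valid pattern.
#'
#' @inheritParams gavage_schedule
#' @param pattern A [drinking_pattern()]; default
#'   [default_drinking_pattern()].
#' @return An `infusion_schedule` with `48 * n_days` events.
#' @export
drinking_schedule <- function(dose, bw, n_days,
                              pattern = default_drinking_pattern(),
                              pulse_duration = PULSE_H) {
  check_dose_args(dose, bw, n_days, pulse_duration)
  if (!inherits(pattern, "drinking_pattern")) pattern <- drinking_pattern(pattern)
  k <- 0:47
  start <- as.vector(outer(0.5 * k, 24 * (seq_len(n_days) - 1), "+"))
  amount <- rep(dose * bw * as.numeric(pattern), n_days)
  new_schedule(start = start,
               duration = pulse_duration,
               amount = amount,
               route = "drinking_water", dose = dose, bw = bw, n_days = n_days)
}

check_dose_args <- function(dose, bw, n_days, pulse_duration) {
  if (!is.finite(dose) || dose < 0) stop("dose must be non-negative (mg/kg/day)")
  if (!is.finite(bw) || bw <= 0) stop("bw must be positive (kg)")
  if (n_days < 1 || n_days != round(n_days)) stop("n_days must be an integer >= 1")
  if (pulse_duration <= 0) stop("pulse_duration must be positive (h)")
  if (pulse_duration > 0.5) stop("pulse_duration must not exceed the 0.5 h slot")
  invisible(TRUE)
}

#' Instantaneous infusion rate of a schedule
#'
#' Piecewise-constant rate: `amount / duration` inside a pulse, 0 outside.
#' Pulse boundaries are right-continuous — a time exactly at a pulse start
#' belongs to that pulse, a time exactly at a pulse end does not.
#'
#' @param t Time(s), h; may be a vector.
#' @param schedule An `infusion_schedule`.
#' @return Infusion rate(s), mg/h.
#' @export
infusion_rate <- function(t, schedule) {
  stopifnot(inherits(schedule, "infusion_schedule"))
  r <- numeric(length(t))
  for (i in seq_len(nrow(schedule))) {
    inside <- t >= schedule$start[i] &
      t < schedule$start[i] + schedule$duration[i]
    r[inside] <- schedule$amount[i] / schedule$duration[i]
  }
  r
}

#' @export
print.infusion_schedule <- function(x, ...) {
  cat(sprintf("Infusion schedule: %s, %g mg/kg/day, %d day(s), %d events, total %.6g mg\n",
              attr(x, "route"), attr(x, "dose"), attr(x, "n_days"),
              nrow(x), sum(x$amount)))
  NextMethod()
}
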
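# State-vector layout shared with src/pbpk.c.
STATE_NAMES <- c("a_gut", paste0("a_", TISSUES),
                 "a_metabolized", "a_exhaled", "a_absorbed",
                 "a_firstpass_escape", "auc_venous")

# Indices of the components that carry physical mass (bookkeeping states
# a_absorbed / a_firstpass_escape / auc_venous are excluded).
MASS_STATES <- c("a_gut", paste0("a_", TISSUES), "a_metabolized", "a_exhaled")

#' Construct a model state vector
#'
#' The model state tracks the unabsorbed amount in the oral dosing
#' compartment, the amount in each of the five tissues, and cumulative
#' metabolized / exhaled / absorbed mass, plus two bookkeeping integrals
#' (first-pass escape and venous AUC).  All amounts are mg.
#'
#' @param a_gut Amount in the dosing (gut) compartment, mg.
#' @param a_tissue Named numeric vector of tissue amounts, mg (names
#'   `liver`, `fat`, `bone_marrow`, `richly`, `slowly`); defaults to zero.
#' @param a_metabolized,a_exhaled,a_absorbed,a_firstpass_escape,auc_venous
#'   Cumulative quantities; default zero.
#' @return Named numeric state vector.
#' @export
pbpk_state <- function(a_gut = 0,
                       a_tissue = c(liver = 0, fat = 0, bone_marrow = 0,
                                    richly = 0, slowly = 0),
                       a_metabolized = 0, a_exhaled = 0, a_absorbed = 0,
                       a_firstpass_escape = 0, auc_venous = 0) {
  if (is.null(names(a_tissue)) || !setequal(names(a_tissue), TISSUES))
    stop("a_tissue must be named with: ", paste(TISSUES, collapse = ", "))
  y <- c(a_gut, unname(a_tissue[TISSUES]), a_metabolized, a_exhaled,
         a_absorbed, a_firstpass_escape, auc_venous)
  names(y) <- STATE_NAMES
  if (any(!is.finite(y)) || any(y[MASS_STATES] < 0))
    stop("state components must be finite and non-negative")
  y
}

#' Mass-balance derivatives of the PBPK model
#'
#' Pure-R evaluation of the model right-hand side, exposed for inspection
#' and testing.  The integrator itself uses an identical compiled version.
#'
#' The structure is flow-limited: the gut loses `ka * a_gut` to the liver;
#' each tissue `i` exchanges with arterial blood at rate
#' `Q_i * (C_art - C_i / P_i)`; the liver additionally receives the
#' absorbed flux and loses `Vmax * CVL / (Km + CVL)` with
#' `CVL = C_liver / P_liver`; mixed venous blood is the flow-weighted
#' mixture of tissue effluents, and arterial blood follows from
#' steady-state alveolar exchange against chemical-free inhaled air through
#' the blood:air partition coefficient.
#'
#' @param state State vector from [pbpk_state()].
#' @param t Time, h (unused; the system is autonomous within a segment).
#' @param params A [pbpk_params()] object.
#' @param infusion_rate Infusion rate into the gut compartment, mg/h.
#' @return Named vector of time derivatives, mg/h (the `auc_venous`
#'   component is in mg/L).
#' @export
pbpk_derivatives <- function(state, t = 0, params = pbpk_params(),
                             infusion_rate = 0) {
  if (infusion_rate < 0) stop("infusion_rate must be non-negative")
  d <- derived_params(params)
  cvt <- unname(state[paste0("a_", TISSUES)]) /
    (d$v_tissue * d$p_tissue)                     # tissue venous effluents
  names(cvt) <- TISSUES
  cv <- sum(d$q_tissue * cvt) / d$q_total
  ca <- d$q_total * cv / (d$q_total + d$q_alv / d$p_blood_air)
  cvl <- cvt[["liver"]]
  rmet <- d$vmax * cvl / (d$km + cvl)
  rabs <- d$ka * state[["a_gut"]]
  rexh <- d$q_alv * ca / d$p_blood_air

  dy <- numeric(length(STATE_NAMES))
  names(dy) <- STATE_NAMES
  dy["a_gut"] <- infusion_rate - rabs
  dy[paste0("a_", TISSUES)] <- d$q_tissue * (ca - cvt)
  dy["a_liver"] <- dy["a_liver"] + rabs - rmet
  dy["a_metabolized"] <- rmet
  dy["a_exhaled"] <- rexh
  dy["a_absorbed"] <- rabs
  dy["a_firstpass_escape"] <-
    rabs * d$q_tissue[["liver"]] /
    (d$q_tissue[["liver"]] + d$vmax / (d$km + cvl))
  dy["auc_venous"] <- cv
  dy
}

#' Venous and arterial blood concentrations for a model state
#'
#' `venous_concentration()` is the flow-weighted mixture of the tissue
#' venous effluents, `sum(Q_i * C_i / P_i) / Q_total`.
#' `arterial_concentration()` applies steady-state alveolar exchange
#' against chemical-free air:
#' `C_art = Q_total * C_ven / (Q_total + Q_alv / P_blood_air)`.
#' With a blood:air partition coefficient of 1492 the two differ by less
#' than 1 percent.
#'
#' @inheritParams pbpk_derivatives
#' @return Concentration in mg/L.
#' @export
venous_concentration <- function(state, params = pbpk_params()) {
  d <- derived_params(params)
  a_t <- state[paste0("a_", TISSUES)]
  sum(d$q_tissue * a_t / (d$v_tissue * d$p_tissue)) / d$q_total
}

#' @rdname venous_concentration
#' @export
arterial_concentration <- function(state, params = pbpk_params()) {
  d <- derived_params(params)
  cv <- venous_concentration(state, params)
  d$q_total * cv / (d$q_total + d$q_alv / d$p_blood_air)
}
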
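#' Rat physiological parameters
#'
#' Container for the physiological constants of the flow-limited PBPK model:
#' body weight, allometric cardiac output and alveolar ventilation, and the
#' fractional blood flows and volumes of the five perfused compartments
#' (liver, fat, bone marrow, richly perfused, slowly perfused).
#'
#' Flows scale as `coeff * BW^exponent` (L/h); tissue volumes are
#' `fraction * BW` litres (tissue density taken as 1 kg/L).  The flow
#' fractions must partition the whole cardiac output (sum to 1); the volume
#' fractions must sum to at most 0.95, the remainder being unperfused mass
#' (bone mineral, gut contents).
#'
#' @param body_weight Body weight, kg.
#' @param cardiac_output_coeff Cardiac output allometric coefficient,
#'   L/h per kg^exponent.
#' @param cardiac_output_exponent Allometric exponent (dimensionless).
#' @param alveolar_ventilation_coeff Alveolar ventilation allometric
#'   coefficient, L/h per kg^exponent (same exponent as cardiac output).
#' @param flow_fractions Named numeric vector: fraction of cardiac output
#'   perfusing each of `liver`, `fat`, `bone_marrow`, `richly`, `slowly`.
#' @param volume_fractions Named numeric vector: fraction of body weight
#'   occupied by each compartment (same names).
#' @return An object of class `physiological_params`.
#' @seealso [default_physiology()] for the standard adult-rat values.
#' @export
physiological_params <- function(body_weight,
                                 cardiac_output_coeff,
                                 cardiac_output_exponent,
                                 alveolar_ventilation_coeff,
                                 flow_fractions,
                                 volume_fractions) {
  stopifnot(is.numeric(body_weight), length(body_weight) == 1L)
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a positive number (kg)")
  if (cardiac_output_coeff <= 0 || alveolar_ventilation_coeff <= 0)
    stop("flow allometric coefficients must be positive")
  flow_fractions <- check_fractions(flow_fractions, "flow_fractions")
  volume_fractions <- check_fractions(volume_fractions, "volume_fractions")
  if (abs(sum(flow_fractions) - 1) > 1e-9)
    stop("flow_fractions must sum to 1 (perfusion fully partitioned); got ",
         format(sum(flow_fractions), digits = 12))
  if (sum(volume_fractions) > 0.95)
    stop("volume_fractions must sum to <= 0.95 ",
         "(remainder is unperfused mass); got ",
         format(sum(volume_fractions), digits = 6))
  structure(
    list(body_weight = body_weight,
         cardiac_output_coeff = cardiac_output_coeff,
         cardiac_output_exponent = cardiac_output_exponent,
         alveolar_ventilation_coeff = alveolar_ventilation_coeff,
         flow_fractions = flow_fractions[TISSUES],
         volume_fractions = volume_fractions[TISSUES]),
    class = "physiological_params")
}

check_fractions <- function(x, what) {
  if (is.null(names(x)) || !setequal(names(x), TISSUES))
    stop(what, " must be a named vector with names: ",
         paste(TISSUES, collapse = ", "))
  x <- x[TISSUES]
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop("all ", what, " must lie strictly in (0, 1)")
  x
}

#' Chemical-specific parameters
#'
#' Molecular weight, partition coefficients and the first-order oral
#' absorption rate constant for the modelled chemical.
#'
#' @param molecular_weight g/mol.
#' @param p_blood_air Blood:air partition coefficient (dimensionless).
#' @param p_tissue_blood Named numeric vector of tissue:blood partition
#'   coefficients for `liver`, `fat`, `bone_marrow`, `richly`, `slowly`.
#' @param ka First-order absorption rate constant from the oral dosing
#'   compartment into the liver, 1/h.
#' @return An object of class `chemical_params`.
#' @seealso [default_chemical()] for the 3-CAA values.
#' @export
chemical_params <- function(molecular_weight, p_blood_air, p_tissue_blood, ka) {
  if (molecular_weight <= 0) stop("molecular_weight must be positive")
  if (p_blood_air <= 0) stop("p_blood_air must be positive")
  if (is.null(names(p_tissue_blood)) || !setequal(names(p_tissue_blood), TISSUES))
    stop("p_tissue_blood must be named with: ", paste(TISSUES, collapse = ", "))
  p_tissue_blood <- p_tissue_blood[TISSUES]
  if (any(p_tissue_blood <= 0)) stop("all partition coefficients must be positive")
  if (ka <= 0) stop("ka must be positive (1/h)")
  structure(
    list(molecular_weight = molecular_weight,
         p_blood_air = p_blood_air,
         p_tissue_blood = p_tissue_blood,
         ka = ka),
    class = "chemical_params")
}

#' Michaelis-Menten metabolic parameters
#'
#' Hepatic metabolic capacity in body-weight-scalable form.  `vmaxc` scales
#' to an individual animal as `Vmax = vmaxc * BW^0.75` (mg/h); `km` is the
#' substrate concentration at half-maximal rate and does not scale with
#' body weight.
#'
#' @param vmaxc Scalable capacity, mg/h/kg^0.75.  May be zero (no
#'   metabolism, e.g. tracer simulations).
#' @param km Affinity constant, mg/L.
#' @return An object of class `metabolic_params`.
#' @export
metabolic_params <- function(vmaxc, km) {
  if (vmaxc < 0) stop("vmaxc must be non-negative")
  if (km <= 0) stop("km must be positive (mg/L)")
  structure(list(vmaxc = vmaxc, km = km), class = "metabolic_params")
}

#' Aggregate PBPK parameter set
#'
#' Bundles physiology, chemical and metabolism into the single parameter
#' object taken by [run_simulation()] and friends.
#'
#' @param physiology A [physiological_params()] object.
#' @param chemical A [chemical_params()] object.
#' @param metabolism A [metabolic_params()] object.
#' @return An object of class `pbpk_params`.
#' @examples
#' p <- pbpk_params()   # default rat / 3-CAA parameterization
#' p$metabolism$km
#' @export
pbpk_params <- function(physiology = default_physiology(),
                        chemical = default_chemical(),
                        metabolism = default_metabolism()) {
  stopifnot(inherits(physiology, "physiological_params"),
            inherits(chemical, "chemical_params"),
            inherits(metabolism, "metabolic_params"))
  structure(list(physiology = physiology,
                 chemical = chemical,
                 metabolism = metabolism),
            class = "pbpk_params")
}

#' Default adult-rat physiology
#'
#' Standard compendium values for an adult rat: body weight 0.225 kg,
#' cardiac output 14 L/h/kg^0.74, alveolar ventilation equal to cardiac
#' output, and conventional fractional flows/volumes for the five
#' compartments.  All values are plain numbers and can be overridden
#' field-by-field or through a JSON parameter file ([read_params()]).
#'
#' @return A [physiological_params()] object.
#' @export
default_physiology <- function() {
  physiological_params(
    body_weight = 0.225,
    cardiac_output_coeff = 14,
    cardiac_output_exponent = 0.74,
    alveolar_ventilation_coeff = 14,
    flow_fractions = c(liver = 0.183, fat = 0.07, bone_marrow = 0.03,
                       richly = 0.47, slowly = 0.247),
    volume_fractions = c(liver = 0.034, fat = 0.07, bone_marrow = 0.03,
                         richly = 0.05, slowly = 0.727))
}

#' Default 3-chloroallyl alcohol chemical parameters
#'
#' Partition coefficients for 3-CAA (blood:air 1492; liver 0.95, fat 1.47,
#' richly perfused 0.95, slowly perfused 0.64, bone marrow 1.06), molecular
#' weight 92.52 g/mol, and oral absorption rate constant 1.0/h.
#'
#' @return A [chemical_params()] object.
#' @export
default_chemical <- function() {
  chemical_params(
    molecular_weight = 92.52,
    p_blood_air = 1492,
    p_tissue_blood = c(liver = 0.95, fat = 1.47, bone_marrow = 1.06,
                       richly = 0.95, slowly = 0.64),
    ka = 1.0)
}

#' Default metabolic parameters for 3-CAA
#'
#' The metabolism-maximizing corner of the read-across scan grid:
#' VmaxC = 1808 mg/h/kg^0.75 and Km = 15.0 mg/L.  These are the values used
#' for the 28-day predictive simulations ([run_reference_scenarios()]).
#'
#' @return A [metabolic_params()] object.
#' @export
default_metabolism <- function() metabolic_params(vmaxc = 1808, km = 15.0)

#' Molecular-weight read-across of Michaelis-Menten parameters
#'
#' Scales a source chemical's measured `Vmax` (mg/h) and `Km` (mg/L) to a
#' structurally related target chemical by the ratio of molecular weights,
#' so that the parameters are equivalent on a molar basis.  Used here to
#' carry the ethanol alcohol-dehydrogenase parameters (Vmax 110.64 mg/h,
#' Km 23 mg/L, MW 46.07) over to 3-CAA (MW 92.52).
#'
#' @param source_vmax Source-chemical Vmax, mg/h.
#' @param source_km Source-chemical Km, mg/L.
#' @param source_mw Source molecular weight, g/mol.
#' @param target_mw Target molecular weight, g/mol.
#' @return Named list with elements `vmax` (mg/h) and `km` (mg/L).
#' @examples
#' mw_read_across(110.64, 23, 46.07, 92.52)  # ethanol -> 3-CAA
#' @export
mw_read_across <- function(source_vmax, source_km, source_mw, target_mw) {
  vals <- c(source_vmax, source_km, source_mw, target_mw)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all read-across inputs must be positive finite numbers")
  r <- target_mw / source_mw
  list(vmax = source_vmax * r, km = source_km * r)
}

#' Convert Vmax to the body-weight-scalable VmaxC (and back)
#'
#' `vmaxc_from_vmax()` converts an animal-specific metabolic capacity Vmax
#' (mg/h) measured at body weight `bw` into the scalable quantity
#' VmaxC = Vmax / BW^0.75 (mg/h/kg^0.75), reflecting the allometry of liver
#' enzyme capacity.  (Some reports typeset this relationship as a
#' multiplication; the numbers only work as a division, which is what is
#' implemented.)  `vmax_from_vmaxc()` is the exact inverse.
#'
#' @param vmax Capacity, mg/h (non-negative).
#' @param vmaxc Scalable capacity, mg/h/kg^0.75 (non-negative).
#' @param bw Body weight, kg (positive).
#' @return A single number.
#' @examples
#' vmaxc_from_vmax(222.16, 0.225)   # ~680 mg/h/kg^0.75
#' @export
vmaxc_from_vmax <- function(vmax, bw) {
  if (vmax < 0) stop("vmax must be non-negative")
  if (!is.finite(bw) || bw <= 0) stop("bw must be positive (kg)")
  vmax / bw^0.75
}

#' @rdname vmaxc_from_vmax
#' @export
vmax_from_vmaxc <- function(vmaxc, bw) {
  if (vmaxc < 0) stop("vmaxc must be non-negative")
  if (!is.finite(bw) || bw <= 0) stop("bw must be positive (kg)")
  vmaxc * bw^0.75
}

# Resolve the aggregate parameter object into the absolute quantities the
# mass balance needs: flows (L/h), volumes (L), Vmax (mg/h).
derived_params <- function(params) {
  stopifnot(inherits(params, "pbpk_params"))
  ph <- params$physiology
  ch <- params$chemical
  me <- params$metabolism
  bw <- ph$body_weight
  q_total <- ph$cardiac_output_coeff * bw^ph$cardiac_output_exponent
  q_alv <- ph$alveolar_ventilation_coeff * bw^ph$cardiac_output_exponent
  list(q_total = q_total,
       q_alv = q_alv,
       q_tissue = ph$flow_fractions * q_total,
       v_tissue = ph$volume_fractions * bw,
       p_tissue = ch$p_tissue_blood,
       p_blood_air = ch$p_blood_air,
       ka = ch$ka,
       vmax = vmax_from_vmaxc(me$vmaxc, bw),
       km = me$km)
}

# Flat numeric parameter vector handed to the compiled right-hand side.
# Order must match src/pbpk.c exactly.  The infusion-rate slot is filled
# per integration segment.
param_vector <- function(params, infusion_rate = 0) {
  d <- derived_params(params)
  c(ka = d$ka, vmax = d$vmax, km = d$km,
    q_total = d$q_total, q_alv = d$q_alv, p_blood_air = d$p_blood_air,
    q = unname(d$q_tissue), v = unname(d$v_tissue), p = unname(d$p_tissue),
    rinf = infusion_rate)
}

#' Read and write PBPK parameter files
#'
#' Parameter profiles are stored as JSON with three top-level sections,
#' `physiology`, `chemical` and `metabolism`, whose keys mirror the
#' constructor arguments of [physiological_params()], [chemical_params()]
#' and [metabolic_params()].  The packaged profile `rat_3caa_default`
#' (in `inst/extdata/`) carries the default rat / 3-CAA parameterization.
#'
#' @param path File path to read from / write to.
#' @param params A [pbpk_params()] object (for writing).
#' @return `read_params()` returns a [pbpk_params()] object.
#' @examples
#' p <- read_params(system.file("extdata", "rat_3caa_default.json",
#'                              package = "caaPBPK"))
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("physiology", "chemical", "metabolism")
  if (!all(need %in% names(x)))
    stop("parameter file must contain sections: ", paste(need, collapse = ", "))
  ph <- x$physiology
  ch <- x$chemical
  me <- x$metabolism
  pbpk_params(
    physiology = physiological_params(
      body_weight = ph$body_weight,
      cardiac_output_coeff = ph$cardiac_output_coeff,
      cardiac_output_exponent = ph$cardiac_output_exponent,
      alveolar_ventilation_coeff = ph$alveolar_ventilation_coeff,
      flow_fractions = unlist(ph$flow_fractions),
      volume_fractions = unlist(ph$volume_fractions)),
    chemical = chemical_params(
      molecular_weight = ch$molecular_weight,
      p_blood_air = ch$p_blood_air,
      p_tissue_blood = unlist(ch$p_tissue_blood),
      ka = ch$ka),
    metabolism = metabolic_params(vmaxc = me$vmaxc, km = me$km))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pbpk_params"))
  x <- list(
    physiology = params$physiology[],
    chemical = params$chemical[],
    metabolism = params$metabolism[])
  x$physiology$flow_fractions <- as.list(x$physiology$flow_fractions)
  x$physiology$volume_fractions <- as.list(x$physiology$volume_fractions)
  x$chemical$p_tissue_blood <- as.list(x$chemical$p_tissue_blood)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.pbpk_params <- function(x, ...) {
  d <- derived_params(x)
  cat("PBPK parameter set\n")
  cat(sprintf("  body weight      : %.4g kg\n", x$physiology$body_weight))
  cat(sprintf("  cardiac output   : %.4g L/h  (alveolar ventilation %.4g L/h)\n",
              d$q_total, d$q_alv))
  cat(sprintf("  ka               : %.4g /h\n", d$ka))
  cat(sprintf("  VmaxC            : %.4g mg/h/kg^0.75  (Vmax %.4g mg/h)\n",
              x$metabolism$vmaxc, d$vmax))
  cat(sprintf("  Km               : %.4g mg/L\n", d$km))
  cat(sprintf("  blood:air PC     : %.4g\n", d$p_blood_air))
  tab <- data.frame(flow_L_h = round(d$q_tissue, 4),
                    volume_L = round(d$v_tissue, 5),
                    partition = d$p_tissue)
  print(tab, ...)
  invisible(x)
}
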
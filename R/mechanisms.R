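#' Pressure unit conversion
#'
#' Darcy-flow quantities are expressed in mmHg-based units while fracture
#' stresses are in kPa; the conversion (1 mmHg = 0.133322 kPa) is
#' centralized here so the two unit systems never mix implicitly.
#'
#' @param x Pressure value(s).
#' @return Converted value(s).
#' @export
mmhg_to_kpa <- function(x) x * 0.133322

#' @rdname mmhg_to_kpa
#' @export
kpa_to_mmhg <- function(x) x / 0.133322

#' Radial Darcy pressure profile of a point source
#'
#' For a constant volumetric injection rate with radial symmetry around the
#' needle tip, Darcy's law integrates to the spherically symmetric
#' point-source solution `P(r) = Q / (4 pi K r)`, with `P -> 0` as
#' `r -> Inf`.
#'
#' @param q_inj Volumetric injection rate, mL/s.
#' @param k Hydraulic conductivity, cm^2 mmHg^-1 s^-1.
#' @param r Distance from the needle tip, cm (vectorized; must be > 0).
#' @return Pressure in mmHg.
#' @export
darcy_pressure_profile <- function(q_inj, k, r) {
  if (q_inj <= 0 || k <= 0) abort("`q_inj` and `k` must be > 0.")
  if (any(r <= 0)) abort("`r` must be > 0: the point-source solution is singular at r = 0.")
  q_inj / (4 * pi * k * r)
}

#' Hydraulic conductivity implied by the depot size
#'
#' Inverts the radial Darcy solution at the distance where flow ceases:
#' fluid stops where the driving pressure falls to the tumor interstitial
#' fluid pressure, so `K = Q / (4 pi R P_i)`.
#'
#' @param q_inj Volumetric injection rate, mL/s.
#' @param r_depot Depot radius `R` at which flow ceases, cm (vectorized).
#' @param p_i Tumor interstitial fluid pressure, mmHg.
#' @return Conductivity in cm^2 mmHg^-1 s^-1.
#' @export
darcy_conductivity <- function(q_inj, r_depot, p_i) {
  if (q_inj <= 0 || p_i <= 0 || any(r_depot <= 0)) {
    abort("All Darcy parameters must be > 0.")
  }
  q_inj / (4 * pi * r_depot * p_i)
}

#' Orders of magnitude by which an estimated conductivity exceeds literature
#'
#' `log10(K_est / K_lit)` evaluated over the supplied ranges: the minimum
#' pairs the smallest estimate with the largest literature value and the
#' maximum the reverse, so the interval brackets every combination.
#'
#' @param k_est Estimated conductivity, scalar or `(low, high)` pair.
#' @param k_lit Literature conductivity, scalar or `(low, high)` pair.
#'   Default 3.1831e-7 cm^2 mmHg^-1 s^-1, a representative reported tumor
#'   hydraulic conductivity.
#' @return Named numeric `c(min, max)` orders of magnitude.
#' @export
conductivity_excess <- function(k_est, k_lit = 3.1831e-7) {
  if (any(k_est <= 0) || any(k_lit <= 0)) abort("Conductivities must be > 0.")
  c(min = log10(min(k_est) / max(k_lit)),
    max = log10(max(k_est) / min(k_lit)))
}

#' Fracture regime parameters
#'
#' Bundles the elastic modulus, mode I toughness and crack width for a
#' crack-tunneling regime. Two regimes are predefined: `"macro"`, a single
#' contiguous crack the size of the imaged depot (toughness 2.5-4.1 kJ/m^2
#' as in adipose/muscle tissue, width 1 cm), and `"micro"`, percolation of
#' fine cracks along brittle interfaces (toughness 330 J/m^2, width
#' 800 um, as observed for injections into adipose tissue). Scalar
#' evaluations use midpoints of ranged parameters; the ranges are kept
#' alongside.
#'
#' @param regime `"macro"` or `"micro"`.
#' @param e_mod_kpa Elastic modulus, kPa (scalar or range; default the
#'   20-30 kPa lung-tumor range).
#' @param toughness Mode I toughness, J/m^2 (scalar or range).
#' @param crack_width_m Crack width `h`, metres.
#' @return An object of class `fracture_params`.
#' @export
fracture_params <- function(regime = c("macro", "micro"),
                            e_mod_kpa = c(20, 30),
                            toughness = NULL,
                            crack_width_m = NULL) {
  regime <- match.arg(regime)
  if (is.null(toughness)) {
    toughness <- switch(regime, macro = c(2500, 4100), micro = 330)
  }
  if (is.null(crack_width_m)) {
    crack_width_m <- switch(regime, macro = 0.01, micro = 8e-4)
  }
  if (any(e_mod_kpa <= 0) || any(toughness <= 0) || any(crack_width_m <= 0)) {
    abort("All fracture parameters must be > 0.")
  }
  structure(
    list(regime = regime, e_mod_kpa = e_mod_kpa, toughness = toughness,
         crack_width_m = crack_width_m),
    class = "fracture_params"
  )
}

#' Crack-tunneling stress threshold
#'
#' The lowest remote stress at which steady-state tunneling of a crack of
#' width `h` can occur in a layer of elastic modulus `E` and mode I
#' toughness `Gamma`: `sigma_th = sqrt(prefactor * E * Gamma / h)` with the
#' default prefactor `pi/2`, i.e. `sqrt(pi E Gamma / (2 h))`. The exact
#' prefactor and a plane-strain correction `E / (1 - nu^2)` are exposed as
#' configuration; with the defaults the micro-crack regime at midpoint
#' parameters evaluates to about 127 kPa.
#'
#' @param params A [fracture_params()], or `NULL` to pass scalars directly.
#' @param e_mod_kpa Elastic modulus, kPa (midpoint of a range is used).
#' @param toughness Mode I toughness, J/m^2.
#' @param crack_width_m Crack width, m.
#' @param prefactor Dimensionless prefactor under the square root
#'   (default `pi/2`).
#' @param poisson Optional Poisson ratio `nu`; when given, `E` is replaced
#'   by the plane-strain modulus `E / (1 - nu^2)`.
#' @return Threshold stress in kPa.
#' @export
fracture_threshold <- function(params = NULL,
                               e_mod_kpa = 25, toughness = 330,
                               crack_width_m = 8e-4,
                               prefactor = pi / 2, poisson = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "fracture_params"))
    e_mod_kpa <- mean(params$e_mod_kpa)
    toughness <- mean(params$toughness)
    crack_width_m <- mean(params$crack_width_m)
  }
  if (e_mod_kpa <= 0 || toughness <= 0 || crack_width_m <= 0) {
    abort("All fracture parameters must be > 0.")
  }
  e_pa <- e_mod_kpa * 1e3
  if (!is.null(poisson)) e_pa <- e_pa / (1 - poisson^2)
  sqrt(prefactor * e_pa * toughness / crack_width_m) / 1e3
}

#' Linear pressure-from-flow scaling
#'
#' Scales a reference needle-tip pressure measured at a reference flow rate
#' to another flow rate, assuming pressure is proportional to flow.
#'
#' @param p_ref Reference pressure, kPa.
#' @param q_ref Reference flow rate, mL/s.
#' @param q Flow rate of interest, mL/s.
#' @return Pressure in kPa.
#' @export
pressure_from_flow <- function(p_ref, q_ref, q) {
  if (p_ref <= 0 || q_ref <= 0 || any(q <= 0)) {
    abort("Pressures and flow rates must be > 0.")
  }
  p_ref * q / q_ref
}

#' Darcy-flow parameter bundle
#'
#' @param q_inj Injection flow rate, mL/s (default 0.4, the lower bound of
#'   the fitted per-injection flows).
#' @param p_i Tumor interstitial fluid pressure, mmHg (default 10).
#' @param r_depot_cm Depot radius range `(low, high)` over which flow
#'   ceases, cm (default 0.1-1).
#' @param k_lit Literature hydraulic conductivity, scalar or range,
#'   cm^2 mmHg^-1 s^-1.
#' @return An object of class `darcy_params`.
#' @export
darcy_params <- function(q_inj = 0.4, p_i = 10, r_depot_cm = c(0.1, 1),
                         k_lit = 3.1831e-7) {
  if (q_inj <= 0 || p_i <= 0 || any(r_depot_cm <= 0) || any(k_lit <= 0)) {
    abort("All Darcy parameters must be > 0.")
  }
  if (length(r_depot_cm) == 2 && r_depot_cm[1] > r_depot_cm[2]) {
    abort("`r_depot_cm` range must be ordered (low, high).")
  }
  structure(
    list(q_inj = q_inj, p_i = p_i, r_depot_cm = r_depot_cm, k_lit = k_lit),
    class = "darcy_params"
  )
}

#' Combined mechanism plausibility report
#'
#' Evaluates both candidate mechanisms of drug accommodation. Porous
#' (Darcy) flow is judged implausible when the hydraulic conductivity
#' implied by the observed depot size exceeds literature values by at
#' least `excess_cutoff` orders of magnitude (default 3; the observed
#' excess is typically 4-5 orders). Tissue fracture is judged plausible
#' when the smallest estimated injection stress exceeds the largest
#' crack-tunneling threshold across the macro- and micro-crack regimes.
#' The report does not attempt to distinguish a single macro-crack from
#' percolating micro-cracks.
#'
#' @param darcy A [darcy_params()].
#' @param fracture_macro,fracture_micro [fracture_params()] for the two
#'   regimes.
#' @param sigma_injection_kpa Estimated injection stress range `(low,
#'   high)`, kPa (default 240-300, from linear pressure-flow scaling of
#'   published needle-tip pressure measurements to a 0.4 mL/s flow).
#' @param excess_cutoff Orders-of-magnitude cutoff for rejecting porous
#'   flow.
#' @return An object of class `mechanism_report`.
#' @export
mechanism_report <- function(darcy = darcy_params(),
                             fracture_macro = fracture_params("macro"),
                             fracture_micro = fracture_params("micro"),
                             sigma_injection_kpa = c(240, 300),
                             excess_cutoff = 3) {
  stopifnot(inherits(darcy, "darcy_params"))
  k_est <- darcy_conductivity(darcy$q_inj, rev(range(darcy$r_depot_cm)),
                              darcy$p_i)
  k_est <- sort(unname(k_est))
  excess <- conductivity_excess(k_est, darcy$k_lit)
  sig_macro <- fracture_threshold(fracture_macro)
  sig_micro <- fracture_threshold(fracture_micro)
  porous <- !(excess[["min"]] >= excess_cutoff)
  fracture <- min(sigma_injection_kpa) > max(sig_macro, sig_micro)
  narrative <- paste0(
    sprintf(
      paste0("Implied hydraulic conductivity %.3g-%.3g cm^2/mmHg/s exceeds ",
             "literature values by %.1f-%.1f orders of magnitude ",
             "(cutoff %.3g): porous Darcy flow %s. "),
      k_est[1], k_est[2], excess[["min"]], excess[["max"]], excess_cutoff,
      if (porous) "remains plausible" else "is implausible"
    ),
    sprintf(
      paste0("Estimated injection stress %.0f-%.0f kPa vs tunneling ",
             "thresholds %.0f kPa (macro-crack) and %.0f kPa ",
             "(micro-crack percolation): tissue fracture is %s."),
      min(sigma_injection_kpa), max(sigma_injection_kpa),
      sig_macro, sig_micro,
      if (fracture) "plausible" else "not supported"
    )
  )
  structure(
    list(
      k_est_range = k_est,
      k_lit = darcy$k_lit,
      k_excess_orders = excess,
      sigma_injection_kpa = sigma_injection_kpa,
      sigma_threshold_macro_kpa = sig_macro,
      sigma_threshold_micro_kpa = sig_micro,
      porous_flow_plausible = porous,
      fracture_plausible = fracture,
      darcy = darcy,
      fracture_macro = fracture_macro,
      fracture_micro = fracture_micro,
      narrative = narrative
    ),
    class = "mechanism_report"
  )
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat("<mechanism_report>\n")
  cat(strwrap(x$narrative, width = 78, prefix = "  "), sep = "\n")
  invisible(x)
}

#' @rdname mechanism_report
#' @param x A `mechanism_report`.
#' @param ... Unused.
#' @export
tidy.mechanism_report <- function(x, ...) {
  tibble::tibble(
    quantity = c(
      "k_est_low", "k_est_high", "k_excess_orders_min", "k_excess_orders_max",
      "sigma_threshold_macro", "sigma_threshold_micro",
      "sigma_injection_low", "sigma_injection_high"
    ),
    value = c(
      x$k_est_range, unname(x$k_excess_orders),
      x$sigma_threshold_macro_kpa, x$sigma_threshold_micro_kpa,
      min(x$sigma_injection_kpa), max(x$sigma_injection_kpa)
    ),
    unit = c(rep("cm^2/mmHg/s", 2), rep("orders of magnitude", 2),
             rep("kPa", 4))
  )
}

#' @rdname mechanism_report
#' @export
glance.mechanism_report <- function(x, ...) {
  tibble::tibble(
    porous_flow_plausible = x$porous_flow_plausible,
    fracture_plausible = x$fracture_plausible
  )
}

#' Read mechanism parameters from a YAML file
#'
#' Keys mirror [darcy_params()] and [fracture_params()] arguments with
#' explicit unit suffixes, e.g. `q_inj_ml_per_s`, `p_i_mmhg`,
#' `r_depot_cm`, `k_lit`, `e_mod_kpa`, `toughness_J_per_m2`,
#' `crack_width_m`, `sigma_injection_kpa`.
#'
#' @param path YAML file.
#' @return A list with `darcy`, `fracture_macro`, `fracture_micro`,
#'   `sigma_injection_kpa` ready for [mechanism_report()].
#' @export
read_mechanism_params <- function(path) {
  y <- yaml::read_yaml(path)
  darcy <- darcy_params(
    q_inj = y$q_inj_ml_per_s %||% 0.4,
    p_i = y$p_i_mmhg %||% 10,
    r_depot_cm = unlist(y$r_depot_cm) %||% c(0.1, 1),
    k_lit = unlist(y$k_lit) %||% 3.1831e-7
  )
  fr <- function(regime, block) {
    fracture_params(
      regime,
      e_mod_kpa = unlist(block$e_mod_kpa) %||% c(20, 30),
      toughness = unlist(block$toughness_J_per_m2),
      crack_width_m = unlist(block$crack_width_m)
    )
  }
  list(
    darcy = darcy,
    fracture_macro = fr("macro", y$macro %||% list()),
    fracture_micro = fr("micro", y$micro %||% list()),
    sigma_injection_kpa = unlist(y$sigma_injection_kpa) %||% c(240, 300)
  )
}
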
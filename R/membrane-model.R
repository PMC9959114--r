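# Pure, vectorised electromechanics of a planar bilayer, SI units throughout.
#
# The bilayer's hydrophobic core is a parallel-plate dielectric: C = e0*er*A/d.
# Under an applied potential psi the compressive Maxwell stress thins the film
# and (in oil-stabilised films) grows its area; the functions here convert
# between capacitance, geometry, the electrostriction proportionality constant
# alpha, and the elastic moduli (Young's modulus E, area-expansion modulus K_A,
# bending rigidity k_c) via thin-plate theory.

#' Capacitance of a planar bilayer
#'
#' Parallel-plate capacitance of the hydrophobic core,
#' \eqn{C = \varepsilon_0 \varepsilon_r A / d}.
#'
#' @param area Bilayer area in m^2.
#' @param thickness Hydrophobic thickness in m.
#' @param dielectric_constant Relative permittivity of the acyl-chain core
#'   (dimensionless). Default 2.5, the standard value for a hydrocarbon film.
#'
#' @return Capacitance in F. Vectorised over all arguments.
#' @seealso [thickness_from_capacitance()], [capacitance_from_volume()]
#' @examples
#' capacitance_planar(area = 6.36e-7, thickness = 2.69e-9) # ~5.23 nF
#' @export
capacitance_planar <- function(area, thickness, dielectric_constant = 2.5) {
  check_positive(area, "area")
  check_positive(thickness, "thickness")
  check_positive(dielectric_constant, "dielectric_constant")
  vacuum_permittivity * dielectric_constant * area / thickness
}

#' Hydrophobic thickness from capacitance and area
#'
#' Inverts the parallel-plate relation: \eqn{d = \varepsilon_0 \varepsilon_r A / C}.
#' This is how the measured capacitance and imaged area channels are turned
#' into a thickness channel.
#'
#' @param capacitance Measured membrane capacitance in F.
#' @param area Measured bilayer area in m^2.
#' @inheritParams capacitance_planar
#'
#' @return Thickness in m.
#' @export
thickness_from_capacitance <- function(capacitance, area,
                                       dielectric_constant = 2.5) {
  check_positive(capacitance, "capacitance")
  check_positive(area, "area")
  check_positive(dielectric_constant, "dielectric_constant")
  vacuum_permittivity * dielectric_constant * area / capacitance
}

#' Capacitance in the volume form
#'
#' With membrane volume \eqn{V = A d} the parallel-plate capacitance can be
#' rewritten \eqn{C = \varepsilon_0 \varepsilon_r V / d^2}. Algebraically
#' identical to [capacitance_planar()] when `volume = area * thickness`.
#'
#' @param volume Membrane volume in m^3.
#' @param thickness Hydrophobic thickness in m.
#' @inheritParams capacitance_planar
#'
#' @return Capacitance in F.
#' @export
capacitance_from_volume <- function(volume, thickness,
                                    dielectric_constant = 2.5) {
  check_positive(volume, "volume")
  check_positive(thickness, "thickness")
  check_positive(dielectric_constant, "dielectric_constant")
  vacuum_permittivity * dielectric_constant * volume / thickness^2
}

#' Constant-volume capacitance
#'
#' The capacitance the membrane would have if only its thickness, and not its
#' area, had changed from the zero-field state:
#' \eqn{C_\psi = \varepsilon_0 \varepsilon_r V_0 / d_\psi^2}, with \eqn{V_0}
#' the zero-field volume and \eqn{d_\psi} the thickness under field.  This is
#' the correction that removes the contribution of voltage-driven area growth
#' (lipid recruited from the Plateau border) from the measured capacitance, so
#' that the voltage dependence reflects electrostrictive thinning alone.
#'
#' @param zero_field_volume Membrane volume at zero field, m^3.
#' @param field_thickness Thickness under the applied field, m.
#' @inheritParams capacitance_planar
#'
#' @return Constant-volume capacitance in F; equals the zero-field capacitance
#'   when `field_thickness` equals the zero-field thickness.
#' @export
constant_volume_capacitance <- function(zero_field_volume, field_thickness,
                                        dielectric_constant = 2.5) {
  check_positive(zero_field_volume, "zero_field_volume")
  check_positive(field_thickness, "field_thickness")
  check_positive(dielectric_constant, "dielectric_constant")
  vacuum_permittivity * dielectric_constant * zero_field_volume /
    field_thickness^2
}

#' Young's modulus from single-step thickness compression (legacy estimator)
#'
#' The classical electrostriction estimator: the Maxwell stress
#' \eqn{C_m \psi^2 / 2} divided by the thickness strain it produced,
#' \eqn{E_\perp = C_m \psi^2 / (2 \Delta d)}.  It implicitly assumes the
#' membrane compresses at constant area, so it underestimates the modulus when
#' the area (and hence volume) grows under field; the constant-volume route
#' ([young_modulus_alvarez()]) is the preferred estimator.
#'
#' @param specific_capacitance Zero-field capacitance per unit area, F/m^2.
#' @param applied_potential Transmembrane potential in V (non-zero).
#' @param thickness_decrease Observed decrease in thickness, m (positive).
#'
#' @return Young's modulus in Pa.
#' @export
young_modulus_hianik <- function(specific_capacitance, applied_potential,
                                 thickness_decrease) {
  check_positive(specific_capacitance, "specific_capacitance")
  if (!is.numeric(applied_potential) || any(!is.finite(applied_potential)) ||
      any(applied_potential == 0)) {
    stop_domain("`applied_potential` must be finite and non-zero.")
  }
  if (!is.numeric(thickness_decrease) || any(!is.finite(thickness_decrease)) ||
      any(thickness_decrease <= 0)) {
    stop_domain(
      "`thickness_decrease` must be strictly positive ",
      "(no measurable compression at this step otherwise)."
    )
  }
  specific_capacitance * applied_potential^2 / (2 * thickness_decrease)
}

#' Electrostriction proportionality constant from a fitted slope
#'
#' The voltage-dependent capacitance is modelled as
#' \eqn{C_\psi = C_0 (1 + \alpha \psi^2)}; a linear fit of the constant-volume
#' capacitance against \eqn{\psi^2} has slope \eqn{m}, and
#' \eqn{\alpha = m / (\mathrm{slope\_factor} \cdot C_0)}.
#'
#' @param slope Fitted slope of capacitance against squared voltage, F/V^2.
#'   May be zero or negative (no, or inverted, voltage dependence); the
#'   returned alpha is then non-positive and downstream moduli are undefined.
#' @param zero_field_capacitance Zero-field capacitance \eqn{C_0} in F.
#' @param slope_factor Dimensionless divisor relating the fitted slope to
#'   alpha. Default 3, the published convention for this analysis; the literal
#'   quadratic model corresponds to 1.  See the methods vignette.
#'
#' @return Alpha in V^-2.
#' @export
alpha_from_slope <- function(slope, zero_field_capacitance, slope_factor = 3) {
  if (!is.numeric(slope) || any(!is.finite(slope))) {
    stop_domain("`slope` must be finite and numeric.")
  }
  check_positive(zero_field_capacitance, "zero_field_capacitance")
  check_positive(slope_factor, "slope_factor")
  slope / (slope_factor * zero_field_capacitance)
}

#' Young's modulus from the constant-volume capacitance fit
#'
#' The constant-volume electrostriction estimator,
#' \eqn{E_\perp = C_m / (\alpha d_0)}, with \eqn{C_m} the zero-field specific
#' capacitance, \eqn{\alpha} the proportionality constant of the quadratic
#' capacitance-voltage law, and \eqn{d_0} the zero-field thickness.
#' Dimensions: (F/m^2) V^2 / m = J/m^3 = Pa.
#'
#' @param specific_capacitance Zero-field capacitance per unit area, F/m^2.
#' @param alpha Electrostriction proportionality constant, V^-2 (positive).
#' @param zero_field_thickness Zero-field hydrophobic thickness, m.
#'
#' @return Young's modulus in Pa.
#' @export
young_modulus_alvarez <- function(specific_capacitance, alpha,
                                  zero_field_thickness) {
  check_positive(specific_capacitance, "specific_capacitance")
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop_domain(
      "`alpha` must be strictly positive ",
      "(capacitance did not increase with voltage otherwise)."
    )
  }
  check_positive(zero_field_thickness, "zero_field_thickness")
  specific_capacitance / (alpha * zero_field_thickness)
}

#' Area-expansion modulus from Young's modulus (thin plate)
#'
#' Thin-plate linear elasticity: \eqn{K_A = E_\perp d / (1 - v)} for a plate
#' of thickness d and Poisson ratio v.
#'
#' @param young_modulus Transverse Young's modulus, Pa.
#' @param thickness Plate (bilayer) thickness, m.
#' @param poisson_ratio Poisson ratio, dimensionless in \[0, 1). Default 0.5
#'   (incompressible material).
#'
#' @return Area-expansion modulus in N/m.
#' @export
area_expansion_modulus <- function(young_modulus, thickness,
                                   poisson_ratio = 0.5) {
  check_positive(young_modulus, "young_modulus")
  check_positive(thickness, "thickness")
  if (!is.numeric(poisson_ratio) || any(!is.finite(poisson_ratio)) ||
      any(poisson_ratio < 0) || any(poisson_ratio >= 1)) {
    stop_domain("`poisson_ratio` must lie in [0, 1).")
  }
  young_modulus * thickness / (1 - poisson_ratio)
}

#' Bending rigidity from the area-expansion modulus (thin plate)
#'
#' \eqn{k_c = K_A d^2 / (24 (1 + v))} for the bilayer treated as two adjacent
#' thin elastic films.  Composed with [area_expansion_modulus()] this is
#' \eqn{k_c = E_\perp d^3 / (24 (1 - v)(1 + v))}; at v = 0.5 it reduces to
#' \eqn{E_\perp d^3 / 18}.
#'
#' @param area_expansion_modulus Area-expansion modulus \eqn{K_A}, N/m.
#' @inheritParams area_expansion_modulus
#'
#' @return Bending rigidity in J.
#' @export
bending_rigidity <- function(area_expansion_modulus, thickness,
                             poisson_ratio = 0.5) {
  check_positive(area_expansion_modulus, "area_expansion_modulus")
  check_positive(thickness, "thickness")
  check_positive(poisson_ratio, "poisson_ratio", allow_zero = TRUE)
  area_expansion_modulus * thickness^2 / (24 * (1 + poisson_ratio))
}
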
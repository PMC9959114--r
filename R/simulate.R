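# Forward simulator: the exact inverse of the analysis chain.
#
# Given a Young's modulus E and zero-field geometry, the electrostriction
# proportionality constant is alpha = C_m/(E*d0) with C_m = e0*er/d0.  Under a
# potential psi the simulated thickness is
#     d_psi = d0 * (1 + slope_factor*alpha*psi^2)^(-1/2)
# so that the constant-volume capacitance e0*er*V0/d_psi^2 is exactly
# C0*(1 + slope_factor*alpha*psi^2) -- the linear-in-psi^2 law the pipeline
# fits.  Area grows independently as A_psi = A0*(1 + gamma*psi^2) (lipid
# recruited from the Plateau border), so the measured capacitance mixes
# thinning and area growth just as in the experiment.

#' Simulation parameter set
#'
#' Collects the physical and noise parameters of the forward simulator.
#' Defaults describe a DOPC bilayer on a 0.9 mm aperture in squalene:
#' d0 = 2.69 nm, A0 = 6.36e-7 m^2, relative permittivity 2.5 and a Young's
#' modulus of 1.757e7 Pa (which maps to a bending rigidity of 1.9e-20 J at
#' Poisson ratio 0.5).
#'
#' @param zero_field_thickness Zero-field hydrophobic thickness d0, m.
#' @param zero_field_area Zero-field bilayer area A0, m^2.
#' @param dielectric_constant Relative permittivity of the core.
#' @param young_modulus Transverse Young's modulus E, Pa.
#' @param poisson_ratio Poisson ratio, in \[0, 0.5\].
#' @param slope_factor Dimensionless constant linking the fitted slope of the
#'   capacitance-voltage law to alpha (default 3; see [alpha_from_slope()]).
#' @param area_growth Area-growth coefficient gamma in V^-2 for the law
#'   A = A0 (1 + gamma psi^2). Default `NULL` means `2 * alpha`, which
#'   reproduces disproportionate area growth (membrane volume increasing with
#'   field).  The special value `"conserve_volume"` makes the area track the
#'   thinning exactly so the membrane volume stays at A0*d0 at every voltage.
#' @param capacitance_noise Relative standard deviation of multiplicative
#'   Gaussian noise on the capacitance channel. Default 0 (noiseless).
#' @param area_noise Same for the area channel. Default 0.
#' @param settle_tau First-order settling time constant of the mechanical
#'   response, s. Default 0 (instantaneous step response); a physical value
#'   when enabled is ~0.05 s.
#' @param seed Integer seed for the noise generator (`NULL` = session RNG).
#' @param lipid Condition label recorded in trace metadata.
#' @param x_factor Ionic-asymmetry factor label recorded in trace metadata.
#'
#' @return A list of class `simulation_params`, including the derived
#'   `alpha` (V^-2), `specific_capacitance` (F/m^2) and `zero_field_volume`
#'   (m^3).
#' @export
simulation_params <- function(zero_field_thickness = 2.69e-9,
                              zero_field_area = 6.36e-7,
                              dielectric_constant = 2.5,
                              young_modulus = 1.757e7,
                              poisson_ratio = 0.5,
                              slope_factor = 3,
                              area_growth = NULL,
                              capacitance_noise = 0,
                              area_noise = 0,
                              settle_tau = 0,
                              seed = NULL,
                              lipid = "DOPC",
                              x_factor = 1) {
  check_positive(zero_field_thickness, "zero_field_thickness")
  check_positive(zero_field_area, "zero_field_area")
  check_positive(dielectric_constant, "dielectric_constant")
  check_positive(young_modulus, "young_modulus")
  if (!is.numeric(poisson_ratio) || poisson_ratio < 0 || poisson_ratio > 0.5) {
    stop_config("`poisson_ratio` must lie in [0, 0.5].")
  }
  check_positive(slope_factor, "slope_factor")
  check_positive(capacitance_noise, "capacitance_noise", allow_zero = TRUE)
  check_positive(area_noise, "area_noise", allow_zero = TRUE)
  check_positive(settle_tau, "settle_tau", allow_zero = TRUE)

  specific_capacitance <- vacuum_permittivity * dielectric_constant /
    zero_field_thickness
  alpha <- specific_capacitance / (young_modulus * zero_field_thickness)
  if (is.null(area_growth)) {
    area_growth <- 2 * alpha
  } else if (!identical(area_growth, "conserve_volume")) {
    check_positive(area_growth, "area_growth", allow_zero = TRUE)
  }
  structure(
    list(
      zero_field_thickness = zero_field_thickness,
      zero_field_area = zero_field_area,
      dielectric_constant = dielectric_constant,
      young_modulus = young_modulus,
      poisson_ratio = poisson_ratio,
      slope_factor = slope_factor,
      area_growth = area_growth,
      capacitance_noise = capacitance_noise,
      area_noise = area_noise,
      settle_tau = settle_tau,
      seed = seed,
      lipid = lipid,
      x_factor = x_factor,
      specific_capacitance = specific_capacitance,
      alpha = alpha,
      zero_field_capacitance = specific_capacitance * zero_field_area,
      zero_field_volume = zero_field_area * zero_field_thickness
    ),
    class = "simulation_params"
  )
}

#' Simulate an electrostriction trace
#'
#' Runs the forward model of the measurement: for each protocol level the
#' membrane thins as \eqn{d_\psi = d_0 (1 + s\alpha\psi^2)^{-1/2}} (s the
#' slope factor), the area grows as \eqn{A_\psi = A_0(1 + \gamma\psi^2)}, and
#' the measured capacitance is \eqn{\varepsilon_0\varepsilon_r A_\psi/d_\psi}.
#' Off-periods sit at the zero-field state.  Optional multiplicative Gaussian
#' noise (seeded) is applied independently to the capacitance and area
#' channels; the potential channel is exact.
#'
#' @param params A [simulation_params()] set.
#' @param protocol A [build_protocol()] schedule.
#' @return An [electro_trace()] sampled at the protocol's rate, beginning with
#'   one off-period, then on/off blocks for each protocol level.
#' @export
simulate_trace <- function(params, protocol = build_protocol()) {
  if (!inherits(params, "simulation_params")) {
    stop_config("`params` must be created by simulation_params().")
  }
  if (!inherits(protocol, "voltage_protocol")) {
    stop_config("`protocol` must be created by build_protocol().")
  }
  rate <- attr(protocol, "sample_rate")
  dt <- 1 / rate
  n_on <- max(1L, round(attr(protocol, "on_duration") * rate))
  n_off <- round(attr(protocol, "off_duration") * rate)

  blocks <- lapply(protocol$amplitude_V, function(a) {
    c(rep(a, n_on), rep(0, n_off))
  })
  potential <- c(rep(0, max(n_off, 1L)), unlist(blocks))
  n <- length(potential)
  time_s <- dt * seq_len(n)

  d0 <- params$zero_field_thickness
  a0 <- params$zero_field_area
  u <- params$slope_factor * params$alpha * potential^2
  d_target <- d0 / sqrt(1 + u)
  a_target <- if (identical(params$area_growth, "conserve_volume")) {
    a0 * sqrt(1 + u) # area exactly compensates thinning: A*d = A0*d0
  } else {
    a0 * (1 + params$area_growth * potential^2)
  }

  if (params$settle_tau > 0) {
    decay <- exp(-dt / params$settle_tau)
    d_target <- first_order_response(d_target, decay, d0)
    a_target <- first_order_response(a_target, decay, a0)
  }

  capacitance <- vacuum_permittivity * params$dielectric_constant *
    a_target / d_target

  if (params$capacitance_noise > 0 || params$area_noise > 0) {
    channels <- with_seed(params$seed, {
      list(
        c = if (params$capacitance_noise > 0) {
          capacitance * (1 + rnorm(n, sd = params$capacitance_noise))
        } else {
          capacitance
        },
        a = if (params$area_noise > 0) {
          a_target * (1 + rnorm(n, sd = params$area_noise))
        } else {
          a_target
        }
      )
    })
    capacitance <- channels$c
    a_target <- channels$a
  }

  electro_trace(
    time_s, potential, capacitance, a_target,
    metadata = list(
      lipid = params$lipid,
      x_factor = params$x_factor,
      dielectric_constant = params$dielectric_constant
    )
  )
}

# y_t = (1 - decay) * target_t + decay * y_{t-1}, starting from `init`.
first_order_response <- function(target, decay, init) {
  out <- stats::filter((1 - decay) * target, decay,
    method = "recursive", init = init
  )
  as.numeric(out)
}
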
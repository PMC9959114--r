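# Trace -> elasticity pipeline: segmentation, zero-field state, per-step
# summaries with the constant-volume correction, the alpha fit, and the two
# modulus estimators.

#' Segment a trace into voltage steps
#'
#' Finds maximal runs of near-constant applied potential.  Runs whose level
#' magnitude is at least `level_floor` are on-segments (voltage steps); all
#' other samples form the zero/low-field baseline used by [estimate_state()].
#' Segments shorter than `min_duration` are discarded as switching artifacts.
#'
#' @param trace An [electro_trace()].
#' @param protocol_hint Optional [build_protocol()]; when given, each detected
#'   level is snapped to the nearest protocol amplitude.
#' @param tolerance Maximum sample-to-sample potential change within one run,
#'   V. Default 2e-3.
#' @param level_floor Minimum step magnitude, V. Default 5e-3 (the ±1 mV
#'   reference level is deliberately below this and contributes to the
#'   baseline instead).
#' @param min_duration Minimum step duration, s. Default 0.5.
#'
#' @return A tibble with one row per on-segment: `step`, `potential_V` (the
#'   level), `start`, `end` (sample indices), `n`, `duration_s`.
#' @export
segment_steps <- function(trace, protocol_hint = NULL, tolerance = 2e-3,
                          level_floor = 5e-3, min_duration = 0.5) {
  validate_trace(trace)
  v <- trace$potential_V
  run_id <- cumsum(c(TRUE, abs(diff(v)) > tolerance))
  runs <- tibble(
    run = run_id,
    idx = seq_along(v),
    potential = v,
    time = trace$time_s
  ) |>
    dplyr::summarise(
      potential_V = stats::median(.data$potential),
      start = min(.data$idx),
      end = max(.data$idx),
      n = dplyr::n(),
      duration_s = max(.data$time) - min(.data$time),
      .by = "run"
    )
  on <- runs |>
    dplyr::filter(
      abs(.data$potential_V) >= level_floor,
      .data$duration_s >= min_duration
    )
  if (nrow(on) == 0L) {
    stop_data("no voltage steps found")
  }
  if (!is.null(protocol_hint)) {
    amps <- protocol_hint$amplitude_V
    on$potential_V <- vapply(on$potential_V, function(p) {
      amps[which.min(abs(amps - p))]
    }, numeric(1L))
  }
  on |>
    dplyr::arrange(.data$start) |>
    dplyr::mutate(step = dplyr::row_number()) |>
    dplyr::select("step", "potential_V", "start", "end", "n", "duration_s")
}

#' Estimate the zero-field membrane state
#'
#' Averages capacitance and area over all zero/low-field samples
#' (|potential| <= `low_field_threshold`, which captures both the off-periods
#' and the ±1 mV reference step) and derives the zero-field thickness,
#' specific capacitance and membrane volume:
#' \eqn{d_0 = \varepsilon_0\varepsilon_r A_0/C_0}, \eqn{C_m = C_0/A_0},
#' \eqn{V_0 = A_0 d_0}.
#'
#' @param trace An [electro_trace()].
#' @param low_field_threshold Largest |potential| counted as baseline, V.
#'   Default 5e-3.
#' @param dielectric_constant Relative permittivity of the core; default
#'   taken from trace metadata, else 2.5.
#' @param detrend Linearly detrend the baseline capacitance against time and
#'   use the value extrapolated to the first sample? Default FALSE (plain
#'   mean).
#'
#' @return A one-row tibble of class `membrane_state` with columns
#'   `zero_field_capacitance` (F), `zero_field_area` (m^2),
#'   `zero_field_thickness` (m), `specific_capacitance` (F/m^2),
#'   `zero_field_volume` (m^3), `dielectric_constant`, `n_samples`.
#' @export
estimate_state <- function(trace, low_field_threshold = 5e-3,
                           dielectric_constant = NULL, detrend = FALSE) {
  validate_trace(trace)
  er <- dielectric_constant %||%
    trace_metadata(trace)$dielectric_constant %||% 2.5
  check_positive(er, "dielectric_constant")
  idx <- which(abs(trace$potential_V) <= low_field_threshold)
  if (length(idx) == 0L) {
    stop_data("no zero- or low-field samples to estimate the membrane state")
  }
  if (detrend && length(idx) > 2L) {
    fit <- lm(trace$capacitance_F[idx] ~ trace$time_s[idx])
    c0 <- unname(coef(fit)[1L] + coef(fit)[2L] * trace$time_s[1L])
  } else {
    c0 <- mean(trace$capacitance_F[idx])
  }
  a0 <- mean(trace$area_m2[idx])
  if (c0 <= 0 || a0 <= 0) {
    stop_data("baseline capacitance/area average is non-positive")
  }
  d0 <- vacuum_permittivity * er * a0 / c0
  out <- tibble(
    zero_field_capacitance = c0,
    zero_field_area = a0,
    zero_field_thickness = d0,
    specific_capacitance = c0 / a0,
    zero_field_volume = a0 * d0,
    dielectric_constant = er,
    n_samples = length(idx)
  )
  class(out) <- c("membrane_state", class(out))
  out
}

#' Summarise voltage steps to steady-state aggregates
#'
#' For each on-segment, averages potential, capacitance and area over the
#' trailing `settle_fraction` of the segment (discarding the settling
#' transient), then derives the thickness under field, the constant-volume
#' capacitance (the step's capacitance had only the thickness changed from
#' the zero-field state) and the measured membrane volume.
#'
#' @param trace An [electro_trace()].
#' @param segments Output of [segment_steps()].
#' @param state Output of [estimate_state()].
#' @param settle_fraction Fraction of each segment, taken from its end, used
#'   for averaging. Default 0.5.
#'
#' @return A tibble with one row per step: `potential_V`,
#'   `mean_capacitance_F`, `mean_area_m2`, `thickness_m`,
#'   `constant_volume_capacitance_F`, `measured_volume_m3`,
#'   `thickness_decrease_m`, `young_modulus_step_Pa` (single-step legacy
#'   estimator, NA where the step shows no compression), `n_samples`.
#' @export
summarize_steps <- function(trace, segments, state, settle_fraction = 0.5) {
  validate_trace(trace)
  if (!is.numeric(settle_fraction) || length(settle_fraction) != 1L ||
      !is.finite(settle_fraction) || settle_fraction <= 0 ||
      settle_fraction > 1) {
    stop_config("`settle_fraction` must lie in (0, 1].")
  }
  er <- state$dielectric_constant
  d0 <- state$zero_field_thickness
  v0 <- state$zero_field_volume
  cm <- state$specific_capacitance

  summaries <- purrr::pmap(
    list(segments$start, segments$end),
    function(start, end) {
      n_seg <- end - start + 1L
      n_keep <- max(1L, ceiling(n_seg * settle_fraction))
      idx <- seq.int(end - n_keep + 1L, end)
      psi <- mean(trace$potential_V[idx])
      cap <- mean(trace$capacitance_F[idx])
      area <- mean(trace$area_m2[idx])
      if (cap <= 0 || area <= 0) {
        stop_data("averaged capacitance or area is non-positive in a step")
      }
      d_psi <- vacuum_permittivity * er * area / cap
      dd <- d0 - d_psi
      tibble(
        potential_V = psi,
        mean_capacitance_F = cap,
        mean_area_m2 = area,
        thickness_m = d_psi,
        constant_volume_capacitance_F =
          vacuum_permittivity * er * v0 / d_psi^2,
        measured_volume_m3 = area * d_psi,
        thickness_decrease_m = dd,
        young_modulus_step_Pa = if (dd > 0 && psi != 0) {
          cm * psi^2 / (2 * dd)
        } else {
          NA_real_
        },
        n_samples = n_keep
      )
    }
  )
  dplyr::bind_rows(summaries)
}

#' Fit the quadratic capacitance-voltage law
#'
#' Ordinary least squares (free intercept) of the constant-volume capacitance
#' against the squared applied potential, pooling positive and negative
#' branches.  The electrostriction proportionality constant is
#' \eqn{\alpha = m/(\mathrm{slope\_factor}\cdot C_0)} from the fitted slope m.
#' Per-branch fits quantify polarity asymmetry as
#' \eqn{|\alpha_+ - \alpha_-| / \bar\alpha} (NA unless both polarities carry
#' at least two distinct magnitudes).
#'
#' @param steps Output of [summarize_steps()].
#' @param state Output of [estimate_state()].
#' @param slope_factor See [alpha_from_slope()]. Default 3.
#'
#' @return A list of class `alpha_fit`: `alpha`, `alpha_se`, `slope`,
#'   `slope_se`, `intercept`, `r_squared`, `branch_asymmetry`,
#'   `alpha_positive`, `alpha_negative`, `intercept_rel_dev` (fitted intercept
#'   vs measured C0, relative), `n_steps`, `slope_factor` and the underlying
#'   `model` (an `lm`).
#' @export
fit_alpha <- function(steps, state, slope_factor = 3) {
  x <- steps$potential_V^2
  y <- steps$constant_volume_capacitance_F
  if (length(unique(signif(x, 10))) < 2L) {
    stop_data("need at least 2 distinct squared-voltage values to fit alpha")
  }
  model <- lm(y ~ x)
  # summary.lm warns on exactly-linear (noiseless, simulated) data; that case
  # is legitimate here, so muffle just that warning.
  sm <- withCallingHandlers(
    summary(model),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  slope <- unname(coef(model)[2L])
  slope_se <- sm$coefficients[2L, 2L]
  c0 <- state$zero_field_capacitance
  alpha <- alpha_from_slope(slope, c0, slope_factor)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0

  branch_alpha <- function(sign_sel) {
    sel <- if (sign_sel > 0) steps$potential_V > 0 else steps$potential_V < 0
    if (sum(sel) < 2L || length(unique(signif(x[sel], 10))) < 2L) {
      return(NA_real_)
    }
    m_b <- unname(coef(lm(y[sel] ~ x[sel]))[2L])
    alpha_from_slope(m_b, c0, slope_factor)
  }
  a_pos <- branch_alpha(+1)
  a_neg <- branch_alpha(-1)
  asym <- if (is.na(a_pos) || is.na(a_neg)) {
    NA_real_
  } else {
    abs(a_pos - a_neg) / ((a_pos + a_neg) / 2)
  }

  if (slope <= 0) {
    warn_flag(
      "fitted capacitance-voltage slope is non-positive (alpha <= 0); ",
      "elastic moduli are undefined for this trace"
    )
  }
  structure(
    list(
      alpha = alpha,
      alpha_se = slope_se / (slope_factor * c0),
      slope = slope,
      slope_se = slope_se,
      intercept = unname(coef(model)[1L]),
      r_squared = r2,
      branch_asymmetry = asym,
      alpha_positive = a_pos,
      alpha_negative = a_neg,
      intercept_rel_dev = (unname(coef(model)[1L]) - c0) / c0,
      n_steps = length(x),
      slope_factor = slope_factor,
      model = model
    ),
    class = "alpha_fit"
  )
}

#' Elastic moduli from the fitted electrostriction response
#'
#' Computes both Young's modulus estimators and the thin-plate conversion:
#' the constant-volume route \eqn{E_\perp = C_m/(\alpha d_0)} from the pooled
#' alpha fit, and the legacy single-thickness route from the least-squares
#' slope s of the thickness decrease against \eqn{\psi^2}, \eqn{E = C_m/(2s)}.
#' The area-expansion modulus and bending rigidity are derived from the
#' constant-volume modulus with the zero-field thickness.
#'
#' When alpha is not positive the moduli are returned as NA with a classed
#' warning rather than an error, so degenerate traces still produce a report.
#'
#' @param steps Output of [summarize_steps()].
#' @param state Output of [estimate_state()].
#' @param fit Output of [fit_alpha()].
#' @param poisson_ratio Poisson ratio used in the thin-plate conversion.
#'   Default 0.5.
#'
#' @return A one-row tibble: `alpha`, `alpha_se`,
#'   `young_modulus_constant_volume_Pa`, `young_modulus_legacy_Pa`,
#'   `modulus_ratio`, `area_expansion_modulus_N_m`, `bending_rigidity_J`,
#'   `fit_r_squared`, `branch_asymmetry`, `volume_growth_ratio` (max measured
#'   volume over V0), `poisson_ratio`.
#' @export
estimate_moduli <- function(steps, state, fit, poisson_ratio = 0.5) {
  cm <- state$specific_capacitance
  d0 <- state$zero_field_thickness

  if (is.finite(fit$alpha) && fit$alpha > 0) {
    e_cv <- young_modulus_alvarez(cm, fit$alpha, d0)
    ka <- area_expansion_modulus(e_cv, d0, poisson_ratio)
    kc <- bending_rigidity(ka, d0, poisson_ratio)
  } else {
    warn_flag("alpha <= 0: Young's modulus and bending rigidity are undefined")
    e_cv <- ka <- kc <- NA_real_
  }

  dd <- steps$thickness_decrease_m
  x <- steps$potential_V^2
  e_legacy <- NA_real_
  if (any(dd > 0) && length(unique(signif(x, 10))) >= 2L) {
    s <- unname(coef(lm(dd ~ x))[2L])
    if (is.finite(s) && s > 0) {
      e_legacy <- cm / (2 * s)
    }
  }
  if (is.na(e_legacy)) {
    warn_flag("no measurable compression: legacy Young's modulus undefined")
  }

  tibble(
    alpha = fit$alpha,
    alpha_se = fit$alpha_se,
    young_modulus_constant_volume_Pa = e_cv,
    young_modulus_legacy_Pa = e_legacy,
    modulus_ratio = e_cv / e_legacy,
    area_expansion_modulus_N_m = ka,
    bending_rigidity_J = kc,
    fit_r_squared = fit$r_squared,
    branch_asymmetry = fit$branch_asymmetry,
    volume_growth_ratio = max(steps$measured_volume_m3) /
      state$zero_field_volume,
    poisson_ratio = poisson_ratio
  )
}

#' Bootstrap confidence intervals for alpha, E and k_c
#'
#' Residual-resampling bootstrap of the constant-volume-capacitance vs
#' squared-voltage regression: leverage-adjusted, centred residuals are
#' resampled onto the fitted line, the slope refitted, and each replicate
#' mapped through \eqn{\alpha = m/(s C_0)}, \eqn{E = C_m/(\alpha d_0)} and the
#' thin-plate chain to \eqn{k_c}.  Percentile intervals are reported.
#'
#' @param steps Output of [summarize_steps()].
#' @param state Output of [estimate_state()].
#' @param B Number of bootstrap replicates (at least 50). Default 1000.
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @param slope_factor See [alpha_from_slope()].
#' @param poisson_ratio Poisson ratio for the thin-plate chain.
#' @param level Confidence level. Default 0.95.
#'
#' @return A tibble with columns `term` (`alpha`,
#'   `young_modulus_constant_volume_Pa`, `bending_rigidity_J`), `estimate`,
#'   `conf.low`, `conf.high`; attributes `B`, `level`, `seed`.
#' @export
bootstrap_uncertainty <- function(steps, state, B = 1000, seed = NULL,
                                  slope_factor = 3, poisson_ratio = 0.5,
                                  level = 0.95) {
  if (!is.numeric(B) || length(B) != 1L || B < 50) {
    stop_config("`B` must be a single number >= 50.")
  }
  B <- as.integer(B)
  x <- steps$potential_V^2
  y <- steps$constant_volume_capacitance_F
  n <- length(x)
  if (length(unique(signif(x, 10))) < 2L) {
    stop_data("need at least 2 distinct squared-voltage values to bootstrap")
  }
  model <- lm(y ~ x)
  h <- pmin(hatvalues(model), 1 - 1e-12)
  r <- resid(model) / sqrt(1 - h)
  r <- r - mean(r)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  m_hat <- unname(coef(model)[2L])

  idx <- with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), n, B))
  m_star <- m_hat + colSums(xc * matrix(r[idx], n, B)) / sxx

  c0 <- state$zero_field_capacitance
  cm <- state$specific_capacitance
  d0 <- state$zero_field_thickness
  alpha_star <- m_star / (slope_factor * c0)
  e_star <- ifelse(alpha_star > 0, cm / (alpha_star * d0), NA_real_)
  kc_star <- e_star * d0^3 /
    (24 * (1 - poisson_ratio) * (1 + poisson_ratio))

  alpha_hat <- m_hat / (slope_factor * c0)
  e_hat <- if (alpha_hat > 0) cm / (alpha_hat * d0) else NA_real_
  kc_hat <- e_hat * d0^3 / (24 * (1 - poisson_ratio) * (1 + poisson_ratio))

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- function(v) {
    if (all(is.na(v))) c(NA_real_, NA_real_) else quantile(v, probs, na.rm = TRUE, names = FALSE)
  }
  qa <- qs(alpha_star)
  qe <- qs(e_star)
  qk <- qs(kc_star)
  out <- tibble(
    term = c("alpha", "young_modulus_constant_volume_Pa",
             "bending_rigidity_J"),
    estimate = c(alpha_hat, e_hat, kc_hat),
    conf.low = c(qa[1L], qe[1L], qk[1L]),
    conf.high = c(qa[2L], qe[2L], qk[2L])
  )
  attr(out, "B") <- B
  attr(out, "level") <- level
  attr(out, "seed") <- seed
  out
}

default_config <- function() {
  list(
    tolerance = 2e-3,
    level_floor = 5e-3,
    min_duration = 0.5,
    settle_fraction = 0.5,
    low_field_threshold = 5e-3,
    detrend = FALSE,
    slope_factor = 3,
    poisson_ratio = 0.5,
    bootstrap_replicates = 1000,
    bootstrap_level = 0.95,
    seed = 1L,
    dielectric_constant = NULL
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    classes <- intersect(
      class(e),
      c("electrobend_config_error", "electrobend_data_error",
        "electrobend_domain_error")
    )
    abort(
      paste0(stage, ": ", conditionMessage(e)),
      class = c(classes, "electrobend_error")
    )
  })
}

#' Run the full electrostriction analysis on a trace
#'
#' Deterministic end-to-end composition of the pipeline: segmentation,
#' zero-field state estimation, per-step summaries with the constant-volume
#' correction, the alpha fit, both modulus estimators, the thin-plate
#' conversion and (optionally) bootstrap intervals.  Errors from individual
#' stages are re-raised with the stage name prefixed.
#'
#' @param trace An [electro_trace()] (or path to a trace CSV).
#' @param config Named list overriding entries of the default configuration:
#'   `tolerance`, `level_floor`, `min_duration` (segmentation, V / V / s);
#'   `settle_fraction`; `low_field_threshold`, `detrend`,
#'   `dielectric_constant` (state estimation); `slope_factor`,
#'   `poisson_ratio`; `bootstrap_replicates` (0 disables the bootstrap),
#'   `bootstrap_level`, `seed`.
#'
#' @return An object of class `electro_fit`: a list with elements `state`,
#'   `segments`, `steps`, `fit` (the `alpha_fit`), `result` (one-row moduli
#'   tibble), `intervals` (bootstrap tibble or NULL) and `config`.  Has
#'   [tidy()], [glance()], [autoplot()] and print methods.
#' @examples
#' trace <- simulate_trace(simulation_params())
#' fit <- run_analysis(trace)
#' tidy(fit)
#' glance(fit)
#' @export
run_analysis <- function(trace, config = list()) {
  cfg <- modifyList(default_config(), config)
  if (is.character(trace)) {
    trace <- with_stage("read", read_trace(trace))
  }
  segments <- with_stage(
    "segmentation",
    segment_steps(trace,
      tolerance = cfg$tolerance, level_floor = cfg$level_floor,
      min_duration = cfg$min_duration
    )
  )
  state <- with_stage(
    "state estimation",
    estimate_state(trace,
      low_field_threshold = cfg$low_field_threshold,
      dielectric_constant = cfg$dielectric_constant,
      detrend = cfg$detrend
    )
  )
  steps <- with_stage(
    "step summary",
    summarize_steps(trace, segments, state,
      settle_fraction = cfg$settle_fraction
    )
  )
  fit <- with_stage(
    "alpha fit",
    fit_alpha(steps, state, slope_factor = cfg$slope_factor)
  )
  result <- with_stage(
    "moduli",
    estimate_moduli(steps, state, fit, poisson_ratio = cfg$poisson_ratio)
  )
  intervals <- NULL
  if (cfg$bootstrap_replicates > 0 && is.finite(fit$alpha) && fit$alpha > 0) {
    intervals <- with_stage(
      "bootstrap",
      bootstrap_uncertainty(steps, state,
        B = cfg$bootstrap_replicates, seed = cfg$seed,
        slope_factor = cfg$slope_factor,
        poisson_ratio = cfg$poisson_ratio,
        level = cfg$bootstrap_level
      )
    )
  }
  structure(
    list(
      state = state, segments = segments, steps = steps, fit = fit,
      result = result, intervals = intervals, config = cfg,
      metadata = trace_metadata(trace)
    ),
    class = "electro_fit"
  )
}
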
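# Methods for fitted electro_fit objects: print, broom-style tidy/glance,
# autoplot, and the JSON report.

#' @export
print.electro_fit <- function(x, ...) {
  st <- x$state
  rs <- x$result
  cat("Electrostriction analysis of a planar bilayer trace\n")
  if (!is.null(x$metadata$lipid)) {
    cat("  condition: ", x$metadata$lipid,
        if (!is.null(x$metadata$x_factor)) {
          paste0(" (x = ", signif(x$metadata$x_factor, 3), ")")
        },
        "\n", sep = "")
  }
  cat(sprintf("  steps: %d  |  C0 = %.4g pF  A0 = %.4g mm^2  d0 = %.4g nm\n",
              nrow(x$steps), st$zero_field_capacitance * 1e12,
              st$zero_field_area * 1e6, st$zero_field_thickness * 1e9))
  cat(sprintf("  alpha = %.4g V^-2 (r^2 = %.4f, branch asymmetry = %.3g)\n",
              rs$alpha, rs$fit_r_squared, rs$branch_asymmetry))
  cat(sprintf("  E (constant volume) = %.4g Pa  |  E (legacy) = %.4g Pa  (ratio %.3g)\n",
              rs$young_modulus_constant_volume_Pa,
              rs$young_modulus_legacy_Pa, rs$modulus_ratio))
  cat(sprintf("  K_A = %.4g N/m  |  k_c = %.4g J\n",
              rs$area_expansion_modulus_N_m, rs$bending_rigidity_J))
  if (!is.null(x$intervals)) {
    kc <- x$intervals[x$intervals$term == "bending_rigidity_J", ]
    cat(sprintf("  k_c %d%% CI: [%.4g, %.4g] J (B = %d)\n",
                round(attr(x$intervals, "level") * 100),
                kc$conf.low, kc$conf.high, attr(x$intervals, "B")))
  }
  invisible(x)
}

#' Tidy the parameter estimates of an electrostriction fit
#'
#' @param x An `electro_fit` from [run_analysis()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`alpha`, the two Young's
#'   modulus estimators, `area_expansion_modulus_N_m`,
#'   `bending_rigidity_J`): `term`, `estimate`, `std.error` (alpha only),
#'   `conf.low`, `conf.high` (bootstrap, where available).
#' @exportS3Method generics::tidy
tidy.electro_fit <- function(x, ...) {
  rs <- x$result
  out <- tibble(
    term = c(
      "alpha", "young_modulus_constant_volume_Pa",
      "young_modulus_legacy_Pa", "area_expansion_modulus_N_m",
      "bending_rigidity_J"
    ),
    estimate = c(
      rs$alpha, rs$young_modulus_constant_volume_Pa,
      rs$young_modulus_legacy_Pa, rs$area_expansion_modulus_N_m,
      rs$bending_rigidity_J
    ),
    std.error = c(rs$alpha_se, NA, NA, NA, NA),
    conf.low = NA_real_,
    conf.high = NA_real_
  )
  if (!is.null(x$intervals)) {
    ii <- match(out$term, x$intervals$term)
    out$conf.low <- x$intervals$conf.low[ii]
    out$conf.high <- x$intervals$conf.high[ii]
  }
  out
}

#' One-row fit diagnostics
#'
#' @param x An `electro_fit` from [run_analysis()].
#' @param ... Unused.
#' @return A one-row tibble: `r.squared` of the capacitance-voltage fit,
#'   `branch_asymmetry`, `intercept_rel_dev` (fitted intercept vs measured
#'   zero-field capacitance), `volume_growth_ratio`, `modulus_ratio`,
#'   `n_steps`.
#' @exportS3Method generics::glance
glance.electro_fit <- function(x, ...) {
  tibble(
    r.squared = x$fit$r_squared,
    branch_asymmetry = x$fit$branch_asymmetry,
    intercept_rel_dev = x$fit$intercept_rel_dev,
    volume_growth_ratio = x$result$volume_growth_ratio,
    modulus_ratio = x$result$modulus_ratio,
    n_steps = x$fit$n_steps
  )
}

#' Plot the constant-volume capacitance against squared voltage
#'
#' The central diagnostic: per-step constant-volume capacitance (pF) against
#' \eqn{\psi^2} (V^2), coloured by polarity, with the pooled linear fit
#' overlaid.  Overlapping polarities indicate a symmetric membrane/bath.
#'
#' @param object An `electro_fit` from [run_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.electro_fit <- function(object, ...) {
  steps <- object$steps |>
    dplyr::mutate(
      psi2 = .data$potential_V^2,
      branch = ifelse(.data$potential_V > 0, "positive", "negative"),
      c_cv_pF = .data$constant_volume_capacitance_F * 1e12
    )
  ggplot2::ggplot(steps, ggplot2::aes(.data$psi2, .data$c_cv_pF)) +
    ggplot2::geom_abline(
      intercept = object$fit$intercept * 1e12,
      slope = object$fit$slope * 1e12,
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$branch), size = 2) +
    ggplot2::labs(
      x = expression(psi^2 ~ (V^2)),
      y = "constant-volume capacitance (pF)",
      colour = "polarity"
    ) +
    ggplot2::theme_minimal()
}

#' Write a structured JSON report of an analysis
#'
#' Serialises the membrane state, per-step table, fit parameters, moduli,
#' bootstrap intervals and diagnostics.
#'
#' @param fit An `electro_fit` from [run_analysis()].
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  report <- list(
    metadata = fit$metadata,
    state = as.list(fit$state),
    steps = fit$steps,
    fit = fit$fit[c(
      "alpha", "alpha_se", "slope", "slope_se", "intercept", "r_squared",
      "branch_asymmetry", "alpha_positive", "alpha_negative",
      "intercept_rel_dev", "n_steps", "slope_factor"
    )],
    moduli = as.list(fit$result),
    intervals = fit$intervals,
    diagnostics = as.list(glance(fit))
  )
  jsonlite::write_json(report, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}
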
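# Calcium-asymmetry bookkeeping and condition-series analysis.
#
# Asymmetry experiments add aliquots of concentrated CaCl2 stock to the top
# chamber only; perfect-mixing dilution gives the top concentration after n
# additions, and the asymmetry factor x is the top/bottom concentration ratio.

#' Top-chamber concentration after successive aliquot additions
#'
#' Perfect-mixing dilution:
#' \deqn{c_n = (c_0 V + n V_a c_s) / (V + n V_a)}
#' where V is the chamber volume, \eqn{V_a} the aliquot volume and \eqn{c_s}
#' the stock concentration.  Monotone increasing in n and bounded above by the
#' stock concentration.
#'
#' @param n_additions Number of aliquots added (vectorised, >= 0).
#' @param chamber_volume Top-chamber volume in L.  Required: depends on the
#'   cell geometry (the standard fixtures use 1.0e-3 L, for which one 50 uL
#'   aliquot of 200 mM stock into 2 mM gives 11.43 mM).
#' @param aliquot_volume Aliquot volume in L. Default 50e-6.
#' @param stock_concentration Stock concentration in mM. Default 200.
#' @param initial_concentration Starting top concentration in mM. Default 2.
#'
#' @return Top-chamber concentration in mM.
#' @export
concentration_after_additions <- function(n_additions, chamber_volume,
                                          aliquot_volume = 50e-6,
                                          stock_concentration = 200,
                                          initial_concentration = 2) {
  if (!is.numeric(n_additions) || any(!is.finite(n_additions)) ||
      any(n_additions < 0)) {
    stop_domain("`n_additions` must be a non-negative count.")
  }
  check_positive(chamber_volume, "chamber_volume")
  check_positive(aliquot_volume, "aliquot_volume")
  check_positive(stock_concentration, "stock_concentration")
  check_positive(initial_concentration, "initial_concentration")
  (initial_concentration * chamber_volume +
     n_additions * aliquot_volume * stock_concentration) /
    (chamber_volume + n_additions * aliquot_volume)
}

#' Ionic asymmetry factor
#'
#' The ratio of the top to bottom chamber concentration of the asymmetric ion
#' (x = 1 for symmetric baths).
#'
#' @param top,bottom Concentrations in the same units (both positive).
#' @return Dimensionless ratio top/bottom.
#' @export
asymmetry_factor <- function(top, bottom) {
  check_positive(top, "top")
  check_positive(bottom, "bottom")
  top / bottom
}

#' Tabulate an aliquot-addition schedule
#'
#' One row per state of the top chamber from 0 to `n_additions` aliquots, with
#' the resulting top concentration and asymmetry factor.
#'
#' @inheritParams concentration_after_additions
#' @param bottom_concentration Constant bottom-chamber concentration, mM.
#'   Default 2.
#' @return A tibble with columns `n_additions`, `top_concentration_mM`,
#'   `bottom_concentration_mM`, `x_factor`.
#' @export
asymmetry_schedule <- function(n_additions, chamber_volume,
                               aliquot_volume = 50e-6,
                               stock_concentration = 200,
                               initial_concentration = 2,
                               bottom_concentration = 2) {
  check_positive(bottom_concentration, "bottom_concentration")
  n <- 0:n_additions
  top <- concentration_after_additions(
    n, chamber_volume, aliquot_volume,
    stock_concentration, initial_concentration
  )
  tibble(
    n_additions = n,
    top_concentration_mM = top,
    bottom_concentration_mM = bottom_concentration,
    x_factor = asymmetry_factor(top, bottom_concentration)
  )
}

#' Analyse a series of traces across asymmetry conditions
#'
#' Runs [run_analysis()] on each trace of a manifest and tabulates the
#' recovered zero-field thickness and bending rigidity against the asymmetry
#' factor, with percent-change columns relative to the symmetric (x = 1, or
#' smallest-x) condition.
#'
#' @param manifest A data frame with columns `trace_path` and optionally
#'   `lipid` and `x_factor`, or the path of a CSV file with that header.
#'   Missing `lipid`/`x_factor` fall back to each trace's metadata.
#' @param config Analysis configuration passed to [run_analysis()].
#' @param by_lipid Allow multiple lipid labels and compute percent changes
#'   within each lipid group? Default FALSE (mixed labels are a configuration
#'   error, to catch accidentally concatenated experiments).
#'
#' @return A tibble of class `electro_series`, one row per trace, ordered by
#'   lipid then `x_factor`: `lipid`, `x_factor`, `thickness_m`,
#'   `bending_rigidity_J`, `bending_rigidity_conf.low`,
#'   `bending_rigidity_conf.high`, `young_modulus_Pa`, `trace_path`, and — when
#'   the series has more than one row — `thickness_pct_change` and
#'   `bending_rigidity_pct_change` relative to the baseline row.
#' @export
run_series <- function(manifest, config = list(), by_lipid = FALSE) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      stop_data("manifest file not found: ", manifest)
    }
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(manifest) || !"trace_path" %in% names(manifest)) {
    stop_config("manifest must have a `trace_path` column.")
  }
  if (nrow(manifest) == 0L) {
    stop_config("manifest is empty.")
  }

  manifest_field <- function(col, i) {
    if (!col %in% names(manifest)) {
      return(NULL)
    }
    v <- manifest[[col]][i]
    if (is.na(v)) NULL else v
  }
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    path <- manifest[["trace_path"]][i]
    trace <- read_trace(path)
    meta <- trace_metadata(trace)
    fit <- run_analysis(trace, config)
    kc_ci <- c(NA_real_, NA_real_)
    if (!is.null(fit$intervals)) {
      row <- fit$intervals[fit$intervals$term == "bending_rigidity_J", ]
      kc_ci <- c(row$conf.low, row$conf.high)
    }
    tibble(
      lipid = as.character(
        manifest_field("lipid", i) %||% meta$lipid %||% NA_character_
      ),
      x_factor = as.numeric(
        manifest_field("x_factor", i) %||% meta$x_factor %||% NA_real_
      ),
      thickness_m = fit$state$zero_field_thickness,
      bending_rigidity_J = fit$result$bending_rigidity_J,
      bending_rigidity_conf.low = kc_ci[1L],
      bending_rigidity_conf.high = kc_ci[2L],
      young_modulus_Pa = fit$result$young_modulus_constant_volume_Pa,
      trace_path = path
    )
  })
  out <- dplyr::bind_rows(rows)

  lipids <- unique(out$lipid[!is.na(out$lipid)])
  if (length(lipids) > 1L && !by_lipid) {
    stop_config(
      "manifest mixes lipid labels (",
      paste(lipids, collapse = ", "),
      "); set `by_lipid = TRUE` to analyse them as separate groups."
    )
  }

  out <- dplyr::arrange(out, .data$lipid, .data$x_factor, .data$trace_path)
  if (nrow(out) > 1L) {
    out <- out |>
      dplyr::group_by(.data$lipid) |>
      dplyr::group_modify(function(g, key) {
        # baseline: the symmetric (x = 1) row if present, else the smallest x
        base_i <- which(abs(g$x_factor - 1) < 1e-9)[1L]
        if (is.na(base_i)) base_i <- which.min(g$x_factor)
        g$thickness_pct_change <- 100 * (g$thickness_m / g$thickness_m[base_i] - 1)
        g$bending_rigidity_pct_change <-
          100 * (g$bending_rigidity_J / g$bending_rigidity_J[base_i] - 1)
        g
      }) |>
      dplyr::ungroup()
  }
  class(out) <- c("electro_series", class(out))
  out
}

#' Plot a condition series
#'
#' Thickness (nm) and bending rigidity (units of 1e-20 J) against the
#' asymmetry factor x, one facet per quantity, coloured by lipid.
#'
#' @param object An `electro_series` from [run_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.electro_series <- function(object, ...) {
  long <- tibble(
    lipid = object$lipid,
    x_factor = object$x_factor,
    `thickness (nm)` = object$thickness_m * 1e9,
    `bending rigidity (1e-20 J)` = object$bending_rigidity_J * 1e20
  ) |>
    tidyr::pivot_longer(-c("lipid", "x_factor"),
      names_to = "quantity", values_to = "value"
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$x_factor, .data$value, colour = .data$lipid)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "asymmetry factor x", y = NULL, colour = "lipid") +
    ggplot2::theme_minimal()
}
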
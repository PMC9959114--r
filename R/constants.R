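# Physical constants and shared input checks.

#' Vacuum permittivity
#'
#' Permittivity of free space, \eqn{\varepsilon_0}, in F/m (CODATA, five
#' significant figures).  All capacitance formulas in the package use this
#' value; it carries more precision than any capacitance measurement the
#' package consumes.
#'
#' @format A length-one numeric, `8.8542e-12` F/m.
#' @export
vacuum_permittivity <- 8.8542e-12

# Condition helpers. Three error classes drive the CLI exit codes:
# domain/data errors -> 1, configuration errors -> 2.
stop_domain <- function(...) {
  abort(paste0(...), class = c("electrobend_domain_error", "electrobend_error"))
}
stop_data <- function(...) {
  abort(paste0(...), class = c("electrobend_data_error", "electrobend_error"))
}
stop_config <- function(...) {
  abort(paste0(...), class = c("electrobend_config_error", "electrobend_error"))
}
warn_flag <- function(...) {
  warn(paste0(...), class = "electrobend_warning")
}

# Positive, finite, numeric -- the precondition shared by every physical input.
check_positive <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop_domain("`", name, "` must be finite and numeric.")
  }
  bad <- if (allow_zero) any(x < 0) else any(x <= 0)
  if (bad) {
    stop_domain(
      "`", name, "` must be ",
      if (allow_zero) "non-negative." else "strictly positive."
    )
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the session RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_config("`seed` must be a single integer.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
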
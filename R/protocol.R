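# Square-wave voltage-clamp protocol.

#' Build a square-wave voltage protocol
#'
#' The standard electrostriction protocol: square pulses of 2 s on and 2 s
#' off, starting from a small ±1 mV reference level and stepping by ±25 mV up
#' to ±200 mV.  At each magnitude the positive pulse precedes the negative one
#' (interleaved sign order).
#'
#' @param step Voltage increment between magnitudes, V. Default 0.025.
#' @param max_level Largest magnitude, V. Default 0.200.
#' @param include_reference Prepend the ±1 mV reference level(s)? Default TRUE.
#' @param signs Which polarities to include: `"both"` (default), `"positive"`
#'   or `"negative"`.
#' @param on_duration Pulse duration, s. Default 2.
#' @param off_duration Zero-field gap after each pulse, s. Default 2.
#' @param sample_rate Acquisition rate for simulation, Hz. Default 1000.
#'
#' @return A tibble of class `voltage_protocol` with columns `level` (ordinal)
#'   and `amplitude_V`, carrying `on_duration`, `off_duration` and
#'   `sample_rate` as attributes.
#' @examples
#' build_protocol() # 18 levels: +/-1 mV then +/-25 ... +/-200 mV
#' @export
build_protocol <- function(step = 0.025, max_level = 0.200,
                           include_reference = TRUE,
                           signs = c("both", "positive", "negative"),
                           on_duration = 2, off_duration = 2,
                           sample_rate = 1000) {
  signs <- match.arg(signs)
  check_positive(step, "step")
  check_positive(max_level, "max_level")
  check_positive(on_duration, "on_duration")
  check_positive(off_duration, "off_duration", allow_zero = TRUE)
  check_positive(sample_rate, "sample_rate")
  if (step > max_level) {
    stop_config("`step` (", step, ") must not exceed `max_level` (",
                max_level, ").")
  }
  magnitudes <- seq_len(floor(max_level / step + 1e-9)) * step
  amplitudes <- switch(signs,
    both = as.vector(rbind(magnitudes, -magnitudes)),
    positive = magnitudes,
    negative = -magnitudes
  )
  if (include_reference) {
    reference <- switch(signs,
      both = c(0.001, -0.001),
      positive = 0.001,
      negative = -0.001
    )
    amplitudes <- c(reference, amplitudes)
  }
  out <- tibble(level = seq_along(amplitudes), amplitude_V = amplitudes)
  structure(out,
    on_duration = on_duration,
    off_duration = off_duration,
    sample_rate = sample_rate,
    class = c("voltage_protocol", class(out))
  )
}
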
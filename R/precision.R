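#' Round half away from zero
#'
#' Printed tables in comparative visual optics conventionally round halves
#' away from zero (18.466 -> 18.5, -0.0029 -> -0.003), whereas base R's
#' [round()] rounds halves to even. All printed-precision reporting in this
#' package goes through this function.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_away(18.466, 1)
#' round_half_away(-0.0029876, 3)
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, is.finite(digits))
  p <- 10^digits
  # tiny epsilon guards against values like 0.4999999999 produced by binary
  # representation of decimal inputs; negligible at the magnitudes used here
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# decimal places used by the printed-report policy, keyed by output quantity
printed_digits <- c(
  P1 = 3, P2 = 3, P3 = 3, P_total = 3,
  f_um = 1, f_image_um = 1, F_number = 1,
  acceptance_angle_deg = 1, airy_halfwidth_deg = 1,
  sensitivity_um2_sr = 2,
  V = 2, interommatidial_angle_geo_deg = 1,
  body_size_mm = 2
)

# fixed-decimal formatting (deterministic bytes for reports)
fmt_fixed <- function(x, digits) {
  out <- ifelse(is.na(x), "—",
    formatC(round_half_away(x, digits), format = "f", digits = digits)
  )
  # normalize "-0.000" style artefacts
  sub("^-(0\\.?0*)$", "\\1", out)
}
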
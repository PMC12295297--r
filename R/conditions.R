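# classed conditions so callers can distinguish bad values from bad files

abort_domain <- function(msg, ...) {
  abort(msg, class = "ommatidia_error_domain", ...)
}

abort_missing_input <- function(field) {
  abort(
    paste0("required morphometric input is missing: ", field),
    class = "ommatidia_error_missing_input",
    field = field
  )
}

abort_parse <- function(msg, line = NA_integer_) {
  abort(msg, class = "ommatidia_error_parse", line = line)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "ommatidia_error_validation", ...)
}

warn_f_number <- function(value) {
  warn(
    paste0(
      "F-number computed as f/D (= ", fmt_fixed(value, 2), "). ",
      "Published values for Ceratosolen gravelyi use a revised formulation ",
      "that is not publicly documented; f/D can differ from such values ",
      "(here: f/D rounds to ", fmt_fixed(value, 1), ")."
    ),
    class = "ommatidia_warning_f_number"
  )
}
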
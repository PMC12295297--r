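#' Optical constants for the compound-eye model
#'
#' Bundles the refractive indices, wavelength and rhabdom absorption
#' coefficient used throughout the optical model. The defaults are the
#' calibrated values used for the *Ceratosolen gravelyi* analysis:
#'
#' * `n_cornea = 1.452`, `n_cone = 1.348`: corneal and crystalline-cone
#'   indices consistent with the comparative thick-lens method for
#'   miniature hymenopteran eyes, and with the published surface powers
#'   for this species' corneal curvatures.
#' * `n_rhabdom = 1.363`, `n_surround = 1.339`: literature-standard
#'   photoreceptor and cytoplasm indices for insect rhabdoms.
#' * `wavelength_um = 0.5`: mid-visible (green) design wavelength.
#' * `absorption_per_um = 0.007`: natural absorption coefficient of the
#'   rhabdom, per micrometre.
#'
#' @param n_outside Refractive index of the object medium (air).
#' @param n_cornea Refractive index of the corneal lens.
#' @param n_cone Refractive index of the crystalline cone (image medium).
#' @param n_rhabdom Refractive index of the rhabdom core.
#' @param n_surround Refractive index of the cytoplasm around the rhabdom.
#' @param wavelength_um Design wavelength in micrometres.
#' @param absorption_per_um Rhabdom absorption coefficient in 1/um.
#' @return An object of class `optical_constants` (a named list).
#' @examples
#' optical_constants()
#' optical_constants(wavelength_um = 0.45)
#' @export
optical_constants <- function(n_outside = 1.000,
                              n_cornea = 1.452,
                              n_cone = 1.348,
                              n_rhabdom = 1.363,
                              n_surround = 1.339,
                              wavelength_um = 0.5,
                              absorption_per_um = 0.007) {
  c0 <- list(
    n_outside = n_outside, n_cornea = n_cornea, n_cone = n_cone,
    n_rhabdom = n_rhabdom, n_surround = n_surround,
    wavelength_um = wavelength_um, absorption_per_um = absorption_per_um
  )
  ok <- vapply(c0, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(ok)) {
    abort_validation(paste0(
      "optical constants must be finite scalars; offending: ",
      paste(names(c0)[!ok], collapse = ", ")
    ))
  }
  idx <- c("n_outside", "n_cornea", "n_cone", "n_rhabdom", "n_surround")
  if (any(unlist(c0[idx]) < 1)) {
    abort_validation("all refractive indices must be >= 1")
  }
  if (c0$n_rhabdom < c0$n_surround) {
    abort_domain("n_rhabdom must be >= n_surround (waveguiding precondition)")
  }
  if (c0$wavelength_um <= 0) abort_validation("wavelength_um must be > 0")
  if (c0$absorption_per_um < 0) abort_validation("absorption_per_um must be >= 0")
  structure(c0, class = "optical_constants")
}

#' @export
print.optical_constants <- function(x, ...) {
  cat("<optical_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read and write optical-constants configuration files
#'
#' Configuration files are YAML or JSON mappings with any subset of the keys
#' `n_outside`, `n_cornea`, `n_cone`, `n_rhabdom`, `n_surround`,
#' `wavelength_um`, `absorption_per_um`. Absent keys take the package
#' defaults (see [optical_constants()]). Write followed by read restores the
#' constants exactly.
#'
#' @param path File path; format chosen by extension (`.json` for JSON,
#'   anything else parsed as YAML).
#' @return `read_optical_constants()` returns an `optical_constants` object;
#'   `write_optical_constants()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_optical_constants(optical_constants(wavelength_um = 0.45), p)
#' read_optical_constants(p)
#' @export
read_optical_constants <- function(path) {
  if (!file.exists(path)) abort_parse(paste0("no such constants file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- names(formals(optical_constants))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warn(paste0("ignoring unknown constants keys: ", paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(optical_constants, lapply(raw, as.numeric))
}

#' @rdname read_optical_constants
#' @param constants An `optical_constants` object.
#' @export
write_optical_constants <- function(constants, path) {
  stopifnot(inherits(constants, "optical_constants"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(constants), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(constants), path)
  }
  invisible(path)
}
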
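#' Thick-lens surface powers of the corneal facet lens
#'
#' The biconvex corneal lens is modelled as a thick lens with two refracting
#' surfaces. The outer surface contributes `P1 = (n_cornea - n_outside) /
#' r_outer`, the inner surface `P2 = (n_cone - n_cornea) / (-r_inner)` with
#' both curvature radii entered positive as measured (the biconvex sign
#' convention is embedded internally), and the lens thickness contributes
#' the neutralizing term `P3 = -(t / n_cornea) * P1 * P2`. The total lens
#' power is `P_total = P1 + P2 + P3`. Powers are in 1/um when radii and
#' thickness are in um.
#'
#' @param r_outer Outer (distal) corneal radius of curvature, um. May also
#'   be an [eye_morphometry()] object, in which case `r_inner` and
#'   `thickness` are taken from it.
#' @param r_inner Inner (proximal) corneal radius of curvature, um, entered
#'   positive.
#' @param thickness Central corneal thickness, um. `thickness = 0` gives the
#'   thin-lens limit (`P3 = 0` exactly).
#' @param constants An [optical_constants()] object.
#' @return A tibble with columns `P1`, `P2`, `P3`, `P_total` (one row per
#'   input element).
#' @examples
#' lens_surface_powers(r_outer = 7.1, r_inner = 8.7, thickness = 5.7)
#' @export
lens_surface_powers <- function(r_outer, r_inner = NULL, thickness = NULL,
                                constants = optical_constants()) {
  if (inherits(r_outer, "eye_morphometry")) {
    morph <- r_outer
    r_outer <- morph_value(morph, "outer_lens_radius")
    r_inner <- morph_value(morph, "inner_lens_radius")
    thickness <- morph_value(morph, "corneal_thickness")
  }
  for (nm in c("r_outer", "r_inner", "thickness")) {
    v <- get(nm)
    if (is.null(v) || anyNA(v)) abort_missing_input(nm)
  }
  if (any(r_outer <= 0) || any(r_inner <= 0)) {
    abort_domain("curvature radii must be strictly positive")
  }
  if (any(thickness < 0)) abort_domain("corneal thickness must be >= 0")
  stopifnot(inherits(constants, "optical_constants"))
  P1 <- (constants$n_cornea - constants$n_outside) / r_outer
  P2 <- (constants$n_cone - constants$n_cornea) / (-r_inner)
  P3 <- -(thickness / constants$n_cornea) * P1 * P2
  tibble(P1 = P1, P2 = P2, P3 = P3, P_total = P1 + P2 + P3)
}

#' Focal lengths of the ommatidial lens
#'
#' The object-side focal length is `f = n_object / P_total` and the
#' image-side focal length `f' = n_image / P_total`, with the crystalline
#' cone as the image medium. Their ratio is exactly `n_image / n_object`.
#'
#' @param P_total Total lens power, 1/um (must be > 0; a diverging lens is
#'   not supported).
#' @param n_object Refractive index of the object medium.
#' @param n_image Refractive index of the image medium (crystalline cone).
#' @return Focal length in um.
#' @examples
#' focal_length(0.073)
#' image_focal_length(0.073, n_image = 1.348)
#' @export
focal_length <- function(P_total, n_object = 1.000) {
  if (anyNA(P_total)) abort_missing_input("P_total")
  if (any(P_total <= 0)) abort_domain("P_total must be > 0 (diverging lens unsupported)")
  n_object / P_total
}

#' @rdname focal_length
#' @export
image_focal_length <- function(P_total, n_image = 1.348) {
  if (anyNA(P_total)) abort_missing_input("P_total")
  if (any(P_total <= 0)) abort_domain("P_total must be > 0 (diverging lens unsupported)")
  n_image / P_total
}

#' F-number of an ommatidial facet
#'
#' Computed as `F = f / D`, the ratio of focal length to facet (aperture)
#' diameter. Note that published comparative tables occasionally use revised
#' species-specific formulations that are not always documented; [eye_summary()]
#' raises a classed warning to surface this.
#'
#' @param f Focal length, um.
#' @param D Facet diameter, um.
#' @return Dimensionless F-number.
#' @examples
#' f_number(6.2, 8.1)
#' @export
f_number <- function(f, D) {
  if (any(f <= 0) || any(D <= 0)) abort_domain("f and D must be > 0")
  f / D
}

#' Rhabdom acceptance angle
#'
#' Small-angle estimate `d / f` of the angular width of one rhabdom's
#' visual field, converted to degrees (ratio, not arctangent, matching
#' standard practice for these small angles).
#'
#' @param d Distal rhabdom diameter, um.
#' @param f Focal length, um.
#' @return Acceptance angle in degrees.
#' @examples
#' acceptance_angle(2.4, 13.7)
#' @export
acceptance_angle <- function(d, f) {
  if (any(d <= 0) || any(f <= 0)) abort_domain("d and f must be > 0")
  if (any(d >= f)) {
    warn("d >= f: outside the small-angle regime, the ratio estimate is crude",
      class = "ommatidia_warning_small_angle"
    )
  }
  (d / f) * 180 / pi
}

#' Airy disk half-width (diffraction blur)
#'
#' The diffraction-limited half-width of the blur circle, `lambda / D`,
#' converted to degrees. Strictly decreasing in facet diameter;
#' `airy_halfwidth(lambda, D) * D` is constant across `D`.
#'
#' @param wavelength Wavelength, um.
#' @param D Facet diameter, um.
#' @return Half-width in degrees.
#' @examples
#' airy_halfwidth(0.5, 11.8)
#' @export
airy_halfwidth <- function(wavelength, D) {
  if (any(wavelength <= 0) || any(D <= 0)) abort_domain("wavelength and D must be > 0")
  (wavelength / D) * 180 / pi
}

#' White-light optical sensitivity
#'
#' Photon-catch capacity of one ommatidium for extended white-light sources,
#' `S = (pi/4)^2 * D^2 * (d/f)^2 * k*l / (2.3 + k*l)`, in um^2/sr. The
#' absorption term saturates at 1 for a long or strongly absorbing rhabdom;
#' the constant 2.3 is ln(10), converting the decadic self-screening optical
#' density into natural units.
#'
#' @param D Facet diameter, um.
#' @param d Distal rhabdom diameter, um.
#' @param f Focal length, um.
#' @param k Rhabdom absorption coefficient, 1/um (>= 0).
#' @param l Rhabdom length, um (>= 0; `l = 0` gives zero sensitivity).
#' @return Sensitivity in um^2/sr.
#' @examples
#' optical_sensitivity(11.8, 2.4, 13.7, k = 0.007, l = 35.7)
#' @export
optical_sensitivity <- function(D, d, f, k, l) {
  if (any(D <= 0) || any(d <= 0) || any(f <= 0)) abort_domain("D, d and f must be > 0")
  if (any(k < 0)) abort_domain("k must be >= 0")
  if (any(l < 0)) abort_domain("l must be >= 0")
  kl <- k * l
  (pi / 4)^2 * D^2 * (d / f)^2 * kl / (2.3 + kl)
}

#' Ratio of optical sensitivities (printed precision)
#'
#' A convenience printed-precision ratio used for cross-species sensitivity
#' comparisons (and, more generally, any positive quantity such as facet
#' counts), reported to one decimal by half-away-from-zero rounding.
#'
#' @param s Sensitivity (or other positive quantity).
#' @param s_ref Reference value (> 0).
#' @return Ratio rounded to one decimal.
#' @examples
#' sensitivity_ratio(0.26, 0.1)
#' @export
sensitivity_ratio <- function(s, s_ref) {
  if (any(s_ref <= 0)) abort_domain("reference value must be > 0")
  round_half_away(s / s_ref, 1)
}

#' Waveguide V-parameter of the rhabdom
#'
#' Step-index waveguide number `V = (pi * d / lambda) * sqrt(n_rhabdom^2 -
#' n_surround^2)`; together with the mode cutoffs (see [mode_orders()]) it
#' determines how many guided light modes the rhabdom supports.
#'
#' @param d Rhabdom diameter, um (the distal diameter by default convention).
#' @param wavelength Wavelength, um.
#' @param n_rhabdom,n_surround Core and surround refractive indices
#'   (`n_rhabdom >= n_surround`).
#' @return Dimensionless V; zero iff the indices are equal.
#' @examples
#' waveguide_parameter(2.4, 0.5, 1.363, 1.339)
#' @export
waveguide_parameter <- function(d, wavelength, n_rhabdom = 1.363, n_surround = 1.339) {
  if (any(d <= 0) || any(wavelength <= 0)) abort_domain("d and wavelength must be > 0")
  if (any(n_rhabdom < n_surround)) {
    abort_domain("n_rhabdom must be >= n_surround (no guided modes otherwise)")
  }
  (pi * d / wavelength) * sqrt(n_rhabdom^2 - n_surround^2)
}

# first zeros of the Bessel functions J0, J1, J2, J3: cutoff V values above
# which successive mode orders become guided; the fundamental mode has no cutoff
mode_cutoffs <- c(2.405, 3.832, 5.136, 6.380)

#' Guided mode orders supported at a given V
#'
#' The fundamental mode is always guided; successive orders switch on at the
#' documented cutoff values `V = 2.405, 3.832, 5.136, 6.380` (first zeros of
#' the relevant Bessel functions). The cutoff table is capped at five orders.
#'
#' @param V Waveguide parameter (scalar, >= 0).
#' @return Integer vector of guided mode orders, `1:k`.
#' @examples
#' mode_orders(3.0)
#' mode_orders(3.84)
#' @export
mode_orders <- function(V) {
  stopifnot(length(V) == 1L, is.numeric(V))
  if (is.na(V) || V < 0) abort_domain("V must be >= 0")
  seq_len(1L + sum(V >= mode_cutoffs))
}

#' Geometric interommatidial angle
#'
#' Consistency estimate `D / R_eye` (in degrees) of the angle between
#' neighbouring ommatidial axes on a spherical eye of radius `R_eye`. It is
#' reported alongside, never in place of, a directly measured
#' interommatidial angle; the two can legitimately differ because facet
#' spacing and local eye curvature vary across the eye.
#'
#' @param D Facet diameter, um.
#' @param R_eye Eye radius of curvature, um (> D).
#' @return Angle in degrees.
#' @examples
#' geometric_interommatidial_angle(11.8, 90.4)
#' @export
geometric_interommatidial_angle <- function(D, R_eye) {
  if (any(D <= 0)) abort_domain("D must be > 0")
  if (any(R_eye <= D)) abort_domain("R_eye must exceed D")
  (D / R_eye) * 180 / pi
}

# Full-precision vectorized optical chain shared by eye_summary() and the
# Monte-Carlo propagation (so the zero-sd degeneracy is exact by construction).
# inputs: list/data.frame with r_outer, r_inner, thickness, D, d, l
compute_optics <- function(inputs, constants) {
  sp <- lens_surface_powers(inputs$r_outer, inputs$r_inner, inputs$thickness,
    constants = constants
  )
  f <- focal_length(sp$P_total, constants$n_outside)
  fi <- image_focal_length(sp$P_total, constants$n_cone)
  kl <- constants$absorption_per_um * inputs$l
  list(
    P1 = sp$P1, P2 = sp$P2, P3 = sp$P3, P_total = sp$P_total,
    f_um = f, f_image_um = fi,
    F_number = f / inputs$D,
    acceptance_angle_deg = (inputs$d / f) * 180 / pi,
    airy_halfwidth_deg = (constants$wavelength_um / inputs$D) * 180 / pi,
    sensitivity_um2_sr = (pi / 4)^2 * inputs$D^2 * (inputs$d / f)^2 * kl / (2.3 + kl),
    V = waveguide_parameter(
      inputs$d, constants$wavelength_um,
      constants$n_rhabdom, constants$n_surround
    )
  )
}

# Table-2-style display labels for summary parameters
optical_labels <- c(
  body_size_mm = "body size (mm)",
  P1 = "P1", P2 = "P2", P3 = "P3", P_total = "Pl",
  f_um = "f (um)", f_image_um = "f' (um)", F_number = "F-number",
  acceptance_angle_deg = "rho_rh (deg)", airy_halfwidth_deg = "rho_1 (deg)",
  sensitivity_um2_sr = "S_w (um^2/sr)",
  V = "V", n_modes = "guided mode orders",
  interommatidial_angle_geo_deg = "D/R (deg)"
)

#' Derived optical summary of one compound eye
#'
#' Composes the full optical chain — surface powers, total lens power, focal
#' lengths, F-number, acceptance angle, Airy half-width, white-light
#' sensitivity, waveguide V-parameter and guided modes, and (when an eye
#' radius is available) the geometric interommatidial angle — from the mean
#' morphometry of one species.
#'
#' Two reporting modes are available. `"full_precision"` carries the
#' unrounded chain throughout. `"printed_precision"` reproduces the chain as
#' conventionally printed in comparative tables: the total lens power is
#' rounded to three decimals *before* the focal lengths are derived from it,
#' the printed focal length then feeds the acceptance angle, F-number and
#' sensitivity, and every output is rounded to its report precision (powers
#' three decimals; lengths, angles and F-number one decimal; sensitivity two
#' decimals; half-away-from-zero rounding throughout). The chains differ
#' visibly: a total power of 0.0726 prints as 0.073 and yields a printed
#' focal length of 13.7 um, while the unrounded chain gives 13.77 um.
#'
#' The F-number is always computed as `f / D` and raises a classed warning
#' (`ommatidia_warning_f_number`), because published species tables sometimes
#' use undocumented revised formulations that `f / D` cannot reproduce.
#'
#' @param morph An [eye_morphometry()] object (or a measurement tibble, in
#'   which case `species` selects the record). Must contain the optical core
#'   fields `outer lens radius`, `inner lens radius`, `corneal thickness`,
#'   `facet diameter`, `rhabdom distal diameter`, `rhabdom length`.
#' @param constants An [optical_constants()] object.
#' @param mode `"printed_precision"` (default) or `"full_precision"`.
#' @param species Species selector when `morph` is a measurement tibble.
#' @return An object of class `eye_summary`; see [tidy()] for the tabular
#'   form (one row per parameter with Table-style labels).
#' @examples
#' m <- eye_morphometry(load_fixture("table1"))
#' s <- suppressWarnings(eye_summary(m))
#' tidy(s)
#' @export
eye_summary <- function(morph, constants = optical_constants(),
                        mode = c("printed_precision", "full_precision"),
                        species = NULL) {
  mode <- match.arg(mode)
  if (!inherits(morph, "eye_morphometry")) {
    morph <- eye_morphometry(morph, species = species)
  }
  inputs <- list(
    r_outer = morph_value(morph, "outer_lens_radius"),
    r_inner = morph_value(morph, "inner_lens_radius"),
    thickness = morph_value(morph, "corneal_thickness"),
    D = morph_value(morph, "facet_diameter"),
    d = morph_value(morph, "rhabdom_distal_diameter"),
    l = morph_value(morph, "rhabdom_length")
  )
  full <- compute_optics(inputs, constants)

  if (mode == "full_precision") {
    vals <- full
  } else {
    P_r <- round_half_away(full$P_total, 3)
    if (P_r <= 0) abort_domain("rounded total lens power is not positive")
    f_p <- round_half_away(focal_length(P_r, constants$n_outside), 1)
    fi_p <- round_half_away(image_focal_length(P_r, constants$n_cone), 1)
    kl <- constants$absorption_per_um * inputs$l
    vals <- list(
      P1 = round_half_away(full$P1, 3),
      P2 = round_half_away(full$P2, 3),
      P3 = round_half_away(full$P3, 3),
      P_total = P_r,
      f_um = f_p,
      f_image_um = fi_p,
      F_number = round_half_away(f_p / inputs$D, 1),
      acceptance_angle_deg = round_half_away((inputs$d / f_p) * 180 / pi, 1),
      airy_halfwidth_deg = round_half_away(full$airy_halfwidth_deg, 1),
      sensitivity_um2_sr = round_half_away(
        (pi / 4)^2 * inputs$D^2 * (inputs$d / f_p)^2 * kl / (2.3 + kl), 2
      ),
      V = round_half_away(full$V, 2)
    )
  }
  warn_f_number(full$f_um / inputs$D)

  modes <- mode_orders(min(full$V, mode_cutoffs[length(mode_cutoffs)]))
  R_eye <- tryCatch(morph_value(morph, "eye_radius"), error = function(e) NA_real_)
  dphi <- if (is.finite(R_eye)) {
    g <- geometric_interommatidial_angle(inputs$D, R_eye)
    if (mode == "printed_precision") round_half_away(g, 1) else g
  } else {
    NA_real_
  }

  structure(
    list(
      species = morph$species, mode = mode, values = vals,
      mode_orders = modes,
      interommatidial_angle_geo_deg = dphi,
      inputs = inputs, constants = constants
    ),
    class = "eye_summary"
  )
}

#' @export
print.eye_summary <- function(x, ...) {
  cat("<eye_summary> ", x$species, " [", x$mode, "]\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy an eye summary into one row per optical parameter
#'
#' @param x An `eye_summary` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` (stable code), `label`
#'   (display label), `value`, `species`, `mode`.
#' @exportS3Method generics::tidy
tidy.eye_summary <- function(x, ...) {
  keys <- names(x$values)
  out <- tibble(
    parameter = c(keys, "n_modes", "interommatidial_angle_geo_deg"),
    value = c(
      unlist(x$values, use.names = FALSE),
      length(x$mode_orders),
      x$interommatidial_angle_geo_deg
    )
  )
  out$label <- unname(optical_labels[out$parameter])
  out$species <- x$species
  out$mode <- x$mode
  out[, c("parameter", "label", "value", "species", "mode")]
}

#' One-row overview of an eye summary
#'
#' @param x An `eye_summary` object.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities.
#' @exportS3Method generics::glance
glance.eye_summary <- function(x, ...) {
  tibble(
    species = x$species, mode = x$mode,
    P_total = x$values$P_total, f_um = x$values$f_um,
    sensitivity_um2_sr = x$values$sensitivity_um2_sr,
    V = x$values$V, n_modes = length(x$mode_orders)
  )
}

#' Write an optical summary as a one-row-per-parameter CSV
#'
#' @param x An `eye_summary` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eye_summary <- function(x, path) {
  stopifnot(inherits(x, "eye_summary"))
  readr::write_csv(tidy(x), path)
  invisible(path)
}
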
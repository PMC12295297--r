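`%||%` <- function(x, y) if (is.null(x)) y else x

# shared fixtures built in code

fix_table1 <- function() load_fixture("table1")
fix_table2 <- function() load_fixture("table2")

fix_morph <- function() eye_morphometry(fix_table1())

# published optics without the focal species (for comparison building)
fix_published_others <- function() {
  dplyr::filter(fix_table2(), species != "Ceratosolen gravelyi")
}

# the demo gradient: measured envelope, anteroventral excess, posteroventral
# deficit, bilateral +12 asymmetry
fix_gradient <- function(seed = 1) {
  gradient_spec(
    base_diameter = 11.8, anteroventral_excess = 1.0,
    posteroventral_deficit = 1.5, noise_sd = 0.3,
    target_count = 247, asymmetry = 12, seed = seed,
    diameter_range = c(9.3, 13.7)
  )
}

# tiny synthetic two-species measurement table exercising reader edge paths
fix_small_table <- function() {
  tibble::tibble(
    species = c("sp A", "sp A", "sp B"),
    parameter = c("facet diameter", "rhabdom length", "facet diameter"),
    unit = c("um", "um", "um"),
    n = c(10L, 5L, 8L),
    mean = c(10, 30, 8),
    sd = c(0.5, 2, 0.4),
    min = c(9, 27, 7.2),
    max = c(11, 33, 8.8),
    known = c(TRUE, TRUE, TRUE)
  )
}

# geometry helpers for lattice checks: rebuild unit vectors from the
# azimuthal-equidistant coordinates and return the surface distance matrix
lattice_distances <- function(df, R_eye) {
  r <- sqrt(df$azimuth_deg^2 + df$elevation_deg^2) * pi / 180
  ph <- atan2(df$elevation_deg, df$azimuth_deg)
  P <- cbind(sin(r) * cos(ph), sin(r) * sin(ph), cos(r))
  Dm <- acos(pmin(pmax(tcrossprod(P), -1), 1)) * R_eye
  diag(Dm) <- Inf
  Dm
}
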
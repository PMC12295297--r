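#' Specification of a synthetic facet-size gradient
#'
#' Describes the ommatidial lattice the generator should emulate: a
#' hexagonal-like packing of facets on a spherical eye cap whose facet
#' diameters follow a regional gradient — largest toward the anteroventral
#' pole, smallest toward the posteroventral pole — plus Gaussian noise, a
#' target per-eye facet count, and a deterministic bilateral count
#' asymmetry (right minus left), as observed in real ommatidial counts.
#'
#' @param base_diameter Baseline facet diameter, um.
#' @param anteroventral_excess Diameter excess at the anteroventral pole, um.
#' @param posteroventral_deficit Diameter deficit at the posteroventral
#'   pole, um.
#' @param noise_sd Gaussian diameter noise, um (>= 0).
#' @param target_count Target facet count for the left eye (>= 7).
#' @param asymmetry Right-minus-left facet count offset (integer).
#' @param seed Integer seed; mandatory so every lattice is reproducible.
#' @param diameter_range Optional length-2 numeric `[min, max]` envelope the
#'   generated diameters are clipped to; defaults to
#'   `base - deficit - 4*noise_sd` .. `base + excess + 4*noise_sd`.
#' @return An object of class `gradient_spec`.
#' @examples
#' gradient_spec(11.8, 1.0, 1.5, noise_sd = 0.3, target_count = 247,
#'               asymmetry = 12, seed = 1)
#' @export
gradient_spec <- function(base_diameter, anteroventral_excess = 0,
                          posteroventral_deficit = 0, noise_sd = 0,
                          target_count, asymmetry = 0L, seed,
                          diameter_range = NULL) {
  if (missing(seed) || is.null(seed)) {
    abort_validation("a seed is mandatory for lattice generation")
  }
  if (base_diameter <= 0) abort_validation("base_diameter must be > 0")
  if (target_count < 7) abort_validation("target_count must be >= 7")
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  if (anteroventral_excess < 0 || posteroventral_deficit < 0) {
    abort_validation("gradient excess/deficit must be >= 0")
  }
  if (is.null(diameter_range)) {
    diameter_range <- c(
      max(base_diameter - posteroventral_deficit - 4 * noise_sd, base_diameter * 0.05),
      base_diameter + anteroventral_excess + 4 * noise_sd
    )
  }
  stopifnot(length(diameter_range) == 2L, diameter_range[1] <= diameter_range[2])
  structure(
    list(
      base_diameter = base_diameter,
      anteroventral_excess = anteroventral_excess,
      posteroventral_deficit = posteroventral_deficit,
      noise_sd = noise_sd,
      target_count = as.integer(target_count),
      asymmetry = as.integer(asymmetry),
      seed = as.integer(seed),
      diameter_range = diameter_range
    ),
    class = "gradient_spec"
  )
}

#' Read a gradient specification from a YAML config
#'
#' Keys mirror the [gradient_spec()] arguments; `seed` is mandatory in
#' files (no silent clock seeding).
#'
#' @param path YAML file path.
#' @return A `gradient_spec` object.
#' @export
read_gradient_spec <- function(path) {
  if (!file.exists(path)) abort_parse(paste0("no such gradient config: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(gradient_spec))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warn(paste0("ignoring unknown gradient keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(gradient_spec, raw[intersect(names(raw), known)])
}

# golden angle, radians
golden_angle <- pi * (3 - sqrt(5))

# chord-based great-circle distance matrix between unit vectors (radians)
angular_dist <- function(P, Q = P) {
  cosd <- tcrossprod(P, Q)
  cosd[cosd > 1] <- 1
  cosd[cosd < -1] <- -1
  acos(cosd)
}

# place n points on a cap of half-angle theta_c (radians) by golden-angle
# spiral, then one local-repulsion relaxation pass: only pairs closer than
# the mean nearest-neighbour spacing push each other apart, which raises the
# minimum spacing (to ~0.93 of the mean) without disturbing the rest of the
# near-hexagonal packing
place_cap_points <- function(n, theta_c, phi0 = 0) {
  i <- seq_len(n) - 0.5
  z <- 1 - (i / n) * (1 - cos(theta_c))
  theta <- acos(pmin(pmax(z, -1), 1))
  phi <- (i * golden_angle + phi0) %% (2 * pi)
  P <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))

  D <- angular_dist(P)
  s0 <- mean(apply(D, 1L, min))
  disp <- matrix(0, n, 3L)
  close <- which(D < s0, arr.ind = TRUE)
  for (r in seq_len(nrow(close))) {
    i <- close[r, 1L]
    j <- close[r, 2L]
    disp[i, ] <- disp[i, ] + ((s0 - D[i, j]) / s0) * (P[i, ] - P[j, ])
  }
  Pn <- P + 0.6 * disp
  Pn <- Pn / sqrt(rowSums(Pn^2))
  th <- acos(pmin(pmax(Pn[, 3], -1), 1))
  over <- th > theta_c
  if (any(over)) {
    ph <- atan2(Pn[over, 2], Pn[over, 1])
    Pn[over, ] <- cbind(
      sin(theta_c) * cos(ph),
      sin(theta_c) * sin(ph),
      rep(cos(theta_c), sum(over))
    )
  }
  Pn
}

# deterministic region partition from cap-centred angular coordinates
facet_regions <- function(az, el, theta_c) {
  rho <- sqrt(az^2 + el^2)
  region <- dplyr::case_when(
    rho < 0.3 * theta_c ~ "central",
    rho > 0.9 * theta_c ~ "dorsal-rim",
    az > 0 & el < 0 ~ "anteroventral",
    az > 0 & el >= 0 ~ "anterodorsal",
    az <= 0 & el < 0 ~ "posteroventral",
    .default = "posterodorsal"
  )
  factor(region, levels = c(
    "anteroventral", "anterodorsal", "posteroventral", "posterodorsal",
    "central", "dorsal-rim"
  ))
}

#' Generate a synthetic ommatidial lattice on a spherical eye cap
#'
#' Places facets by a golden-angle spiral on a spherical cap (followed by
#' one local-repulsion relaxation pass), yielding a deterministic,
#' hexagonal-like packing, and assigns diameters by a bilinear regional
#' gradient: `base + excess * u - deficit * v`, where `u` and `v` are the
#' positive parts of the facet direction's normalized projections onto the
#' anteroventral and posteroventral cap directions, plus Gaussian noise.
#' Diameters are clipped to the spec's envelope and, where necessary, to
#' 1.05 x the facet's nearest-neighbour distance, which guarantees the
#' non-overlap invariant (no two facet centres closer than 0.95 x the mean
#' of their diameters along the eye surface).
#'
#' The left eye receives `target_count` facets and the right eye
#' `target_count + asymmetry`; the right eye's spiral is rotated by a
#' seed-derived phase so the two sides are independent packings of the same
#' statistical population. The cap half-angle is derived from the facet
#' count, base diameter and eye radius assuming hexagonal packing with a
#' spacing margin standing in for the interommatidial space (and is then
#' enlarged by a few percent if needed so baseline-sized facets never
#' trigger the overlap clip), unless given explicitly.
#'
#' @param spec A [gradient_spec()].
#' @param R_eye Eye radius of curvature, um.
#' @param cap_half_angle_deg Optional cap half-angle override, degrees.
#' @param sides Which eyes to generate (`"left"`, `"right"` or both).
#' @return An object of class `facet_lattice`: a tibble with columns
#'   `side`, `azimuth_deg` (anterior positive), `elevation_deg` (dorsal
#'   positive), `diameter_um`, `region`, with attributes `R_eye`,
#'   `cap_half_angle_deg` and `spec`.
#' @examples
#' spec <- gradient_spec(11.8, 1.0, 1.5, noise_sd = 0.3,
#'                       target_count = 247, asymmetry = 12, seed = 1)
#' lat <- generate_facet_lattice(spec, R_eye = 90.4)
#' dplyr::count(lat, side)
#' @export
generate_facet_lattice <- function(spec, R_eye,
                                   cap_half_angle_deg = NULL,
                                   sides = c("left", "right")) {
  stopifnot(inherits(spec, "gradient_spec"))
  if (R_eye <= 0) abort_domain("R_eye must be > 0")
  sides <- match.arg(sides, several.ok = TRUE)
  counts <- c(
    left = spec$target_count,
    right = spec$target_count + spec$asymmetry
  )[sides]
  if (any(counts < 7)) abort_validation("side facet count below 7; check asymmetry")

  # hexagonal-packing area demand with a 15% spacing margin (facet diameter
  # plus a clearance standing in for the interommatidial space)
  spacing <- 1.15 * spec$base_diameter
  area_per_facet <- (sqrt(3) / 2) * spacing^2
  theta_max <- 1.48 # ~85 deg: an eye cap never wraps past a hemisphere here
  user_cap <- !is.null(cap_half_angle_deg)
  if (!user_cap) {
    frac <- max(counts) * area_per_facet / (2 * pi * R_eye^2)
    if (frac > 1 - cos(theta_max)) {
      abort_domain("infeasible packing: facet area demand exceeds the eye surface")
    }
    theta_c <- acos(1 - frac)
  } else {
    theta_c <- cap_half_angle_deg * pi / 180
    if (max(counts) * area_per_facet > 2 * pi * R_eye^2 * (1 - cos(theta_c))) {
      abort_domain("infeasible packing: facet area demand exceeds the cap area")
    }
  }

  set.seed(spec$seed)
  phi0s <- c(left = 0, right = runif(1, 0, 2 * pi))[sides]

  # unless the cap was fixed by the caller, enlarge it (deterministically,
  # a few percent at most) until the minimum facet spacing clears 0.96 x the
  # base diameter, so the non-overlap clip stays inactive at baseline size
  if (!user_cap) {
    for (iter in 1:4) {
      dmin <- min(vapply(sides, function(side) {
        P <- place_cap_points(counts[[side]], theta_c, phi0 = phi0s[[side]])
        Dm <- angular_dist(P) * R_eye
        diag(Dm) <- Inf
        min(Dm)
      }, numeric(1)))
      target <- 0.96 * spec$base_diameter
      if (dmin >= target || theta_c >= theta_max) break
      theta_c <- min(theta_c * min(1.2, target / dmin), theta_max)
    }
  }

  out <- purrr::map(sides, function(side) {
    n <- counts[[side]]
    P <- place_cap_points(n, theta_c, phi0 = phi0s[[side]])
    theta <- acos(pmin(pmax(P[, 3], -1), 1))
    phi <- atan2(P[, 2], P[, 1])
    az <- theta * cos(phi)
    el <- theta * sin(phi)

    u <- pmax(0, (az - el) / (sqrt(2) * theta_c))
    v <- pmax(0, (-az - el) / (sqrt(2) * theta_c))
    d <- spec$base_diameter +
      spec$anteroventral_excess * u -
      spec$posteroventral_deficit * v +
      rnorm(n, 0, spec$noise_sd)
    d <- pmin(pmax(d, spec$diameter_range[1]), spec$diameter_range[2])

    # non-overlap guarantee: d_i <= 1.05 * nearest-neighbour distance implies
    # (d_i + d_j)/2 <= 1.05 * dist <= dist / 0.95 for every pair
    Dm <- angular_dist(P) * R_eye
    diag(Dm) <- Inf
    nnd <- apply(Dm, 1L, min)
    d <- pmin(d, 1.05 * nnd)

    tibble(
      side = side,
      azimuth_deg = az * 180 / pi,
      elevation_deg = el * 180 / pi,
      diameter_um = d,
      region = facet_regions(az, el, theta_c)
    )
  })
  out <- bind_rows(out)
  structure(out,
    class = c("facet_lattice", class(tibble())),
    R_eye = R_eye,
    cap_half_angle_deg = theta_c * 180 / pi,
    spec = spec
  )
}

#' Read and write facet lattices as CSV
#'
#' The interchange schema is `side, azimuth_deg, elevation_deg,
#' diameter_um, region`; externally produced facet maps in the same schema
#' can be read back for regional analysis.
#'
#' @param x A `facet_lattice` (or any tibble in the interchange schema).
#' @param path File path.
#' @param R_eye,cap_half_angle_deg Geometry attached on read (needed only
#'   for overlap checks, not for regional statistics).
#' @return `write_facet_lattice()` returns `path` invisibly;
#'   `read_facet_lattice()` returns a `facet_lattice` tibble.
#' @export
write_facet_lattice <- function(x, path) {
  cols <- c("side", "azimuth_deg", "elevation_deg", "diameter_um", "region")
  stopifnot(all(cols %in% names(x)))
  readr::write_csv(as_tibble(x)[, cols], path)
  invisible(path)
}

#' @rdname write_facet_lattice
#' @export
read_facet_lattice <- function(path, R_eye = NA_real_, cap_half_angle_deg = NA_real_) {
  out <- readr::read_csv(path,
    col_types = readr::cols(
      side = readr::col_character(),
      azimuth_deg = readr::col_double(),
      elevation_deg = readr::col_double(),
      diameter_um = readr::col_double(),
      region = readr::col_character()
    ), progress = FALSE
  )
  structure(out,
    class = c("facet_lattice", class(tibble())),
    R_eye = R_eye, cap_half_angle_deg = cap_half_angle_deg, spec = NULL
  )
}

#' Per-region facet statistics
#'
#' Summarises facet diameters by eye side and region (n, mean, sample sd
#' with the n-1 denominator, min, max); empty regions are reported with
#' `n = 0` and missing moments. The regions with the largest and smallest
#' pooled mean diameter are identified — on a lattice generated with an
#' anteroventral-excess / posteroventral-deficit gradient these recover the
#' injected pattern.
#'
#' @param lattice A `facet_lattice`.
#' @return An object of class `facet_region_stats`: a tibble `side,
#'   region, n, mean, sd, min, max` with attributes `argmax_region`,
#'   `argmin_region` (pooled over sides) and `counts` (facets per side).
#' @examples
#' spec <- gradient_spec(11.8, 1.0, 1.5, noise_sd = 0.3,
#'                       target_count = 247, asymmetry = 12, seed = 1)
#' st <- facet_region_stats(generate_facet_lattice(spec, R_eye = 90.4))
#' attr(st, "argmax_region")
#' @export
facet_region_stats <- function(lattice) {
  if (nrow(lattice) == 0L) abort_validation("empty lattice")
  x <- as_tibble(lattice)
  x$region <- factor(as.character(x$region), levels = levels(facet_regions(0, 0, 1)))
  grid <- tidyr::expand_grid(
    side = unique(x$side),
    region = levels(x$region)
  )
  st <- x |>
    mutate(region = as.character(.data$region)) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$diameter_um),
      sd = ifelse(dplyr::n() > 1L, sd(.data$diameter_um), 0),
      min = min(.data$diameter_um),
      max = max(.data$diameter_um),
      .by = c("side", "region")
    )
  st <- grid |>
    left_join(st, by = c("side", "region")) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))

  pooled <- x |>
    mutate(region = as.character(.data$region)) |>
    summarise(mean = mean(.data$diameter_um), .by = "region")
  counts <- x |> summarise(n = dplyr::n(), .by = "side")
  structure(st,
    class = c("facet_region_stats", class(tibble())),
    argmax_region = pooled$region[which.max(pooled$mean)],
    argmin_region = pooled$region[which.min(pooled$mean)],
    counts = setNames(counts$n, counts$side)
  )
}

#' One-row overview of regional facet statistics
#'
#' @param x A `facet_region_stats` object.
#' @param ... Unused.
#' @return A one-row tibble with total and per-side counts and the
#'   largest-/smallest-facet regions.
#' @exportS3Method generics::glance
glance.facet_region_stats <- function(x, ...) {
  counts <- attr(x, "counts")
  tibble(
    total_facets = sum(counts),
    left = counts[["left"]] %||% NA_integer_,
    right = counts[["right"]] %||% NA_integer_,
    argmax_region = attr(x, "argmax_region"),
    argmin_region = attr(x, "argmin_region")
  )
}

#' Map of a synthetic facet lattice
#'
#' @param object A `facet_lattice`.
#' @param colour `"diameter"` (default) or `"region"`.
#' @param ... Unused.
#' @return A ggplot object (azimuth-elevation map, one panel per side).
#' @exportS3Method ggplot2::autoplot
autoplot.facet_lattice <- function(object, colour = c("diameter", "region"), ...) {
  colour <- match.arg(colour)
  x <- as_tibble(object)
  p <- ggplot2::ggplot(x, ggplot2::aes(.data$azimuth_deg, .data$elevation_deg)) +
    ggplot2::facet_wrap(~side) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "azimuth (deg, anterior +)", y = "elevation (deg, dorsal +)",
      title = "Synthetic ommatidial lattice"
    ) +
    ggplot2::theme_minimal()
  if (colour == "diameter") {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$diameter_um, size = .data$diameter_um)) +
      ggplot2::scale_size_continuous(range = c(0.5, 2.5), guide = "none") +
      ggplot2::labs(colour = "diameter (um)")
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$region), size = 1.2) +
      ggplot2::labs(colour = "region")
  }
}
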
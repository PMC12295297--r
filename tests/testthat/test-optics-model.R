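test_that("surface powers reproduce the published three-decimal values", {
  sp <- lens_surface_powers(r_outer = 7.1, r_inner = 8.7, thickness = 5.7)
  expect_equal(round_half_away(sp$P1, 3), 0.064)
  expect_equal(round_half_away(sp$P2, 3), 0.012)
  expect_equal(round_half_away(sp$P3, 3), -0.003)
  expect_equal(round_half_away(sp$P_total, 3), 0.073)
  # the total is the sum of the parts to machine precision
  expect_equal(sp$P_total, sp$P1 + sp$P2 + sp$P3, tolerance = 1e-15)
  expect_lte(sp$P3, 0)
})

test_that("surface powers honour the thin-lens and index-matched limits", {
  thin <- lens_surface_powers(7.1, 8.7, thickness = 0)
  expect_identical(thin$P3, 0)
  expect_equal(thin$P_total, thin$P1 + thin$P2)
  # |P3| grows monotonically with thickness
  t_grid <- seq(0, 8, by = 0.5)
  p3 <- lens_surface_powers(7.1, 8.7, thickness = t_grid)$P3
  expect_true(all(diff(abs(p3)) > 0))
  matched <- lens_surface_powers(7.1, 8.7, 5.7,
    constants = optical_constants(n_cornea = 1, n_cone = 1, n_outside = 1)
  )
  expect_equal(unlist(matched), c(P1 = 0, P2 = 0, P3 = 0, P_total = 0))
  expect_error(focal_length(matched$P_total), class = "ommatidia_error_domain")
})

test_that("surface powers reject bad geometry and name missing fields", {
  expect_error(lens_surface_powers(-7.1, 8.7, 5.7), class = "ommatidia_error_domain")
  expect_error(lens_surface_powers(7.1, 0, 5.7), class = "ommatidia_error_domain")
  err <- expect_error(
    lens_surface_powers(7.1, NULL, 5.7),
    class = "ommatidia_error_missing_input"
  )
  expect_match(conditionMessage(err), "r_inner")
  # missing morphometric field is named when computing from a partial record
  partial <- fix_table1() |> dplyr::filter(parameter != "rhabdom length")
  err <- expect_error(
    suppressWarnings(eye_summary(eye_morphometry(partial))),
    class = "ommatidia_error_missing_input"
  )
  expect_match(conditionMessage(err), "rhabdom_length")
})

test_that("focal lengths follow f = n/P with exact f'/f index ratio", {
  expect_equal(round_half_away(focal_length(0.073), 1), 13.7)
  expect_equal(round_half_away(focal_length(0.161), 1), 6.2)
  expect_equal(focal_length(1.0, 1.0), 1.0)
  expect_equal(round_half_away(image_focal_length(0.073, 1.348), 1), 18.5)
  expect_equal(image_focal_length(0.073, 1.000), focal_length(0.073))
  expect_equal(round_half_away(image_focal_length(0.112, 1.34), 2), 11.96)
  # property: f'/f = n_image/n_object exactly, over random optics
  set.seed(11)
  for (i in 1:50) {
    P <- runif(1, 0.01, 0.5)
    no <- runif(1, 1, 1.4)
    ni <- runif(1, 1, 1.6)
    expect_equal(
      image_focal_length(P, ni) / focal_length(P, no),
      ni / no,
      tolerance = 1e-12
    )
  }
  expect_error(focal_length(0), class = "ommatidia_error_domain")
  expect_error(focal_length(-0.1), class = "ommatidia_error_domain")
})

test_that("the F-number reproduces published values where f/D was used", {
  expect_equal(round_half_away(f_number(6.2, 8.1), 1), 0.8)
  expect_equal(round_half_away(f_number(8.9, 6.39), 1), 1.4)
  # ... but gives 1.16, not the published 1.1, for the focal species
  expect_equal(round_half_away(f_number(13.7, 11.8), 2), 1.16)
  expect_error(f_number(0, 8.1), class = "ommatidia_error_domain")
})

test_that("acceptance angle is the small-angle rhabdom/focal ratio in degrees", {
  expect_equal(round_half_away(acceptance_angle(2.4, 13.7), 1), 10.0)
  expect_equal(round_half_away(acceptance_angle(2.4, 6.2), 1), 22.2)
  # vanishes with the rhabdom diameter
  expect_lt(acceptance_angle(1e-9, 13.7), 1e-7)
  # invariant under joint scaling of d and f
  expect_equal(acceptance_angle(2.4, 13.7), acceptance_angle(24, 137))
  expect_warning(acceptance_angle(14, 13.7), class = "ommatidia_warning_small_angle")
  expect_error(acceptance_angle(-1, 13.7), class = "ommatidia_error_domain")
})

test_that("Airy half-width matches published blur circles and scales as 1/D", {
  expect_equal(round_half_away(airy_halfwidth(0.5, 11.8), 1), 2.4)
  expect_equal(round_half_away(airy_halfwidth(0.5, 8.1), 1), 3.5)
  expect_equal(round_half_away(airy_halfwidth(0.5, 6.39), 1), 4.5)
  # product with D is constant (= wavelength in degree-um units)
  D <- c(2, 5, 8.1, 11.8, 40)
  expect_equal(
    airy_halfwidth(0.5, D) * D,
    rep(0.5 * 180 / pi, length(D)),
    tolerance = 1e-12
  )
  expect_true(all(diff(airy_halfwidth(0.5, D)) < 0))
})

test_that("optical sensitivity matches the published value and its limits", {
  expect_equal(
    round_half_away(optical_sensitivity(11.8, 2.4, 13.7, k = 0.007, l = 35.7), 2),
    0.26
  )
  expect_identical(optical_sensitivity(11.8, 2.4, 13.7, k = 0.007, l = 0), 0)
  # saturation bound: absorption term -> 1 as k*l -> Inf
  cap <- (pi / 4)^2 * 11.8^2 * (2.4 / 13.7)^2
  expect_equal(optical_sensitivity(11.8, 2.4, 13.7, k = 1e9, l = 35.7), cap,
    tolerance = 1e-6
  )
  expect_lt(optical_sensitivity(11.8, 2.4, 13.7, k = 0.007, l = 35.7), cap)
  # strictly increasing in D, d and l
  set.seed(12)
  for (i in 1:25) {
    D <- runif(1, 4, 20)
    d <- runif(1, 0.5, 3)
    l <- runif(1, 5, 60)
    f <- runif(1, 5, 25)
    base <- optical_sensitivity(D, d, f, 0.007, l)
    expect_gt(optical_sensitivity(D * 1.1, d, f, 0.007, l), base)
    expect_gt(optical_sensitivity(D, d * 1.1, f, 0.007, l), base)
    expect_gt(optical_sensitivity(D, d, f, 0.007, l * 1.1), base)
  }
  expect_error(optical_sensitivity(0, 2.4, 13.7, 0.007, 35.7), class = "ommatidia_error_domain")
})

test_that("sensitivity ratios report at one-decimal printed precision", {
  expect_equal(sensitivity_ratio(0.26, 0.1), 2.6)
  expect_equal(sensitivity_ratio(0.37, 0.37), 1.0)
  expect_equal(sensitivity_ratio(0.26, 0.04), 6.5)
  # also serves count comparisons: focal species vs the smallest eye
  expect_equal(sensitivity_ratio(247, 29), 8.5)
  expect_error(sensitivity_ratio(0.26, 0), class = "ommatidia_error_domain")
})

test_that("waveguide V-parameter and mode orders follow the cutoff table", {
  expect_identical(waveguide_parameter(2.4, 0.5, 1.35, 1.35), 0)
  expect_equal(round_half_away(waveguide_parameter(2.4, 0.5, 1.363, 1.339), 2), 3.84)
  # linear in d
  expect_equal(
    waveguide_parameter(4.8, 0.5, 1.363, 1.339),
    2 * waveguide_parameter(2.4, 0.5, 1.363, 1.339)
  )
  expect_error(waveguide_parameter(2.4, 0.5, 1.3, 1.35), class = "ommatidia_error_domain")

  expect_identical(mode_orders(0), 1L)
  expect_identical(mode_orders(3.0), 1:2)
  expect_identical(mode_orders(3.84), 1:3)
  # boundary behaviour at each documented cutoff
  for (k in seq_along(c(2.405, 3.832, 5.136, 6.380))) {
    cut <- c(2.405, 3.832, 5.136, 6.380)[k]
    expect_identical(mode_orders(cut - 1e-9), seq_len(k))
    expect_identical(mode_orders(cut), seq_len(k + 1L))
  }
  expect_error(mode_orders(-0.1), class = "ommatidia_error_domain")
})

test_that("the geometric interommatidial angle is D/R in degrees", {
  expect_equal(round_half_away(geometric_interommatidial_angle(11.8, 90.4), 1), 7.5)
  expect_lt(geometric_interommatidial_angle(1e-9, 90.4), 1e-9)
  expect_equal(
    geometric_interommatidial_angle(11.8, 2 * 90.4),
    geometric_interommatidial_angle(11.8, 90.4) / 2
  )
  expect_error(geometric_interommatidial_angle(11.8, 10), class = "ommatidia_error_domain")
})

test_that("eye_summary printed mode reproduces the published optics column", {
  expect_warning(s <- eye_summary(fix_morph()), class = "ommatidia_warning_f_number")
  v <- s$values
  expect_equal(v$P1, 0.064)
  expect_equal(v$P2, 0.012)
  expect_equal(v$P3, -0.003)
  expect_equal(v$P_total, 0.073)
  expect_equal(v$f_um, 13.7)
  expect_equal(v$f_image_um, 18.5)
  expect_equal(v$acceptance_angle_deg, 10.0)
  expect_equal(v$airy_halfwidth_deg, 2.4)
  expect_equal(v$sensitivity_um2_sr, 0.26)
  expect_identical(s$mode_orders, 1:3)
  expect_equal(s$interommatidial_angle_geo_deg, 7.5)
})

test_that("eye_summary full precision equals an independent recomputation", {
  s <- suppressWarnings(eye_summary(fix_morph(), mode = "full_precision"))
  # independent single-expression oracle, written directly from the formulas
  n_c <- 1.452
  n_k <- 1.348
  P1 <- (n_c - 1) / 7.1
  P2 <- (n_k - n_c) / (-8.7)
  P3 <- -(5.7 / n_c) * P1 * P2
  P <- P1 + P2 + P3
  f <- 1 / P
  kl <- 0.007 * 35.7
  expect_equal(s$values$P_total, P, tolerance = 1e-12)
  expect_equal(s$values$f_um, f, tolerance = 1e-12)
  expect_equal(s$values$f_image_um, n_k / P, tolerance = 1e-12)
  expect_equal(s$values$acceptance_angle_deg, (2.4 / f) * 180 / pi, tolerance = 1e-12)
  expect_equal(s$values$airy_halfwidth_deg, (0.5 / 11.8) * 180 / pi, tolerance = 1e-12)
  expect_equal(
    s$values$sensitivity_um2_sr,
    (pi / 4)^2 * 11.8^2 * (2.4 / f)^2 * kl / (2.3 + kl),
    tolerance = 1e-12
  )
  expect_equal(
    s$values$V,
    (pi * 2.4 / 0.5) * sqrt(1.363^2 - 1.339^2),
    tolerance = 1e-12
  )
  # the two modes differ exactly where the printed-chain rounding bites
  expect_equal(round_half_away(s$values$f_um, 2), 13.77)
})

test_that("scaling all lengths scales powers and focal lengths inversely", {
  set.seed(13)
  for (i in 1:20) {
    scl <- runif(1, 0.2, 5)
    base <- lens_surface_powers(7.1, 8.7, 5.7)
    scaled <- lens_surface_powers(7.1 * scl, 8.7 * scl, 5.7 * scl)
    expect_equal(unlist(scaled), unlist(base) / scl, tolerance = 1e-12)
    expect_equal(
      focal_length(scaled$P_total),
      focal_length(base$P_total) * scl,
      tolerance = 1e-12
    )
  }
})

test_that("summaries tidy and glance into well-formed tibbles", {
  s <- suppressWarnings(eye_summary(fix_morph()))
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("P1", "f_um", "sensitivity_um2_sr", "n_modes") %in% td$parameter))
  expect_false(any(is.na(td$label)))
  g <- glance(s)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_modes, 3L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_eye_summary(s, p)
  back <- readr::read_csv(p, show_col_types = FALSE)
  expect_equal(back$value, td$value)
})
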
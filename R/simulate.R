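#' Summarise raw measurements as mean, sd, n, range
#'
#' The summary convention of morphometric tables: arithmetic mean, sample
#' standard deviation (n - 1 denominator), sample size, minimum and
#' maximum. A single value has an undefined sd, reported as 0 with
#' `sd_defined = FALSE`.
#'
#' @param values Numeric vector (length >= 1).
#' @param unit Unit symbol carried alongside (e.g. `"um"`, `"count"`).
#' @return A one-row tibble: `unit, n, mean, sd, min, max, sd_defined`.
#' @examples
#' summarize_measurements(c(248, 247, 228, 262, 263, 256), unit = "count")
#' @export
summarize_measurements <- function(values, unit = "um") {
  if (length(values) < 1L || anyNA(values)) {
    abort_validation("need at least one non-missing value")
  }
  n <- length(values)
  tibble(
    unit = unit, n = n, mean = mean(values),
    sd = if (n > 1L) sd(values) else 0,
    min = min(values), max = max(values),
    sd_defined = n > 1L
  )
}

# exact inverse-CDF sampling from a normal truncated at 0 (left); sd = 0
# degenerates to the mean; strictly positive means assumed
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(mean, n))
  }
  lo <- pnorm(0, mean, sd)
  x <- qnorm(runif(n, lo, 1), mean, sd)
  # runif can hit its lower endpoint; resample the (measure-zero) boundary
  while (any(x <= 0)) {
    i <- which(x <= 0)
    x[i] <- qnorm(runif(length(i), lo, 1), mean, sd)
  }
  x
}

#' Simulate a measurement table from per-field truth and spread
#'
#' Synthetic stand-in for a morphometric measurement campaign: for each row
#' of `truth`, draws `n` independent values from a normal distribution with
#' the row's `mean` (the truth) and `sd`, truncated at zero (lengths cannot
#' be negative), and summarises the draws back into the measurement-table
#' schema. Deterministic for a fixed seed.
#'
#' @param truth A measurement tibble (see [read_measurement_table()]); its
#'   `mean` column is the ground truth, `sd` the measurement spread and `n`
#'   the number of replicate measurements per field (missing sds are
#'   treated as 0).
#' @param seed Integer seed (mandatory).
#' @param species Species name for the simulated record; defaults to the
#'   input species.
#' @return A measurement tibble with simulated `mean`, `sd`, `min`, `max`.
#' @examples
#' sim <- simulate_measurement_table(load_fixture("table1"), seed = 7)
#' @export
simulate_measurement_table <- function(truth, seed, species = NULL) {
  stopifnot(all(measurement_schema %in% names(truth)))
  if (missing(seed) || is.null(seed)) abort_validation("a seed is mandatory")
  if (any(is.na(truth$n) | truth$n < 1L)) {
    abort_validation("every field needs n >= 1 replicate measurements")
  }
  set.seed(as.integer(seed))
  sims <- purrr::pmap(
    list(truth$n, truth$mean, dplyr::coalesce(truth$sd, 0)),
    function(n, m, s) {
      draws <- rtruncnorm0(n, m, s)
      summarize_measurements(draws)
    }
  ) |> bind_rows()
  out <- truth
  out$species <- species %||% truth$species
  out$mean <- sims$mean
  out$sd <- sims$sd
  out$min <- sims$min
  out$max <- sims$max
  out
}

# optical-core fields drawn by the Monte-Carlo propagation
propagation_fields <- c(
  r_outer = "outer lens radius",
  r_inner = "inner lens radius",
  thickness = "corneal thickness",
  D = "facet diameter",
  d = "rhabdom distal diameter",
  l = "rhabdom length"
)

#' Monte-Carlo uncertainty propagation through the optical model
#'
#' Propagates measurement uncertainty (the published mean +- sd of the six
#' optical-core morphometric fields) through the full-precision optical
#' chain. Input fields are drawn as independent zero-truncated normals (no
#' covariances are published); each draw is pushed through the same
#' vectorized chain that [eye_summary()] evaluates in full-precision mode,
#' so with all sds at zero the output collapses exactly to the
#' deterministic summary. Draws violating the model preconditions are
#' rejected and resampled; a rejection rate above 10% raises a warning.
#'
#' @param measurements A measurement tibble containing the optical core
#'   fields with means and sds.
#' @param constants An [optical_constants()] object.
#' @param n_draws Number of Monte-Carlo draws (>= 100).
#' @param seed Integer seed (mandatory).
#' @param species Species selector when the table holds several species.
#' @return An object of class `uncertainty_summary`: a tibble with one row
#'   per optical parameter (`parameter`, `label`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `deterministic` — the zero-uncertainty full-precision value),
#'   with attributes `n_draws`, `seed` and `rejection_rate`.
#' @examples
#' pu <- propagate_uncertainty(load_fixture("table1"), n_draws = 200, seed = 7)
#' pu
#' @export
propagate_uncertainty <- function(measurements, constants = optical_constants(),
                                  n_draws = 2000, seed, species = NULL) {
  if (missing(seed) || is.null(seed)) abort_validation("a seed is mandatory")
  if (n_draws < 100) abort_validation("n_draws must be >= 100")
  morph <- eye_morphometry(measurements, species = species)
  tab <- morph$table
  idx <- match(propagation_fields, tab$parameter)
  if (anyNA(idx)) {
    abort_missing_input(propagation_fields[is.na(idx)][1])
  }
  mu <- tab$mean[idx]
  sg <- dplyr::coalesce(tab$sd[idx], 0)
  names(mu) <- names(sg) <- names(propagation_fields)

  set.seed(as.integer(seed))
  draws <- lapply(names(propagation_fields), function(f) rtruncnorm0(n_draws, mu[[f]], sg[[f]]))
  names(draws) <- names(propagation_fields)

  # precondition screen (positivity is guaranteed by the truncation; the
  # rejection loop guards the remaining domain constraints)
  n_rejected <- 0L
  repeat {
    bad <- draws$r_outer <= 0 | draws$r_inner <= 0 | draws$thickness < 0 |
      draws$D <= 0 | draws$d <= 0 | draws$l < 0
    if (!any(bad)) break
    n_rejected <- n_rejected + sum(bad)
    for (f in names(draws)) {
      draws[[f]][bad] <- rtruncnorm0(sum(bad), mu[[f]], sg[[f]])
    }
  }
  rejection_rate <- n_rejected / (n_draws + n_rejected)
  if (rejection_rate > 0.10) {
    warn(sprintf(
      "%.1f%% of Monte-Carlo draws violated model preconditions and were resampled",
      100 * rejection_rate
    ), class = "ommatidia_warning_rejection")
  }

  sims <- compute_optics(draws, constants)
  point <- compute_optics(as.list(mu), constants)

  out <- purrr::imap(sims, function(v, key) {
    tibble(
      parameter = key,
      label = unname(optical_labels[key]),
      mean = mean(v), sd = sd(v),
      q2.5 = unname(quantile(v, 0.025, type = 7)),
      q97.5 = unname(quantile(v, 0.975, type = 7)),
      deterministic = point[[key]]
    )
  }) |> bind_rows()
  structure(out,
    class = c("uncertainty_summary", class(tibble())),
    species = morph$species, n_draws = n_draws, seed = as.integer(seed),
    rejection_rate = rejection_rate
  )
}

#' Plot Monte-Carlo uncertainty intervals per optical parameter
#'
#' @param object An `uncertainty_summary`.
#' @param ... Unused.
#' @return A ggplot object (free-scale panels; 95% intervals around the
#'   Monte-Carlo mean, deterministic value overlaid).
#' @exportS3Method ggplot2::autoplot
autoplot.uncertainty_summary <- function(object, ...) {
  x <- as_tibble(object)
  ggplot2::ggplot(x, ggplot2::aes(x = "", y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$deterministic),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "value",
      title = "Monte-Carlo propagation of morphometric uncertainty",
      subtitle = paste0(attr(object, "species"), ", ", attr(object, "n_draws"), " draws")
    ) +
    ggplot2::theme_minimal()
}
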
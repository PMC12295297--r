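# fixed row set and order of the comparison table (body size + ten optical rows)
comparison_parameters <- c(
  "body_size_mm", "P1", "P2", "P3", "P_total", "f_um", "f_image_um",
  "F_number", "acceptance_angle_deg", "airy_halfwidth_deg", "sensitivity_um2_sr"
)

#' Multi-species optical comparison table
#'
#' Assembles the eleven-parameter comparison table (body size, surface
#' powers P1/P2/P3, total power, focal lengths f and f', F-number,
#' acceptance angle, Airy half-width, sensitivity) across species. Species
#' with raw morphometry are *computed* through [eye_summary()] in the
#' requested mode; species with only published optics are *transcribed*
#' verbatim and never recomputed. Every cell carries a provenance flag, and
#' cells a source does not provide are explicitly missing (rendered as an
#' em dash), never silently blank.
#'
#' @param measurements A measurement tibble (see
#'   [read_measurement_table()]) for the species to compute, or `NULL`.
#' @param published A published-optics tibble (see
#'   [load_fixture()]`("table2")` for the schema) for the species to
#'   transcribe, or `NULL`.
#' @param constants An [optical_constants()] object.
#' @param mode Reporting mode passed to [eye_summary()].
#' @return An object of class `eye_comparison`: a long tibble with columns
#'   `parameter`, `label`, `species`, `value`, `value_min`, `value_max`,
#'   `provenance`, with the species order of the inputs (computed species
#'   first).
#' @examples
#' cmp <- suppressWarnings(build_comparison(
#'   measurements = load_fixture("table1"),
#'   published = dplyr::filter(
#'     load_fixture("table2"),
#'     species != "Ceratosolen gravelyi"
#'   )
#' ))
#' cmp
#' @export
build_comparison <- function(measurements = NULL, published = NULL,
                             constants = optical_constants(),
                             mode = c("printed_precision", "full_precision")) {
  mode <- match.arg(mode)
  computed_species <- if (is.null(measurements)) character() else unique(measurements$species)
  published_species <- if (is.null(published)) character() else unique(published$species)
  species_order <- c(computed_species, setdiff(published_species, computed_species))
  if (length(species_order) == 0L) {
    abort_validation("no species supplied: need measurements and/or published optics")
  }
  overlap <- intersect(computed_species, published_species)
  if (length(overlap)) {
    abort_validation(paste0(
      "species present in both inputs (use compare_computed_published() for that): ",
      paste(overlap, collapse = ", ")
    ))
  }

  rows <- list()
  for (sp in computed_species) {
    s <- eye_summary(measurements, constants = constants, mode = mode, species = sp)
    vals <- unlist(s$values)
    body <- tryCatch(
      morph_value(eye_morphometry(measurements, species = sp), "body_size_mm"),
      error = function(e) NA_real_
    )
    rows[[sp]] <- tibble(
      parameter = comparison_parameters,
      species = sp,
      value = unname(c(body, vals[comparison_parameters[-1]])),
      value_min = NA_real_, value_max = NA_real_,
      provenance = "computed"
    )
  }
  for (sp in setdiff(published_species, computed_species)) {
    pub <- filter(published, .data$species == sp)
    if (nrow(pub) == 0L || all(is.na(pub$value) & is.na(pub$value_min))) {
      abort_validation(paste0("species has neither morphometry nor published optics: ", sp))
    }
    pub_idx <- match(comparison_parameters, pub$parameter)
    rows[[sp]] <- tibble(
      parameter = comparison_parameters,
      species = sp,
      value = pub$value[pub_idx],
      value_min = if ("value_min" %in% names(pub)) pub$value_min[pub_idx] else NA_real_,
      value_max = if ("value_max" %in% names(pub)) pub$value_max[pub_idx] else NA_real_,
      provenance = "transcribed"
    )
  }

  out <- bind_rows(rows[species_order])
  out$label <- unname(optical_labels[out$parameter])
  out <- out[, c(
    "parameter", "label", "species", "value", "value_min", "value_max",
    "provenance"
  )]
  structure(out,
    class = c("eye_comparison", class(tibble())),
    species_order = species_order, mode = mode
  )
}

#' @export
print.eye_comparison <- function(x, ...) {
  cat("<eye_comparison> ", length(attr(x, "species_order")), " species [",
    attr(x, "mode"), "]\n",
    sep = ""
  )
  cat(format_comparison(x, format = "markdown"), sep = "\n")
  invisible(x)
}

# display string for one cell under the per-row precision policy
comparison_cell <- function(value, value_min, value_max, parameter) {
  digits <- unname(printed_digits[parameter])
  if (!is.na(value_min) && !is.na(value_max)) {
    return(paste0(
      fmt_fixed(value_min, 1), "-", fmt_fixed(value_max, 1)
    ))
  }
  fmt_fixed(value, digits)
}

#' Render a comparison table as CSV or Markdown
#'
#' Rendering is deterministic: identical inputs give byte-identical output.
#' Precisions mirror the published table (powers three decimals; lengths,
#' angles, F-number and body size one to two decimals; sensitivity two
#' decimals), with half-away-from-zero rounding; missing cells render as
#' an em dash; published ranges render as `min-max`.
#'
#' @param x An `eye_comparison` object.
#' @param format `"csv"` or `"markdown"`.
#' @return A character vector of output lines.
#' @export
format_comparison <- function(x, format = c("csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "eye_comparison"))
  species <- attr(x, "species_order")
  cells <- as_tibble(x) |>
    mutate(display = purrr::pmap_chr(
      list(.data$value, .data$value_min, .data$value_max, .data$parameter),
      comparison_cell
    )) |>
    select(all_of(c("parameter", "label", "species", "display"))) |>
    tidyr::pivot_wider(names_from = "species", values_from = "display")
  cells <- cells[match(comparison_parameters, cells$parameter), c("label", species)]
  names(cells)[1] <- "parameter"
  if (format == "csv") {
    header <- paste(names(cells), collapse = ",")
    body <- apply(as.matrix(cells), 1L, paste, collapse = ",")
    c(header, unname(body))
  } else {
    widths <- pmax(nchar(names(cells)), apply(nchar(as.matrix(cells)), 2L, max))
    pad <- function(v, w) formatC(v, width = w, flag = "-")
    line <- function(v) paste0("| ", paste(mapply(pad, v, widths), collapse = " | "), " |")
    c(
      line(names(cells)),
      paste0("|", paste(strrep("-", widths + 2), collapse = "|"), "|"),
      unname(apply(as.matrix(cells), 1L, line))
    )
  }
}

#' @rdname format_comparison
#' @param path Output file path.
#' @export
write_comparison <- function(x, path, format = c("csv", "markdown")) {
  lines <- format_comparison(x, format = match.arg(format))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Tidy a comparison table
#'
#' @param x An `eye_comparison` object.
#' @param ... Unused.
#' @return The underlying long tibble.
#' @exportS3Method generics::tidy
tidy.eye_comparison <- function(x, ...) {
  as_tibble(x)
}

#' Cross-species ratios of one comparison-table row
#'
#' Divides each species' value of `parameter` by a reference — either one of
#' the table's species or an external positive scalar (for example a
#' published honeybee sensitivity) — and reports the ratios at one-decimal
#' printed precision. Where a species holds a published range rather than a
#' point value (body size), its midpoint is used.
#'
#' @param x An `eye_comparison` object.
#' @param parameter One of the table's parameter codes, e.g.
#'   `"sensitivity_um2_sr"`.
#' @param reference A species name present in `x`, or a positive number.
#' @return A tibble with columns `species`, `value`, `ratio`.
#' @examples
#' cmp <- suppressWarnings(build_comparison(
#'   measurements = load_fixture("table1"),
#'   published = dplyr::filter(load_fixture("table2"), species != "Ceratosolen gravelyi")
#' ))
#' cross_species_ratios(cmp, "sensitivity_um2_sr", reference = 0.1)
#' @export
cross_species_ratios <- function(x, parameter, reference) {
  stopifnot(inherits(x, "eye_comparison"))
  if (!parameter %in% comparison_parameters) {
    abort_validation(paste0("unknown comparison parameter: ", parameter))
  }
  row <- filter(as_tibble(x), .data$parameter == !!parameter) |>
    mutate(value = ifelse(
      is.na(.data$value) & !is.na(.data$value_min),
      (.data$value_min + .data$value_max) / 2, .data$value
    ))
  if (is.character(reference)) {
    if (!reference %in% row$species) {
      abort_validation(paste0("reference species not in table: ", reference))
    }
    ref <- row$value[row$species == reference]
  } else {
    ref <- as.numeric(reference)
  }
  if (is.na(ref) || ref <= 0) abort_domain("reference value must be > 0")
  tibble(
    species = row$species,
    value = row$value,
    ratio = round_half_away(row$value / ref, 1)
  )
}

#' Compare a computed optical summary with a transcribed published column
#'
#' Cell-wise comparison, at each row's printed precision, of an
#' [eye_summary()] computed from raw morphometry against the published
#' optics for the same species. Used to verify that a reproduction matches
#' the published table and to surface exactly which rows differ (for
#' *C. gravelyi*, the F-number row, whose published value uses a revised
#' formulation that `f/D` does not reproduce).
#'
#' @param summary An `eye_summary` (printed-precision mode recommended).
#' @param published A published-optics tibble (see [load_fixture()]).
#' @param species Species name to compare against; defaults to the
#'   summary's species.
#' @return A tibble with columns `parameter`, `computed`, `published`,
#'   `agree`; rows the summary does not compute (body size) are dropped.
#' @export
compare_computed_published <- function(summary, published, species = NULL) {
  stopifnot(inherits(summary, "eye_summary"))
  species <- species %||% summary$species
  pub <- filter(published, .data$species == !!species)
  if (nrow(pub) == 0L) {
    abort_validation(paste0("no published optics for species: ", species))
  }
  vals <- unlist(summary$values)
  keys <- intersect(comparison_parameters, names(vals))
  pub_v <- pub$value[match(keys, pub$parameter)]
  comp_v <- unname(vals[keys])
  digits <- unname(printed_digits[keys])
  agree <- mapply(function(a, b, d) {
    !is.na(a) && !is.na(b) &&
      round_half_away(a, d) == round_half_away(b, d)
  }, comp_v, pub_v, digits)
  keep <- !is.na(pub_v)
  tibble(
    parameter = keys[keep], computed = comp_v[keep],
    published = pub_v[keep], agree = agree[keep]
  )
}

#' Plot a comparison-table row across species
#'
#' @param object An `eye_comparison` object.
#' @param parameter Parameter code to plot (default: sensitivity).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eye_comparison <- function(object, parameter = "sensitivity_um2_sr", ...) {
  row <- filter(as_tibble(object), .data$parameter == !!parameter)
  ggplot2::ggplot(
    row,
    ggplot2::aes(
      x = factor(.data$species, levels = attr(object, "species_order")),
      y = .data$value, fill = .data$provenance
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = unname(optical_labels[parameter]),
      title = "Cross-species optical comparison"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
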
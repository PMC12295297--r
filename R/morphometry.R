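#' Measurement-parameter vocabulary
#'
#' The interchange names accepted in measurement tables, with their expected
#' unit and the canonical field each maps to. Names follow the published
#' morphometric table's row labels (lower-cased); where a bare label is
#' reused across structural elements ("length", "distal diameter",
#' "number"), the label is prefixed with its element ("rhabdom length",
#' "cone length", "hair number", ...) so the flat `species, parameter`
#' schema stays unambiguous. Matching is case-insensitive; `"µm"` is
#' accepted as an alias of `"um"`. Lengths recorded in nm (microvillus
#' diameter, basal matrix thickness) are converted to um by
#' [eye_morphometry()]; the original unit is preserved in the table for
#' display.
#'
#' @return A tibble with columns `parameter`, `field`, `unit`, `kind`.
#' @examples
#' measurement_vocabulary()
#' @export
measurement_vocabulary <- function() {
  tibble::tribble(
    ~parameter, ~field, ~unit, ~kind,
    "eye height", "eye_height", "um", "length",
    "eye width", "eye_width", "um", "length",
    "facet number", "facet_number", "count", "count",
    "eye radius", "eye_radius", "um", "length",
    "facet diameter", "facet_diameter", "um", "length",
    "ommatidium length", "ommatidium_length", "um", "length",
    "interommatidial angle", "interommatidial_angle_deg", "deg", "angle",
    "outer lens radius", "outer_lens_radius", "um", "length",
    "inner lens radius", "inner_lens_radius", "um", "length",
    "corneal thickness", "corneal_thickness", "um", "length",
    "chitin layer number", "chitin_layer_count", "count", "count",
    "cone length", "cone_length", "um", "length",
    "cone distal diameter", "cone_distal_diameter", "um", "length",
    "ppc pigment granule diameter", "ppc_granule_diameter", "um", "length",
    "spc pigment granule diameter", "spc_granule_diameter", "um", "length",
    "retinular pigment granule diameter", "retinular_granule_diameter", "um", "length",
    "rhabdom length", "rhabdom_length", "um", "length",
    "rhabdom distal diameter", "rhabdom_distal_diameter", "um", "length",
    "rhabdom proximal diameter", "rhabdom_proximal_diameter", "um", "length",
    "microvillus diameter", "microvillus_diameter", "nm", "length",
    "hair number", "hair_count", "count", "count",
    "hair length", "hair_length", "um", "length",
    "hair basal diameter", "hair_basal_diameter", "um", "length",
    "basal matrix thickness", "basal_matrix_thickness", "nm", "length",
    "median ocellus diameter", "median_ocellus_diameter", "um", "length",
    "lateral ocellus diameter", "lateral_ocellus_diameter", "um", "length",
    "body size", "body_size_mm", "mm", "length"
  )
}

measurement_schema <- c("species", "parameter", "unit", "n", "mean", "sd", "min", "max")

normalize_unit <- function(u) {
  u <- trimws(tolower(u))
  u[u == "µm" | u == "μm"] <- "um"
  u[u == "degree" | u == "degrees" | u == "°"] <- "deg"
  u[u == "-" | u == ""] <- "count"
  u
}

#' Read and write per-species morphometric measurement tables
#'
#' Measurement tables are plain-text tables with the exact columns
#' `species, parameter, unit, n, mean, sd, min, max` (comma-delimited on
#' write; a tab-delimited dialect is also accepted on read). `parameter`
#' names come from [measurement_vocabulary()]; rows with unknown parameter
#' names are kept (they travel in the pass-through map of
#' [eye_morphometry()]) and reported in a single warning. Missing cells are
#' encoded as empty strings, never 0. Writing then reading a valid table
#' restores it exactly.
#'
#' Malformed numeric cells raise a parse error naming the file line;
#' duplicate `(species, parameter)` pairs, negative lengths/sds, `n < 1`,
#' and `min <= mean <= max` violations raise validation errors; a unit that
#' contradicts the vocabulary raises a validation error.
#'
#' @param path File path (`read_measurement_table()` also accepts a
#'   connection understood by readr).
#' @return A tibble with the schema columns (`parameter`/`unit`
#'   normalized) plus a logical `known` column flagging vocabulary
#'   membership.
#' @examples
#' tbl <- load_fixture("table1")
#' p <- tempfile(fileext = ".csv")
#' write_measurement_table(tbl, p)
#' identical(read_measurement_table(p), tbl)
#' @export
read_measurement_table <- function(path) {
  if (is.character(path) && !file.exists(path)) {
    abort_parse(paste0("no such measurement table: ", path))
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  if (!identical(names(raw), measurement_schema)) {
    abort_parse(paste0(
      "measurement table must have columns exactly: ",
      paste(measurement_schema, collapse = ","),
      " (got: ", paste(names(raw), collapse = ","), ")"
    ))
  }
  if (nrow(raw) == 0L) {
    out <- tibble(
      species = character(), parameter = character(), unit = character(),
      n = integer(), mean = double(), sd = double(),
      min = double(), max = double(), known = logical()
    )
    return(out)
  }

  num <- function(col) {
    x <- raw[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(v))
    if (length(bad)) {
      abort_parse(
        paste0(
          "malformed numeric value in column '", col, "' at file line ",
          bad[1] + 1L, ": '", x[bad[1]], "'"
        ),
        line = bad[1] + 1L
      )
    }
    v[x == ""] <- NA_real_
    v
  }

  out <- tibble(
    species = raw$species,
    parameter = trimws(tolower(raw$parameter)),
    unit = normalize_unit(raw$unit),
    n = {
      nv <- num("n")
      if (any(!is.na(nv) & (nv < 1 | nv != floor(nv)))) {
        abort_validation("column 'n' must contain positive integers")
      }
      as.integer(nv)
    },
    mean = num("mean"), sd = num("sd"), min = num("min"), max = num("max")
  )
  if (any(out$species == "")) abort_validation("empty species name")

  dup <- out |>
    summarise(n_rows = dplyr::n(), .by = c("species", "parameter")) |>
    filter(.data$n_rows > 1L)
  if (nrow(dup)) {
    abort_validation(paste0(
      "duplicate (species, parameter) rows: ",
      paste(dup$species, dup$parameter, sep = " / ", collapse = "; ")
    ))
  }

  voc <- measurement_vocabulary()
  out$known <- out$parameter %in% voc$parameter
  if (any(!out$known)) {
    warn(
      paste0(
        "unknown parameter names kept as pass-through: ",
        paste(unique(out$parameter[!out$known]), collapse = ", ")
      ),
      class = "ommatidia_warning_unknown_parameter"
    )
  }
  mism <- out |>
    left_join(voc, by = "parameter", suffix = c("", ".voc")) |>
    filter(.data$known, .data$unit != .data$unit.voc)
  if (nrow(mism)) {
    abort_validation(paste0(
      "unit disagrees with vocabulary for: ",
      paste(unique(paste0(mism$parameter, " (", mism$unit, " vs ", mism$unit.voc, ")")),
        collapse = "; "
      )
    ))
  }

  lengths_neg <- out |>
    left_join(voc, by = "parameter", suffix = c("", ".voc")) |>
    filter(.data$known, .data$kind == "length") |>
    filter(dplyr::if_any(all_of(c("mean", "sd", "min", "max")), ~ !is.na(.x) & .x < 0))
  if (nrow(lengths_neg)) {
    abort_validation(paste0(
      "negative length values for: ",
      paste(unique(lengths_neg$parameter), collapse = ", ")
    ))
  }
  if (any(!is.na(out$sd) & out$sd < 0)) abort_validation("sd must be >= 0")
  bad_order <- (!is.na(out$min) & !is.na(out$mean) & out$min > out$mean) |
    (!is.na(out$mean) & !is.na(out$max) & out$mean > out$max)
  if (any(bad_order)) {
    abort_validation(paste0(
      "min <= mean <= max violated for: ",
      paste(unique(out$parameter[bad_order]), collapse = ", ")
    ))
  }
  out
}

#' @rdname read_measurement_table
#' @param x A measurement tibble as returned by `read_measurement_table()`.
#' @export
write_measurement_table <- function(x, path) {
  stopifnot(all(measurement_schema %in% names(x)))
  readr::write_csv(x[, measurement_schema], path, na = "")
  invisible(path)
}

#' Packaged fixtures: published morphometric and optical tables
#'
#' `"table1"` is the morphometric table of the compound eye of female
#' *Ceratosolen gravelyi* (means, sds, sample sizes and ranges for every
#' measured structural element), returned as a measurement tibble. The
#' published ocellus row prints two means (median ocellus 35.0 um, lateral
#' 33.2 um) over one shared range and no per-type sd; the fixture stores
#' them as two parameters with the shared range and a missing sd.
#'
#' `"table2"` is the comparative optical table: published optical parameters
#' (surface powers, total power, focal lengths, F-number, acceptance angle,
#' Airy half-width, sensitivity, body size) for *C. gravelyi* and three
#' parasitoid wasps (*Megaphragma mymaripenne*, *Trichogramma evanescens*,
#' *Anaphes flavipes*), plus each species' published facet diameter, which
#' the optical table itself does not repeat. Ranges (the *T. evanescens*
#' body size) are carried in `value_min`/`value_max`.
#'
#' @param name `"table1"` or `"table2"`.
#' @return A tibble (see Details for each fixture's schema).
#' @examples
#' load_fixture("table1")
#' load_fixture("table2")
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  if (!is.character(name) || length(name) != 1L || !name %in% c("table1", "table2")) {
    abort_validation("unknown fixture name; use \"table1\" or \"table2\"")
  }
  if (name == "table1") {
    read_measurement_table(
      system.file("extdata", "table1_cgravelyi.csv", package = "ommatidia", mustWork = TRUE)
    )
  } else {
    readr::read_csv(
      system.file("extdata", "table2_comparative.csv", package = "ommatidia", mustWork = TRUE),
      col_types = readr::cols(
        species = readr::col_character(),
        parameter = readr::col_character(),
        unit = readr::col_character(),
        value = readr::col_double(),
        value_min = readr::col_double(),
        value_max = readr::col_double()
      ),
      na = "", progress = FALSE
    )
  }
}

#' Typed per-species morphometry
#'
#' Extracts one species' record from a measurement table, maps known
#' parameters to canonical fields, converts nm-recorded lengths to um, and
#' validates the record's invariants (positive lengths, `min <= mean <=
#' max`, proximal rhabdom diameter not exceeding the distal one). Unknown
#' parameters are preserved in the `extra` pass-through table.
#'
#' @param measurements A measurement tibble (see
#'   [read_measurement_table()]).
#' @param species Species to extract; may be omitted when the table holds a
#'   single species.
#' @return An object of class `eye_morphometry` with elements `species`,
#'   `values` (named vector of field means, um/deg/count), `table` (the
#'   species' rows), and `extra` (pass-through rows).
#' @examples
#' eye_morphometry(load_fixture("table1"))
#' @export
eye_morphometry <- function(measurements, species = NULL) {
  stopifnot(all(measurement_schema %in% names(measurements)))
  if (is.null(species)) {
    sp <- unique(measurements$species)
    if (length(sp) != 1L) {
      abort_validation("measurement table holds several species; supply `species`")
    }
    species <- sp
  }
  rows <- filter(measurements, .data$species == !!species)
  if (nrow(rows) == 0L) {
    abort(paste0("species not present in measurement table: ", species),
      class = "ommatidia_error_missing_species"
    )
  }
  voc <- measurement_vocabulary()
  known <- rows |> filter(.data$parameter %in% voc$parameter)
  extra <- rows |> filter(!.data$parameter %in% voc$parameter)

  joined <- known |> left_join(voc, by = "parameter", suffix = c("", ".voc"))
  scale <- ifelse(joined$unit.voc == "nm", 1e-3, 1)
  values <- setNames(joined$mean * scale, joined$field)

  pos <- joined$kind == "length" & !is.na(joined$mean)
  if (any(pos & joined$mean <= 0)) {
    abort_validation(paste0(
      "non-positive length for: ",
      paste(joined$parameter[pos & joined$mean <= 0], collapse = ", ")
    ))
  }
  if (all(c("rhabdom_proximal_diameter", "rhabdom_distal_diameter") %in% names(values)) &&
    isTRUE(values[["rhabdom_proximal_diameter"]] > values[["rhabdom_distal_diameter"]])) {
    abort_validation("rhabdom proximal diameter exceeds distal diameter")
  }

  structure(
    list(species = species, values = values, table = rows, extra = extra),
    class = "eye_morphometry"
  )
}

#' @export
print.eye_morphometry <- function(x, ...) {
  cat("<eye_morphometry> ", x$species, ": ", length(x$values), " fields",
    if (nrow(x$extra)) paste0(" (+", nrow(x$extra), " pass-through)") else "",
    "\n",
    sep = ""
  )
  print(x$table, n = Inf)
  invisible(x)
}

# mean value of a canonical field, or a missing-input error naming it
morph_value <- function(morph, field) {
  stopifnot(inherits(morph, "eye_morphometry"))
  if (!field %in% names(morph$values) || is.na(morph$values[[field]])) {
    abort_missing_input(field)
  }
  unname(morph$values[[field]])
}
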
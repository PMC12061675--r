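require_columns <- function(data, cols, what, call = rlang::caller_env()) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(
      paste0("`", what, "` is missing required column(s): ",
             paste(missing, collapse = ", "), "."),
      class = "stemseason_schema_error", call = call
    )
  }
  invisible(TRUE)
}

read_validated_csv <- function(path, numeric_cols, character_cols = NULL,
                               what = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "stemseason_io_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(tbl, c(numeric_cols, character_cols), what)
  for (col in numeric_cols) {
    v <- tbl[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad) > 0) {
        abort(
          paste0("Non-numeric value in column `", col, "` of ", what,
                 " (first at row ", bad[1], ")."),
          class = "stemseason_parse_error"
        )
      }
      tbl[[col]] <- parsed
    }
  }
  tbl
}

#' Read the four trial input tables
#'
#' CSV readers with schema validation (RFC-4180, UTF-8, "." decimal).
#' Required columns are checked by name; unknown columns are preserved
#' but ignored by the pipeline. A missing column or a non-numeric value
#' in a numeric column is an error naming the column (and row).
#'
#' * `read_stem_series()`: `plant_id`, `year`, `length_cm`, and `day`
#'   (day of year, 1-based) or `thermal_cd`.
#' * `read_weather()`: `day`, `tmax_c`, `tmin_c`.
#' * `read_metadata()`: `plant_id`, `genotype`, `block`, `species_group`
#'   (optionally `lat`, `lon`, `alt_m`).
#' * `read_harvest()`: `plant_id`, `year`, `wet_g`, `sub_wet_g`,
#'   `sub_dry_g`.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_stem_series <- function(path) {
  tbl <- read_validated_csv(path, numeric_cols = c("year", "length_cm"),
                            character_cols = "plant_id")
  if (!any(c("day", "thermal_cd") %in% names(tbl))) {
    abort("Stem series needs a `day` or `thermal_cd` column.",
          class = "stemseason_schema_error")
  }
  for (col in intersect(c("day", "thermal_cd"), names(tbl))) {
    if (!is.numeric(tbl[[col]])) {
      tbl[[col]] <- as.numeric(tbl[[col]])
    }
  }
  tbl
}

#' @rdname read_tables
#' @export
read_weather <- function(path) {
  read_validated_csv(path, numeric_cols = c("day", "tmax_c", "tmin_c"))
}

#' @rdname read_tables
#' @export
read_metadata <- function(path) {
  read_validated_csv(path, numeric_cols = "block",
                     character_cols = c("plant_id", "genotype",
                                        "species_group"))
}

#' @rdname read_tables
#' @export
read_harvest <- function(path) {
  read_validated_csv(
    path,
    numeric_cols = c("year", "wet_g", "sub_wet_g", "sub_dry_g"),
    character_cols = "plant_id"
  )
}

#' Write pipeline tables to CSV
#'
#' Thin wrappers over [readr::write_csv()]; `write_traits()` applies the
#' reporting convention of rounding `day_max_gr` to the nearest day when
#' the explanatory variable is the day of year (full precision is kept in
#' memory for analysis).
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @param domain `"julian_day"` or `"thermal_time"`; controls the
#'   `day_max_gr` rounding convention.
#' @return `x`, invisibly.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_traits <- function(x, path, domain = c("julian_day",
                                             "thermal_time")) {
  domain <- match.arg(domain)
  out <- x
  if (domain == "julian_day" && "day_max_gr" %in% names(out)) {
    out$day_max_gr <- round(out$day_max_gr)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(x)
}

#' @rdname write_tables
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}
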
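#' Column mapping for long-format assemblage time-series tables
#'
#' Defaults follow the public BioTIME export layout. Any long-format CSV with
#' one row per (assemblage, year, sampling occasion, species) count can be read
#' by remapping the names.
#'
#' @param assemblage_id,year,sample_id,species_id,abundance Column names in the
#'   source file for, respectively: the assemblage (study/site) identifier, the
#'   calendar year, the within-year sampling-occasion identifier, the species
#'   identifier, and the abundance count.
#' @return A named list of column names.
#' @examples
#' biotime_schema()
#' biotime_schema(assemblage_id = "site", abundance = "count")
#' @export
biotime_schema <- function(assemblage_id = "STUDY_ID",
                           year = "YEAR",
                           sample_id = "SAMPLE_DESC",
                           species_id = "GENUS_SPECIES",
                           abundance = "sum.allrawdata.ABUNDANCE") {
  list(assemblage_id = assemblage_id, year = year, sample_id = sample_id,
       species_id = species_id, abundance = abundance)
}

#' Read a long-format assemblage time-series CSV
#'
#' Reads one row per (assemblage, year, sampling occasion, species) abundance
#' count and returns a tidy records table. Ingestion rules:
#' * rows with abundance <= 0 are dropped with a warning (zeroes are implicit
#'   absences and must not appear as explicit rows);
#' * positive non-integer abundances are floored with a warning (some sources
#'   store summed counts as numeric);
#' * duplicated (assemblage, year, sample, species) rows are summed, with a
#'   message giving the number collapsed.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Column mapping, see [biotime_schema()].
#' @return A tibble with columns `assemblage_id`, `year`, `sample_id`,
#'   `species_id`, `abundance` (positive integer-valued).
#' @seealso [write_assemblage_csv()], [validate_series()]
#' @export
read_assemblage_csv <- function(path, schema = biotime_schema()) {
  if (!file.exists(path)) {
    stop("input error: file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    stop("input error: '", path, "' contains no data rows", call. = FALSE)
  }
  missing <- setdiff(unname(unlist(schema)), names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::tibble(
    assemblage_id = as.character(raw[[schema$assemblage_id]]),
    year          = raw[[schema$year]],
    sample_id     = as.character(raw[[schema$sample_id]]),
    species_id    = as.character(raw[[schema$species_id]]),
    abundance     = raw[[schema$abundance]]
  )
  as_assemblage_records(df)
}

#' Coerce a data frame of abundance rows to a clean records table
#'
#' Applies the same ingestion rules as [read_assemblage_csv()] to an in-memory
#' data frame already using the canonical column names.
#'
#' @param df Data frame with columns `assemblage_id`, `year`, `sample_id`,
#'   `species_id`, `abundance`.
#' @return A tibble of cleaned records.
#' @export
as_assemblage_records <- function(df) {
  need <- c("assemblage_id", "year", "sample_id", "species_id", "abundance")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ab <- suppressWarnings(as.numeric(df$abundance))
  if (anyNA(ab)) {
    stop("input error: abundance column is not numeric (",
         sum(is.na(ab)), " unparseable values)", call. = FALSE)
  }
  yr <- suppressWarnings(as.integer(df$year))
  if (anyNA(yr)) {
    stop("input error: year column is not integer-valued", call. = FALSE)
  }
  df <- tibble::tibble(
    assemblage_id = as.character(df$assemblage_id),
    year = yr,
    sample_id = as.character(df$sample_id),
    species_id = as.character(df$species_id),
    abundance = ab
  )
  n_nonpos <- sum(df$abundance <= 0)
  if (n_nonpos > 0) {
    warning(n_nonpos, " row(s) with abundance <= 0 dropped (implicit absences)",
            call. = FALSE)
    df <- df[df$abundance > 0, ]
  }
  if (nrow(df) == 0) {
    stop("input error: no rows with positive abundance remain", call. = FALSE)
  }
  nonint <- df$abundance != floor(df$abundance)
  if (any(nonint)) {
    warning(sum(nonint), " non-integer abundance value(s) floored to counts",
            call. = FALSE)
    df$abundance <- floor(df$abundance)
    dropped <- df$abundance < 1
    if (any(dropped)) {
      warning(sum(dropped), " row(s) floored to zero dropped", call. = FALSE)
      df <- df[!dropped, ]
    }
  }
  n_before <- nrow(df)
  df <- df |>
    dplyr::group_by(.data$assemblage_id, .data$year, .data$sample_id,
                    .data$species_id) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
  if (nrow(df) < n_before) {
    message(n_before - nrow(df),
            " duplicated (assemblage, year, sample, species) row(s) summed")
  }
  dplyr::arrange(df, .data$assemblage_id, .data$year, .data$sample_id,
                 .data$species_id)
}

#' Write a records table back to CSV
#'
#' @param x Records tibble as returned by [read_assemblage_csv()].
#' @param path Output file path.
#' @param schema Column mapping used to name the output columns.
#' @return `path`, invisibly.
#' @export
write_assemblage_csv <- function(x, path, schema = biotime_schema()) {
  out <- stats::setNames(
    x[, c("assemblage_id", "year", "sample_id", "species_id", "abundance")],
    unlist(schema)[c("assemblage_id", "year", "sample_id", "species_id",
                     "abundance")]
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Number of distinct sampling occasions per assemblage-year
#'
#' @param x Records tibble.
#' @return A tibble with columns `assemblage_id`, `year`, `n_samples`.
#' @export
sampling_effort <- function(x) {
  x |>
    dplyr::distinct(.data$assemblage_id, .data$year, .data$sample_id) |>
    dplyr::count(.data$assemblage_id, .data$year, name = "n_samples")
}

#' Check that each assemblage series has enough years for trend fitting
#'
#' @param x Records tibble.
#' @param min_years Minimum number of distinct years required (default 10,
#'   matching the usual inclusion rule for assemblage trend analyses; trend
#'   fitting itself needs at least 2).
#' @return A tibble with one row per assemblage: `assemblage_id`, `n_years`,
#'   `n_records`, `pass` (logical), `reason` (`NA` when passing).
#' @examples
#' rec <- tibble::tibble(
#'   assemblage_id = "A", year = 2000:2011, sample_id = "s1",
#'   species_id = "sp1", abundance = 1
#' )
#' validate_series(rec, min_years = 10)
#' @export
validate_series <- function(x, min_years = 10) {
  x |>
    dplyr::group_by(.data$assemblage_id) |>
    dplyr::summarise(
      n_years = dplyr::n_distinct(.data$year),
      n_records = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pass = .data$n_years >= min_years,
      reason = ifelse(.data$pass, NA_character_,
                      paste0("too few years (", .data$n_years, " < ",
                             min_years, ")"))
    )
}
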
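presence_vector <- function(presence) {
  if (is.character(presence) && length(presence) == 1) {
    v <- as.integer(strsplit(presence, "")[[1]])
  } else {
    v <- as.integer(presence)
  }
  if (anyNA(v) || !all(v %in% c(0L, 1L))) {
    stop("presence must be a binary string or 0/1 vector", call. = FALSE)
  }
  v
}

#' Count immigration and extinction events in a presence string
#'
#' An immigration event is an adjacent 0 -> 1 transition, a local extinction
#' an adjacent 1 -> 0 transition; the boundaries of the string contribute
#' nothing.
#'
#' @param presence A binary string like `"00111"` or a 0/1 vector.
#' @return Named integer vector `c(immigrations =, extinctions =)`.
#' @examples
#' count_transitions("0110101") # 3 immigrations, 2 extinctions
#' @export
count_transitions <- function(presence) {
  v <- presence_vector(presence)
  stopifnot(length(v) >= 1)
  d <- diff(v)
  c(immigrations = sum(d == 1L), extinctions = sum(d == -1L))
}

#' Wald-Wolfowitz runs test for a binary presence string
#'
#' Two-sided runs test using the normal approximation without continuity
#' correction: with `n1` ones, `n0` zeros and `R` observed runs,
#' `E[R] = 1 + 2*n1*n0/(n1+n0)` and
#' `Var[R] = 2*n1*n0*(2*n1*n0 - n1 - n0) / ((n1+n0)^2 * (n1+n0-1))`;
#' `p = 2 * pnorm(-|R - E[R]| / sqrt(Var[R]))`. Used to gate transition
#' counting so that noisy detection does not inflate immigration and
#' extinction events.
#'
#' @param presence A binary string or 0/1 vector of length >= 2.
#' @return The two-sided p-value, or `NA` when the sequence has only one
#'   level (all 0s or all 1s), for which the test is undefined.
#' @examples
#' runs_test("0101010101") # ~ 0.0073: far more runs than random
#' runs_test("1111")       # NA
#' @export
runs_test <- function(presence) {
  v <- presence_vector(presence)
  if (length(v) < 2) {
    stop("precondition error: runs test needs length >= 2", call. = FALSE)
  }
  n1 <- sum(v == 1L)
  n0 <- sum(v == 0L)
  if (n0 == 0 || n1 == 0) return(NA_real_)
  n <- n0 + n1
  R <- 1 + sum(diff(v) != 0L)
  ER <- 1 + 2 * n1 * n0 / n
  VR <- 2 * n1 * n0 * (2 * n1 * n0 - n) / (n^2 * (n - 1))
  if (VR <= 0) return(1)
  2 * pnorm(-abs((R - ER) / sqrt(VR)))
}

#' Select rare-species populations from rarefied data
#'
#' A population (one species in one assemblage) is selected when its rarefied
#' abundance is 1 or 2 in at least one retained year. The full trajectory is
#' kept — abundances may rise above 2 or fall to 0 in other years — and years
#' in which the assemblage was sampled but the species absent are explicit
#' zeros. The presence string is `abundance > 0` over the retained years in
#' order.
#'
#' @param rarefied Rarefied tibble for a single rarefaction iteration (see
#'   [rarefy()]); an `iteration` column may be present but must hold a single
#'   value.
#' @return A tibble with one row per selected population: `assemblage_id`,
#'   `species_id`, list-columns `years` and `abundance`, and the `presence`
#'   string.
#' @export
select_rare_populations <- function(rarefied) {
  if ("iteration" %in% names(rarefied) &&
      dplyr::n_distinct(rarefied$iteration) > 1) {
    stop("rarefied data contain multiple iterations; ",
         "select populations from one iteration at a time", call. = FALSE)
  }
  full <- rarefied |>
    dplyr::group_by(.data$assemblage_id) |>
    tidyr::complete(year = sort(unique(.data$year)), .data$species_id,
                    fill = list(abundance = 0)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$assemblage_id, .data$species_id, .data$year)
  full |>
    dplyr::group_by(.data$assemblage_id, .data$species_id) |>
    dplyr::filter(any(.data$abundance %in% c(1, 2))) |>
    dplyr::summarise(
      presence = paste(as.integer(.data$abundance > 0), collapse = ""),
      years = list(.data$year),
      abundance = list(.data$abundance),
      .groups = "drop"
    ) |>
    dplyr::relocate("presence", .after = "abundance")
}

#' Classify one rare-species population
#'
#' Classification rules, applied to the binary presence string:
#' 1. no absences at all: `persistent`;
#' 2. otherwise, if the runs test ([runs_test()]) is undefined or
#'    non-significant at `alpha`, the apparent events are not distinguishable
#'    from noise: `persistent`;
#' 3. otherwise, by transition counts: exactly one immigration and no
#'    extinction: `immigration`; exactly one extinction and no immigration:
#'    `extinction`; two or more events in total: `multiple`.
#'
#' @param presence Binary string or 0/1 vector containing at least one 1.
#' @param alpha Runs-test significance threshold (default 0.05, two-sided).
#' @return A list with `category` (one of persistent / immigration /
#'   extinction / multiple), `n_immigration_events`, `n_extinction_events`,
#'   `runs_p`.
#' @examples
#' classify_population("0000111111")$category # immigration
#' @export
classify_population <- function(presence, alpha = 0.05) {
  v <- presence_vector(presence)
  if (!any(v == 1L)) {
    stop("precondition error: population was never present", call. = FALSE)
  }
  tr <- count_transitions(v)
  p <- if (length(v) >= 2) runs_test(v) else NA_real_
  category <- if (all(v == 1L)) {
    "persistent"
  } else if (is.na(p) || p >= alpha) {
    "persistent"
  } else {
    tot <- sum(tr)
    if (tr[["immigrations"]] == 1 && tr[["extinctions"]] == 0) {
      "immigration"
    } else if (tr[["extinctions"]] == 1 && tr[["immigrations"]] == 0) {
      "extinction"
    } else if (tot >= 2) {
      "multiple"
    } else {
      stop("internal inconsistency: significant runs test with no transitions",
           call. = FALSE)
    }
  }
  list(category = category,
       n_immigration_events = unname(tr[["immigrations"]]),
       n_extinction_events = unname(tr[["extinctions"]]),
       runs_p = p)
}

#' Classify a table of rare-species populations
#'
#' @param populations Tibble from [select_rare_populations()] (or any tibble
#'   with `assemblage_id`, `species_id`, `presence`).
#' @param alpha Runs-test significance threshold (default 0.05).
#' @return A tibble with columns `assemblage_id`, `species_id`, `category`
#'   (factor), `n_immigration_events`, `n_extinction_events`, `runs_p`,
#'   `string_length`.
#' @export
classify_populations <- function(populations, alpha = 0.05) {
  stopifnot(nrow(populations) > 0)
  res <- purrr::map(populations$presence, classify_population, alpha = alpha)
  tibble::tibble(
    assemblage_id = populations$assemblage_id,
    species_id = populations$species_id,
    category = factor(purrr::map_chr(res, "category"),
                      levels = c("persistent", "immigration", "extinction",
                                 "multiple")),
    n_immigration_events = purrr::map_int(res, "n_immigration_events"),
    n_extinction_events = purrr::map_int(res, "n_extinction_events"),
    runs_p = purrr::map_dbl(res, "runs_p"),
    string_length = nchar(populations$presence)
  )
}

#' Tabulate persistence categories
#'
#' @param results Tibble with a `category` column (see
#'   [classify_populations()]).
#' @return A tibble with one row per category: `category`, `n`, `proportion`.
#'   Counts sum to the number of populations and proportions to 1.
#' @export
tabulate_categories <- function(results) {
  stopifnot(nrow(results) > 0)
  cat <- factor(results$category,
                levels = c("persistent", "immigration", "extinction",
                           "multiple"))
  tb <- table(cat)
  tibble::tibble(
    category = names(tb),
    n = as.integer(tb),
    proportion = as.numeric(tb) / nrow(results)
  )
}
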
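#' Exclude under-sampled years from each assemblage series
#'
#' For each assemblage, the mean number of distinct sampling occasions per year
#' is computed once on the series as supplied, and years with fewer than half
#' that mean are excluded. Ties (exactly half) are retained.
#'
#' @param x Records tibble (see [read_assemblage_csv()]).
#' @return The filtered records tibble. The per-assemblage set of excluded
#'   years is attached as attribute `"excluded_years"` (a tibble with columns
#'   `assemblage_id`, `year`, `n_samples`, `threshold`).
#' @examples
#' rec <- tibble::tibble(
#'   assemblage_id = "A",
#'   year = c(2000, 2000, 2000, 2000, 2001, 2001, 2001, 2001, 2002),
#'   sample_id = c("a", "b", "c", "d", "a", "b", "c", "d", "a"),
#'   species_id = "sp1", abundance = 1
#' )
#' # mean effort 3, threshold 1.5: the single-sample year 2002 is excluded
#' filter_years(rec)
#' @export
filter_years <- function(x) {
  if (nrow(x) == 0) {
    stop("degenerate series: no records to filter", call. = FALSE)
  }
  eff <- sampling_effort(x) |>
    dplyr::group_by(.data$assemblage_id) |>
    dplyr::mutate(threshold = mean(.data$n_samples) / 2) |>
    dplyr::ungroup()
  dropped <- eff[eff$n_samples < eff$threshold, ]
  kept <- eff[eff$n_samples >= eff$threshold, ]
  if (nrow(kept) == 0) {
    stop("degenerate series: all years excluded by the effort filter",
         call. = FALSE)
  }
  out <- dplyr::semi_join(x, kept, by = c("assemblage_id", "year"))
  attr(out, "excluded_years") <- dropped
  out
}

#' Sample-based rarefaction of an assemblage time series
#'
#' Equalizes sampling effort across the retained years of each assemblage: the
#' minimum number of distinct sampling occasions over years (`n_min`) is found,
#' and exactly `n_min` whole occasions are drawn uniformly without replacement
#' from every year (the year attaining the minimum contributes all of its
#' occasions). Occasions are kept intact — every record of a drawn occasion is
#' retained — and species abundances are then summed within each year over the
#' drawn occasions. Each year is also centred around the mean retained year of
#' its assemblage, giving the trend predictor.
#'
#' Apply [filter_years()] first; this function assumes the effort filter has
#' already been applied.
#'
#' @param x Filtered records tibble.
#' @param seed Integer RNG seed; identical `(x, seed)` give identical output.
#'   The global RNG state is left untouched.
#' @return A tibble with columns `assemblage_id`, `year`, `centered_year`,
#'   `species_id`, `abundance` (one row per species per retained year, all
#'   abundances >= 1). Attributes: `"n_min"` (tibble `assemblage_id`, `n_min`)
#'   and `"plan"` (tibble of the drawn `assemblage_id`, `year`, `sample_id`).
#' @examples
#' rec <- tibble::tibble(
#'   assemblage_id = "A",
#'   year = c(2000, 2000, 2000, 2001, 2001),
#'   sample_id = c("a", "b", "c", "a", "b"),
#'   species_id = "sp1", abundance = c(2, 1, 1, 3, 1)
#' )
#' rarefy(rec, seed = 1)
#' @export
rarefy <- function(x, seed) {
  stopifnot(nrow(x) > 0)
  ids <- sort(unique(x$assemblage_id))
  plan <- withr::with_seed(seed, {
    purrr::map(ids, function(a) {
      xa <- x[x$assemblage_id == a, ]
      samples_by_year <- tapply(xa$sample_id, xa$year,
                                function(s) sort(unique(s)))
      years <- sort(as.integer(names(samples_by_year)))
      n_min <- min(lengths(samples_by_year))
      drawn <- purrr::map(as.character(years), function(y) {
        s <- samples_by_year[[y]]
        if (length(s) > n_min) sort(sample(s, n_min)) else s
      })
      tibble::tibble(
        assemblage_id = a,
        year = rep(years, times = lengths(drawn)),
        sample_id = unlist(drawn),
        n_min = n_min
      )
    }) |> purrr::list_rbind()
  })
  kept <- dplyr::semi_join(x, plan,
                           by = c("assemblage_id", "year", "sample_id"))
  out <- kept |>
    dplyr::group_by(.data$assemblage_id, .data$year, .data$species_id) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    dplyr::group_by(.data$assemblage_id) |>
    dplyr::mutate(centered_year = .data$year -
                    mean(sort(unique(.data$year)))) |>
    dplyr::ungroup() |>
    dplyr::select("assemblage_id", "year", "centered_year", "species_id",
                  "abundance") |>
    dplyr::arrange(.data$assemblage_id, .data$year, .data$species_id)
  attr(out, "n_min") <- dplyr::distinct(plan, .data$assemblage_id,
                                        .data$n_min)
  attr(out, "plan") <- dplyr::select(plan, -"n_min")
  out
}

#' Repeat the rarefaction with independent deterministic seeds
#'
#' Iteration `k` uses [iteration_seed()]`(base_seed, k)`, so any iteration can
#' be reproduced in isolation. Downstream statistics can be recomputed per
#' iteration to assess robustness to the random occasion draws; by convention
#' the first iteration is the headline run.
#'
#' @param x Filtered records tibble (see [filter_years()]).
#' @param n_iterations Number of rarefaction iterations (default 20).
#' @param base_seed Integer base seed.
#' @return A tibble like [rarefy()]'s output with an extra leading `iteration`
#'   column. Attributes `"n_min"` (identical across iterations) and `"plans"`
#'   (list of per-iteration drawn-occasion tibbles).
#' @export
rarefy_iterations <- function(x, n_iterations = 20, base_seed = 1) {
  stopifnot(n_iterations >= 1)
  runs <- purrr::map(seq_len(n_iterations), function(k) {
    r <- rarefy(x, iteration_seed(base_seed, k))
    list(data = dplyr::mutate(r, iteration = k, .before = 1),
         plan = attr(r, "plan"), n_min = attr(r, "n_min"))
  })
  out <- purrr::list_rbind(purrr::map(runs, "data"))
  attr(out, "n_min") <- runs[[1]]$n_min
  attr(out, "plans") <- purrr::map(runs, "plan")
  out
}
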
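#' Pair per-assemblage slopes from two trend fits
#'
#' @param fit_x,fit_y `"trend_fit"` objects for the two facets.
#' @return A tibble with columns `assemblage_id`, `slope_x`, `slope_y`
#'   restricted to assemblages present in both fits, with attributes
#'   `facet_x`/`facet_y`.
#' @export
pair_slopes <- function(fit_x, fit_y) {
  sx <- extract_assemblage_slopes(fit_x)
  sy <- extract_assemblage_slopes(fit_y)
  ids <- intersect(names(sx), names(sy))
  out <- tibble::tibble(
    assemblage_id = ids,
    slope_x = unname(sx[ids]),
    slope_y = unname(sy[ids])
  )
  attr(out, "facet_x") <- fit_x$response
  attr(out, "facet_y") <- fit_y$response
  out
}

#' Pearson correlation between two sets of per-assemblage slopes
#'
#' @param pair A slope-pair tibble (see [pair_slopes()]), or any data frame
#'   with `slope_x` and `slope_y` columns.
#' @return Pearson's r.
#' @examples
#' correlate_slopes(tibble::tibble(slope_x = 1:3, slope_y = 1:3)) # 1
#' @export
correlate_slopes <- function(pair) {
  stopifnot(all(c("slope_x", "slope_y") %in% names(pair)))
  if (nrow(pair) < 3) {
    stop("precondition error: need >= 3 paired slopes for a correlation",
         call. = FALSE)
  }
  if (sd(pair$slope_x) == 0 || sd(pair$slope_y) == 0) {
    stop("degenerate correlation: zero variance in one slope vector",
         call. = FALSE)
  }
  cor(pair$slope_x, pair$slope_y, method = "pearson")
}

#' Drop-a-fraction sensitivity analysis for a slope correlation
#'
#' Re-estimates Pearson's r `n_reps` times, each time removing
#' `round(drop_fraction * n)` assemblages uniformly at random without
#' replacement, to check that the correlation is not driven by a few extreme
#' series. Replicates left with fewer than 3 pairs or zero variance are
#' skipped and counted.
#'
#' @param pair Slope-pair tibble.
#' @param drop_fraction Fraction of pairs removed per replicate (in (0, 1);
#'   conventionally 0.05, 0.10 or 0.20).
#' @param n_reps Number of replicates (default 200).
#' @param seed Integer seed; results are bit-for-bit reproducible given
#'   `(pair, drop_fraction, n_reps, seed)`.
#' @return An object of class `"slope_sensitivity"`: list with `r_full`, `r`
#'   (length `n_reps`, `NA` for skipped replicates), `summary` (median and
#'   2.5/97.5 percentiles of the non-skipped r), `n_skipped`, `drop_fraction`,
#'   `n_dropped`.
#' @export
sensitivity_correlations <- function(pair, drop_fraction, n_reps = 200,
                                     seed = 1) {
  stopifnot(drop_fraction > 0, drop_fraction < 1, n_reps >= 1)
  n <- nrow(pair)
  k <- round(drop_fraction * n)
  r_full <- correlate_slopes(pair)
  r <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(j) {
      keep <- if (k > 0) sort(sample.int(n, n - k)) else seq_len(n)
      sub <- pair[keep, ]
      if (nrow(sub) < 3 || sd(sub$slope_x) == 0 || sd(sub$slope_y) == 0) {
        return(NA_real_)
      }
      cor(sub$slope_x, sub$slope_y)
    }, numeric(1))
  })
  structure(
    list(
      r_full = r_full,
      r = r,
      summary = c(
        median = stats::median(r, na.rm = TRUE),
        q025 = unname(quantile(r, 0.025, na.rm = TRUE)),
        q975 = unname(quantile(r, 0.975, na.rm = TRUE))
      ),
      n_skipped = sum(is.na(r)),
      drop_fraction = drop_fraction,
      n_dropped = k
    ),
    class = "slope_sensitivity"
  )
}

#' @export
print.slope_sensitivity <- function(x, ...) {
  cat(sprintf(
    "Slope-correlation sensitivity: drop %.0f%% (%d of pairs), %d reps\n",
    100 * x$drop_fraction, x$n_dropped, length(x$r)))
  cat(sprintf("  full-data r = %.3f; replicate median %.3f [%.3f, %.3f]",
              x$r_full, x$summary[["median"]], x$summary[["q025"]],
              x$summary[["q975"]]))
  if (x$n_skipped > 0) cat("; ", x$n_skipped, " replicate(s) skipped",
                           sep = "")
  cat("\n")
  invisible(x)
}

#' Correlation matrix of per-assemblage slopes across facets
#'
#' Computes Pearson's r for the default facet pairs: rarity vs richness,
#' rarity vs size, richness vs size, plus the metric-agreement pairs rarity vs
#' singletons-only and rarity vs Fisher's alpha (when those fits are
#' supplied).
#'
#' @param fits Named list of `"trend_fit"` objects (names are responses).
#' @param pairs Optional list of length-2 character vectors of responses.
#' @return A tibble with columns `facet_x`, `facet_y`, `n`, `r`.
#' @export
slope_correlation_matrix <- function(fits, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- list(
      c("n_rare", "log10_richness"),
      c("n_rare", "log10_size"),
      c("log10_richness", "log10_size"),
      c("n_rare", "n_singletons"),
      c("n_rare", "fisher_alpha")
    )
  }
  pairs <- purrr::keep(pairs, ~ all(.x %in% names(fits)))
  purrr::map(pairs, function(p) {
    pr <- pair_slopes(fits[[p[1]]], fits[[p[2]]])
    r <- tryCatch(correlate_slopes(pr), error = function(e) {
      warning("correlation ", p[1], " ~ ", p[2], " undefined: ",
              conditionMessage(e), call. = FALSE)
      NA_real_
    })
    tibble::tibble(facet_x = p[1], facet_y = p[2], n = nrow(pr), r = r)
  }) |> purrr::list_rbind()
}
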
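#' Count singleton species
#'
#' A singleton is a species represented by exactly one individual in a
#' (rarefaction-standardized) yearly sample.
#'
#' @param abundances Vector of per-species counts, all >= 1.
#' @return Integer count of species with abundance exactly 1.
#' @examples
#' count_singletons(c(1, 1, 5)) # 2
#' @export
count_singletons <- function(abundances) {
  stopifnot(all(abundances >= 1))
  sum(abundances == 1)
}

#' Count rare species (singletons plus doubletons)
#'
#' Local rarity is operationalized as the number of species represented by one
#' or two individuals in a yearly sample.
#'
#' @inheritParams count_singletons
#' @return Integer count of species with abundance 1 or 2.
#' @examples
#' count_rare(c(1, 2, 2, 9)) # 3
#' @export
count_rare <- function(abundances) {
  stopifnot(all(abundances >= 1))
  sum(abundances <= 2)
}

#' Fisher's log-series alpha from richness and total abundance
#'
#' Solves `S = alpha * log(1 + N / alpha)` for the unique positive root by
#' bracketed root-finding followed by Newton polishing, so that substituting
#' the returned alpha back recovers `S` to within `1e-8 * S`. This is the
#' classical diversity estimator of the log-series species-abundance model.
#'
#' @param S Species richness (1 <= S <= N). Vectorized.
#' @param N Total number of individuals. Vectorized (recycled against `S`).
#' @param on_degenerate What to do when `S == N` (all species singletons), for
#'   which no finite root exists: `"error"` (default) raises a degenerate-SAD
#'   error, `"na"` returns `NA`.
#' @return Positive numeric vector of alpha values.
#' @examples
#' fisher_alpha(10, 100)
#' @export
fisher_alpha <- function(S, N, on_degenerate = c("error", "na")) {
  on_degenerate <- match.arg(on_degenerate)
  n <- max(length(S), length(N))
  S <- rep_len(S, n)
  N <- rep_len(N, n)
  vapply(seq_len(n), function(i) fisher_alpha1(S[i], N[i], on_degenerate),
         numeric(1))
}

fisher_alpha1 <- function(S, N, on_degenerate) {
  if (is.na(S) || is.na(N)) return(NA_real_)
  if (S < 1 || N < 1) {
    stop("precondition error: need S >= 1 and N >= 1", call. = FALSE)
  }
  if (S > N) {
    stop("precondition error: richness S cannot exceed total abundance N",
         call. = FALSE)
  }
  if (S == N) {
    if (on_degenerate == "error") {
      stop("degenerate SAD: S == N (all singletons), Fisher's alpha diverges",
           call. = FALSE)
    }
    return(NA_real_)
  }
  f <- function(a) a * log1p(N / a) - S
  hi <- max(S, 1)
  while (f(hi) < 0) hi <- hi * 2
  a <- stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
  # Newton polish: f'(a) = log1p(N/a) - N/(a+N)
  for (i in 1:5) {
    fp <- log1p(N / a) - N / (a + N)
    a <- a - f(a) / fp
  }
  a
}

#' Per-year assemblage summary metrics
#'
#' Collapses a rarefied table (see [rarefy()] / [rarefy_iterations()]) to one
#' row per assemblage-year with the rarity, richness and size metrics used by
#' the trend models: number of singletons, number of rare species (singletons
#' plus doubletons), Fisher's alpha, species richness `S` and assemblage size
#' `N` (total individuals).
#'
#' Years where `S == N` (every species a singleton) have no finite Fisher's
#' alpha; these get `NA` with a single warning rather than an imputed value.
#'
#' @param rarefied Rarefied tibble; an `iteration` column, if present, is kept
#'   as a grouping column.
#' @return A tibble with columns (`iteration`,) `assemblage_id`, `year`,
#'   `centered_year`, `n_singletons`, `n_rare`, `fisher_alpha`, `richness_S`,
#'   `size_N`.
#' @export
summarize_years <- function(rarefied) {
  stopifnot(nrow(rarefied) > 0)
  grp <- intersect(c("iteration", "assemblage_id", "year", "centered_year"),
                   names(rarefied))
  out <- rarefied |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_singletons = sum(.data$abundance == 1),
      n_rare = sum(.data$abundance <= 2),
      richness_S = dplyr::n_distinct(.data$species_id),
      size_N = sum(.data$abundance),
      .groups = "drop"
    )
  out$fisher_alpha <- fisher_alpha(out$richness_S, out$size_N,
                                   on_degenerate = "na")
  n_deg <- sum(is.na(out$fisher_alpha))
  if (n_deg > 0) {
    warning(n_deg, " assemblage-year(s) with S == N: Fisher's alpha set to NA",
            call. = FALSE)
  }
  dplyr::relocate(out, "fisher_alpha", .after = "n_rare")
}
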
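#' Configuration for an end-to-end pipeline run
#'
#' Defaults mirror the standard analysis settings: at least 10 years per
#' assemblage, 20 rarefaction iterations (the first is the headline run), 200
#' sensitivity replicates at drop fractions 5/10/20%, and a two-sided
#' runs-test gate at alpha = 0.05.
#'
#' @param input Path to a long-format CSV (see [read_assemblage_csv()]), or
#'   `NULL` when `scenario` is given.
#' @param scenario A `"scenario_config"` to simulate instead of reading a
#'   file.
#' @param schema Column mapping for `input`.
#' @param min_years Minimum distinct years per assemblage.
#' @param n_iterations Rarefaction iterations.
#' @param seed Base seed for every stochastic stage.
#' @param responses Responses to fit (default all five facets).
#' @param drop_fractions Sensitivity-analysis drop fractions.
#' @param n_sensitivity_reps Sensitivity replicates per fraction.
#' @param runs_alpha Runs-test significance threshold for the classifier.
#' @param robustness Refit the rarity and richness trends on every
#'   rarefaction iteration (`TRUE` by default; the extra iterations feed only
#'   the robustness summary).
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input = NULL, scenario = NULL,
                       schema = biotime_schema(), min_years = 10,
                       n_iterations = 20, seed = 1,
                       responses = trend_responses(),
                       drop_fractions = c(0.05, 0.10, 0.20),
                       n_sensitivity_reps = 200, runs_alpha = 0.05,
                       robustness = TRUE, out_dir = NULL) {
  if (is.null(input) && is.null(scenario)) {
    stop("run_config needs either an input path or a scenario", call. = FALSE)
  }
  if (!is.null(scenario)) stopifnot(inherits(scenario, "scenario_config"))
  responses <- match.arg(responses, trend_responses(), several.ok = TRUE)
  structure(
    list(input = input, scenario = scenario, schema = schema,
         min_years = min_years, n_iterations = n_iterations,
         seed = as.integer(seed), responses = responses,
         drop_fractions = drop_fractions,
         n_sensitivity_reps = n_sensitivity_reps, runs_alpha = runs_alpha,
         robustness = robustness, out_dir = out_dir),
    class = "run_config"
  )
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full rarity-trend pipeline
#'
#' Executes, in order: ingestion (file or synthetic scenario), series
#' validation, year filtering, repeated rarefaction, per-year metrics, the
#' five mixed-effect trend fits on the first rarefaction iteration,
#' per-iteration rarity/richness slope robustness, slope correlations with
#' drop-a-fraction sensitivity, and the runs-test-gated persistence
#' classification. All randomness derives from `config$seed`, so two runs of
#' the same config are identical.
#'
#' @param config A `"run_config"`.
#' @return An object of class `"rarity_run"`: list with `config`, `excluded`
#'   (assemblages failing the min-years rule), `metrics` (iteration 1),
#'   `fits`, `trend_table`, `assemblage_trends`, `correlations`,
#'   `sensitivity`, `robustness`, `populations`, `categories`, `truth`
#'   (ground truth when a scenario was simulated). When `config$out_dir` is
#'   set, per-stage CSV artifacts and a JSON report are written as the stages
#'   complete (so partial artifacts survive a late failure).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  art <- artifact_writer(config$out_dir)

  truth <- NULL
  records <- with_stage("ingest", {
    if (!is.null(config$scenario)) {
      scn <- generate_scenario(config$scenario)
      truth <- scn$truth
      as_assemblage_records(scn$records)
    } else {
      read_assemblage_csv(config$input, config$schema)
    }
  })

  validation <- with_stage("validate", {
    validate_series(records, min_years = config$min_years)
  })
  excluded <- validation[!validation$pass, ]
  if (all(!validation$pass)) {
    stop("stage 'validate' failed: no assemblage has >= ", config$min_years,
         " years", call. = FALSE)
  }
  records <- dplyr::semi_join(records, validation[validation$pass, ],
                              by = "assemblage_id")
  art("validation.csv", validation)

  rarefied <- with_stage("rarefaction", {
    rarefy_iterations(filter_years(records),
                      n_iterations = config$n_iterations,
                      base_seed = config$seed)
  })

  metrics_all <- with_stage("metrics", summarize_years(rarefied))
  metrics1 <- metrics_all[metrics_all$iteration == 1, ]
  art("metrics.csv", metrics_all)

  fits <- with_stage("trend_models", {
    fl <- purrr::map(config$responses,
                     ~ suppressWarnings(fit_trend(metrics1, .x)))
    names(fl) <- config$responses
    fl
  })
  trend_table <- purrr::imap(fits, function(f, nm) {
    tibble::tibble(
      response = nm, family = f$family, beta1 = f$beta1,
      lower = f$interval95[["lower"]], upper = f$interval95[["upper"]],
      yearly_ratio = if (grepl("^log10", nm)) slope_to_ratio(f$beta1)
        else NA_real_,
      fallback = f$convergence$fallback
    )
  }) |> purrr::list_rbind()
  art("trends.csv", trend_table)

  assemblage_trends <- purrr::imap(
    fits, ~ dplyr::mutate(classify_assemblage_trends(.x), response = .y,
                          .before = 1)
  ) |> purrr::list_rbind()
  art("assemblage_slopes.csv", assemblage_trends)

  robustness <- NULL
  if (config$robustness && config$n_iterations > 1) {
    robustness <- with_stage("robustness", {
      purrr::map(seq_len(config$n_iterations), function(k) {
        mk <- metrics_all[metrics_all$iteration == k, ]
        purrr::map(intersect(c("n_rare", "log10_richness"),
                             config$responses), function(r) {
          f <- tryCatch(suppressWarnings(fit_trend(mk, r)),
                        error = function(e) NULL)
          tibble::tibble(
            iteration = k, response = r,
            beta1 = if (is.null(f)) NA_real_ else f$beta1,
            lower = if (is.null(f)) NA_real_ else f$interval95[["lower"]],
            upper = if (is.null(f)) NA_real_ else f$interval95[["upper"]]
          )
        }) |> purrr::list_rbind()
      }) |> purrr::list_rbind()
    })
    art("robustness.csv", robustness)
  }

  correlations <- with_stage("slope_relationships",
                             slope_correlation_matrix(fits))
  art("correlations.csv", correlations)

  sensitivity <- with_stage("sensitivity", {
    main_pairs <- list(c("n_rare", "log10_richness"),
                       c("n_rare", "log10_size"),
                       c("log10_richness", "log10_size"))
    main_pairs <- purrr::keep(main_pairs, ~ all(.x %in% names(fits)))
    purrr::imap(main_pairs, function(p, i) {
      pr <- pair_slopes(fits[[p[1]]], fits[[p[2]]])
      purrr::imap(config$drop_fractions, function(f, j) {
        s <- tryCatch(
          sensitivity_correlations(
            pr, f, n_reps = config$n_sensitivity_reps,
            seed = iteration_seed(config$seed, 3000 + 10 * i + j)),
          error = function(e) NULL  # degenerate full-data correlation
        )
        if (is.null(s)) {
          return(tibble::tibble(facet_x = p[1], facet_y = p[2],
                                drop_fraction = f, r_full = NA_real_,
                                median = NA_real_, q025 = NA_real_,
                                q975 = NA_real_, n_skipped = NA_integer_))
        }
        tibble::tibble(facet_x = p[1], facet_y = p[2], drop_fraction = f,
                       r_full = s$r_full, median = s$summary[["median"]],
                       q025 = s$summary[["q025"]], q975 = s$summary[["q975"]],
                       n_skipped = s$n_skipped)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  art("sensitivity.csv", sensitivity)

  class_res <- with_stage("persistence_classifier", {
    rare1 <- rarefied[rarefied$iteration == 1, ]
    pops <- select_rare_populations(rare1)
    cl <- classify_populations(pops, alpha = config$runs_alpha)
    list(populations = cl, categories = tabulate_categories(cl))
  })
  art("populations.csv", class_res$populations)
  art("categories.csv", class_res$categories)

  run <- structure(
    list(config = config, excluded = excluded, metrics = metrics1,
         fits = fits, trend_table = trend_table,
         assemblage_trends = assemblage_trends,
         correlations = correlations, sensitivity = sensitivity,
         robustness = robustness, populations = class_res$populations,
         categories = class_res$categories, truth = truth),
    class = "rarity_run"
  )
  if (!is.null(config$out_dir)) {
    report <- list(
      n_assemblages = dplyr::n_distinct(records$assemblage_id),
      excluded_assemblages = excluded$assemblage_id,
      trends = trend_table, correlations = correlations,
      categories = class_res$categories,
      seed = config$seed, n_iterations = config$n_iterations
    )
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

artifact_writer <- function(out_dir) {
  if (is.null(out_dir)) return(function(name, x) invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  function(name, x) {
    if ("years" %in% names(x)) {
      x <- dplyr::select(x, -dplyr::any_of(c("years", "abundance")))
    }
    readr::write_csv(x, file.path(out_dir, name))
    invisible(NULL)
  }
}

#' @export
print.rarity_run <- function(x, ...) {
  cat("Rarity-trend pipeline run\n")
  cat("  assemblages analysed:",
      dplyr::n_distinct(x$metrics$assemblage_id),
      " (", nrow(x$excluded), " excluded )\n")
  cat("  overall slopes (per year, link scale):\n")
  for (i in seq_len(nrow(x$trend_table))) {
    r <- x$trend_table[i, ]
    cat(sprintf("    %-15s %+0.5f  [%+0.5f, %+0.5f]%s\n", r$response,
                r$beta1, r$lower, r$upper,
                if (!is.na(r$yearly_ratio))
                  sprintf("  (x%.3f per year)", r$yearly_ratio) else ""))
  }
  cat("  slope correlations:\n")
  for (i in seq_len(nrow(x$correlations))) {
    r <- x$correlations[i, ]
    cat(sprintf("    %s ~ %s: r = %.3f (n = %d)\n", r$facet_x, r$facet_y,
                r$r, r$n))
  }
  cat("  rare populations:", nrow(x$populations), "\n")
  for (i in seq_len(nrow(x$categories))) {
    r <- x$categories[i, ]
    cat(sprintf("    %-11s %5d (%4.1f%%)\n", r$category, r$n,
                100 * r$proportion))
  }
  invisible(x)
}
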
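#' Configuration for a synthetic multi-assemblage scenario
#'
#' Defines the generative process for assemblage count time series with known
#' ground truth. Each assemblage starts from a pool of resident species whose
#' initial expected yearly abundances `lambda_s(0)` are drawn from a
#' log-series species-abundance distribution with parameter `sad_alpha` (the
#' log-series mixing parameter `x` is derived from `n_species_pool` and
#' `sad_alpha`). Each species follows a log-linear latent trend
#' `lambda_s(t) = lambda_s(0) * exp(b_s * t)` with
#' `b_s ~ Normal(trend_mean, trend_sd^2)`. Immigrants arrive as a Poisson
#' process (`immigration_rate` expected arrivals per assemblage-year) with
#' initial expected abundance `arrival_abundance` and their own trend from the
#' arrival year. The observation layer draws a yearly number of sampling
#' occasions uniformly from `samples_per_year` and splits each species' yearly
#' expectation across occasions (`obs_model = "poisson"`: independent Poisson
#' counts per occasion; `"multinomial"`: the yearly total is fixed at
#' `round(sum(lambda))` and allocated to species and occasions).
#'
#' With `extinction_mode = "none"` latent abundances are floored at
#' `lambda_floor` so declining species linger as rare rather than vanish;
#' with `"trend_driven"` a species whose latent abundance falls below
#' `presence_threshold` goes locally extinct (lambda set to 0 thereafter).
#'
#' @param n_assemblages,n_years Numbers of assemblages and of years.
#' @param samples_per_year Integer range (min, max) of sampling occasions per
#'   year.
#' @param n_species_pool Resident species per assemblage.
#' @param sad_alpha Log-series alpha of the initial abundance distribution.
#' @param trend_mean,trend_sd Mean and SD of per-species log-linear slopes.
#' @param immigration_rate Expected new-species arrivals per assemblage-year.
#' @param arrival_abundance Initial expected abundance of an immigrant.
#' @param extinction_mode `"none"` or `"trend_driven"`.
#' @param obs_model `"poisson"` or `"multinomial"`.
#' @param lambda_floor Floor applied to latent abundances under
#'   `extinction_mode = "none"`.
#' @param presence_threshold Latent abundance above which a species counts as
#'   present in the noise-free trajectories (and below which it goes extinct
#'   under `"trend_driven"`).
#' @param rare_band Latent-abundance band counted as "rare" in the noise-free
#'   trajectories.
#' @param seed Integer RNG seed; identical configs give identical records.
#' @return An object of class `"scenario_config"`.
#' @seealso [scenario_preset()], [generate_scenario()]
#' @export
scenario_config <- function(n_assemblages = 60, n_years = 20,
                            samples_per_year = c(2, 4),
                            n_species_pool = 60, sad_alpha = 15,
                            trend_mean = 0, trend_sd = 0.01,
                            immigration_rate = 0, arrival_abundance = 1,
                            extinction_mode = c("none", "trend_driven"),
                            obs_model = c("poisson", "multinomial"),
                            lambda_floor = 0.5, presence_threshold = 0.5,
                            rare_band = c(0.5, 2.5), seed = 1) {
  extinction_mode <- match.arg(extinction_mode)
  obs_model <- match.arg(obs_model)
  stopifnot(n_years >= 2, n_species_pool >= 1, n_assemblages >= 1,
            immigration_rate >= 0, trend_sd >= 0, sad_alpha > 0,
            arrival_abundance >= 1,
            length(samples_per_year) == 2,
            samples_per_year[1] >= 1,
            samples_per_year[2] >= samples_per_year[1])
  structure(
    list(n_assemblages = n_assemblages, n_years = n_years,
         samples_per_year = as.integer(samples_per_year),
         n_species_pool = n_species_pool, sad_alpha = sad_alpha,
         trend_mean = trend_mean, trend_sd = trend_sd,
         immigration_rate = immigration_rate,
         arrival_abundance = arrival_abundance,
         extinction_mode = extinction_mode, obs_model = obs_model,
         lambda_floor = lambda_floor,
         presence_threshold = presence_threshold,
         rare_band = rare_band, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Scenario presets for the three canonical processes of rarity change
#'
#' * `"population_decline"`: resident populations decline (5% per year on
#'   average) with no increase in local extinctions — declining species linger
#'   at low abundance. Rarity rises, richness stays flat, assemblage size
#'   falls.
#' * `"decline_extinction"`: the same declines but species whose expected
#'   abundance drops below the presence threshold go locally extinct. Rarity
#'   rises while richness and size both fall.
#' * `"immigration"`: resident populations are stable on average and new
#'   species continually arrive in low numbers. Rarity and richness rise
#'   together, size rises slightly.
#'
#' @param name Preset name.
#' @param n_assemblages,n_years,seed Passed to [scenario_config()].
#' @param ... Further overrides passed to [scenario_config()].
#' @return A `"scenario_config"`.
#' @export
scenario_preset <- function(name = c("immigration", "population_decline",
                                     "decline_extinction"),
                            n_assemblages = 60, n_years = 20, seed = 1,
                            ...) {
  name <- match.arg(name)
  args <- switch(name,
    population_decline = list(trend_mean = -0.05, trend_sd = 0.03,
                              immigration_rate = 0,
                              extinction_mode = "none"),
    decline_extinction = list(trend_mean = -0.05, trend_sd = 0.03,
                              immigration_rate = 0,
                              extinction_mode = "trend_driven"),
    immigration = list(trend_mean = 0, trend_sd = 0.01,
                       immigration_rate = 0.5, arrival_abundance = 1,
                       extinction_mode = "none")
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_config,
          c(list(n_assemblages = n_assemblages, n_years = n_years,
                 seed = seed), args))
}

logseries_x <- function(S, alpha) {
  # community size implied by (S, alpha): N = alpha * (exp(S/alpha) - 1)
  N <- alpha * (expm1(S / alpha))
  N / (N + alpha)
}

rlogseries <- function(n, x) {
  kmax <- 10
  repeat {
    k <- seq_len(kmax)
    p <- x^k / k
    if (sum(p) / (-log1p(-x)) > 1 - 1e-10 || kmax > 1e6) break
    kmax <- kmax * 4
  }
  sample(k, n, replace = TRUE, prob = p)
}

#' Generate a synthetic multi-assemblage dataset with known ground truth
#'
#' @param config A `"scenario_config"` (see [scenario_config()],
#'   [scenario_preset()]).
#' @return An object of class `"rarity_scenario"`: a list with
#' * `records`: abundance records in the canonical long schema (ready for the
#'   pipeline);
#' * `truth`: a list with `species` (per-species `lambda0`, `slope`,
#'   `arrival_year`, `extinction_year`), `lambda` (latent expected abundance
#'   per assemblage, species and year), `trajectories` (noise-free
#'   per-assemblage-year `rarity_true`, `richness_true`, `size_true` computed
#'   from the latent abundances), `effort` (occasions per assemblage-year)
#'   and the `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  years <- 2000L + seq_len(cfg$n_years)
  tt <- seq_len(cfg$n_years) - 1L
  x <- logseries_x(cfg$n_species_pool, cfg$sad_alpha)
  aw <- max(2, nchar(cfg$n_assemblages))
  out <- withr::with_seed(cfg$seed, {
    purrr::map(seq_len(cfg$n_assemblages), function(a) {
      aid <- sprintf("A%0*d", aw, a)
      lam0 <- rlogseries(cfg$n_species_pool, x)
      n_arr <- if (cfg$immigration_rate > 0 && cfg$n_years > 1) {
        rpois(cfg$n_years - 1, cfg$immigration_rate)
      } else {
        integer(cfg$n_years - 1)
      }
      arr_t <- rep(seq_len(cfg$n_years - 1), n_arr) # 0-based arrival index
      nsp <- cfg$n_species_pool + length(arr_t)
      sp_id <- c(sprintf("sp%03d", seq_len(cfg$n_species_pool)),
                 if (length(arr_t) > 0) sprintf("im%03d",
                                                seq_along(arr_t)))
      slope <- rnorm(nsp, cfg$trend_mean, cfg$trend_sd)
      start <- c(rep(0L, cfg$n_species_pool), arr_t)
      lam_init <- c(lam0, rep(cfg$arrival_abundance, length(arr_t)))
      raw <- outer(seq_len(nsp), tt, function(s, t) {
        ifelse(t >= start[s], lam_init[s] * exp(slope[s] * (t - start[s])), 0)
      })
      ext_year <- rep(NA_integer_, nsp)
      if (cfg$extinction_mode == "trend_driven") {
        for (s in seq_len(nsp)) {
          active <- which(tt >= start[s])
          below <- active[raw[s, active] < cfg$presence_threshold]
          if (length(below) > 0) {
            e <- below[1]
            raw[s, e:cfg$n_years] <- 0
            ext_year[s] <- years[e]
          }
        }
        lam <- raw
      } else {
        lam <- raw
        for (s in seq_len(nsp)) {
          active <- tt >= start[s]
          lam[s, active] <- pmax(lam[s, active], cfg$lambda_floor)
        }
      }
      samp_range <- seq(cfg$samples_per_year[1], cfg$samples_per_year[2])
      n_samp <- samp_range[sample.int(length(samp_range), cfg$n_years,
                                      replace = TRUE)]
      rec <- purrr::map(seq_len(cfg$n_years), function(ti) {
        m <- n_samp[ti]
        cnt <- if (cfg$obs_model == "poisson") {
          matrix(rpois(nsp * m, rep(lam[, ti] / m, m)), nrow = nsp)
        } else {
          Nt <- round(sum(lam[, ti]))
          cm <- matrix(0L, nrow = nsp, ncol = m)
          if (Nt > 0 && sum(lam[, ti]) > 0) {
            per_sp <- as.integer(rmultinom(1, Nt, lam[, ti]))
            for (s in which(per_sp > 0)) {
              cm[s, ] <- tabulate(sample.int(m, per_sp[s], replace = TRUE),
                                  nbins = m)
            }
          }
          cm
        }
        nz <- which(cnt > 0, arr.ind = TRUE)
        if (nrow(nz) == 0) return(NULL)
        tibble::tibble(
          assemblage_id = aid,
          year = years[ti],
          sample_id = sprintf("%d_%d", years[ti], nz[, "col"]),
          species_id = sp_id[nz[, "row"]],
          abundance = cnt[nz]
        )
      }) |> purrr::list_rbind()
      band <- cfg$rare_band
      traj <- tibble::tibble(
        assemblage_id = aid,
        year = years,
        rarity_true = colSums(lam >= band[1] & lam <= band[2]),
        richness_true = colSums(lam >= cfg$presence_threshold),
        size_true = colSums(lam)
      )
      list(
        records = rec,
        species = tibble::tibble(
          assemblage_id = aid, species_id = sp_id,
          lambda0 = lam_init, slope = slope,
          arrival_year = ifelse(start > 0, years[start + 1L], NA_integer_),
          extinction_year = ext_year
        ),
        lambda = tibble::tibble(
          assemblage_id = aid,
          species_id = rep(sp_id, times = cfg$n_years),
          year = rep(years, each = nsp),
          lambda = as.vector(lam)
        ),
        trajectories = traj,
        effort = tibble::tibble(assemblage_id = aid, year = years,
                                n_samples = n_samp)
      )
    })
  })
  structure(
    list(
      records = purrr::list_rbind(purrr::map(out, "records")),
      truth = list(
        species = purrr::list_rbind(purrr::map(out, "species")),
        lambda = purrr::list_rbind(purrr::map(out, "lambda")),
        trajectories = purrr::list_rbind(purrr::map(out, "trajectories")),
        effort = purrr::list_rbind(purrr::map(out, "effort")),
        config = cfg
      )
    ),
    class = "rarity_scenario"
  )
}

#' Per-assemblage slopes of the noise-free ground-truth trajectories
#'
#' Ordinary least-squares slopes of the latent trajectories against
#' mean-centred year, one row per assemblage. To match the scales the trend
#' models operate on, the rarity slope is on the count scale while richness
#' and size slopes are on the log10 scale (the analysis models log10 richness
#' and log10 size); zero values are clamped below before taking logs. These
#' are the generator's ground truth, untouched by the sampling layer.
#'
#' @param scenario A `"rarity_scenario"` (or its `truth` element).
#' @return A tibble with columns `assemblage_id`, `rarity_slope`,
#'   `richness_slope`, `size_slope`.
#' @export
truth_slopes <- function(scenario) {
  truth <- if (inherits(scenario, "rarity_scenario")) scenario$truth else
    scenario
  truth$trajectories |>
    dplyr::group_by(.data$assemblage_id) |>
    dplyr::summarise(
      rarity_slope = ols_slope(.data$year, .data$rarity_true),
      richness_slope = ols_slope(.data$year,
                                 log10(pmax(.data$richness_true, 1))),
      size_slope = ols_slope(.data$year, log10(pmax(.data$size_true, 1e-6))),
      .groups = "drop"
    )
}

ols_slope <- function(t, y) {
  tc <- t - mean(t)
  if (all(y == y[1])) return(0)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Expected rarefied rarity slope implied by the ground truth
#'
#' For each assemblage this computes, year by year, the exact expectation of
#' the rarefied number of rare species (singletons plus doubletons) implied by
#' the latent abundances, the realized sampling effort, and the rarefaction
#' design: with `n_t` occasions in year `t` and `n_min` the minimum over
#' retained years, the rarefied count of species `s` is Poisson with mean
#' `lambda_s(t) * n_min / n_t`, so
#' `E[rare_t] = sum_s P(X_s = 1) + P(X_s = 2)`. The per-assemblage true slope
#' is the OLS slope of `log(E[rare_t])` against mean-centred year — the same
#' log-linear functional the negative-binomial trend model estimates. Year
#' retention follows the same under-sampling filter as [filter_years()].
#'
#' Only meaningful for `obs_model = "poisson"` scenarios.
#'
#' @param scenario A `"rarity_scenario"`.
#' @return A tibble with columns `assemblage_id`, `expected_slope`.
#' @export
expected_rarity_slope <- function(scenario) {
  stopifnot(inherits(scenario, "rarity_scenario"))
  truth <- scenario$truth
  lam <- truth$lambda
  truth$effort |>
    dplyr::group_by(.data$assemblage_id) |>
    dplyr::group_modify(function(eff, key) {
      keep <- eff$n_samples >= mean(eff$n_samples) / 2
      eff <- eff[keep, ]
      n_min <- min(eff$n_samples)
      la <- lam[lam$assemblage_id == key$assemblage_id &
                  lam$year %in% eff$year, ]
      thin <- setNames(n_min / eff$n_samples, eff$year)
      lt <- la$lambda * thin[as.character(la$year)]
      E <- tapply(dpois(1, lt) + dpois(2, lt), la$year, sum)
      yr <- as.integer(names(E))
      tibble::tibble(expected_slope = ols_slope(yr, log(pmax(E, 1e-12))))
    }) |>
    dplyr::ungroup()
}

#' Construct presence strings with known persistence labels
#'
#' Fixture factory for the persistence classifier: emits binary presence
#' strings built so that, at sufficient length, the runs-test gate is passed
#' and the classifier recovers the intended label. `persistent` strings are
#' all ones; `immigration` / `extinction` strings are a single clean block
#' switch; `multiple` strings have 3-4 alternating blocks. At short lengths
#' (below about 10) single-switch strings can fall below runs-test
#' significance and are then classified persistent — a known gate limitation,
#' not a construction error.
#'
#' @param n Number of strings.
#' @param prob Named probabilities (or weights) over the four labels.
#' @param length String length (>= 4).
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `label` (intended category),
#'   `presence`.
#' @export
generate_population_strings <- function(n,
                                        prob = c(persistent = 0.25,
                                                 immigration = 0.25,
                                                 extinction = 0.25,
                                                 multiple = 0.25),
                                        length = 20, seed = 1) {
  stopifnot(length >= 4, n >= 1,
            all(names(prob) %in% c("persistent", "immigration",
                                   "extinction", "multiple")))
  min_block <- if (length >= 12) 3L else 1L
  withr::with_seed(seed, {
    labels <- sample(names(prob), n, replace = TRUE, prob = prob)
    presence <- vapply(labels, function(lb) {
      switch(lb,
        persistent = paste(rep("1", length), collapse = ""),
        immigration = {
          k0 <- sample(seq(min_block, length - min_block), 1)
          paste0(strrep("0", k0), strrep("1", length - k0))
        },
        extinction = {
          k1 <- sample(seq(min_block, length - min_block), 1)
          paste0(strrep("1", k1), strrep("0", length - k1))
        },
        multiple = {
          nb <- if (length >= 4 * min_block + 4) sample(3:4, 1) else 3L
          extra <- length - nb * min_block
          lens <- min_block + tabulate(sample.int(nb, extra, replace = TRUE),
                                       nbins = nb)
          first <- sample(0:1, 1)
          sym <- rep(c(first, 1 - first), length.out = nb)
          paste(mapply(strrep, as.character(sym), lens), collapse = "")
        }
      )
    }, character(1))
    tibble::tibble(id = seq_len(n), label = labels, presence = presence)
  })
}

#' Slope-recovery experiment for the rarity trend model
#'
#' Repeatedly simulates an immigration-driven scenario, runs the rarefaction
#' and metric stages, fits the negative-binomial mixed trend model for the
#' number of rare species, and compares the fitted overall slope with the
#' ground-truth expected slope ([expected_rarity_slope()], averaged over
#' assemblages). Used to verify that the estimator recovers the sign of the
#' true trend and that its 95% interval has close-to-nominal coverage.
#'
#' @param n_reps Number of simulation replicates.
#' @param n_assemblages,n_years Scenario size per replicate.
#' @param base_seed Base seed; replicate k derives its scenario and
#'   rarefaction seeds via [iteration_seed()].
#' @param preset Scenario preset name (default `"immigration"`).
#' @return A tibble with one row per replicate: `rep`, `truth` (mean expected
#'   slope), `beta1`, `lower`, `upper`, `sign_ok`, `covered`, `error`
#'   (message when a replicate failed to fit, else `NA`).
#' @export
rarity_slope_recovery <- function(n_reps = 50, n_assemblages = 60,
                                  n_years = 20, base_seed = 1,
                                  preset = "immigration") {
  purrr::map(seq_len(n_reps), function(k) {
    scn <- generate_scenario(scenario_preset(
      preset, n_assemblages = n_assemblages, n_years = n_years,
      seed = iteration_seed(base_seed, 100 + k)))
    truth <- mean(expected_rarity_slope(scn)$expected_slope)
    res <- tryCatch({
      met <- summarize_years(rarefy(filter_years(scn$records),
                                    seed = iteration_seed(base_seed,
                                                          500 + k)))
      fit <- suppressWarnings(fit_trend(met, "n_rare"))
      list(beta1 = fit$beta1, lower = fit$interval95[["lower"]],
           upper = fit$interval95[["upper"]], error = NA_character_)
    }, error = function(e) {
      list(beta1 = NA_real_, lower = NA_real_, upper = NA_real_,
           error = conditionMessage(e))
    })
    tibble::tibble(
      rep = k, truth = truth, beta1 = res$beta1, lower = res$lower,
      upper = res$upper,
      sign_ok = sign(res$beta1) == sign(truth),
      covered = res$lower <= truth & truth <= res$upper,
      error = res$error
    )
  }) |> purrr::list_rbind()
}
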
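#' @rdname fit_trend
#' @export
trend_responses <- function() {
  c("n_rare", "n_singletons", "fisher_alpha", "log10_richness", "log10_size")
}

response_family <- function(response) {
  switch(response,
    n_rare = ,
    n_singletons = "negative_binomial",
    log10_richness = ,
    log10_size = "gaussian",
    fisher_alpha = "gaussian_power_variance",
    stop("unknown response: ", response, call. = FALSE)
  )
}

#' Mixed-effect trend model for one biodiversity facet
#'
#' Fits `y ~ centered_year` with a random intercept and random slope per
#' assemblage, estimating one overall slope (per-year change on the link
#' scale) plus per-assemblage slopes (overall slope + conditional mode of the
#' random slope deviation). The family follows the response:
#'
#' * `n_rare`, `n_singletons`: negative binomial (log link, mean-dispersion
#'   parameterization `Var = mu + mu^2/theta`), fit by maximum likelihood with
#'   the Laplace approximation (glmmTMB).
#' * `log10_richness`, `log10_size`: Gaussian on the log10-transformed metric
#'   (glmmTMB).
#' * `fisher_alpha`: Gaussian with a power-of-fitted-values residual variance
#'   `Var(e) = sigma^2 * |fitted|^(2*delta)` (nlme::lme with `varPower`),
#'   absorbing the larger residual spread of assemblages with high alpha.
#'
#' The random intercept-slope covariance is unstructured by default; if the
#' fit is singular or fails to converge it falls back to independent intercept
#' and slope with a warning, recorded in the fit object. `"none"` drops the
#' random effects entirely (an ordinary GLM/GLS), which is mainly useful for
#' equivalence checks.
#'
#' @param metrics Metrics tibble from [summarize_years()], one iteration only.
#' @param response One of `trend_responses()`.
#' @param random_effects `"unstructured"` (default), `"diagonal"`, or
#'   `"none"`.
#' @param conf_level Confidence level for the Wald interval on the overall
#'   slope (default 0.95).
#' @return An object of class `"trend_fit"`: a list with elements `response`,
#'   `family`, `beta0`, `beta1`, `se_beta1`, `interval95` (named lower/upper),
#'   `dispersion`, `random_effect_sd` (sd_intercept, sd_slope, correlation),
#'   `assemblage_slopes` (named vector, beta1 + conditional mode),
#'   `assemblage_slope_sd` (conditional SDs of the slope deviations),
#'   `n_assemblages`, `n_obs`, `convergence` (list: `converged`, `fallback`,
#'   `boundary`, `messages`) and the underlying `model`.
#' @examples
#' \donttest{
#' scn <- generate_scenario(scenario_preset("immigration",
#'   n_assemblages = 10, n_years = 12, seed = 1))
#' met <- summarize_years(rarefy(filter_years(scn$records), seed = 1))
#' fit <- fit_trend(met, "n_rare")
#' fit$beta1
#' }
#' @export
fit_trend <- function(metrics,
                      response = trend_responses(),
                      random_effects = c("unstructured", "diagonal", "none"),
                      conf_level = 0.95) {
  response <- match.arg(response)
  random_effects <- match.arg(random_effects)
  if ("iteration" %in% names(metrics) &&
      dplyr::n_distinct(metrics$iteration) > 1) {
    stop("metrics contain multiple rarefaction iterations; ",
         "fit one iteration at a time", call. = FALSE)
  }
  dat <- data.frame(
    assemblage_id = factor(metrics$assemblage_id),
    centered_year = metrics$centered_year,
    y = switch(response,
      n_rare = metrics$n_rare,
      n_singletons = metrics$n_singletons,
      fisher_alpha = metrics$fisher_alpha,
      log10_richness = log10(metrics$richness_S),
      log10_size = log10(metrics$size_N)
    )
  )
  if (anyNA(dat$y)) {
    message(sum(is.na(dat$y)), " year(s) with missing ", response, " dropped")
    dat <- dat[!is.na(dat$y), ]
    dat$assemblage_id <- droplevels(dat$assemblage_id)
  }
  if (random_effects != "none") {
    if (nlevels(dat$assemblage_id) < 2) {
      stop("precondition error: mixed trend models need >= 2 assemblages",
           call. = FALSE)
    }
    yrs <- tapply(dat$centered_year, dat$assemblage_id,
                  function(v) length(unique(v)))
    if (any(yrs < 2)) {
      stop("precondition error: every assemblage needs >= 2 distinct years",
           call. = FALSE)
    }
  }
  family <- response_family(response)
  if (stats::var(dat$y) == 0) {
    # constant response: the exact-fit ML limit is a flat line with zero
    # residual variance, so the slope is identically 0
    warning("response is constant; returning a degenerate zero-slope fit",
            call. = FALSE)
    ids <- levels(dat$assemblage_id)
    fit <- list(
      beta0 = dat$y[1], beta1 = 0, se_beta1 = 0,
      interval95 = c(lower = 0, upper = 0),
      dispersion = list(sigma = 0),
      random_effect_sd = c(sd_intercept = 0, sd_slope = 0, correlation = 0),
      assemblage_slopes = setNames(rep(0, length(ids)), ids),
      assemblage_slope_sd = setNames(rep(0, length(ids)), ids),
      convergence = list(converged = TRUE, fallback = FALSE,
                         structure = "degenerate", boundary = TRUE,
                         messages = "constant response"),
      model = NULL
    )
    fit$response <- response
    fit$family <- family
    fit$n_obs <- nrow(dat)
    fit$n_assemblages <- nlevels(dat$assemblage_id)
    class(fit) <- "trend_fit"
    return(fit)
  }
  fit <- if (family == "gaussian_power_variance") {
    fit_lme_power(dat, random_effects, conf_level)
  } else {
    fit_glmmtmb(dat, family, random_effects, conf_level)
  }
  fit$response <- response
  fit$family <- family
  fit$n_obs <- nrow(dat)
  fit$n_assemblages <- nlevels(dat$assemblage_id)
  class(fit) <- "trend_fit"
  fit
}

fit_glmmtmb <- function(dat, family, random_effects, conf_level) {
  fam <- if (family == "negative_binomial") glmmTMB::nbinom2() else gaussian()
  forms <- list(
    unstructured = y ~ centered_year + (centered_year | assemblage_id),
    diagonal = y ~ centered_year + (centered_year || assemblage_id),
    intercept_only = y ~ centered_year + (1 | assemblage_id),
    none = y ~ centered_year
  )
  chain <- forms[seq(match(random_effects, names(forms)), length(forms))]
  msgs <- character()
  one_fit <- function(f) {
    withCallingHandlers(
      glmmTMB::glmmTMB(f, data = dat, family = fam),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }
  # a fit is usable when the fixed effects and their SEs are finite; variance
  # components at the boundary (non-pd Hessian) are tolerated with a warning
  usable <- function(m) {
    if (anyNA(glmmTMB::fixef(m)$cond)) return(FALSE)
    V <- try(vcov(m)$cond, silent = TRUE)
    !inherits(V, "try-error") && all(is.finite(V))
  }
  m <- NULL
  structure_used <- random_effects
  for (nm in names(chain)) {
    cand <- try(one_fit(chain[[nm]]), silent = TRUE)
    if (!inherits(cand, "try-error") && usable(cand)) {
      m <- cand
      structure_used <- nm
      break
    }
  }
  if (is.null(m)) {
    stop("trend model failed to converge for every random-effect structure; ",
         paste(unique(msgs), collapse = "; "), call. = FALSE)
  }
  fallback <- structure_used != random_effects
  if (fallback) {
    warning("random-effect structure '", random_effects,
            "' gave an unstable fit; fell back to '", structure_used, "'",
            call. = FALSE)
  }
  boundary <- !isTRUE(m$sdr$pdHess) || m$fit$convergence != 0
  if (boundary) {
    warning("variance parameters at or near the boundary; ",
            "random-effect SEs may be unreliable", call. = FALSE)
  }
  beta <- glmmTMB::fixef(m)$cond
  V <- vcov(m)$cond
  se1 <- sqrt(V["centered_year", "centered_year"])
  z <- qnorm(1 - (1 - conf_level) / 2)
  re_sd <- c(sd_intercept = NA_real_, sd_slope = NA_real_,
             correlation = NA_real_)
  ids <- levels(dat$assemblage_id)
  slopes <- setNames(rep(unname(beta["centered_year"]), length(ids)), ids)
  slope_sd <- setNames(rep(0, length(ids)), ids)
  if (structure_used != "none") {
    vc <- glmmTMB::VarCorr(m)$cond$assemblage_id
    sds <- attr(vc, "stddev")
    corr <- attr(vc, "correlation")
    re_sd <- c(
      sd_intercept = unname(sds["(Intercept)"]),
      sd_slope = if (structure_used == "intercept_only") 0
        else unname(sds["centered_year"]),
      correlation = if (structure_used == "unstructured")
        unname(corr["(Intercept)", "centered_year"]) else 0
    )
    if (structure_used != "intercept_only") {
      re <- as.data.frame(glmmTMB::ranef(m))
      re <- re[re$term == "centered_year", ]
      sl <- setNames(beta["centered_year"] + re$condval,
                     as.character(re$grp))
      sd_ <- setNames(re$condsd, as.character(re$grp))
      slopes[names(sl)] <- sl
      slope_sd[names(sd_)] <- ifelse(is.finite(sd_), sd_, 0)
    }
  }
  list(
    beta0 = unname(beta["(Intercept)"]),
    beta1 = unname(beta["centered_year"]),
    se_beta1 = unname(se1),
    interval95 = c(lower = unname(beta["centered_year"] - z * se1),
                   upper = unname(beta["centered_year"] + z * se1)),
    dispersion = if (family == "negative_binomial") {
      list(theta = stats::sigma(m))
    } else {
      list(sigma = stats::sigma(m))
    },
    random_effect_sd = re_sd,
    assemblage_slopes = slopes,
    assemblage_slope_sd = slope_sd,
    convergence = list(converged = m$fit$convergence == 0,
                       fallback = fallback, structure = structure_used,
                       boundary = boundary, messages = unique(msgs)),
    model = m
  )
}

fit_lme_power <- function(dat, random_effects, conf_level) {
  ctrl <- nlme::lmeControl(maxIter = 200, msMaxIter = 200, niterEM = 50,
                           returnObject = FALSE)
  if (random_effects == "none") {
    m <- nlme::gls(y ~ centered_year, data = dat,
                   weights = nlme::varPower(form = ~ fitted(.)))
    beta <- coef(m)
    V <- vcov(m)
    se1 <- sqrt(V["centered_year", "centered_year"])
    z <- qnorm(1 - (1 - conf_level) / 2)
    ids <- levels(dat$assemblage_id)
    return(list(
      beta0 = unname(beta["(Intercept)"]),
      beta1 = unname(beta["centered_year"]),
      se_beta1 = unname(se1),
      interval95 = c(lower = unname(beta["centered_year"] - z * se1),
                     upper = unname(beta["centered_year"] + z * se1)),
      dispersion = list(sigma = m$sigma,
                        delta = unname(coef(m$modelStruct$varStruct,
                                            unconstrained = FALSE))),
      random_effect_sd = c(sd_intercept = NA_real_, sd_slope = NA_real_,
                           correlation = NA_real_),
      assemblage_slopes = setNames(
        rep(unname(beta["centered_year"]), length(ids)), ids),
      assemblage_slope_sd = setNames(rep(0, length(ids)), ids),
      convergence = list(converged = TRUE, fallback = FALSE,
                         boundary = FALSE, messages = character()),
      model = m
    ))
  }
  random <- list(
    unstructured = stats::as.formula("~ centered_year | assemblage_id"),
    diagonal = nlme::pdDiag(~ centered_year)
  )
  one_fit <- function(r) {
    nlme::lme(y ~ centered_year, random = r, data = dat,
              weights = nlme::varPower(form = ~ fitted(.)),
              control = ctrl, method = "REML")
  }
  fallback <- FALSE
  m <- try(suppressWarnings(one_fit(random$unstructured)), silent = TRUE)
  if (inherits(m, "try-error") && random_effects == "unstructured") {
    m <- try(suppressWarnings(one_fit(random$diagonal)), silent = TRUE)
    if (!inherits(m, "try-error")) {
      warning("unstructured random-effect covariance failed to converge; ",
              "falling back to independent intercept and slope",
              call. = FALSE)
      fallback <- TRUE
    }
  } else if (random_effects == "diagonal") {
    m <- try(suppressWarnings(one_fit(random$diagonal)), silent = TRUE)
  }
  if (inherits(m, "try-error")) {
    stop("power-variance trend model failed to converge: ",
         attr(m, "condition")$message, call. = FALSE)
  }
  beta <- nlme::fixef(m)
  V <- vcov(m)
  se1 <- sqrt(V["centered_year", "centered_year"])
  z <- qnorm(1 - (1 - conf_level) / 2)
  delta <- unname(coef(m$modelStruct$varStruct, unconstrained = FALSE))
  G <- as.matrix(nlme::getVarCov(m))
  sds <- sqrt(diag(G))
  corr <- if (fallback) 0 else G[1, 2] / prod(sds)
  re <- nlme::ranef(m)
  slopes <- setNames(unname(beta["centered_year"] + re[["centered_year"]]),
                     rownames(re))
  # conditional covariance of (b0, b1) per group:
  # C_i = (Z_i' R_i^-1 Z_i + G^-1)^-1 with R_i = sigma^2 |fitted|^(2 delta)
  fit_vals <- fitted(m)
  sigma2 <- m$sigma^2
  Ginv <- solve(G)
  slope_sd <- vapply(rownames(re), function(a) {
    idx <- dat$assemblage_id == a
    Zi <- cbind(1, dat$centered_year[idx])
    Ri <- sigma2 * abs(fit_vals[idx])^(2 * delta)
    Ci <- solve(crossprod(Zi, Zi / Ri) + Ginv)
    sqrt(Ci[2, 2])
  }, numeric(1))
  list(
    beta0 = unname(beta["(Intercept)"]),
    beta1 = unname(beta["centered_year"]),
    se_beta1 = unname(se1),
    interval95 = c(lower = unname(beta["centered_year"] - z * se1),
                   upper = unname(beta["centered_year"] + z * se1)),
    dispersion = list(sigma = m$sigma, delta = delta),
    random_effect_sd = c(sd_intercept = unname(sds[1]),
                         sd_slope = unname(sds[2]),
                         correlation = unname(corr)),
    assemblage_slopes = slopes,
    assemblage_slope_sd = slope_sd,
    convergence = list(converged = TRUE, fallback = fallback,
                       boundary = FALSE, messages = character()),
    model = m
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Trend fit:", x$response, "(", x$family, ")\n")
  cat(sprintf("  overall slope: %.5f  95%% CI [%.5f, %.5f]\n",
              x$beta1, x$interval95[["lower"]], x$interval95[["upper"]]))
  cat(sprintf("  assemblages: %d  observations: %d\n",
              x$n_assemblages, x$n_obs))
  if (x$convergence$fallback) {
    cat("  note: diagonal random-effect fallback used\n")
  }
  invisible(x)
}

#' Per-assemblage trend slopes from a fitted model
#'
#' Returns `beta1 + b1_i` for every assemblage in the training data, where
#' `b1_i` is the conditional mode (BLUP) of that assemblage's random slope
#' deviation.
#'
#' @param fit A `"trend_fit"` object.
#' @return Named numeric vector of per-assemblage slopes.
#' @export
extract_assemblage_slopes <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  fit$assemblage_slopes
}

#' Classify per-assemblage trends as positive, negative or indeterminate
#'
#' An assemblage's slope is `positive` if its 95% interval lies entirely above
#' zero, `negative` if entirely below, and `indeterminate` otherwise. The
#' interval combines the Wald SE of the overall slope with the conditional SD
#' of the assemblage's random slope deviation (treated as independent).
#'
#' @param fit A `"trend_fit"` object.
#' @param conf_level Interval level (default 0.95).
#' @return A tibble with columns `assemblage_id`, `slope`, `lower`, `upper`,
#'   `trend` (factor: positive / negative / indeterminate).
#' @export
classify_assemblage_trends <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "trend_fit"))
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(fit$se_beta1^2 + fit$assemblage_slope_sd^2)
  lower <- fit$assemblage_slopes - z * se
  upper <- fit$assemblage_slopes + z * se
  tibble::tibble(
    assemblage_id = names(fit$assemblage_slopes),
    slope = unname(fit$assemblage_slopes),
    lower = unname(lower),
    upper = unname(upper),
    trend = factor(
      ifelse(lower > 0, "positive", ifelse(upper < 0, "negative",
                                           "indeterminate")),
      levels = c("positive", "negative", "indeterminate")
    )
  )
}

#' Interpret a log10-scale slope as a yearly multiplicative change
#'
#' A mixed-model slope `b` fitted on a log10-transformed response corresponds
#' to a multiplicative change of `10^b` per year; e.g. a slope of 0.0007 is a
#' factor 1.002, i.e. +0.2% per year.
#'
#' @param slope Numeric slope(s) on the log10 scale.
#' @param digits Rounding applied to the ratio for reporting (default 3).
#' @return Numeric vector of per-year ratios.
#' @examples
#' slope_to_ratio(c(0.0007, 0.0043))
#' @export
slope_to_ratio <- function(slope, digits = 3) {
  round(10^slope, digits)
}
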
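# Independent oracles, kept deliberately separate from the package's own code
# paths: bisection for Fisher's alpha, brute-force enumeration for the runs
# test, and a log-series community sampler.

# bisection on S - a*ln(1 + N/a) over a in (1e-9, 1e6)
oracle_fisher_alpha <- function(S, N) {
  f <- function(a) S - a * log(1 + N / a)
  lo <- 1e-9
  hi <- 1e6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# exact two-sided runs-test p by enumerating all C(n, n1) arrangements:
# the fraction of arrangements whose run count is at least as far from E[R]
# as the observed one
oracle_runs_exact <- function(v) {
  n <- length(v)
  n1 <- sum(v == 1L)
  n0 <- n - n1
  if (n0 == 0 || n1 == 0) return(NA_real_)
  ER <- 1 + 2 * n1 * n0 / n
  R_obs <- 1 + sum(diff(v) != 0L)
  pos <- utils::combn(n, n1)
  Rs <- apply(pos, 2, function(idx) {
    w <- integer(n)
    w[idx] <- 1L
    1 + sum(diff(w) != 0L)
  })
  mean(abs(Rs - ER) >= abs(R_obs - ER) - 1e-12)
}

# one random log-series community: species counts at abundance k arrive as
# Poisson(alpha * x^k / k), the expected-frequencies form of the model
oracle_logseries_community <- function(alpha, x, kmax = 5000) {
  k <- seq_len(kmax)
  mu <- alpha * x^k / k
  n_sp <- rpois(kmax, mu)
  rep(k, n_sp)
}

# small records builder
make_records <- function(assemblage_id, year, sample_id, species_id,
                         abundance) {
  tibble::tibble(assemblage_id = as.character(assemblage_id),
                 year = as.integer(year),
                 sample_id = as.character(sample_id),
                 species_id = as.character(species_id),
                 abundance = abundance)
}

# balanced mixed-model metrics table simulated from the model's own
# generative form (used by trend-model recovery tests)
simulate_metrics <- function(n_assemblages, n_years, beta0, beta1,
                             sd_int, sd_slope, family = c("nb", "gaussian"),
                             theta = 5, sigma = 0.05, seed = 1) {
  family <- match.arg(family)
  withr::with_seed(seed, {
    ids <- sprintf("A%03d", seq_len(n_assemblages))
    yrs <- 2000 + seq_len(n_years)
    met <- expand.grid(assemblage_id = ids, year = yrs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    met$centered_year <- met$year - mean(yrs)
    b0 <- rnorm(n_assemblages, 0, sd_int)
    b1 <- rnorm(n_assemblages, 0, sd_slope)
    i <- match(met$assemblage_id, ids)
    eta <- beta0 + b0[i] + (beta1 + b1[i]) * met$centered_year
    met$n_singletons <- 1L
    met$fisher_alpha <- 5
    if (family == "nb") {
      met$n_rare <- rnbinom(nrow(met), mu = exp(eta), size = theta)
      met$richness_S <- met$n_rare + 10L
      met$size_N <- met$richness_S * 10L
    } else {
      met$n_rare <- 5L
      met$richness_S <- pmax(1, round(10^(eta + rnorm(nrow(met), 0, sigma))))
      met$size_N <- met$richness_S * 10L
    }
    tibble::as_tibble(met)
  })
}
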
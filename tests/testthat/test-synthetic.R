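test_that("identical configs generate identical records", {
  cfg <- scenario_preset("immigration", n_assemblages = 3, n_years = 8,
                         seed = 21)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$trajectories, b$truth$trajectories)
  c_ <- generate_scenario(scenario_preset("immigration", n_assemblages = 3,
                                          n_years = 8, seed = 22))
  expect_false(identical(a$records, c_$records))
})

test_that("emitted records conform to the ingestion schema", {
  scn <- generate_scenario(scenario_preset("decline_extinction",
                                           n_assemblages = 3, n_years = 8,
                                           seed = 2))
  rec <- scn$records
  expect_true(all(c("assemblage_id", "year", "sample_id", "species_id",
                    "abundance") %in% names(rec)))
  expect_true(all(rec$abundance >= 1))
  expect_true(all(rec$abundance == floor(rec$abundance)))
  # clean ingestion: no warnings, nothing dropped
  expect_no_warning(clean <- as_assemblage_records(rec))
  expect_equal(sum(clean$abundance), sum(rec$abundance))
})

test_that("ground truth is internally consistent with the records", {
  scn <- generate_scenario(scenario_preset("immigration", n_assemblages = 4,
                                           n_years = 12, seed = 31,
                                           immigration_rate = 1))
  sp <- scn$truth$species
  lam <- scn$truth$lambda
  imm <- sp[!is.na(sp$arrival_year), ]
  expect_gt(nrow(imm), 0)
  # immigrants have zero latent abundance before their arrival year
  pre <- dplyr::inner_join(lam, imm,
                           by = c("assemblage_id", "species_id")) |>
    dplyr::filter(year < arrival_year)
  expect_true(all(pre$lambda == 0))
  # no observed individuals before arrival either
  obs <- dplyr::inner_join(scn$records, imm,
                           by = c("assemblage_id", "species_id"))
  expect_true(all(obs$year >= obs$arrival_year))
})

test_that("trend-driven extinction zeroes latent abundance permanently", {
  scn <- generate_scenario(scenario_preset("decline_extinction",
                                           n_assemblages = 3, n_years = 15,
                                           seed = 5))
  sp <- scn$truth$species
  ext <- sp[!is.na(sp$extinction_year), ]
  expect_gt(nrow(ext), 0)
  post <- dplyr::inner_join(scn$truth$lambda, ext,
                            by = c("assemblage_id", "species_id")) |>
    dplyr::filter(year >= extinction_year)
  expect_true(all(post$lambda == 0))
})

test_that("scenario presets realize their intended trajectory logic", {
  ts_of <- function(name) {
    truth_slopes(generate_scenario(scenario_preset(name, n_assemblages = 30,
                                                   n_years = 15, seed = 6)))
  }
  # declines without extinction: rarity up, richness exactly flat, size down
  d <- ts_of("population_decline")
  expect_gt(mean(d$rarity_slope), 0)
  expect_true(all(d$richness_slope == 0))
  expect_lt(mean(d$size_slope), 0)
  # declines with extinction: richness and size jointly negative
  e <- ts_of("decline_extinction")
  expect_lt(mean(e$richness_slope), 0)
  expect_lt(mean(e$size_slope), 0)
  # immigration: rarity, richness and size all increase, rarity with richness
  i <- ts_of("immigration")
  expect_gt(mean(i$rarity_slope), 0)
  expect_gt(mean(i$richness_slope), 0)
  expect_gt(mean(i$size_slope), 0)
  expect_gt(cor(i$rarity_slope, i$richness_slope), 0)
})

test_that("multinomial observation fixes yearly totals at round(sum(lambda))", {
  scn <- generate_scenario(scenario_preset("immigration", n_assemblages = 2,
                                           n_years = 5, seed = 3,
                                           obs_model = "multinomial"))
  tot <- scn$records |>
    dplyr::group_by(assemblage_id, year) |>
    dplyr::summarise(n = sum(abundance), .groups = "drop")
  lamtot <- scn$truth$lambda |>
    dplyr::group_by(assemblage_id, year) |>
    dplyr::summarise(expect = round(sum(lambda)), .groups = "drop")
  cmp <- dplyr::inner_join(tot, lamtot, by = c("assemblage_id", "year"))
  expect_equal(cmp$n, cmp$expect)
})

test_that("constructed presence strings carry recoverable labels", {
  # all-persistent spec: trivially perfect accuracy
  fx <- generate_population_strings(50, prob = c(persistent = 1),
                                    length = 20, seed = 1)
  cl <- vapply(fx$presence, function(s) classify_population(s)$category,
               character(1))
  expect_true(all(cl == "persistent"))
  # balanced labels at length 20: the gate passes by construction
  fx2 <- generate_population_strings(200, length = 20, seed = 9)
  cl2 <- vapply(fx2$presence, function(s) classify_population(s)$category,
                character(1))
  expect_gte(mean(cl2 == fx2$label), 0.95)
  # length-4 single-switch strings fall below runs-test significance
  expect_equal(classify_population("0011")$category, "persistent")
  expect_gte(runs_test("0011"), 0.05)
})

test_that("expected rarity slopes track the immigration calibration", {
  scn <- generate_scenario(scenario_preset("immigration", n_assemblages = 20,
                                           n_years = 20, seed = 4))
  es <- expected_rarity_slope(scn)
  expect_equal(nrow(es), 20)
  # immigration at the preset rate yields a positive trend of roughly 1%/yr
  expect_gt(mean(es$expected_slope), 0)
  expect_equal(mean(es$expected_slope), 0.01, tolerance = 0.5)
})
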
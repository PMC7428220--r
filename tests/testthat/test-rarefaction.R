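effort_records <- function(per_year) {
  # one species, one record per occasion
  purrr::imap(per_year, function(n, yr) {
    make_records("A", as.integer(yr), paste0("s", seq_len(n)), "sp1", 1)
  }) |> purrr::list_rbind()
}

test_that("years with fewer than half the mean occasions are excluded", {
  # {4, 4, 1}: mean 3, threshold 1.5 -> 2002 excluded
  f <- filter_years(effort_records(c("2000" = 4, "2001" = 4, "2002" = 1)))
  expect_equal(sort(unique(f$year)), c(2000L, 2001L))
  expect_equal(attr(f, "excluded_years")$year, 2002L)

  # {2, 2}: threshold 1, both retained
  f <- filter_years(effort_records(c("2000" = 2, "2001" = 2)))
  expect_equal(sort(unique(f$year)), c(2000L, 2001L))

  # {10, 5, 5, 4}: mean 6, threshold 3, all retained
  f <- filter_years(effort_records(c("2000" = 10, "2001" = 5, "2002" = 5,
                                     "2003" = 4)))
  expect_equal(dplyr::n_distinct(f$year), 4)
  # the tie (count == threshold) is retained
  f <- filter_years(effort_records(c("2000" = 4, "2001" = 2)))
  expect_equal(dplyr::n_distinct(f$year), 2)
})

test_that("rarefaction keeps whole occasions and is deterministic", {
  rec <- dplyr::bind_rows(
    make_records("A", 2000, c("s1", "s1", "s2", "s2", "s3"),
                 c("sp1", "sp2", "sp1", "sp3", "sp1"), c(2, 1, 3, 1, 1)),
    make_records("A", 2001, c("s1", "s1", "s2"),
                 c("sp1", "sp2", "sp2"), c(4, 2, 1))
  )
  r1 <- rarefy(rec, seed = 11)
  # n_min = 2: every year contributes exactly 2 whole occasions
  plan <- attr(r1, "plan")
  expect_equal(attr(r1, "n_min")$n_min, 2L)
  expect_equal(unname(table(plan$year)), array(c(2L, 2L)))
  # the year attaining the minimum keeps all its occasions
  expect_setequal(plan$sample_id[plan$year == 2001], c("s1", "s2"))
  # occasion integrity: 2001 sums are the full within-year species sums
  y2 <- r1[r1$year == 2001, ]
  expect_equal(stats::setNames(y2$abundance, y2$species_id),
               c(sp1 = 4, sp2 = 3))
  # rarefied sums never exceed raw within-year sums
  raw <- rec |>
    dplyr::group_by(year, species_id) |>
    dplyr::summarise(raw = sum(abundance), .groups = "drop")
  cmp <- dplyr::inner_join(r1, raw, by = c("year", "species_id"))
  expect_true(all(cmp$abundance <= cmp$raw))
  # determinism
  expect_equal(rarefy(rec, seed = 11), r1, ignore_attr = TRUE)
  # single-occasion years: rarefaction is the identity on species sums
  one <- make_records("A", c(2000, 2000, 2001), "s1",
                      c("sp1", "sp2", "sp1"), c(5, 1, 2))
  r_one <- rarefy(one, seed = 3)
  expect_equal(sum(r_one$abundance), sum(one$abundance))
})

test_that("centered years are centred on the retained years per assemblage", {
  scn <- generate_scenario(scenario_preset("immigration", n_assemblages = 4,
                                           n_years = 8, seed = 5))
  r <- rarefy(filter_years(scn$records), seed = 2)
  cs <- tapply(r$centered_year[!duplicated(paste(r$assemblage_id, r$year))],
               r$assemblage_id[!duplicated(paste(r$assemblage_id, r$year))],
               sum)
  expect_true(all(abs(cs) < 1e-9))
})

test_that("repeated rarefaction derives per-iteration seeds deterministically", {
  rec <- dplyr::bind_rows(
    make_records("A", 2000, paste0("s", 1:3), "sp1", c(1, 2, 3)),
    make_records("A", 2001, paste0("s", 1:2), "sp1", c(4, 5))
  )
  it1 <- rarefy_iterations(rec, n_iterations = 1, base_seed = 99)
  direct <- rarefy(rec, iteration_seed(99, 1))
  expect_equal(dplyr::select(it1, -iteration), direct, ignore_attr = TRUE)

  # equal effort in every year: nothing is subsampled, all iterations equal
  eq <- dplyr::bind_rows(
    make_records("A", 2000, paste0("s", 1:2), c("sp1", "sp2"), c(1, 2)),
    make_records("A", 2001, paste0("s", 1:2), c("sp1", "sp2"), c(3, 4))
  )
  its <- rarefy_iterations(eq, n_iterations = 20, base_seed = 1)
  per_it <- split(dplyr::select(its, -iteration), its$iteration)
  expect_true(all(vapply(per_it, identical, logical(1), y = per_it[[1]])))

  # unequal effort: retained years and n_min constant, totals vary
  scn <- generate_scenario(scenario_preset("immigration", n_assemblages = 2,
                                           n_years = 6, seed = 8,
                                           samples_per_year = c(1, 4)))
  f <- filter_years(scn$records)
  its <- rarefy_iterations(f, n_iterations = 10, base_seed = 4)
  yrs <- tapply(its$year, its$iteration, function(y) sort(unique(y)))
  expect_true(all(vapply(yrs, identical, logical(1), y = yrs[[1]])))
  totals <- tapply(its$abundance, its$iteration, sum)
  expect_gt(length(unique(totals)), 1)
})
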
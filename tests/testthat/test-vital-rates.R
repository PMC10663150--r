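test_that("counts convert to rates per 1,000 with guarded denominators", {
  counts <- data.frame(unit_id = 1:3, country_id = 1, year = 2000,
                       rate_type = "birth", events = c(200, 0, 125))
  pop <- data.frame(unit_id = 1:3, year = 2000,
                    population = c(1e4, 5e3, 1e5))
  rs <- counts_to_rates(counts, pop)
  expect_equal(rs$value, c(20, 0, 1.25))
  pop$population[1] <- 0
  expect_error(counts_to_rates(counts, pop), "zero population")
})

test_that("combine pools events over pooled population", {
  s <- rate_rows(c(1, 2), 2000, c(40, 10), c(1e3, 99e3))
  ctx <- gapfill_context(combine_registry = data.frame(
    small_unit_id = 1, host_unit_id = 2))
  out <- apply_combine(s, ctx)
  expect_equal(out$value, c(10.3, 10.3))
  expect_equal(out$source_flag, c("combined", "combined"))
  # identical rates are invariant under pooling
  s2 <- rate_rows(c(1, 2), 2000, c(12, 12), c(1e3, 99e3))
  expect_equal(apply_combine(s2, ctx)$value, c(12, 12))
  # empty registry is the identity
  expect_identical(apply_combine(s, gapfill_context()), s)
  # missing host data errors
  expect_error(apply_combine(rate_rows(1, 2000, 40, 1e3), ctx), "host")
})

test_that("split backcast reproduces the ratio arithmetic", {
  # children report from 2014; parent (id 9) reported 12 in 2013
  s <- rbind(rate_rows(9, 2013, 12, 4e5),
             rate_rows(c(1, 2), 2014, c(20, 10), c(1e5, 3e5)))
  ctx <- gapfill_context(split_registry = data.frame(
    parent_id = 9, child_id = c(1, 2), split_year = 2014))
  out <- apply_split_backcast(s, ctx)
  expect_false(9 %in% out$unit_id)
  back <- out[out$year == 2013, ]
  back <- back[order(back$unit_id), ]
  # combined = (1e5*20 + 3e5*10)/4e5 = 12.5; ratios 1.6, 0.8
  expect_equal(back$value, c(1.6 * 12, 0.8 * 12))
  expect_equal(back$source_flag, rep("split_backcast", 2))
  # re-aggregating back-cast children with first-year weights returns parent
  expect_equal(sum(back$value * c(1e5, 3e5)) / 4e5, 12)
})

test_that("split backcast with equal child rates copies the parent rate", {
  s <- rbind(rate_rows(9, 2013, 14, 4e5),
             rate_rows(c(1, 2), 2014, c(11, 11), c(1e5, 3e5)))
  ctx <- gapfill_context(split_registry = data.frame(
    parent_id = 9, child_id = c(1, 2), split_year = 2014))
  out <- apply_split_backcast(s, ctx)
  expect_equal(out$value[out$year == 2013], c(14, 14))
})

test_that("partial fill scales by the least-difference neighbour", {
  # unit 1 misses 2001; neighbours 2 (close rate) and 3 (far rate)
  s <- rbind(rate_rows(1, 2000, 10, 1e4),
             rate_rows(2, c(2000, 2001), c(20, 22), 1e4),
             rate_rows(3, c(2000, 2001), c(50, 60), 1e4))
  ctx <- gapfill_context(neighbour_graph = list("1" = c(2L, 3L),
                                                "2" = 1L, "3" = 1L))
  out <- fill_partial(s, ctx, years = 2000:2001)
  filled <- out[out$unit_id == 1 & out$year == 2001, ]
  expect_equal(filled$value, 10 / 20 * 22)   # 11.0
  expect_equal(filled$source_flag, "neighbour_scaled")
  # a neighbour constant in time reproduces the unit's reference value
  s2 <- rbind(rate_rows(1, 2000, 10, 1e4),
              rate_rows(2, c(2000, 2001), c(20, 20), 1e4))
  out2 <- fill_partial(s2, gapfill_context(neighbour_graph =
                                             list("1" = 2L, "2" = 1L)),
                       years = 2000:2001)
  expect_equal(out2$value[out2$unit_id == 1 & out2$year == 2001], 10)
})

test_that("national fallback copies the national series only for dataless
           units", {
  nat <- data.frame(country_id = 1, year = rep(2000:2002, 2),
                    rate_type = rep(c("birth", "death"), each = 3),
                    value = 15)
  units <- data.frame(unit_id = 1:2, country_id = 1)
  upop <- data.frame(unit_id = rep(1:2, each = 3),
                     year = rep(2000:2002, 2), population = 1e4)
  s <- rate_rows(1, 2000:2002, c(9, 10, 11), 1e4)
  out <- fill_national(s, nat, units, upop)
  got <- out[out$unit_id == 2, ]
  expect_equal(nrow(got), 6)
  expect_true(all(got$value == 15))
  expect_true(all(got$source_flag == "national_fallback"))
  expect_equal(out[out$unit_id == 1, ], s, ignore_attr = TRUE)
  # two dataless units in one country end up identical
  out2 <- fill_national(s[0, ], nat, units, upop)
  expect_equal(out2$value[out2$unit_id == 1], out2$value[out2$unit_id == 2])
})

test_that("interior gaps interpolate linearly; edges follow the macro trend
           multiplicatively", {
  region_map <- data.frame(country_id = 1, region_id = 1)
  # flat trend: extrapolated years equal the edge value
  flat <- data.frame(region_id = 1, year = 2014:2018, rate_type = "birth",
                     trend_value = 8)
  s <- rate_rows(1, c(2015, 2017), c(10, 20), 1e4)
  out <- interpolate_extrapolate(s, flat, region_map, 2014:2018)
  expect_equal(out$value[out$year == 2016], 15)
  expect_equal(out$value[out$year == 2014], 10)
  expect_equal(out$value[out$year == 2018], 20)
  # declining trend, 2 %/yr: 10 -> 9.8 -> 9.604
  dec <- data.frame(region_id = 1, year = 2015:2017, rate_type = "birth",
                    trend_value = 8 * 0.98^(0:2))
  s2 <- rate_rows(1, 2015, 10, 1e4)
  out2 <- interpolate_extrapolate(s2, dec, region_map, 2015:2017)
  expect_equal(out2$value[out2$year == 2016], 9.8)
  expect_equal(out2$value[out2$year == 2017], 9.604)
})

test_that("macro trends are population-weighted over full-coverage
           countries", {
  nat <- data.frame(country_id = rep(1:3, each = 2),
                    year = rep(2000:2001, 3), rate_type = "birth",
                    value = c(10, 12, 20, 24, 99, NA))
  nat <- nat[!is.na(nat$value), ]   # country 3 lacks 2001 -> not full
  region_map <- data.frame(country_id = 1:3, region_id = 1)
  npop <- data.frame(country_id = rep(1:3, each = 2),
                     year = rep(2000:2001, 3),
                     population = c(1e6, 1e6, 3e6, 3e6, 1e6, 1e6))
  tr <- compute_macro_trends(nat, region_map, npop, 2000:2001)
  expect_equal(tr$trend_value[tr$year == 2000], (10 * 1 + 20 * 3) / 4)
  expect_equal(tr$trend_value[tr$year == 2001], (12 * 1 + 24 * 3) / 4)
})

test_that("national bias correction forces exact national agreement", {
  s <- rate_rows(c(1, 2), 2000, c(10, 12), c(1e4, 1e4))
  rep_nat <- data.frame(country_id = 1, year = 2000, rate_type = "birth",
                        value = 10)
  out <- national_bias_correct(s, rep_nat)
  expect_equal(sum(out$value * out$population) / sum(out$population), 10)
  expect_equal(out$value, c(10, 12) * 10 / 11)
  # already-consistent series is untouched
  rep_nat$value <- 11
  expect_equal(national_bias_correct(s, rep_nat)$value, s$value)
  # single-unit country is forced to the national rate
  s1 <- rate_rows(1, 2000, 13.7, 5e4)
  rep1 <- data.frame(country_id = 1, year = 2000, rate_type = "birth",
                     value = 9.1)
  expect_equal(national_bias_correct(s1, rep1)$value, 9.1)
})

test_that("harmonization of a defect-free census changes nothing", {
  w <- tiny_world()
  res <- suppressMessages(run_pipeline(w$config,
                                       stages = c("synth", "harmonize")))
  h <- res$harmonized
  key <- paste(h$unit_id, h$year, h$rate_type)
  ckey <- paste(w$censuses$unit_id, w$censuses$year, w$censuses$rate_type)
  expect_setequal(key, ckey)
  expect_equal(h$value[match(ckey, key)], w$censuses$value,
               tolerance = 1e-12)
})

test_that("the full chain yields one nonnegative value per unit-year-type", {
  cfg <- world_config(grid_height = 24, grid_width = 24, n_countries = 4,
                      units_per_country = 4, subunits_per_unit = 2,
                      years = 2000:2005, seed = 13, rate_noise_sd = 1,
                      missingness_fractions = c(combine = 0.07,
                                                split = 0.07,
                                                partial = 0.12,
                                                absent = 0.07))
  res <- suppressMessages(run_pipeline(cfg,
                                       stages = c("synth", "harmonize")))
  h <- res$harmonized
  units <- res$world$units$unit_id
  expect_equal(nrow(h), length(units) * length(res$world$years) * 2)
  expect_false(any(duplicated(h[c("unit_id", "year", "rate_type")])))
  expect_true(all(h$value >= 0))
  expect_setequal(h$unit_id, units)
})
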
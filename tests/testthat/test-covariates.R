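test_that("delta-change correction rescales by the overlap-year ratio", {
  yrs <- 1995:1997
  early <- raster_stack(rep(c(40, 10), each = 4, times = 3), 2, 2, yrs)
  early[, , "1997"] <- matrix(c(50, 50, 12, 12), 2, 2)
  ref <- raster_stack(rep(100, 4 * 3), 2, 2, yrs)
  out <- delta_correct_population(early, ref, 1997)
  expect_equal(unname(out[1, 1, "1995"]), 40 * 100 / 50)   # factor 2
  # early == reference at overlap -> identity
  ref2 <- early
  expect_equal(delta_correct_population(early, ref2, 1997), early)
  # an all-zero early cell stays zero
  early0 <- early; early0[2, 2, ] <- 0
  out0 <- delta_correct_population(early0, ref, 1997)
  expect_equal(out0[2, 2, ], c("1995" = 0, "1996" = 0, "1997" = 0))
  expect_error(delta_correct_population(early, ref, 1980), "overlap")
})

test_that("scaled density maps the 5th/95th percentile band onto [0, 1]", {
  # one country, densities chosen so percentiles are known exactly
  h <- 10; w <- 10
  dens <- seq(1, 100, length.out = h * w)
  pop <- raster_stack(dens * 100, h, w, 2000)  # cell area 100 km2
  labs <- matrix(1L, h, w)
  sc <- scaled_population_density(pop, labs, cell_area_km2 = 100)
  q <- quantile(dens, c(0.05, 0.95), names = FALSE)
  mid <- (dens - q[1]) / (q[2] - q[1])
  expect_equal(as.vector(sc[, , 1]), pmin(pmax(mid, 0), 1))
  expect_equal(min(sc), 0)   # below-5th cells clamp to 0
  expect_equal(max(sc), 1)   # above-95th cells clamp to 1
  # invariant to a uniform rescaling of all densities
  sc2 <- scaled_population_density(pop * 3, labs, cell_area_km2 = 100)
  expect_equal(sc, sc2, tolerance = 1e-12)
  # monotone non-decreasing in raw density
  o <- order(dens)
  expect_true(all(diff(as.vector(sc[, , 1])[o]) >= 0))
})

test_that("degenerate density percentiles map cells to 0.5 with a warning", {
  pop <- raster_stack(rep(500, 8), 2, 2, 2000:2001)
  expect_warning(sc <- scaled_population_density(pop, matrix(1L, 2, 2)),
                 "degenerate")
  expect_true(all(sc == 0.5))
})

make_agesex <- function(counts_by_band, h = 1, w = 1) {
  lower <- seq(0, 80, 5); upper <- c(seq(4, 79, 5), Inf)
  bands <- data.frame(sex = rep(c("f", "m"), each = 17),
                      lower = rep(lower, 2), upper = rep(upper, 2))
  arr <- array(0, c(h, w, 34))
  for (nm in names(counts_by_band)) {
    i <- which(bands$sex == substr(nm, 1, 1) &
                 bands$lower == as.numeric(substr(nm, 3, nchar(nm))))
    arr[, , i] <- counts_by_band[[nm]]
  }
  list(counts = arr, bands = bands)
}

test_that("reproductive-women share counts female 15-49 over total", {
  # all-female population aged 20-24 -> 1
  expect_equal(reproductive_women_share(make_agesex(list(f_20 = 100)))[1, 1],
               1)
  # no females 15-49 -> 0
  expect_equal(reproductive_women_share(
    make_agesex(list(m_20 = 50, f_55 = 50)))[1, 1], 0)
  # 2,600 of 10,000 -> 0.26
  ag <- make_agesex(list(f_20 = 1300, f_45 = 1300, m_30 = 5000, f_60 = 2400))
  expect_equal(reproductive_women_share(ag)[1, 1], 0.26)
  # invariant under uniform scaling of all counts
  ag2 <- ag; ag2$counts <- ag$counts * 7
  expect_equal(reproductive_women_share(ag2),
               reproductive_women_share(ag))
})

test_that("age/life-expectancy ratio uses band midpoints and the national
           80+ mean age", {
  over80 <- data.frame(country_id = 1, sex = c("f", "m"),
                       mean_age = c(86, 86))
  labs <- matrix(1L, 1, 1)
  # everyone in band 5-9, life expectancy 70 -> 7/70
  le <- matrix(70, 1, 1)
  expect_equal(age_life_expectancy_ratio(make_agesex(list(f_5 = 10)),
                                         over80, le, labs)[1, 1], 0.1)
  # uniform counts in 0-4 and 10-14, LE 50 -> ((2+12)/2)/50
  le <- matrix(50, 1, 1)
  expect_equal(age_life_expectancy_ratio(
    make_agesex(list(m_0 = 5, m_10 = 5)), over80, le, labs)[1, 1], 0.14)
  # all in 80+ with national mean age 86 and LE 86 -> 1
  le <- matrix(86, 1, 1)
  expect_equal(age_life_expectancy_ratio(make_agesex(list(f_80 = 9)),
                                         over80, le, labs)[1, 1], 1)
})

test_that("unit aggregation supports unweighted and population weighting", {
  labs <- matrix(1L, 1, 2)
  stack <- list(x = raster_stack(c(0.2, 0.4), 1, 2, 2000))
  pop <- raster_stack(c(100, 300), 1, 2, 2000)
  un <- aggregate_covariates_to_units(stack, labs, years = 2000)
  expect_equal(un$x, 0.3)
  wt <- aggregate_covariates_to_units(stack, labs, population = pop,
                                      weighting = "population",
                                      years = 2000)
  expect_equal(wt$x, 0.35)
  # constant covariate: both weightings agree; single-cell unit: the value
  stack$x[] <- 0.7
  expect_equal(aggregate_covariates_to_units(stack, labs,
                                             years = 2000)$x, 0.7)
  expect_equal(aggregate_covariates_to_units(
    stack, matrix(c(1L, 2L), 1, 2), years = 2000)$x, c(0.7, 0.7))
})
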
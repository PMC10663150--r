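make_unit_table <- function(n, beta, noise_sd = 0, seed = 1,
                            group = "high") {
  set.seed(seed)
  d <- data.frame(group = group,
                  scaled_density = runif(n),
                  hdi = runif(n, 0.3, 0.95),
                  repro_women_share = runif(n, 0.15, 0.35))
  d$value <- beta[1] + beta[2] * d$scaled_density + beta[3] * d$hdi +
    beta[4] * d$repro_women_share + rnorm(n, 0, noise_sd)
  d
}

test_that("exact linear rates are recovered with R-squared 1", {
  beta <- c(20, -5, -12, 24)
  m <- fit_income_models(make_unit_table(60, beta), "birth")
  expect_equal(unname(m$high$coefficients), beta, tolerance = 1e-8)
  expect_equal(m$high$r_squared, 1, tolerance = 1e-10)
})

test_that("a constant rate gives intercept-only structure", {
  d <- make_unit_table(40, c(17, 0, 0, 0))
  m <- fit_income_models(d, "birth")
  expect_equal(unname(m$high$coefficients),
               c(17, 0, 0, 0), tolerance = 1e-9)
})

test_that("noisy slopes land inside the OLS sampling bound", {
  beta <- c(20, -5, -12, 24)
  m <- fit_income_models(make_unit_table(500, beta, noise_sd = 1,
                                         seed = 4), "birth")
  expect_lt(abs(m$high$coefficients[["scaled_density"]] - beta[2]), 0.5)
})

test_that("collinear predictors raise an informative error", {
  d <- make_unit_table(40, c(20, -5, -12, 24))
  d$hdi <- 2 * d$scaled_density
  expect_error(fit_income_models(d, "birth"), "collinear")
})

test_that("the mass-preserving adjustment matches the worked arithmetic", {
  # cells (R, p) = (10, 100), (20, 300), census 13
  labs <- matrix(1L, 1, 2)
  approx <- raster_stack(c(10, 20), 1, 2, 2000)
  pop <- raster_stack(c(100, 300), 1, 2, 2000)
  cen <- data.frame(unit_id = 1, year = 2000, value = 13)
  adj <- adjust_rates(approx, cen, pop, labs)
  mult <- 13 * 400 / (10 * 100 + 20 * 300)
  expect_equal(as.vector(adj[, , 1]), c(10, 20) * mult)
  expect_equal(sum(adj[, , 1] * c(100, 300)) / 400, 13)
  # already-consistent rates are untouched
  cen$value <- sum(c(10, 20) * c(100, 300)) / 400
  expect_equal(adjust_rates(approx, cen, pop, labs), approx)
  # a single-cell unit is forced to the census rate
  adj1 <- adjust_rates(raster_stack(10, 1, 1, 2000),
                       data.frame(unit_id = 1, year = 2000, value = 7.5),
                       raster_stack(50, 1, 1, 2000), matrix(1L, 1, 1))
  expect_equal(as.vector(adj1), 7.5)
})

test_that("zero-population cells keep their approximated rate and a
           zero-mass unit falls back to a uniform census rate", {
  labs <- matrix(c(1L, 1L, 2L, 2L), 1, 4)
  approx <- raster_stack(c(10, 20, 0, 0), 1, 4, 2000)
  pop <- raster_stack(c(100, 0, 50, 50), 1, 4, 2000)
  cen <- data.frame(unit_id = c(1, 2), year = 2000, value = c(12, 9))
  expect_message(adj <- adjust_rates(approx, cen, pop, labs), "fallback")
  expect_equal(unname(adj[1, 2, 1]), 20)          # p = 0: unadjusted
  expect_equal(unname(adj[1, 1, 1]), 12)          # single populated cell -> census
  expect_equal(as.vector(adj[1, 3:4, 1]), c(9, 9))   # uniform fallback
})

test_that("ATPK surfaces are coherent and constant residuals stay
           constant", {
  labs <- rbind(c(1L, 1L, 2L, 2L),
                c(1L, 1L, 2L, 2L),
                c(3L, 3L, 4L, 4L),
                c(3L, 3L, 4L, 4L))
  cent <- unit_centroids(labs)
  # constant residual c across units -> constant surface c
  resc <- data.frame(unit_id = 1:4, year = 2000, residual = 2.5)
  rf <- list(residuals = resc, centroids = cent,
             variogram = list(model = "exponential", nugget = 0.01,
                              psill = 1, range = 2))
  surf <- atpk_distribute(rf, labs)
  expect_equal(as.vector(surf[, , 1]), rep(2.5, 16), tolerance = 1e-9)
  # opposite residuals: smooth variation, unit means preserved
  res2 <- data.frame(unit_id = 1:4, year = 2000,
                     residual = c(-1, 1, 1, -1))
  rf$residuals <- res2
  surf2 <- atpk_distribute(rf, labs)
  mu <- zonal_mean(surf2[, , 1], labs)
  expect_equal(as.numeric(mu), res2$residual, tolerance = 1e-9)
  expect_gt(stats::sd(surf2[, , 1][labs == 1]), 0)   # not piecewise constant
  # degenerate variogram -> uniform within-unit fallback
  rf$variogram <- NULL
  expect_message(surf3 <- atpk_distribute(rf, labs), "fallback")
  expect_equal(as.vector(surf3[, , 1]),
               res2$residual[as.vector(labs)])
})

test_that("white-noise residuals fit a short-range variogram", {
  set.seed(10)
  cent <- expand.grid(row = seq(2, 40, 8), col = seq(2, 40, 8))
  cent <- data.frame(unit_id = seq_len(nrow(cent)), row = cent$row,
                     col = cent$col)
  res <- do.call(rbind, lapply(2000:2004, function(y)
    data.frame(unit_id = cent$unit_id, year = y,
               residual = rnorm(nrow(cent)))))
  vg <- fit_residual_variogram(res, cent)
  expect_false(is.null(vg))
  # white noise: the semivariance saturates by the first lag (spacing 8),
  # i.e. no structure persists beyond the centroid spacing
  g1 <- vg$nugget + vg$psill * (1 - exp(-8 / vg$range))
  sill <- vg$nugget + vg$psill
  expect_gt(g1 / sill, 0.6)
})

test_that("zero-noise downscaling leaves negligible areal residuals", {
  res <- zero_noise_pipeline()
  expect_lt(max(abs(
    res$downscaled$birth$residual_field$residuals$residual)), 1e-8)
  expect_lt(max(abs(
    res$downscaled$death$residual_field$residuals$residual)), 1e-8)
})
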
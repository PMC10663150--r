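# brute-force truth table for the impact criteria, written directly from the
# strict-sign definitions (order-free because the six patterns are disjoint)
impact_oracle <- function(pop_change, net_mgr_sum) {
  womgr <- pop_change - net_mgr_sum
  if (womgr > 0 && net_mgr_sum > 0) return("increases_growth")
  if (pop_change < 0 && net_mgr_sum > 0) return("slows_decline")
  if (womgr < 0 && pop_change > 0) return("turns_decline_to_growth")
  if (womgr < 0 && net_mgr_sum < 0) return("increases_decline")
  if (pop_change > 0 && net_mgr_sum < 0) return("slows_growth")
  if (womgr > 0 && pop_change < 0) return("turns_growth_to_decline")
  "negligible"
}

direction_oracle <- function(u, r) {
  if (u > 0 && r > 0) return("net_receiving")
  if (u < 0 && r < 0) return("net_sending")
  if (u < 0 && r > 0) return("rural_pull_urban_push")
  if (u > 0 && r < 0) return("urban_pull_rural_push")
  "zero"
}

test_that("impact classes match the worked sign examples", {
  # woMgr +100, mgr +50 -> migration amplifies growth
  expect_equal(as.character(impact_class(150, 50)), "increases_growth")
  # woMgr -80, mgr +100 (popChange +20) -> decline turned to growth
  expect_equal(as.character(impact_class(20, 100)),
               "turns_decline_to_growth")
  # boundary: zero migration is negligible regardless of growth
  expect_equal(as.character(impact_class(10, 0)), "negligible")
  expect_equal(as.character(impact_class(0, 0)), "negligible")
})

test_that("impact classifier agrees with the truth table over all sign
           patterns", {
  grid <- expand.grid(womgr = c(-3, -1, 0, 1, 3),
                      mgr = c(-2, -1, 0, 1, 2))
  pc <- grid$womgr + grid$mgr
  got <- as.character(impact_class(pc, grid$mgr))
  want <- mapply(impact_oracle, pc, grid$mgr)
  expect_equal(got, unname(want))
  # exactly one class per input (total function over the factor levels)
  expect_false(any(is.na(impact_class(pc, grid$mgr))))
})

test_that("impact classes are antisymmetric under joint negation", {
  set.seed(17)
  n <- 1e4
  pc <- sample(c(rnorm(n), 0, 0), n)
  mg <- sample(c(rnorm(n), 0, 0), n)
  a <- as.character(impact_class(pc, mg))
  b <- as.character(impact_class(-pc, -mg))
  swap <- c(increases_growth = "increases_decline",
            increases_decline = "increases_growth",
            slows_decline = "slows_growth",
            slows_growth = "slows_decline",
            turns_decline_to_growth = "turns_growth_to_decline",
            turns_growth_to_decline = "turns_decline_to_growth",
            negligible = "negligible")
  expect_equal(b, unname(swap[a]))
})

test_that("direction classes read the urban/rural sign pair", {
  expect_equal(as.character(direction_class(10, 5)), "net_receiving")
  expect_equal(as.character(direction_class(-3, 7)),
               "rural_pull_urban_push")
  expect_equal(as.character(direction_class(3, -7)),
               "urban_pull_rural_push")
  expect_equal(as.character(direction_class(-1, -1)), "net_sending")
  expect_equal(as.character(direction_class(0, 0)), "zero")
  # exhaustive sign grid against the oracle
  g <- expand.grid(u = c(-1, 0, 1), r = c(-1, 0, 1))
  expect_equal(as.character(direction_class(g$u, g$r)),
               unname(mapply(direction_oracle, g$u, g$r)))
  # one-zero patterns are main-class zero with an audit subclass
  aud <- direction_class(c(0, 5), c(5, 0), audit = TRUE)
  expect_equal(as.character(aud$class), c("zero", "zero"))
  expect_equal(aud$audit, c("zero_urban_rural_gain",
                            "zero_rural_urban_gain"))
})

test_that("unit classification covers all units and shares sum to 100", {
  res <- zero_noise_pipeline()
  cls <- res$classes
  expect_equal(sum(cls$shares$impact), 100, tolerance = 1e-9)
  expect_equal(sum(cls$shares$direction), 100, tolerance = 1e-9)
  expect_equal(nrow(cls$units), nrow(res$world$units))
  expect_false(any(is.na(cls$units$impact)))
})

test_that("a world without migration classifies as negligible/zero", {
  w <- tiny_world()
  mig0 <- w$true_net_migration * 0
  # make population change exactly the natural change
  pop <- w$population
  for (t in seq_len(length(w$years) - 1)) {
    nat <- pop[, , t] * (w$true_birth_rate[, , t] -
                           w$true_death_rate[, , t]) / 1000
    pop[, , t + 1] <- pop[, , t] + nat
  }
  masks <- urban_masks(pop, w$covariates$scaled_density, w$admin$adm0,
                       w$urban_share)
  cls <- classify_all_units(mig0, pop, w$admin$adm1, masks)
  expect_true(all(cls$units$direction == "zero"))
  expect_equal(unname(cls$shares$direction[["zero"]]), 100)
})
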
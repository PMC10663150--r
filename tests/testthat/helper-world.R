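# memoized fixture worlds so expensive generations run once per session

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

# small quiet world, zero noise, complete censuses
tiny_world <- function() {
  memo("tiny", function() generate_world(world_config(
    grid_height = 16, grid_width = 16, n_countries = 4,
    units_per_country = 2, subunits_per_unit = 2,
    years = 2000:2004, seed = 42, rate_noise_sd = 0)))
}

# the study-condition world: default 64x64 grid, 8 countries, 32 admin-1
# units, 10 years, cell-level rate noise sd 1.0 per 1,000
noisy_world_pipeline <- function() {
  memo("noisy_pipe", function() suppressMessages(run_pipeline(
    world_config(seed = 1, rate_noise_sd = 1.0))))
}

zero_noise_pipeline <- function() {
  memo("zero_pipe", function() suppressMessages(run_pipeline(
    world_config(seed = 1, rate_noise_sd = 0))))
}

# 64x64 world with exactly 16 admin-1 units (4 countries x 4 units)
sixteen_unit_downscale <- function() {
  memo("sixteen", function() suppressMessages(run_pipeline(
    world_config(n_countries = 4, units_per_country = 4,
                 subunits_per_unit = 2, seed = 5, rate_noise_sd = 1.0),
    stages = c("synth", "harmonize", "downscale"))))
}

# minimal single-type RateSeries builder for unit tests
rate_rows <- function(unit_id, year, value, population,
                      country_id = 1, rate_type = "birth",
                      source_flag = "reported") {
  data.frame(unit_id = unit_id, country_id = country_id, year = year,
             rate_type = rate_type, value = value, population = population,
             source_flag = source_flag, missing_flag = "none")
}
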
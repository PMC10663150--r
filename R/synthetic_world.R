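#' Synthetic miniature world with known ground truth
#'
#' Generates a self-consistent world — nested admin hierarchy on a raster,
#' spatially correlated log-normal population, covariates, per-income-group
#' linear vital rates, a smooth signed migration field and censuses — so that
#' every downstream stage of the pipeline can be validated against truth.
#' The defining property is exact demographic bookkeeping: per cell and year,
#' `pop(t+1) = pop(t) + births - deaths + net_migration`.
#'
#' @name synthetic_world
NULL

INCOME_GROUPS <- c("low", "lower-middle", "upper-middle", "high")

# true per-income-group regression coefficients used by the generator; rates
# are per 1,000 persons per year
TRUE_COEF <- list(
  birth = rbind( # intercept, scaled_density, hdi, repro_women_share
    "low"          = c(38, -8, -25, 30),
    "lower-middle" = c(33, -7, -22, 28),
    "upper-middle" = c(27, -6, -18, 26),
    "high"         = c(20, -5, -12, 24)
  ),
  death = rbind( # intercept, scaled_density, hdi, age_le_ratio
    "low"          = c(16, -3.0, -10, 8),
    "lower-middle" = c(14, -2.8,  -9, 8),
    "upper-middle" = c(12, -2.5,  -8, 7),
    "high"         = c(10, -2.2,  -6, 7)
  )
)

#' Configuration for a synthetic world
#'
#' @param grid_height,grid_width grid dimensions in cells (>= 4).
#' @param n_countries number of countries (vertical strips).
#' @param units_per_country admin-1 units per country (horizontal bands).
#' @param subunits_per_unit admin-2 units per admin-1 unit (vertical splits).
#' @param years strictly increasing calendar years, length >= 3.
#' @param seed integer RNG seed; the whole world is deterministic given it.
#' @param rate_noise_sd cell-level Gaussian noise on vital rates
#'   (per 1,000 persons per year).
#' @param missingness_fractions named fractions of admin-1 units subjected to
#'   each census defect: `combine`, `split`, `partial`, `absent`; must lie in
#'   \[0, 1\] and sum to at most 1.
#' @param migration_scale amplitude of true net migration as a fraction of
#'   local natural change magnitude (keeps populations positive).
#' @param cell_area_km2 constant cell area used for densities.
#' @return validated `world_config` list.
#' @export
world_config <- function(grid_height = 64, grid_width = 64, n_countries = 8,
                         units_per_country = 4, subunits_per_unit = 2,
                         years = 2000:2009, seed = 1L, rate_noise_sd = 1.0,
                         missingness_fractions = c(combine = 0, split = 0,
                                                   partial = 0, absent = 0),
                         migration_scale = 0.5, cell_area_km2 = 100) {
  stopifnot(grid_height >= 4, grid_width >= 4,
            n_countries >= 1, units_per_country >= 1, subunits_per_unit >= 1,
            length(years) >= 3, all(diff(years) > 0),
            rate_noise_sd >= 0, migration_scale >= 0, cell_area_km2 > 0)
  mf <- c(combine = 0, split = 0, partial = 0, absent = 0)
  mf[names(missingness_fractions)] <- missingness_fractions
  if (any(mf < 0 | mf > 1))
    stop("missingness fractions must lie in [0, 1]")
  if (sum(mf) > 1)
    stop("missingness fractions sum to ", sum(mf), " > 1")
  if (grid_width < n_countries * subunits_per_unit)
    stop("grid too narrow for the requested countries and subunits")
  if (grid_height < units_per_country)
    stop("grid too short for the requested units per country")
  structure(list(grid_height = as.integer(grid_height),
                 grid_width = as.integer(grid_width),
                 n_countries = as.integer(n_countries),
                 units_per_country = as.integer(units_per_country),
                 subunits_per_unit = as.integer(subunits_per_unit),
                 years = as.integer(years), seed = as.integer(seed),
                 rate_noise_sd = rate_noise_sd,
                 missingness_fractions = mf,
                 migration_scale = migration_scale,
                 cell_area_km2 = cell_area_km2),
            class = "world_config")
}

# split n items into k contiguous chunks as evenly as possible
chunk_bounds <- function(n, k) {
  sizes <- diff(round(seq(0, n, length.out = k + 1)))
  ends <- cumsum(sizes)
  cbind(start = c(1, utils::head(ends, -1) + 1), end = ends)
}

# axis-aligned nested admin layout: countries are column strips, admin-1
# units row bands within a country, admin-2 units column splits of admin-1
admin_layout <- function(cfg) {
  h <- cfg$grid_height; w <- cfg$grid_width
  adm0 <- matrix(NA_integer_, h, w)
  adm1 <- matrix(NA_integer_, h, w)
  adm2 <- matrix(NA_integer_, h, w)
  ccols <- chunk_bounds(w, cfg$n_countries)
  urows <- chunk_bounds(h, cfg$units_per_country)
  units <- NULL
  for (c in seq_len(cfg$n_countries)) {
    jc <- ccols[c, 1]:ccols[c, 2]
    adm0[, jc] <- c
    scols <- chunk_bounds(length(jc), cfg$subunits_per_unit)
    for (u in seq_len(cfg$units_per_country)) {
      uid <- (c - 1L) * cfg$units_per_country + u
      ir <- urows[u, 1]:urows[u, 2]
      adm1[ir, jc] <- uid
      units <- rbind(units, data.frame(unit_id = uid, country_id = c))
      for (s in seq_len(cfg$subunits_per_unit)) {
        sid <- (uid - 1L) * cfg$subunits_per_unit + s
        adm2[ir, jc[scols[s, 1]:scols[s, 2]]] <- sid
      }
    }
  }
  list(adm0 = adm0, adm1 = adm1, adm2 = adm2, units = units)
}

# standardized smooth Gaussian field
smooth_noise <- function(h, w, sigma) {
  f <- smooth_field(matrix(stats::rnorm(h * w), h, w), sigma)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic world
#'
#' Population starts from a spatially correlated log-normal surface with
#' per-country level factors and evolves by exact bookkeeping. True birth and
#' death rates are affine in (scaled density, HDI, extra covariate) with
#' per-income-group coefficients plus Gaussian noise, so the downscaling
#' regression is well-specified. Because scaled density itself depends on the
#' population trajectory, generation iterates population -> covariates ->
#' rates -> population to a fixed point.
#'
#' @param config a [world_config()].
#' @return `synthetic_world` list: admin labels, population, true rates and
#'   migration, covariate stack, age-sex structure, censuses (complete, and
#'   with injected missingness when fractions are positive), national rates,
#'   urban shares, income groups, macro regions and the true coefficients.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  h <- cfg$grid_height; w <- cfg$grid_width
  years <- cfg$years; Y <- length(years); ylab <- as.character(years)
  set.seed(cfg$seed)

  lay <- admin_layout(cfg)
  n_units <- nrow(lay$units)

  # income groups cycle over countries; HDI levels track the income group
  group_idx <- ((seq_len(cfg$n_countries) - 1L) %% 4L) + 1L
  income <- data.frame(country_id = seq_len(cfg$n_countries),
                       group = INCOME_GROUPS[group_idx])
  hdi_base_country <- c(0.35, 0.50, 0.65, 0.80)[group_idx]

  # --- static random structure -------------------------------------------
  sig <- max(2, min(h, w) / 8)
  g_pop <- smooth_noise(h, w, sig)
  country_level <- exp(stats::rnorm(cfg$n_countries, 0, 0.4))
  pop0 <- 2000 * exp(1.0 * g_pop - 0.5) * country_level[lay$adm0]

  u_age <- stats::plogis(1.2 * smooth_noise(h, w, sig / 2))   # youth index
  aridity <- exp(0.8 * smooth_noise(h, w, sig / 2))

  unit_jit <- stats::runif(n_units, -0.10, 0.10)
  hdi_unit0 <- pmin(pmax(hdi_base_country[lay$units$country_id] + unit_jit,
                         0.05), 0.95)
  hdi <- raster_stack(0, h, w, years)
  for (t in seq_len(Y)) {
    v <- pmin(hdi_unit0 + 0.004 * (t - 1), 0.98)
    hdi[, , t] <- matrix(v[lay$adm1], h, w)
  }

  le_country <- pmin(pmax(40 + 50 * hdi_base_country +
                            stats::rnorm(cfg$n_countries, 0, 2), 50), 85)
  life_expectancy <- matrix(le_country[lay$adm0], h, w)

  # age-sex structure: per-cell mixture of a young and an old pyramid
  lower <- seq(0, 80, 5); upper <- c(seq(4, 79, 5), Inf)
  mids <- (lower + pmin(upper, 84)) / 2   # placeholder midpoint for 80+
  # a young pyramid peaked in the reproductive ages and an old pyramid
  # peaked past them, so cells differ in both repro share and mean age
  young_w <- exp(-abs(mids - 25) / 16); young_w <- young_w / sum(young_w)
  old_w <- exp(-abs(mids - 62) / 16); old_w <- old_w / sum(old_w)
  nb <- length(lower)
  frac <- array(0, c(h, w, nb))
  for (k in seq_len(nb))
    frac[, , k] <- u_age * young_w[k] + (1 - u_age) * old_w[k]
  bands <- data.frame(sex = rep(c("f", "m"), each = nb),
                      lower = rep(lower, 2), upper = rep(upper, 2))
  counts <- array(0, c(h, w, 2 * nb))
  for (k in seq_len(nb)) {
    counts[, , k] <- pop0 * frac[, , k] * 0.5        # female
    counts[, , nb + k] <- pop0 * frac[, , k] * 0.5   # male
  }
  agesex <- list(counts = counts, bands = bands, year = years[1])

  over80 <- do.call(rbind, lapply(seq_len(cfg$n_countries), function(c)
    data.frame(country_id = c, sex = c("f", "m"),
               mean_age = c(84.5, 83.5) + 0.05 * (le_country[c] - 70))))

  repro <- reproductive_women_share(agesex)
  ageratio <- age_life_expectancy_ratio(agesex, over80, life_expectancy,
                                        lay$adm0)

  noise_b <- raster_stack(stats::rnorm(h * w * Y, 0, cfg$rate_noise_sd),
                          h, w, years)
  noise_d <- raster_stack(stats::rnorm(h * w * Y, 0, cfg$rate_noise_sd),
                          h, w, years)
  mig_shape <- lapply(seq_len(Y - 1), function(t) {
    f <- smooth_noise(h, w, sig / 2)
    f / max(abs(f))
  })

  gidx_cell <- matrix(group_idx[lay$adm0], h, w)   # income group per cell

  rates_from <- function(sdens, noise, type) {
    co <- TRUE_COEF[[type]]
    extra <- if (type == "birth") repro else ageratio
    out <- raster_stack(0, h, w, years)
    for (t in seq_len(Y)) {
      r <- co[gidx_cell, 1] + co[gidx_cell, 2] * as.vector(sdens[, , t]) +
        co[gidx_cell, 3] * as.vector(hdi[, , t]) +
        co[gidx_cell, 4] * as.vector(extra) + as.vector(noise[, , t])
      out[, , t] <- matrix(pmax(r, 0.05), h, w)
    }
    out
  }

  # --- fixed-point iteration: population <-> scaled density ---------------
  pop <- raster_stack(rep(pop0, Y), h, w, years)
  birth <- death <- mig <- NULL
  for (it in 1:100) {
    sdens <- scaled_population_density(pop, lay$adm0, cfg$cell_area_km2)
    birth <- rates_from(sdens, noise_b, "birth")
    death <- rates_from(sdens, noise_d, "death")
    newpop <- raster_stack(0, h, w, years)
    newpop[, , 1] <- pop0
    mig <- raster_stack(0, h, w, years[-Y])
    for (t in seq_len(Y - 1)) {
      p <- newpop[, , t]
      nat <- p * (birth[, , t] - death[, , t]) / 1000
      m <- cfg$migration_scale * mig_shape[[t]] * abs(nat)
      mig[, , t] <- m
      newpop[, , t + 1] <- p + nat + m
    }
    delta <- max(abs(newpop - pop) / pmax(pop, 1))
    pop <- newpop
    if (delta < 1e-13) break
  }
  covariates <- list(
    scaled_density = scaled_population_density(pop, lay$adm0,
                                               cfg$cell_area_km2),
    hdi = hdi, repro_women_share = repro, age_le_ratio = ageratio,
    aridity = aridity)

  # --- censuses and national series --------------------------------------
  censuses <- NULL
  national <- NULL
  for (t in seq_len(Y)) {
    p <- pop[, , t]
    for (type in c("birth", "death")) {
      r <- if (type == "birth") birth[, , t] else death[, , t]
      v <- zonal_mean(r, lay$adm1, weights = p)
      pu <- zonal_sum(p, lay$adm1)
      censuses <- rbind(censuses, data.frame(
        unit_id = as.integer(names(v)),
        country_id = lay$units$country_id[match(as.integer(names(v)),
                                                lay$units$unit_id)],
        year = years[t], rate_type = type, value = as.numeric(v),
        population = as.numeric(pu), source_flag = "reported",
        missing_flag = "none"))
      vn <- zonal_mean(r, lay$adm0, weights = p)
      national <- rbind(national, data.frame(
        country_id = as.integer(names(vn)), year = years[t],
        rate_type = type, value = as.numeric(vn)))
    }
  }

  urban_share <- do.call(rbind, lapply(seq_len(cfg$n_countries), function(c)
    data.frame(country_id = c, year = years,
               share = pmin(pmax(0.25 + 0.5 * hdi_base_country[c] +
                                   0.004 * (seq_len(Y) - 1), 0.15), 0.9))))

  world <- structure(list(
    config = cfg, years = years,
    admin = lay[c("adm0", "adm1", "adm2")], units = lay$units,
    population = pop,
    true_birth_rate = birth, true_death_rate = death,
    true_net_migration = mig,
    covariates = covariates, agesex = agesex,
    life_expectancy = life_expectancy, over80_mean_age = over80,
    censuses = censuses, national_reported = national,
    urban_share = urban_share, income_groups = income,
    macro_regions = data.frame(country_id = seq_len(cfg$n_countries),
                               region_id = group_idx),
    true_coefficients = TRUE_COEF
  ), class = "synthetic_world")

  if (sum(cfg$missingness_fractions) > 0) {
    inj <- inject_missingness(censuses, cfg, lay$units,
                              neighbours_from_labels(lay$adm1))
    world$censuses_missing <- inj$series
    world$gapfill_context <- inj$context
  } else {
    world$censuses_missing <- censuses
    world$gapfill_context <- gapfill_context(
      neighbour_graph = neighbours_from_labels(lay$adm1))
  }
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("synthetic world: %d x %d grid, %d countries, ",
                     "%d admin-1 units, years %d-%d\n"),
              cfg$grid_height, cfg$grid_width, cfg$n_countries,
              nrow(x$units), min(x$years), max(x$years)))
  cat(sprintf("  total population %d -> %d\n",
              round(sum(x$population[, , 1])),
              round(sum(x$population[, , length(x$years)]))))
  invisible(x)
}

#' Gap-fill context: registries and neighbour graph
#'
#' @param neighbour_graph adjacency list among admin-1 units
#'   (see [neighbours_from_labels()]).
#' @param split_registry data.frame (`parent_id`, `child_id`, `split_year`);
#'   one row per child.
#' @param combine_registry data.frame (`small_unit_id`, `host_unit_id`).
#' @return `gapfill_context` list.
#' @export
gapfill_context <- function(neighbour_graph = list(),
                            split_registry = NULL,
                            combine_registry = NULL) {
  if (is.null(split_registry))
    split_registry <- data.frame(parent_id = integer(), child_id = integer(),
                                 split_year = integer())
  if (is.null(combine_registry))
    combine_registry <- data.frame(small_unit_id = integer(),
                                   host_unit_id = integer())
  structure(list(neighbour_graph = neighbour_graph,
                 split_registry = split_registry,
                 combine_registry = combine_registry),
            class = "gapfill_context")
}

#' Inject census missingness patterns
#'
#' Applies the four defect patterns found in real subnational vital
#' statistics: `combine` (a tiny unit whose reported rates are implausible
#' and must be pooled with a neighbour), `split` (two units reported as one
#' before a split year), `partial` (randomly blanked unit-years) and
#' `absent` (no records at all). Units are chosen without replacement;
#' combine candidates are the smallest-population units.
#'
#' @param series complete census RateSeries (data.frame).
#' @param config the [world_config()] whose `missingness_fractions` and
#'   `seed` drive the injection.
#' @param units data.frame (`unit_id`, `country_id`).
#' @param neighbours adjacency list among admin-1 units.
#' @return list with `series` (defective RateSeries, `missing_flag` set) and
#'   `context` (a [gapfill_context()] recording what was done).
#' @export
inject_missingness <- function(series, config, units, neighbours) {
  mf <- config$missingness_fractions
  years <- config$years; Y <- length(years)
  n <- nrow(units)
  set.seed(config$seed + 77L)

  n_combine <- round(mf[["combine"]] * n)
  n_split <- round(mf[["split"]] * n)
  n_partial <- round(mf[["partial"]] * n)
  n_absent <- round(mf[["absent"]] * n)

  mean_pop <- tapply(series$population, series$unit_id, mean)
  taken <- integer(0)

  # combine: the n smallest units, each hosted by its most populous neighbour
  comb <- data.frame(small_unit_id = integer(), host_unit_id = integer())
  if (n_combine > 0) {
    small <- as.integer(names(sort(mean_pop)))[seq_len(n_combine)]
    for (u in small) {
      nb <- setdiff(neighbours[[as.character(u)]], c(taken, small))
      nb <- nb[units$country_id[match(nb, units$unit_id)] ==
                 units$country_id[units$unit_id == u]]
      if (length(nb) == 0) next
      host <- nb[which.max(mean_pop[as.character(nb)])]
      comb <- rbind(comb, data.frame(small_unit_id = u, host_unit_id = host))
      taken <- c(taken, u, host)
      # the tiny unit's reported rates are implausible: inflate them
      bad <- series$unit_id == u
      series$value[bad] <- series$value[bad] * 2.5
      series$missing_flag[bad] <- "combine"
    }
  }

  # split: adjacent same-country pairs reported as one unit before split_year
  spl <- data.frame(parent_id = integer(), child_id = integer(),
                    split_year = integer())
  if (n_split > 0) {
    split_year <- years[floor(Y / 2) + 1]
    cand <- sample(setdiff(units$unit_id, taken))
    next_parent <- max(units$unit_id) + 1L
    made <- 0
    for (u in cand) {
      if (made >= n_split) break
      nb <- setdiff(neighbours[[as.character(u)]], taken)
      nb <- nb[units$country_id[match(nb, units$unit_id)] ==
                 units$country_id[units$unit_id == u]]
      nb <- setdiff(nb, u)
      if (length(nb) == 0) next
      sib <- nb[1]
      kids <- c(u, sib)
      pre <- series$unit_id %in% kids & series$year < split_year
      # merge the two children into one parent record per year and rate type
      merged <- NULL
      for (y in years[years < split_year]) for (ty in c("birth", "death")) {
        rows <- series[series$unit_id %in% kids & series$year == y &
                         series$rate_type == ty, ]
        if (nrow(rows) == 0) next
        merged <- rbind(merged, data.frame(
          unit_id = next_parent, country_id = rows$country_id[1], year = y,
          rate_type = ty,
          value = sum(rows$value * rows$population) / sum(rows$population),
          population = sum(rows$population), source_flag = "reported",
          missing_flag = "split"))
      }
      series <- rbind(series[!pre, ], merged)
      spl <- rbind(spl, data.frame(parent_id = next_parent, child_id = kids,
                                   split_year = split_year))
      next_parent <- next_parent + 1L
      taken <- c(taken, kids)
      made <- made + 1
    }
  }

  # partial: blank ~30% of years in each chosen unit (never all years)
  if (n_partial > 0) {
    cand <- sample(setdiff(units$unit_id, taken), n_partial)
    for (u in cand) {
      k <- max(1, min(round(0.3 * Y), Y - 1))
      blank <- sample(years, k)
      series <- series[!(series$unit_id == u & series$year %in% blank), ]
      taken <- c(taken, u)
    }
  }

  # absent: remove every record of the chosen units
  if (n_absent > 0) {
    cand <- sample(setdiff(units$unit_id, taken), n_absent)
    series <- series[!(series$unit_id %in% cand), ]
    taken <- c(taken, cand)
  }

  rownames(series) <- NULL
  list(series = series,
       context = gapfill_context(neighbour_graph = neighbours,
                                 split_registry = spl,
                                 combine_registry = comb))
}

#' Write a synthetic world to plain-text files
#'
#' Admin labels, annual population and covariates go to long-format CSVs;
#' censuses, national rates and urban shares to flat CSVs.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  lab <- expand.grid(row = seq_len(nrow(world$admin$adm0)),
                     col = seq_len(ncol(world$admin$adm0)))
  lab$adm0 <- as.vector(world$admin$adm0)
  lab$adm1 <- as.vector(world$admin$adm1)
  lab$adm2 <- as.vector(world$admin$adm2)
  wr(lab, "admin_labels.csv")
  long <- function(stack) {
    do.call(rbind, lapply(dimnames(stack)[[3]], function(y)
      data.frame(row = seq_len(nrow(stack)),
                 col = rep(seq_len(ncol(stack)), each = nrow(stack)),
                 year = as.integer(y), value = as.vector(stack[, , y]))))
  }
  wr(long(world$population), "population.csv")
  wr(long(world$true_net_migration), "true_net_migration.csv")
  wr(world$censuses_missing, "censuses.csv")
  wr(world$national_reported, "national_rates.csv")
  wr(world$urban_share, "urban_share.csv")
  wr(world$income_groups, "income_groups.csv")
  invisible(files)
}
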
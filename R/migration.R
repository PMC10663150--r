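#' Net migration by demographic accounting
#'
#' Net migration is the residual of the demographic balancing equation:
#' reported population change minus natural change (births minus deaths).
#' It is signed — negative means net out-migration. Start-of-interval
#' population converts rates to event counts, matching how the rates were
#' harmonized against same-year population.
#'
#' @name migration
NULL

#' Natural population change per cell
#'
#' @param birth_rates,death_rates 3-D arrays of rates per 1,000.
#' @param population 3-D population array (same years).
#' @return 3-D array of persons: `population * (birth - death) / 1000`.
#' @export
natural_change <- function(birth_rates, death_rates, population) {
  check_coregistered(birth_rates[, , 1], death_rates[, , 1],
                     population[, , 1])
  population[, , dimnames(birth_rates)[[3]], drop = FALSE] *
    (birth_rates - death_rates) / 1000
}

#' Net migration per cell-year
#'
#' For each pair of consecutive years `(t, t+1)`:
#' `net = (pop(t+1) - pop(t)) - natural(t)`. The series necessarily ends one
#' year before the population record does.
#'
#' @param population 3-D population array over years `t = 1..Y`.
#' @param natural 3-D array of natural change covering years `1..Y-1`.
#' @return 3-D array of net migrants (signed persons) for years `1..Y-1`.
#' @export
net_migration <- function(population, natural) {
  years <- as.integer(dimnames(population)[[3]])
  if (any(diff(years) != 1))
    stop("population series must cover consecutive years; gaps at ",
         paste(years[which(diff(years) != 1)], collapse = ", "))
  Y <- length(years)
  out <- raster_stack(0, nrow(population), ncol(population), years[-Y])
  for (t in seq_len(Y - 1)) {
    out[, , t] <- (population[, , t + 1] - population[, , t]) -
      natural[, , as.character(years[t])]
  }
  out
}

#' Aggregate net migration to admin units
#'
#' Zonal sums per unit-year, annual rates per 1,000 (same-year population),
#' cumulative window sums whose rates use the window-average population, and
#' the OLS trend slope of annual net migration on calendar year.
#'
#' @param migration 3-D array of net migrants.
#' @param admin_labels integer label matrix for the requested level.
#' @param population 3-D population array.
#' @param windows list of year vectors for cumulative sums; default the
#'   5-year/10-year halves and the full period.
#' @return list: `annual` (data.frame `unit_id`, `year`, `net_migration`,
#'   `population`, `rate`), `cumulative` (per window), `trend` (per unit).
#' @export
aggregate_migration <- function(migration, admin_labels, population,
                                windows = NULL) {
  years <- as.integer(dimnames(migration)[[3]])
  if (is.null(windows)) {
    halves <- split(years, cut(years, 2, labels = FALSE))
    qs <- split(years, cut(years, 4, labels = FALSE))
    windows <- c(unname(qs), unname(halves), list(years))
  }
  ann <- NULL
  for (y in years) {
    s <- zonal_sum(slice2d(migration, y), admin_labels)
    p <- zonal_sum(slice2d(population, y), admin_labels)
    rate <- ifelse(p > 0, 1000 * s / p, NA_real_)
    ann <- rbind(ann, data.frame(unit_id = as.integer(names(s)), year = y,
                                 net_migration = as.numeric(s),
                                 population = as.numeric(p),
                                 rate = as.numeric(rate)))
  }
  cum <- NULL
  for (wyrs in windows) {
    d <- ann[ann$year %in% wyrs, ]
    s <- tapply(d$net_migration, d$unit_id, sum)
    pbar <- tapply(d$population, d$unit_id, mean)
    cum <- rbind(cum, data.frame(
      unit_id = as.integer(names(s)),
      window = paste0(min(wyrs), "-", max(wyrs)),
      net_migration = as.numeric(s),
      rate = as.numeric(1000 * s / pbar)))
  }
  trend <- if (length(years) >= 3) {
    do.call(rbind, lapply(split(ann, ann$unit_id), function(d)
      data.frame(unit_id = d$unit_id[1],
                 slope = trend_slope(d$net_migration, d$year))))
  } else NULL
  list(annual = ann, cumulative = cum, trend = trend)
}

#' OLS trend slope of a migration series
#'
#' @param values annual net migration (persons).
#' @param years calendar years (>= 3).
#' @return slope in persons per year.
#' @export
trend_slope <- function(values, years) {
  if (length(years) < 3) stop("trend requires at least 3 years")
  unname(stats::coef(stats::lm(values ~ years))[2])
}

#' Compare estimated unit migration with observations
#'
#' @param estimated data.frame (`unit_id`, `value`).
#' @param observed data.frame (`unit_id`, `value`).
#' @return list: paired data, Pearson and Spearman correlations, mean bias
#'   (estimated minus observed) and n.
#' @export
compare_to_observations <- function(estimated, observed) {
  m <- merge(estimated, observed, by = "unit_id",
             suffixes = c("_est", "_obs"))
  if (nrow(m) == 0)
    stop("no overlapping units between estimates and observations")
  list(paired = m,
       pearson = stats::cor(m$value_est, m$value_obs),
       spearman = stats::cor(m$value_est, m$value_obs, method = "spearman"),
       bias = mean(m$value_est - m$value_obs),
       n = nrow(m))
}
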
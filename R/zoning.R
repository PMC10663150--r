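#' Urban extents and socioclimatic bins
#'
#' Urban extent is delineated per country-year from relative population
#' density: cells are taken in descending density order until their
#' cumulative population meets the national urban population
#' (`urbanPop = totPop * shr_urbanPop`), so the sparsest urban cell is
#' always denser than the densest rural populated cell. Socioclimatic bins
#' partition populated cells into 10 population-weighted HDI deciles, each
#' split into 10 population-weighted aridity deciles — 100 bins holding
#' ~1% of the population each, numbered `10 * hdi_decile + aridity_decile`
#' (0-based, so the driest-poorest cells land in bin 0).
#'
#' @name zoning
NULL

#' Delineate one country-year urban mask
#'
#' @param population population matrix (persons per cell).
#' @param density_rank density ranking field (e.g. scaled density); ties are
#'   broken by raw population, then cell index.
#' @param country_labels integer matrix of country ids.
#' @param urban_share data.frame (`country_id`, `share` in \[0, 1\]).
#' @return binary matrix (1 urban, 0 rural; `NA` outside countries).
#' @export
urban_mask <- function(population, density_rank, country_labels,
                       urban_share) {
  check_coregistered(population, density_rank, country_labels)
  if (any(urban_share$share < 0 | urban_share$share > 1))
    stop("urban share outside [0, 1]")
  out <- matrix(NA_real_, nrow(population), ncol(population))
  for (cid in unique(urban_share$country_id)) {
    inc <- which(country_labels == cid)
    shr <- urban_share$share[urban_share$country_id == cid][1]
    tot <- sum(population[inc])
    target <- tot * shr
    o <- inc[order(-density_rank[inc], -population[inc], inc)]
    cum_before <- cumsum(population[o]) - population[o]
    urban <- o[cum_before < target & population[o] > 0]
    out[inc] <- 0
    out[urban] <- 1
  }
  out
}

#' Annual urban masks for all countries
#'
#' @param population 3-D population array.
#' @param density_rank 3-D array (or matrix) of the density ranking field.
#' @param country_labels integer matrix of country ids.
#' @param urban_share data.frame (`country_id`, `year`, `share`).
#' @return 3-D binary array (row, col, year).
#' @export
urban_masks <- function(population, density_rank, country_labels,
                        urban_share) {
  years <- dimnames(population)[[3]]
  out <- raster_stack(NA_real_, nrow(country_labels), ncol(country_labels),
                      as.integer(years))
  for (y in years) {
    dr <- if (length(dim(density_rank)) == 3) slice2d(density_rank, y)
    else density_rank
    shr <- urban_share[urban_share$year == as.integer(y),
                       c("country_id", "share")]
    out[, , y] <- urban_mask(slice2d(population, y), dr, country_labels,
                             shr)
  }
  out
}

# population-weighted decile (0-9) of `values` under weights `w`,
# deterministic under ties: sort by (value, index), accumulate weights,
# decile = first decile whose cumulative bound is not yet exceeded
weighted_decile <- function(values, w) {
  o <- order(values, seq_along(values))
  cum_before <- cumsum(w[o]) - w[o]
  dec <- pmin(floor(cum_before / (sum(w) / 10)), 9)
  out <- integer(length(values))
  out[o] <- dec
  out
}

#' Assign socioclimatic bins
#'
#' @param hdi HDI matrix (a long-term representative layer).
#' @param aridity aridity-index matrix.
#' @param population population-weight matrix (e.g. full-period mean).
#' @return integer matrix of bin ids 0-99 (`NA` where unpopulated or a
#'   covariate is missing).
#' @export
assign_bins <- function(hdi, aridity, population) {
  check_coregistered(hdi, aridity, population)
  ok <- which(population > 0 & is.finite(hdi) & is.finite(aridity))
  if (length(ok) == 0) stop("no populated cells with valid covariates")
  if (length(unique(hdi[ok])) == 1)
    message("all-equal HDI: deciles degenerate, resolved by cell-index ties")
  hd <- weighted_decile(hdi[ok], population[ok])
  bin <- integer(length(ok))
  for (d in 0:9) {
    sel <- hd == d
    if (!any(sel)) next
    bin[sel] <- 10L * d + weighted_decile(aridity[ok][sel],
                                          population[ok][sel])
  }
  out <- matrix(NA_integer_, nrow(hdi), ncol(hdi))
  out[ok] <- bin
  out
}

#' Per-bin migration statistics, split urban/rural
#'
#' Net migration is accumulated over the full period separately over urban
#' and rural cells of each bin (using the annual masks), then divided by the
#' respective period-mean urban/rural population, per 1,000.
#'
#' @param bins bin-id matrix from [assign_bins()].
#' @param migration 3-D net-migration array.
#' @param masks 3-D urban-mask array (years covering the migration years).
#' @param population 3-D population array.
#' @return data.frame per bin: urban/rural migrant sums, mean populations
#'   and rates per 1,000 (rates `NA` where a bin has no such population).
#' @export
bin_statistics <- function(bins, migration, masks, population) {
  years <- dimnames(migration)[[3]]
  ids <- sort(unique(as.vector(bins[!is.na(bins)])))
  acc <- data.frame(bin = ids, urban_mgr = 0, rural_mgr = 0,
                    urban_pop = 0, rural_pop = 0)
  for (y in years) {
    m <- slice2d(migration, y)
    u <- slice2d(masks, y)
    p <- slice2d(population, y)
    for (part in c("urban", "rural")) {
      sel <- if (part == "urban") u == 1 else u == 0
      sel[is.na(sel)] <- FALSE
      mm <- m; mm[!sel] <- 0
      pp <- p; pp[!sel] <- 0
      s <- zonal_sum(mm, bins)
      q <- zonal_sum(pp, bins)
      i <- match(as.integer(names(s)), acc$bin)
      acc[[paste0(part, "_mgr")]][i] <- acc[[paste0(part, "_mgr")]][i] + s
      acc[[paste0(part, "_pop")]][i] <- acc[[paste0(part, "_pop")]][i] + q
    }
  }
  acc$urban_pop <- acc$urban_pop / length(years)
  acc$rural_pop <- acc$rural_pop / length(years)
  acc$urban_rate <- ifelse(acc$urban_pop > 0,
                           1000 * acc$urban_mgr / acc$urban_pop, NA_real_)
  acc$rural_rate <- ifelse(acc$rural_pop > 0,
                           1000 * acc$rural_mgr / acc$rural_pop, NA_real_)
  acc
}
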
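#' Gridded predictor variables for downscaling
#'
#' Four predictors drive the downscaling regressions: within-country scaled
#' population density (urbanization proxy), the human development index, the
#' share of women of reproductive age (births only) and the ratio of average
#' age to life expectancy (deaths only). Functions here build each predictor
#' from primary rasters and aggregate them to admin units.
#'
#' @name covariates
NULL

#' Delta-change bias correction of an early population series
#'
#' Scales each cell of an earlier population series by the ratio of a
#' reference series to the early series at an overlap year, making the two
#' sources consistent where they meet.
#'
#' @param early 3-D population array (row, col, year) to be corrected.
#' @param reference 3-D population array covering the overlap year.
#' @param overlap_year year present in both series.
#' @return corrected array with the geometry and years of `early`.
#' @export
delta_correct_population <- function(early, reference, overlap_year) {
  oy <- as.character(overlap_year)
  if (!(oy %in% dimnames(early)[[3]]) || !(oy %in% dimnames(reference)[[3]]))
    stop("overlap year ", overlap_year, " not present in both series")
  check_coregistered(early[, , 1], reference[, , 1])
  e0 <- early[, , oy]
  r0 <- reference[, , oy]
  fac <- r0 / e0
  # cells empty in the early source at overlap carry no ratio information:
  # apply the mean factor over informative cells instead
  bad <- !is.finite(fac)
  fac[bad] <- mean(fac[!bad])
  out <- early
  for (y in dimnames(early)[[3]]) out[, , y] <- early[, , y] * fac
  out
}

#' Scaled population density per country
#'
#' For each country, population densities are pooled across all years, cells
#' below 1 person/km2 are dropped, and the 5th/95th percentiles of the
#' remaining densities define a linear rescaling to \[0, 1\]:
#' `popdScaled = (popd - popd5th) / (popd95th - popd5th)`, clamped so that
#' values below 0 map to 0 and above 1 map to 1. The result expresses how
#' urbanized a cell is relative to the densest state its country reaches.
#'
#' @param population 3-D array of persons per cell (row, col, year).
#' @param country_labels integer matrix of country ids.
#' @param cell_area_km2 area of one cell in km2 (constant grid).
#' @return 3-D array of scaled densities in \[0, 1\].
#' @export
scaled_population_density <- function(population, country_labels,
                                      cell_area_km2 = 100) {
  check_coregistered(population[, , 1], country_labels)
  dens <- population / cell_area_km2
  out <- dens
  years <- dimnames(population)[[3]]
  for (cid in sort(unique(as.vector(country_labels[!is.na(country_labels)])))) {
    inc <- country_labels == cid
    pool <- as.vector(dens[rep(inc, length(years))])
    pool <- pool[pool >= 1]
    if (length(pool) == 0)
      stop("country ", cid, " has no cell with density >= 1 person/km2")
    q <- stats::quantile(pool, c(0.05, 0.95), names = FALSE, type = 7)
    if (q[2] <= q[1])
      warning("degenerate density percentiles in country ", cid,
              "; mapping all cells to 0.5")
    for (y in years) {
      v <- dens[, , y][inc]
      if (q[2] > q[1]) {
        s <- (v - q[1]) / (q[2] - q[1])
        s <- pmin(pmax(s, 0), 1)
      } else {
        s <- rep(0.5, length(v))
      }
      slice <- out[, , y]
      slice[inc] <- s
      out[, , y] <- slice
    }
  }
  out
}

#' Share of women of reproductive age (15-49) of total population
#'
#' @param agesex age-sex structure: list with `counts`, a 3-D array
#'   (row, col, band), and `bands`, a data.frame with columns `sex`
#'   (`"f"`/`"m"`), `lower` and `upper` (years; the open-ended band has
#'   `upper = Inf`) matching the third dimension.
#' @return matrix of shares in \[0, 1\]; cells with zero population are `NA`.
#' @export
reproductive_women_share <- function(agesex) {
  b <- agesex$bands
  repro <- b$sex == "f" & b$lower >= 15 & b$upper <= 49
  if (!any(repro)) stop("no female 15-49 bands present in the age-sex stack")
  tot <- apply(agesex$counts, c(1, 2), sum)
  fem <- apply(agesex$counts[, , repro, drop = FALSE], c(1, 2), sum)
  out <- fem / tot
  out[tot == 0] <- NA_real_
  out
}

#' Ratio of average age to life expectancy
#'
#' Cell average age is the count-weighted mean of age-band midpoints
#' (`(lower + upper) / 2`, e.g. 7 years for the 5-9 band); the open-ended 80+
#' band is assigned the national sex-specific mean age. The ratio to life
#' expectancy measures the share of expected life already lived.
#'
#' @param agesex age-sex structure (see [reproductive_women_share()]).
#' @param over80_mean_age data.frame with columns `country_id`, `sex`,
#'   `mean_age` (years) for the open-ended band.
#' @param life_expectancy matrix of life expectancy at birth (years, > 0).
#' @param country_labels integer matrix of country ids.
#' @return matrix of ratios (>= 0); empty cells are `NA`.
#' @export
age_life_expectancy_ratio <- function(agesex, over80_mean_age,
                                      life_expectancy, country_labels) {
  b <- agesex$bands
  stopifnot(all(life_expectancy > 0, na.rm = TRUE))
  open <- !is.finite(b$upper)
  mid <- (b$lower + b$upper) / 2
  tot <- apply(agesex$counts, c(1, 2), sum)
  agesum <- array(0, dim(tot))
  for (k in seq_len(nrow(b))) {
    if (open[k]) {
      # national sex-specific mean age painted per country
      ma <- matrix(NA_real_, nrow(tot), ncol(tot))
      for (cid in unique(over80_mean_age$country_id)) {
        v <- over80_mean_age$mean_age[over80_mean_age$country_id == cid &
                                        over80_mean_age$sex == b$sex[k]]
        if (length(v) != 1)
          stop("missing 80+ mean age for country ", cid, " sex ", b$sex[k])
        ma[country_labels == cid] <- v
      }
      agesum <- agesum + agesex$counts[, , k] * ma
    } else {
      agesum <- agesum + agesex$counts[, , k] * mid[k]
    }
  }
  out <- (agesum / tot) / life_expectancy
  out[tot == 0] <- NA_real_
  out
}

#' Aggregate gridded covariates to admin units
#'
#' @param stack named list of 3-D covariate arrays (row, col, year) and/or
#'   static matrices (recycled over years).
#' @param admin_labels integer matrix of unit ids.
#' @param population 3-D population array; required for `weighting =
#'   "population"`.
#' @param weighting `"unweighted"` (simple cell mean, the default used when
#'   preparing predictor tables) or `"population"` (population-weighted mean,
#'   used when aggregating predictions for comparison with census rates).
#' @param years years to aggregate (default: all years of the first stack
#'   entry that has a year dimension).
#' @return data.frame with columns `unit_id`, `year`, one column per
#'   covariate.
#' @export
aggregate_covariates_to_units <- function(stack, admin_labels,
                                          population = NULL,
                                          weighting = c("unweighted",
                                                        "population"),
                                          years = NULL) {
  weighting <- match.arg(weighting)
  if (weighting == "population" && is.null(population))
    stop("population rasters required for population weighting")
  if (is.null(years)) {
    for (v in stack) if (length(dim(v)) == 3) { years <- dimnames(v)[[3]]; break }
    if (is.null(years)) stop("no year dimension found; supply `years`")
  }
  years <- as.character(years)
  out <- NULL
  for (y in years) {
    w <- if (weighting == "population") slice2d(population, y) else NULL
    row <- data.frame(unit_id = as.integer(names(
      zonal_sum(array(1, dim(admin_labels)), admin_labels))))
    row$year <- as.integer(y)
    for (nm in names(stack)) {
      v <- stack[[nm]]
      m <- if (length(dim(v)) == 3) slice2d(v, y) else v
      mu <- zonal_mean(m, admin_labels, weights = w)
      if (any(!is.finite(mu)))
        stop("unit(s) ", paste(names(mu)[!is.finite(mu)], collapse = ", "),
             " have no valid cells for covariate ", nm)
      row[[nm]] <- as.numeric(mu)
    }
    out <- rbind(out, row)
  }
  out
}
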
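#' Harmonization of subnational vital-rate series
#'
#' Raw subnational birth/death data arrive as incomplete, inconsistently
#' reported series. The harmonization chain turns them into complete annual
#' rate series (events per 1,000 persons) per admin-1 unit that aggregate
#' exactly to the reported national rates:
#' combine -> split backcast -> partial fill -> national fallback ->
#' interpolate/extrapolate -> national bias correction.
#'
#' A RateSeries is a data.frame with columns `unit_id`, `country_id`, `year`,
#' `rate_type` ("birth"/"death"), `value` (per 1,000), `population` (persons)
#' and `source_flag`.
#'
#' @name vital_rates
NULL

new_rate_rows <- function(unit_id, country_id, year, rate_type, value,
                          population, source_flag) {
  data.frame(unit_id = unit_id, country_id = country_id, year = year,
             rate_type = rate_type, value = value, population = population,
             source_flag = source_flag, missing_flag = "none")
}

# keep shared columns when mixing rows from different provenance
bind_series <- function(a, b) {
  cols <- intersect(names(a), names(b))
  rbind(a[cols], b[cols])
}

lookup_pop <- function(unit_pop, unit, year) {
  v <- unit_pop$population[unit_pop$unit_id == unit & unit_pop$year == year]
  if (length(v) == 1) v else NA_real_
}

#' Convert event counts to crude rates
#'
#' @param counts data.frame (`unit_id`, `country_id`, `year`, `rate_type`,
#'   `events`).
#' @param population data.frame (`unit_id`, `year`, `population`), persons.
#' @return RateSeries with `value = 1000 * events / population`.
#' @export
counts_to_rates <- function(counts, population) {
  key <- paste(counts$unit_id, counts$year)
  pop <- population$population[match(key, paste(population$unit_id,
                                                population$year))]
  if (any(is.na(pop)))
    stop("no population for unit-years: ",
         paste(unique(key[is.na(pop)]), collapse = ", "))
  if (any(pop <= 0 & counts$events > 0))
    stop("zero population with nonzero event counts")
  new_rate_rows(counts$unit_id, counts$country_id, counts$year,
                counts$rate_type, 1000 * counts$events / pop, pop, "reported")
}

#' Pool a tiny unit with a neighbouring host unit
#'
#' Both units receive the identical rate computed from their summed implied
#' events over summed population, removing implausible rates that arise when
#' events are referenced to a population defined differently from the
#' denominator (classic small-capital-district artefact).
#'
#' @param series RateSeries.
#' @param ctx a [gapfill_context()] with a populated `combine_registry`.
#' @return RateSeries with combined pairs flagged `combined`.
#' @export
apply_combine <- function(series, ctx) {
  for (i in seq_len(nrow(ctx$combine_registry))) {
    s <- ctx$combine_registry$small_unit_id[i]
    h <- ctx$combine_registry$host_unit_id[i]
    si <- series$unit_id == s
    for (y in unique(series$year[si])) for (ty in unique(series$rate_type[si])) {
      a <- which(series$unit_id == s & series$year == y &
                   series$rate_type == ty)
      b <- which(series$unit_id == h & series$year == y &
                   series$rate_type == ty)
      if (length(a) == 0) next
      if (length(b) == 0)
        stop("combine host ", h, " lacks data for year ", y, " (", ty, ")")
      ev <- series$value[c(a, b)] * series$population[c(a, b)] / 1000
      pool <- 1000 * sum(ev) / sum(series$population[c(a, b)])
      series$value[c(a, b)] <- pool
      series$source_flag[c(a, b)] <- "combined"
    }
  }
  series
}

#' Back-cast rates of units that were split from a common parent
#'
#' At the first year after the split the children's population-weighted
#' combined rate is formed; each child's ratio to that combined rate is then
#' applied to the parent's pre-split rates, yielding child-level series for
#' the years in which they were still one unit. Parent records are replaced
#' by the back-cast child records.
#'
#' @param series RateSeries containing parent records before `split_year` and
#'   child records from `split_year` on.
#' @param ctx a [gapfill_context()] with a populated `split_registry`.
#' @return RateSeries with children covering the full period, flagged
#'   `split_backcast` before the split.
#' @export
apply_split_backcast <- function(series, ctx) {
  reg <- ctx$split_registry
  for (p in unique(reg$parent_id)) {
    kids <- reg$child_id[reg$parent_id == p]
    sy <- reg$split_year[reg$parent_id == p][1]
    for (ty in unique(series$rate_type[series$unit_id == p])) {
      post <- series[series$unit_id %in% kids & series$rate_type == ty &
                       series$year >= sy, ]
      if (nrow(post) == 0)
        stop("no post-split child records for parent ", p, " (", ty, ")")
      y0 <- min(post$year)
      first <- post[post$year == y0, ]
      if (!all(kids %in% first$unit_id))
        stop("child missing first post-split record for parent ", p,
             " (", ty, ")")
      combined <- sum(first$value * first$population) / sum(first$population)
      ratio <- stats::setNames(first$value / combined,
                               as.character(first$unit_id))
      popshare <- stats::setNames(first$population / sum(first$population),
                                  as.character(first$unit_id))
      par_rows <- which(series$unit_id == p & series$rate_type == ty &
                          series$year < sy)
      new <- NULL
      for (r in par_rows) for (k in kids) {
        new <- rbind(new, new_rate_rows(
          k, series$country_id[r], series$year[r], ty,
          ratio[as.character(k)] * series$value[r],
          popshare[as.character(k)] * series$population[r],
          "split_backcast"))
      }
      series <- bind_series(series[setdiff(seq_len(nrow(series)), par_rows), ],
                            new)
    }
  }
  rownames(series) <- NULL
  series
}

#' Fill gaps in a unit's series by neighbour scaling
#'
#' For each missing unit-year, the scaling neighbour is the adjacent unit
#' with the least absolute rate difference at the reference year (the year
#' closest to the gap in which both units report; ties resolved toward the
#' earlier year). The missing value is the unit-to-neighbour ratio at the
#' reference year times the neighbour's value in the missing year. When no
#' neighbour reports in the missing year, the national rate is used and
#' flagged.
#'
#' @param series RateSeries.
#' @param ctx a [gapfill_context()] (for the neighbour graph).
#' @param years full set of years that should be present.
#' @param unit_pop optional data.frame (`unit_id`, `year`, `population`) for
#'   the population of filled records; otherwise the unit's nearest reported
#'   population is carried over.
#' @param national optional data.frame (`country_id`, `year`, `rate_type`,
#'   `value`) used as fallback.
#' @return RateSeries with neighbour-filled records flagged
#'   `neighbour_scaled` (or `national_fallback`).
#' @export
fill_partial <- function(series, ctx, years, unit_pop = NULL,
                         national = NULL) {
  units_present <- unique(series$unit_id)
  for (u in units_present) {
    cid <- series$country_id[series$unit_id == u][1]
    for (ty in unique(series$rate_type[series$unit_id == u])) {
      have <- sort(series$year[series$unit_id == u & series$rate_type == ty])
      if (length(have) == 0) next
      for (y in setdiff(years, have)) {
        nbs <- ctx$neighbour_graph[[as.character(u)]]
        best <- NULL
        for (nb in nbs) {
          nb_val_y <- series$value[series$unit_id == nb &
                                     series$rate_type == ty &
                                     series$year == y &
                                     series$source_flag != "national_fallback"]
          if (length(nb_val_y) != 1) next
          nb_years <- series$year[series$unit_id == nb &
                                    series$rate_type == ty]
          common <- intersect(have, nb_years)
          if (length(common) == 0) next
          d <- abs(common - y)
          ref <- min(common[d == min(d)])   # tie toward the earlier year
          uref <- series$value[series$unit_id == u & series$year == ref &
                                 series$rate_type == ty]
          nref <- series$value[series$unit_id == nb & series$year == ref &
                                 series$rate_type == ty]
          score <- abs(uref - nref)
          if (is.null(best) || score < best$score)
            best <- list(score = score, uref = uref, nref = nref,
                         nb = nb, ref = ref,
                         nb_y = nb_val_y)
        }
        pop <- if (!is.null(unit_pop)) lookup_pop(unit_pop, u, y) else NA_real_
        if (is.na(pop)) {
          near <- have[which.min(abs(have - y))]
          pop <- series$population[series$unit_id == u & series$year == near &
                                     series$rate_type == ty][1]
        }
        if (!is.null(best)) {
          val <- best$uref / best$nref * best$nb_y
          series <- bind_series(series, new_rate_rows(
            u, cid, y, ty, val, pop, "neighbour_scaled"))
        } else if (!is.null(national)) {
          nv <- national$value[national$country_id == cid &
                                 national$year == y &
                                 national$rate_type == ty]
          if (length(nv) == 1)
            series <- bind_series(series, new_rate_rows(
              u, cid, y, ty, nv, pop, "national_fallback"))
        }
      }
    }
  }
  rownames(series) <- NULL
  series
}

#' National-average fallback for units with no data at all
#'
#' @param series RateSeries.
#' @param national data.frame (`country_id`, `year`, `rate_type`, `value`).
#' @param units data.frame (`unit_id`, `country_id`) of all units that should
#'   be present.
#' @param unit_pop data.frame (`unit_id`, `year`, `population`).
#' @return RateSeries where dataless units carry their national series,
#'   flagged `national_fallback`.
#' @export
fill_national <- function(series, national, units, unit_pop) {
  missing_units <- setdiff(units$unit_id, unique(series$unit_id))
  for (u in missing_units) {
    cid <- units$country_id[units$unit_id == u]
    nat <- national[national$country_id == cid, ]
    if (nrow(nat) == 0)
      stop("no national series for country ", cid, " (unit ", u, ")")
    pop <- vapply(nat$year, function(y) lookup_pop(unit_pop, u, y), 0)
    if (any(is.na(pop)))
      stop("no population for dataless unit ", u)
    series <- bind_series(series, new_rate_rows(
      u, cid, nat$year, nat$rate_type, nat$value, pop, "national_fallback"))
  }
  rownames(series) <- NULL
  series
}

#' Macroregional rate trends from full-coverage countries
#'
#' Population-weighted mean rates per macroregion and year, computed over the
#' countries whose national series cover every year of the extended period.
#' Used to extrapolate unit series beyond their reported range.
#'
#' @param national data.frame (`country_id`, `year`, `rate_type`, `value`).
#' @param region_map data.frame (`country_id`, `region_id`).
#' @param national_pop data.frame (`country_id`, `year`, `population`).
#' @param years the extended period.
#' @return data.frame (`region_id`, `year`, `rate_type`, `trend_value`).
#' @export
compute_macro_trends <- function(national, region_map, national_pop, years) {
  out <- NULL
  for (ty in unique(national$rate_type)) {
    nat <- national[national$rate_type == ty, ]
    cover <- tapply(nat$year, nat$country_id,
                    function(ys) all(years %in% ys))
    full <- as.integer(names(cover))[cover]
    if (length(full) == 0)
      stop("no country with full coverage for rate type ", ty)
    for (r in sort(unique(region_map$region_id))) {
      cs <- intersect(full, region_map$country_id[region_map$region_id == r])
      if (length(cs) == 0) next
      for (y in years) {
        v <- nat$value[nat$country_id %in% cs & nat$year == y]
        w <- national_pop$population[match(
          paste(cs, y), paste(national_pop$country_id, national_pop$year))]
        out <- rbind(out, data.frame(region_id = r, year = y, rate_type = ty,
                                     trend_value = sum(v * w) / sum(w)))
      }
    }
  }
  out
}

#' Complete each unit's series by interpolation and trend extrapolation
#'
#' Interior gaps are filled by linear interpolation in year. Years before the
#' first (after the last) reported value are filled by applying the
#' macroregion's year-over-year trend ratio multiplicatively outward from the
#' nearest reported value, which preserves nonnegativity of rates.
#'
#' @param series RateSeries (each unit has >= 1 record per rate type).
#' @param trends output of [compute_macro_trends()].
#' @param region_map data.frame (`country_id`, `region_id`).
#' @param years the extended period to complete.
#' @param unit_pop optional population table for new records.
#' @return complete RateSeries over `years`.
#' @export
interpolate_extrapolate <- function(series, trends, region_map, years,
                                    unit_pop = NULL) {
  for (u in unique(series$unit_id)) {
    cid <- series$country_id[series$unit_id == u][1]
    rid <- region_map$region_id[region_map$country_id == cid]
    for (ty in unique(series$rate_type[series$unit_id == u])) {
      rows <- series$unit_id == u & series$rate_type == ty
      have <- series$year[rows]
      vals <- series$value[rows]
      o <- order(have); have <- have[o]; vals <- vals[o]
      tr <- trends[trends$region_id == rid & trends$rate_type == ty, ]
      tr <- tr[order(tr$year), ]
      trv <- stats::setNames(tr$trend_value, as.character(tr$year))
      fill <- function(y) {
        if (y > min(have) && y < max(have)) {
          list(v = stats::approx(have, vals, xout = y)$y,
               flag = "interpolated")
        } else if (y < min(have)) {
          e <- min(have)
          list(v = vals[have == e] *
                 trv[as.character(y)] / trv[as.character(e)],
               flag = "extrapolated")
        } else {
          e <- max(have)
          list(v = vals[have == e] *
                 trv[as.character(y)] / trv[as.character(e)],
               flag = "extrapolated")
        }
      }
      for (y in setdiff(years, have)) {
        f <- fill(y)
        pop <- if (!is.null(unit_pop)) lookup_pop(unit_pop, u, y) else NA_real_
        if (is.na(pop)) {
          near <- have[which.min(abs(have - y))]
          pop <- series$population[series$unit_id == u &
                                     series$year == near &
                                     series$rate_type == ty][1]
        }
        series <- bind_series(series, new_rate_rows(
          u, cid, y, ty, as.numeric(f$v), pop, f$flag))
      }
    }
  }
  rownames(series) <- NULL
  series
}

#' Scale unit rates so national aggregates match reported national rates
#'
#' Per country-year and rate type, every unit's rate is multiplied by
#' `reported / weighted_mean(subnational)` with population weights, after
#' which the population-weighted national mean equals the reported national
#' rate to machine precision.
#'
#' @param series complete RateSeries.
#' @param reported_national data.frame (`country_id`, `year`, `rate_type`,
#'   `value`).
#' @return bias-corrected RateSeries.
#' @export
national_bias_correct <- function(series, reported_national) {
  for (i in seq_len(nrow(reported_national))) {
    cid <- reported_national$country_id[i]
    y <- reported_national$year[i]
    ty <- reported_national$rate_type[i]
    rows <- which(series$country_id == cid & series$year == y &
                    series$rate_type == ty)
    if (length(rows) == 0) next
    wmean <- sum(series$value[rows] * series$population[rows]) /
      sum(series$population[rows])
    rep_v <- reported_national$value[i]
    if (wmean == 0) {
      if (rep_v == 0) next
      stop("zero subnational aggregate with nonzero national rate (country ",
           cid, ", ", y, ", ", ty, ")")
    }
    series$value[rows] <- series$value[rows] * rep_v / wmean
  }
  series
}

#' Run the full harmonization chain
#'
#' combine -> split backcast -> partial fill -> national fallback ->
#' interpolate/extrapolate -> national bias correction.
#'
#' @param series raw RateSeries (with injected defects, if any).
#' @param ctx a [gapfill_context()].
#' @param national national rate series (used for fallback, trends and bias
#'   correction).
#' @param region_map data.frame (`country_id`, `region_id`).
#' @param units data.frame (`unit_id`, `country_id`) of all admin-1 units.
#' @param unit_pop data.frame (`unit_id`, `year`, `population`).
#' @param national_pop data.frame (`country_id`, `year`, `population`).
#' @param years the extended period.
#' @return harmonized complete RateSeries.
#' @export
harmonize_rates <- function(series, ctx, national, region_map, units,
                            unit_pop, national_pop, years) {
  s <- apply_combine(series, ctx)
  s <- apply_split_backcast(s, ctx)
  s <- fill_partial(s, ctx, years, unit_pop = unit_pop, national = national)
  s <- fill_national(s, national, units, unit_pop)
  trends <- compute_macro_trends(national, region_map, national_pop, years)
  s <- interpolate_extrapolate(s, trends, region_map, years,
                               unit_pop = unit_pop)
  s <- national_bias_correct(s, national)
  s[order(s$rate_type, s$unit_id, s$year), ]
}
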
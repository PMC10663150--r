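#' Downscaling harmonized rates to the grid
#'
#' Unit-level rates are downscaled in three steps: (1) per-income-group
#' ordinary least squares of rates on gridded predictors aggregated to units;
#' (2) area-to-point kriging (ATPK) of the unit-level residuals onto the
#' grid, coherent with the areal values; (3) a mass-preserving adjustment so
#' that, population-weighted, every unit's gridded rates aggregate exactly
#' back to its harmonized census rate.
#'
#' @name downscale
NULL

PREDICTORS <- list(
  birth = c("scaled_density", "hdi", "repro_women_share"),
  death = c("scaled_density", "hdi", "age_le_ratio")
)

#' Fit per-income-group rate regressions
#'
#' One OLS fit per income group, pooling unit-years across the whole period.
#' Birth models use scaled density, HDI and the reproductive-women share;
#' death models use scaled density, HDI and the age/life-expectancy ratio.
#'
#' @param unit_table data.frame with columns `group`, `value` (census rate)
#'   and the predictor columns; one row per unit-year.
#' @param rate_type `"birth"` or `"death"`.
#' @return named list (one element per income group) of
#'   `list(coefficients, r_squared, n)`.
#' @export
fit_income_models <- function(unit_table, rate_type = c("birth", "death")) {
  rate_type <- match.arg(rate_type)
  preds <- PREDICTORS[[rate_type]]
  fml <- stats::as.formula(paste("value ~", paste(preds, collapse = " + ")))
  groups <- intersect(INCOME_GROUPS, unique(unit_table$group))
  out <- list()
  for (g in groups) {
    d <- unit_table[unit_table$group == g, ]
    if (nrow(d) < length(preds) + 2)
      stop("income group ", g, " has only ", nrow(d), " unit-years")
    fit <- stats::lm(fml, data = d)
    co <- stats::coef(fit)
    if (any(is.na(co)))
      stop("rank-deficient design in group ", g, ": collinear predictor(s) ",
           paste(names(co)[is.na(co)], collapse = ", "))
    out[[g]] <- list(coefficients = co,
                     r_squared = suppressWarnings(summary(fit))$r.squared,
                     n = nrow(d))
  }
  out
}

#' Predict cell rates from fitted income-group models
#'
#' @param models output of [fit_income_models()].
#' @param covariates named list of covariate arrays/matrices.
#' @param group_cells character matrix of income group per cell.
#' @param rate_type `"birth"` or `"death"`.
#' @param years years to predict.
#' @return 3-D array of predicted rates (per 1,000).
#' @export
predict_rate_cells <- function(models, covariates, group_cells,
                               rate_type = c("birth", "death"),
                               years) {
  rate_type <- match.arg(rate_type)
  preds <- PREDICTORS[[rate_type]]
  h <- nrow(group_cells); w <- ncol(group_cells)
  out <- raster_stack(NA_real_, h, w, years)
  for (g in names(models)) {
    co <- models[[g]]$coefficients
    inc <- group_cells == g
    for (y in as.character(years)) {
      v <- rep(co[["(Intercept)"]], sum(inc))
      for (p in preds) {
        m <- covariates[[p]]
        pm <- if (length(dim(m)) == 3) m[, , y] else m
        v <- v + co[[p]] * pm[inc]
      }
      slice <- out[, , y]
      slice[inc] <- v
      out[, , y] <- slice
    }
  }
  out
}

#' Areal residuals of the regression at unit level
#'
#' Residual per unit-year = harmonized census rate minus the
#' population-weighted aggregate of model-predicted cell rates, plus an
#' exponential-with-nugget variogram fitted to the unit-centroid residuals
#' (method of moments on binned semivariances, pooling within-year pairs).
#'
#' @param predicted 3-D array of predicted cell rates.
#' @param census harmonized RateSeries for one rate type.
#' @param admin_labels integer matrix of unit ids.
#' @param population 3-D population array.
#' @return list with `residuals` (data.frame `unit_id`, `year`, `residual`),
#'   `variogram` (`nugget`, `psill`, `range`; `NULL` when residual variance
#'   is degenerate) and `centroids`.
#' @export
compute_areal_residuals <- function(predicted, census, admin_labels,
                                    population) {
  years <- dimnames(predicted)[[3]]
  cent <- unit_centroids(admin_labels)
  res <- NULL
  for (y in years) {
    p <- population[, , y]
    agg <- zonal_mean(predicted[, , y], admin_labels, weights = p)
    bad <- !is.finite(agg)
    if (any(bad))
      warning("unit(s) ", paste(names(agg)[bad], collapse = ", "),
              " have zero population in ", y, "; residual undefined, excluded")
    for (u in names(agg)[!bad]) {
      cv <- census$value[census$unit_id == as.integer(u) &
                           census$year == as.integer(y)]
      if (length(cv) != 1) next
      res <- rbind(res, data.frame(unit_id = as.integer(u),
                                   year = as.integer(y),
                                   residual = cv - agg[[u]]))
    }
  }
  list(residuals = res,
       variogram = fit_residual_variogram(res, cent),
       centroids = cent)
}

#' Fit an exponential variogram to areal residuals at unit centroids
#'
#' @param residuals data.frame (`unit_id`, `year`, `residual`).
#' @param centroids data.frame (`unit_id`, `row`, `col`).
#' @param n_bins number of distance bins for the empirical semivariance.
#' @return list (`model = "exponential"`, `nugget`, `psill`, `range`) or
#'   `NULL` when the residual variance is degenerate (coherence fallback).
#' @export
fit_residual_variogram <- function(residuals, centroids, n_bins = 8) {
  if (is.null(residuals) || stats::var(residuals$residual) < 1e-12 ||
      nrow(centroids) < 3)
    return(NULL)
  d <- g <- NULL
  for (y in unique(residuals$year)) {
    r <- residuals[residuals$year == y, ]
    i <- match(r$unit_id, centroids$unit_id)
    xy <- cbind(centroids$row[i], centroids$col[i])
    dd <- as.vector(stats::dist(xy))
    pairs <- utils::combn(nrow(r), 2)
    gg <- 0.5 * (r$residual[pairs[1, ]] - r$residual[pairs[2, ]])^2
    d <- c(d, dd); g <- c(g, gg)
  }
  br <- seq(0, max(d), length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE)
  emp <- data.frame(h = tapply(d, bin, mean),
                    gamma = tapply(g, bin, mean),
                    n = as.numeric(table(bin)))
  emp <- emp[emp$n > 0, ]
  sse <- function(par) {
    nug <- par[1]; psill <- par[2]; rng <- par[3]
    mod <- nug + psill * (1 - exp(-emp$h / rng))
    sum(emp$n * (emp$gamma - mod)^2)
  }
  init <- c(0, stats::var(residuals$residual), max(d) / 4)
  fit <- try(stats::optim(init, sse, method = "L-BFGS-B",
                          lower = c(0, 1e-10, max(d) / 100)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  list(model = "exponential", nugget = fit$par[1], psill = fit$par[2],
       range = fit$par[3])
}

#' Distribute areal residuals to the grid (ATPK with coherence correction)
#'
#' Ordinary kriging from unit centroids (areal residuals treated as the
#' units' support points under the fitted variogram) gives a smooth cell
#' surface; a per-unit additive correction then enforces exact area-to-point
#' coherence: the unweighted mean over each unit's cells equals its areal
#' residual. When the variogram is degenerate or the kriging system singular,
#' cells receive their unit's residual uniformly (logged via a message).
#'
#' @param residual_field output of [compute_areal_residuals()].
#' @param admin_labels integer matrix of unit ids.
#' @param max_neighbours cap on kriging neighbours per cell.
#' @return 3-D array of cell residuals (row, col, year).
#' @export
atpk_distribute <- function(residual_field, admin_labels,
                            max_neighbours = 32) {
  res <- residual_field$residuals
  if (is.null(res) || nrow(res) == 0) stop("no valid areal residuals")
  vg <- residual_field$variogram
  cent <- residual_field$centroids
  years <- sort(unique(res$year))
  h <- nrow(admin_labels); w <- ncol(admin_labels)
  out <- raster_stack(0, h, w, years)
  cellr <- matrix(seq_len(h), h, w)
  cellc <- matrix(seq_len(w), h, w, byrow = TRUE)

  uniform <- function(r) {
    v <- stats::setNames(r$residual, as.character(r$unit_id))
    matrix(v[as.character(admin_labels)], h, w)
  }

  for (y in years) {
    r <- res[res$year == y, ]
    surf <- NULL
    if (!is.null(vg) && nrow(r) >= 3) {
      i <- match(r$unit_id, cent$unit_id)
      xy <- cbind(cent$row[i], cent$col[i])
      covf <- function(hh) vg$psill * exp(-hh / vg$range)
      n <- nrow(r)
      use_all <- n <= max_neighbours
      D <- as.matrix(stats::dist(xy))
      surf <- try({
        if (use_all) {
          A <- rbind(cbind(covf(D) + diag(vg$nugget, n), 1), c(rep(1, n), 0))
          dc <- outer(as.vector(cellr), xy[, 1], "-")^2 +
            outer(as.vector(cellc), xy[, 2], "-")^2
          B <- rbind(t(covf(sqrt(dc))), 1)
          Wt <- solve(A, B)
          matrix(colSums(Wt[seq_len(n), , drop = FALSE] * r$residual), h, w)
        } else {
          pred <- numeric(h * w)
          for (k in seq_len(h * w)) {
            dk <- sqrt((cellr[k] - xy[, 1])^2 + (cellc[k] - xy[, 2])^2)
            nb <- order(dk)[seq_len(max_neighbours)]
            A <- rbind(cbind(covf(D[nb, nb]) +
                               diag(vg$nugget, length(nb)), 1),
                       c(rep(1, length(nb)), 0))
            b <- c(covf(dk[nb]), 1)
            lam <- solve(A, b)
            pred[k] <- sum(lam[seq_along(nb)] * r$residual[nb])
          }
          matrix(pred, h, w)
        }
      }, silent = TRUE)
      if (inherits(surf, "try-error")) surf <- NULL
    }
    if (is.null(surf)) {
      message("ATPK fallback: uniform within-unit residual assignment (",
              y, ")")
      surf <- uniform(r)
    }
    # coherence correction: unit means must equal the areal residuals
    mu <- zonal_mean(surf, admin_labels)
    delta <- stats::setNames(r$residual, as.character(r$unit_id))[names(mu)] -
      mu
    delta[is.na(delta)] <- 0
    surf <- surf + matrix(delta[as.character(admin_labels)], h, w)
    out[, , as.character(y)] <- surf
  }
  out
}

#' Mass-preserving adjustment of approximated cell rates
#'
#' Each cell's approximated rate is rescaled by
#' `C_n * sum(p_j) / sum(R_j * p_j)` over its unit, so that the
#' population-weighted mean of adjusted rates equals the unit's census rate
#' — total implied events match the census exactly. Negative approximated
#' rates are floored at 0 before adjustment; zero-population cells keep
#' their approximated rate (they cannot carry events); a unit whose
#' population-weighted approximation is zero while the census rate is
#' positive receives the census rate uniformly.
#'
#' @param approx 3-D array of approximated rates (regression + distributed
#'   residual).
#' @param census harmonized RateSeries for one rate type.
#' @param population 3-D population array.
#' @param admin_labels integer matrix of unit ids.
#' @return 3-D array of adjusted rates.
#' @export
adjust_rates <- function(approx, census, population, admin_labels) {
  years <- dimnames(approx)[[3]]
  out <- approx
  for (y in years) {
    R <- pmax(slice2d(approx, y), 0)
    p <- slice2d(population, y)
    cn <- census[census$year == as.integer(y), ]
    cnv <- stats::setNames(cn$value, as.character(cn$unit_id))
    sum_p <- zonal_sum(p, admin_labels)
    sum_rp <- zonal_sum(R * p, admin_labels)
    ids <- names(sum_p)
    mult <- stats::setNames(rep(1, length(ids)), ids)
    unif <- character(0)
    for (u in ids) {
      if (!u %in% names(cnv)) next
      if (sum_rp[[u]] > 0) {
        mult[[u]] <- cnv[[u]] * sum_p[[u]] / sum_rp[[u]]
      } else if (cnv[[u]] > 0) {
        unif <- c(unif, u)
      }
    }
    adj <- R * matrix(mult[as.character(admin_labels)], nrow(R), ncol(R))
    if (length(unif) > 0) {
      message("uniform-rate fallback for unit(s) ",
              paste(unif, collapse = ", "), " in ", y)
      pick <- matrix(as.character(admin_labels) %in% unif, nrow(R), ncol(R))
      adj[pick] <- matrix(cnv[as.character(admin_labels)],
                          nrow(R), ncol(R))[pick]
    }
    adj[p == 0] <- R[p == 0]
    out[, , y] <- adj
  }
  out
}

#' Full downscaling of one rate type
#'
#' @param census harmonized RateSeries for one rate type (admin-1).
#' @param covariates named list of covariate rasters.
#' @param population 3-D population array.
#' @param admin_labels admin-1 label matrix.
#' @param country_labels admin-0 label matrix.
#' @param income_groups data.frame (`country_id`, `group`).
#' @param rate_type `"birth"` or `"death"`.
#' @param predictor_weighting aggregation of predictors to units for the
#'   regression table: `"population"` (default; consistent with census rates
#'   being population-weighted aggregates) or `"unweighted"`.
#' @return list: `models`, `unit_table`, `predicted`, `residual_field`,
#'   `residual_surface`, `adjusted` (the DownscaledRates array).
#' @export
downscale_rates <- function(census, covariates, population, admin_labels,
                            country_labels, income_groups,
                            rate_type = c("birth", "death"),
                            predictor_weighting = c("population",
                                                    "unweighted")) {
  rate_type <- match.arg(rate_type)
  predictor_weighting <- match.arg(predictor_weighting)
  years <- sort(unique(census$year))
  preds <- PREDICTORS[[rate_type]]
  ut <- aggregate_covariates_to_units(
    covariates[preds], admin_labels, population = population,
    weighting = if (predictor_weighting == "population") "population"
    else "unweighted",
    years = years)
  ut$value <- census$value[match(paste(ut$unit_id, ut$year),
                                 paste(census$unit_id, census$year))]
  ut$country_id <- census$country_id[match(ut$unit_id, census$unit_id)]
  ut$group <- income_groups$group[match(ut$country_id,
                                        income_groups$country_id)]
  ut <- ut[!is.na(ut$value), ]
  models <- fit_income_models(ut, rate_type)
  group_cells <- matrix(
    income_groups$group[match(as.vector(country_labels),
                              income_groups$country_id)],
    nrow(country_labels), ncol(country_labels))
  predicted <- predict_rate_cells(models, covariates, group_cells,
                                  rate_type, years)
  rf <- compute_areal_residuals(predicted, census, admin_labels, population)
  rsurf <- atpk_distribute(rf, admin_labels)
  approx <- predicted + rsurf[, , dimnames(predicted)[[3]]]
  adjusted <- adjust_rates(approx, census, population, admin_labels)
  list(models = models, unit_table = ut, predicted = predicted,
       residual_field = rf, residual_surface = rsurf, adjusted = adjusted)
}
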
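#' End-to-end pipeline
#'
#' Runs the stages in dependency order on a synthetic world: synth ->
#' harmonize -> downscale -> migrate -> urban -> bins -> classify ->
#' validate. All randomness derives from the single seed in the world
#' configuration (the generator adds fixed small offsets per use), so two
#' runs with the same config produce identical results; the manifest records
#' parameters and per-stage numeric summaries and is hash-comparable.
#'
#' @param config a [world_config()].
#' @param stages ordered subset of the stage names above; earlier stages a
#'   requested stage depends on must be included (or have run before).
#' @param predictor_weighting see [downscale_rates()].
#' @param state optionally, the result of a previous partial run to extend.
#' @return named list of stage artifacts plus `manifest`.
#' @export
run_pipeline <- function(config = world_config(),
                         stages = c("synth", "harmonize", "downscale",
                                    "migrate", "urban", "bins", "classify",
                                    "validate"),
                         predictor_weighting = "population",
                         state = NULL) {
  all_stages <- c("synth", "harmonize", "downscale", "migrate", "urban",
                  "bins", "classify", "validate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  st <- if (is.null(state)) list() else state
  manifest <- if (is.null(st$manifest)) {
    list(parameters = unclass(config), stages = list())
  } else st$manifest

  chk <- function(x) {
    v <- suppressWarnings(as.numeric(unlist(x)))
    sprintf("%.12g", sum(v[is.finite(v)]) + 1e-3 * sum(!is.finite(v)))
  }
  need <- function(what, from) {
    if (is.null(st[[what]]))
      stop("missing upstream artifact '", what, "': rerun stage '", from,
           "' first")
  }

  for (stage in all_stages[all_stages %in% stages]) {
    if (stage == "synth") {
      st$world <- generate_world(config)
      manifest$stages$synth <- list(
        population_checksum = chk(st$world$population),
        censuses_checksum = chk(st$world$censuses_missing$value))
    }
    if (stage == "harmonize") {
      need("world", "synth")
      w <- st$world
      unit_pop <- NULL
      national_pop <- NULL
      for (y in w$years) {
        p <- w$population[, , as.character(y)]
        up <- zonal_sum(p, w$admin$adm1)
        np <- zonal_sum(p, w$admin$adm0)
        unit_pop <- rbind(unit_pop, data.frame(
          unit_id = as.integer(names(up)), year = y,
          population = as.numeric(up)))
        national_pop <- rbind(national_pop, data.frame(
          country_id = as.integer(names(np)), year = y,
          population = as.numeric(np)))
      }
      st$unit_pop <- unit_pop
      st$harmonized <- harmonize_rates(
        w$censuses_missing, w$gapfill_context, w$national_reported,
        w$macro_regions, w$units, unit_pop, national_pop, w$years)
      manifest$stages$harmonize <- list(
        n_records = nrow(st$harmonized),
        values_checksum = chk(st$harmonized$value))
    }
    if (stage == "downscale") {
      need("harmonized", "harmonize")
      w <- st$world
      st$downscaled <- lapply(c(birth = "birth", death = "death"),
        function(ty) downscale_rates(
          st$harmonized[st$harmonized$rate_type == ty, ],
          w$covariates, w$population, w$admin$adm1, w$admin$adm0,
          w$income_groups, ty, predictor_weighting))
      manifest$stages$downscale <- list(
        birth_r2 = vapply(st$downscaled$birth$models,
                          function(m) m$r_squared, 0),
        death_r2 = vapply(st$downscaled$death$models,
                          function(m) m$r_squared, 0),
        rates_checksum = chk(list(st$downscaled$birth$adjusted,
                                  st$downscaled$death$adjusted)))
    }
    if (stage == "migrate") {
      need("downscaled", "downscale")
      w <- st$world
      st$natural <- natural_change(st$downscaled$birth$adjusted,
                                   st$downscaled$death$adjusted,
                                   w$population)
      Y <- length(w$years)
      st$migration <- net_migration(
        w$population, st$natural[, , seq_len(Y - 1)])
      st$summaries <- lapply(
        list(adm0 = w$admin$adm0, adm1 = w$admin$adm1, adm2 = w$admin$adm2),
        function(lab) aggregate_migration(st$migration, lab, w$population))
      manifest$stages$migrate <- list(
        migration_checksum = chk(st$migration),
        global_sum = sum(st$migration))
    }
    if (stage == "urban") {
      need("world", "synth")
      w <- st$world
      st$masks <- urban_masks(w$population, w$covariates$scaled_density,
                              w$admin$adm0, w$urban_share)
      manifest$stages$urban <- list(urban_cells = sum(st$masks == 1,
                                                      na.rm = TRUE))
    }
    if (stage == "bins") {
      need("world", "synth")
      w <- st$world
      hdi_ref <- apply(w$covariates$hdi, c(1, 2), mean)
      pop_ref <- apply(w$population, c(1, 2), mean)
      st$bins <- assign_bins(hdi_ref, w$covariates$aridity, pop_ref)
      if (!is.null(st$migration) && !is.null(st$masks)) {
        st$bin_stats <- bin_statistics(st$bins, st$migration, st$masks,
                                       w$population)
      }
      manifest$stages$bins <- list(n_bins = length(unique(
        as.vector(st$bins[!is.na(st$bins)]))))
    }
    if (stage == "classify") {
      need("migration", "migrate"); need("masks", "urban")
      w <- st$world
      st$classes <- classify_all_units(st$migration, w$population,
                                       w$admin$adm1, st$masks)
      manifest$stages$classify <- list(
        impact_shares = as.list(st$classes$shares$impact),
        direction_shares = as.list(st$classes$shares$direction))
    }
    if (stage == "validate") {
      need("summaries", "migrate")
      w <- st$world
      true_sum <- zonal_sum(apply(w$true_net_migration, c(1, 2), sum),
                            w$admin$adm1)
      est <- st$summaries$adm1$cumulative
      est <- est[est$window == paste0(min(w$years), "-",
                                      max(w$years) - 1), ]
      st$validation <- compare_to_observations(
        data.frame(unit_id = est$unit_id, value = est$net_migration),
        data.frame(unit_id = as.integer(names(true_sum)),
                   value = as.numeric(true_sum)))
      manifest$stages$validate <- list(
        pearson = st$validation$pearson, bias = st$validation$bias)
    }
  }
  st$manifest <- manifest
  st
}

#' Write pipeline outputs and the manifest to a directory
#'
#' Tables go to CSV, the manifest to JSON; rasters are written in long CSV
#' form by [write_world()] for the world itself.
#'
#' @param result output of [run_pipeline()].
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  if (!is.null(result$harmonized)) wr(result$harmonized, "harmonized_rates.csv")
  if (!is.null(result$summaries)) {
    for (lv in names(result$summaries)) {
      wr(result$summaries[[lv]]$annual,
         paste0("net_migration_", lv, "_annual.csv"))
      wr(result$summaries[[lv]]$cumulative,
         paste0("net_migration_", lv, "_cumulative.csv"))
    }
  }
  if (!is.null(result$bin_stats)) wr(result$bin_stats, "bin_statistics.csv")
  if (!is.null(result$classes)) wr(result$classes$units,
                                   "unit_classification.csv")
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
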
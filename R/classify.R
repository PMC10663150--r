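#' Categorical classification of migration's demographic role
#'
#' Two classifiers, applicable at any zonal level. The impact classifier
#' compares total population change over a window (`popChange`), accumulated
#' net migration (`netMgrSum`) and the counterfactual change without
#' migration (`popChange_woMgr = popChange - netMgrSum`); six strict-sign
#' criteria describe how migration reshapes natural growth or decline, and
#' any boundary case with an exact zero falls into a seventh `negligible`
#' class. The direction classifier reads the sign pair of accumulated urban
#' and rural net migration within a unit.
#'
#' @name classify
NULL

IMPACT_LEVELS <- c("increases_growth", "slows_decline",
                   "turns_decline_to_growth", "increases_decline",
                   "slows_growth", "turns_growth_to_decline", "negligible")

DIRECTION_LEVELS <- c("net_receiving", "net_sending",
                      "rural_pull_urban_push", "urban_pull_rural_push",
                      "zero")

#' Impact of migration on population change
#'
#' Criteria (strict inequalities; `woMgr = pop_change - net_mgr_sum`):
#' growth turned from decline (`woMgr < 0 & popChange > 0`), decline turned
#' from growth (`woMgr > 0 & popChange < 0`), slowed decline
#' (`popChange < 0 & netMgrSum > 0`), slowed growth
#' (`popChange > 0 & netMgrSum < 0`), amplified growth
#' (`woMgr > 0 & netMgrSum > 0`), amplified decline
#' (`woMgr < 0 & netMgrSum < 0`). The "turns" classes are evaluated first;
#' any exact zero matches no strict criterion and yields `negligible`.
#'
#' @param pop_change total population change over the window (persons).
#' @param net_mgr_sum accumulated net migration over the window (persons).
#' @return factor with levels `r toString(IMPACT_LEVELS)`; vectorized.
#' @export
impact_class <- function(pop_change, net_mgr_sum) {
  womgr <- pop_change - net_mgr_sum
  out <- rep("negligible", length(pop_change))
  pick <- function(cond, label) {
    hit <- cond & out == "negligible"
    out[hit] <<- label
  }
  pick(womgr < 0 & pop_change > 0, "turns_decline_to_growth")
  pick(womgr > 0 & pop_change < 0, "turns_growth_to_decline")
  pick(pop_change < 0 & net_mgr_sum > 0, "slows_decline")
  pick(pop_change > 0 & net_mgr_sum < 0, "slows_growth")
  pick(womgr > 0 & net_mgr_sum > 0, "increases_growth")
  pick(womgr < 0 & net_mgr_sum < 0, "increases_decline")
  factor(out, levels = IMPACT_LEVELS)
}

#' Direction of rural/urban migration
#'
#' Sign-pattern lookup: both positive = net-receiving, both negative =
#' net-sending, urban negative with rural positive = rural pull-urban push,
#' urban positive with rural negative = urban pull-rural push, both zero =
#' zero. Mixed zero/nonzero patterns match no strict criterion and are
#' reported as `zero` (the audit subclass records which side moved).
#'
#' @param urban_mgr,rural_mgr accumulated urban / rural net migration
#'   (persons); vectorized.
#' @param audit when `TRUE`, return a data.frame with the main class and an
#'   `audit` column naming zero-adjacent subclasses.
#' @return factor with levels `r toString(DIRECTION_LEVELS)` (or a
#'   data.frame when `audit = TRUE`).
#' @export
direction_class <- function(urban_mgr, rural_mgr, audit = FALSE) {
  out <- rep("zero", length(urban_mgr))
  out[urban_mgr > 0 & rural_mgr > 0] <- "net_receiving"
  out[urban_mgr < 0 & rural_mgr < 0] <- "net_sending"
  out[urban_mgr < 0 & rural_mgr > 0] <- "rural_pull_urban_push"
  out[urban_mgr > 0 & rural_mgr < 0] <- "urban_pull_rural_push"
  cls <- factor(out, levels = DIRECTION_LEVELS)
  if (!audit) return(cls)
  aud <- rep("", length(urban_mgr))
  one_zero <- xor(urban_mgr == 0, rural_mgr == 0)
  aud[one_zero & urban_mgr == 0] <- ifelse(
    rural_mgr[one_zero & urban_mgr == 0] > 0, "zero_urban_rural_gain",
    "zero_urban_rural_loss")
  aud[one_zero & rural_mgr == 0] <- ifelse(
    urban_mgr[one_zero & rural_mgr == 0] > 0, "zero_rural_urban_gain",
    "zero_rural_urban_loss")
  data.frame(class = cls, audit = aud)
}

#' Classify all units and report population shares per class
#'
#' Per unit: the overall impact class, urban- and rural-specific impact
#' classes, the direction class, and global population shares per class
#' (summing to 100% over classified units).
#'
#' @param migration 3-D net-migration array.
#' @param population 3-D population array (one more year than migration).
#' @param admin_labels label matrix of the requested level.
#' @param masks 3-D urban-mask array.
#' @return list: `units` (per-unit table) and `shares` (population share per
#'   impact and direction class, in percent).
#' @export
classify_all_units <- function(migration, population, admin_labels, masks) {
  myears <- dimnames(migration)[[3]]
  pyears <- dimnames(population)[[3]]
  y0 <- pyears[1]; y1 <- pyears[length(pyears)]

  mig_sum <- apply(migration, c(1, 2), sum)
  dim(mig_sum) <- dim(admin_labels)
  tot_mgr <- zonal_sum(mig_sum, admin_labels)
  dpop <- zonal_sum(slice2d(population, y1) - slice2d(population, y0),
                    admin_labels)
  endpop <- zonal_sum(slice2d(population, y1), admin_labels)

  part_sums <- function(part) {
    mgr <- stats::setNames(rep(0, length(tot_mgr)), names(tot_mgr))
    dp <- mgr
    for (y in myears) {
      msk <- slice2d(masks, y)
      sel <- if (part == "urban") msk == 1 else msk == 0
      sel[is.na(sel)] <- FALSE
      m <- slice2d(migration, y); m[!sel] <- 0
      mgr <- mgr + zonal_sum(m, admin_labels)[names(mgr)]
      # within-mask population change over the year
      d <- slice2d(population, as.integer(y) + 1) - slice2d(population, y)
      d[!sel] <- 0
      dp <- dp + zonal_sum(d, admin_labels)[names(dp)]
    }
    list(mgr = mgr, dpop = dp)
  }
  urb <- part_sums("urban")
  rur <- part_sums("rural")

  keep <- endpop > 0
  if (any(!keep))
    message("unit(s) without population excluded: ",
            paste(names(endpop)[!keep], collapse = ", "))
  ids <- names(tot_mgr)[keep]
  units <- data.frame(
    unit_id = as.integer(ids),
    pop_change = as.numeric(dpop[ids]),
    net_mgr_sum = as.numeric(tot_mgr[ids]),
    impact = impact_class(dpop[ids], tot_mgr[ids]),
    impact_urban = impact_class(urb$dpop[ids], urb$mgr[ids]),
    impact_rural = impact_class(rur$dpop[ids], rur$mgr[ids]),
    population = as.numeric(endpop[ids]))
  dc <- direction_class(urb$mgr[ids], rur$mgr[ids], audit = TRUE)
  units$direction <- dc$class
  units$direction_audit <- dc$audit

  share_of <- function(f, levels) {
    s <- tapply(units$population, factor(f, levels = levels), sum,
                default = 0)
    100 * s / sum(units$population)
  }
  list(units = units,
       shares = list(impact = share_of(units$impact, IMPACT_LEVELS),
                     direction = share_of(units$direction,
                                          DIRECTION_LEVELS)))
}
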
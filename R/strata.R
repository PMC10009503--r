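#' Poverty stratum levels
#'
#' Ordered from poorest to most prosperous.
#' @return `c("Low", "Medium", "High")`
#' @export
stratum_levels <- function() c("Low", "Medium", "High")

#' Classify households into the three poverty strata
#'
#' Two thresholds define three strata: households at or above the
#' international poverty line in total value of activities per MAE per day
#' are `High`; of the rest, those at or above the calorie line in food
#' availability are `Medium`; the remainder, unable to cover basic calorie
#' needs, are `Low`. The value test dominates the calorie test, so a
#' household above the poverty line is High even when its FA falls short of
#' the calorie line; such discordant households are counted in the
#' `discordant` attribute. Both comparisons are closed on the upper side
#' (`>=`).
#'
#' @param fa food availability, kcal/MAE/day (non-negative).
#' @param tva_per_mae_day total value of activities, PPP $/MAE/day
#'   (non-negative).
#' @param calorie_line lower threshold, kcal/MAE/day.
#' @param poverty_line upper threshold, PPP $/MAE/day.
#' @return factor with levels Low < Medium < High; attribute `discordant`
#'   holds the number of High households below the calorie line.
#' @export
classify_stratum <- function(fa, tva_per_mae_day,
                             calorie_line = 3000, poverty_line = 1.90) {
  if (any(fa < 0, na.rm = TRUE) || any(tva_per_mae_day < 0, na.rm = TRUE))
    stop("fa and tva_per_mae_day must be non-negative")
  s <- ifelse(tva_per_mae_day >= poverty_line, "High",
              ifelse(fa >= calorie_line, "Medium", "Low"))
  out <- factor(s, levels = stratum_levels(), ordered = TRUE)
  attr(out, "discordant") <- sum(tva_per_mae_day >= poverty_line &
                                   fa < calorie_line, na.rm = TRUE)
  out
}

#' Stratum assignments for an indicator table
#'
#' Applies [classify_stratum()] to every household x round row of a
#' [compute_indicators()] result.
#'
#' @param indicators a `povdyn_indicators` data.frame.
#' @param calorie_line,poverty_line thresholds, see [classify_stratum()].
#' @return data.frame with `household_id`, `site`, `round`, `fa`,
#'   `tva_per_mae_day`, `stratum`.
#' @export
assign_strata <- function(indicators, calorie_line = 3000,
                          poverty_line = 1.90) {
  s <- classify_stratum(indicators$fa, indicators$tva_per_mae_day,
                        calorie_line, poverty_line)
  out <- data.frame(household_id = indicators$household_id,
                    site = indicators$site, round = indicators$round,
                    fa = indicators$fa,
                    tva_per_mae_day = indicators$tva_per_mae_day,
                    stratum = s, stringsAsFactors = FALSE)
  attr(out, "discordant") <- attr(s, "discordant")
  out
}

#' Nine-group household trajectory
#'
#' A household's trajectory is its stratum in the first panel followed by
#' its stratum in the second, giving nine groups ("Low to Low" ... "High to
#' High"), each rising, steady or falling by the stratum order
#' Low < Medium < High.
#'
#' @param from,to strata (`"Low"`, `"Medium"`, `"High"`).
#' @return list with `label` and `direction`.
#' @export
trajectory_label <- function(from, to) {
  lv <- stratum_levels()
  stopifnot(from %in% lv, to %in% lv)
  i <- match(from, lv); j <- match(to, lv)
  list(label = paste(from, "to", to),
       direction = if (j > i) "rising" else if (j < i) "falling" else "steady")
}

#' Assign trajectories for all households resurveyed in round 2
#'
#' @param assignments output of [assign_strata()] covering both rounds.
#' @return data.frame with `household_id`, `from_stratum`, `to_stratum`,
#'   `label`, `direction`; one row per household present in both rounds.
#' @export
assign_trajectories <- function(assignments) {
  a1 <- assignments[assignments$round == 1, ]
  a2 <- assignments[assignments$round == 2, ]
  common <- intersect(a1$household_id, a2$household_id)
  from <- as.character(a1$stratum[match(common, a1$household_id)])
  to <- as.character(a2$stratum[match(common, a2$household_id)])
  lv <- stratum_levels()
  i <- match(from, lv); j <- match(to, lv)
  data.frame(household_id = common, from_stratum = from, to_stratum = to,
             label = paste(from, "to", to),
             direction = ifelse(j > i, "rising",
                                ifelse(j < i, "falling", "steady")),
             stringsAsFactors = FALSE)
}

#' Per-round strata proportions
#'
#' @param assignments output of [assign_strata()].
#' @return matrix with one row per round and columns Low, Medium, High;
#'   rows sum to 1.
#' @export
strata_proportions <- function(assignments) {
  stopifnot(nrow(assignments) > 0)
  tab <- table(assignments$round,
               factor(assignments$stratum, levels = stratum_levels()))
  out <- sweep(unclass(tab), 1, rowSums(tab), "/")
  out
}

#' Flow matrix between strata across the two rounds
#'
#' Counts of households by (round-1 stratum, round-2 stratum) on the matched
#' panel subsample, plus the shares of households rising, steady and
#' falling. Row sums equal round-1 strata counts among resurveyed
#' households; the grand total is the number of panel households.
#'
#' @param trajectories output of [assign_trajectories()].
#' @return list with `counts` (3x3 matrix, rows = round 1), `proportions`,
#'   and `shares` (named vector rising/steady/falling summing to 1).
#' @export
flow_matrix <- function(trajectories) {
  lv <- stratum_levels()
  counts <- table(factor(trajectories$from_stratum, levels = lv),
                  factor(trajectories$to_stratum, levels = lv))
  counts <- unclass(counts)
  n <- sum(counts)
  shares <- c(rising = mean(trajectories$direction == "rising"),
              steady = mean(trajectories$direction == "steady"),
              falling = mean(trajectories$direction == "falling"))
  list(counts = counts, proportions = counts / n, shares = shares, n = n)
}

#' Ratio of value share to land share
#'
#' The ratio step of [share_table()]: a stratum's share of farm-produce
#' value divided by its share of land, reported at two decimal places. A
#' value above 1 means the stratum extracts more value per unit land than
#' the population average.
#'
#' @param value_share,land_share percentages (or proportions, consistently).
#' @param digits decimal places for reporting (default 2).
#' @return numeric ratio(s), rounded to `digits`.
#' @export
value_land_ratio <- function(value_share, land_share, digits = 2) {
  if (any(land_share <= 0)) stop("land share must be positive")
  round(value_share / land_share, digits)
}

#' Per-stratum shares of population, land and farm-produce value
#'
#' For each round and stratum: the share of households, of land cultivated,
#' and of total farm-produce value (crop plus livestock value, excluding
#' off-farm income), plus the value:land share ratio. Shares are
#' percentages summing to 100 within a round; ratios are computed from the
#' unrounded shares and reported at 2 decimal places.
#'
#' @param assignments output of [assign_strata()].
#' @param indicators matching `povdyn_indicators` table (provides land and
#'   produce value).
#' @return data.frame with one row per round x stratum.
#' @export
share_table <- function(assignments, indicators) {
  key_a <- paste(assignments$household_id, assignments$round)
  key_i <- paste(indicators$household_id, indicators$round)
  idx <- match(key_a, key_i)
  if (anyNA(idx)) stop("indicators missing for some assigned households")
  land <- indicators$land[idx]
  value <- indicators$crop_value[idx] + indicators$livestock_value[idx]
  out <- NULL
  for (r in sort(unique(assignments$round))) {
    sel <- assignments$round == r
    if (sum(land[sel]) <= 0) stop(sprintf("zero total land in round %s", r))
    if (sum(value[sel]) <= 0) stop(sprintf("zero total produce value in round %s", r))
    for (s in stratum_levels()) {
      g <- sel & assignments$stratum == s
      pop <- 100 * sum(g) / sum(sel)
      land_sh <- 100 * sum(land[g]) / sum(land[sel])
      val_sh <- 100 * sum(value[g]) / sum(value[sel])
      out <- rbind(out, data.frame(
        round = r, stratum = s, pop_pct = pop, land_pct = land_sh,
        value_pct = val_sh,
        ratio = if (land_sh > 0) value_land_ratio(val_sh, land_sh) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Net change in value and intensity by trajectory group
#'
#' Per-household round-2 minus round-1 differences in the value of crop,
#' livestock and off-farm activities and in the three intensity metrics,
#' grouped by the nine trajectory labels, with group medians. Households
#' missing from either round are excluded and recorded in the `excluded`
#' attribute.
#'
#' @param indicators `povdyn_indicators` covering both rounds.
#' @param trajectories output of [assign_trajectories()].
#' @return list with `deltas` (one row per matched household) and `medians`
#'   (one row per trajectory label x metric).
#' @export
net_change_by_trajectory <- function(indicators, trajectories) {
  metrics <- c("crop_value", "livestock_value", "off_farm_income",
               "crop_intensity", "livestock_intensity", "offfarm_intensity")
  i1 <- indicators[indicators$round == 1, ]
  i2 <- indicators[indicators$round == 2, ]
  m1 <- match(trajectories$household_id, i1$household_id)
  m2 <- match(trajectories$household_id, i2$household_id)
  ok <- !is.na(m1) & !is.na(m2)
  excluded <- trajectories$household_id[!ok]
  deltas <- data.frame(household_id = trajectories$household_id[ok],
                       label = trajectories$label[ok],
                       direction = trajectories$direction[ok],
                       stringsAsFactors = FALSE)
  for (m in metrics) deltas[[paste0("d_", m)]] <- i2[[m]][m2[ok]] - i1[[m]][m1[ok]]
  med <- NULL
  for (lab in unique(deltas$label)) {
    sel <- deltas$label == lab
    for (m in metrics) {
      med <- rbind(med, data.frame(
        label = lab, metric = m,
        median_delta = stats::median(deltas[[paste0("d_", m)]][sel], na.rm = TRUE),
        n = sum(sel), stringsAsFactors = FALSE))
    }
  }
  structure(list(deltas = deltas, medians = med), excluded = excluded)
}

#' Composition of the total value of activities by stratum
#'
#' Average share of each household's TVA derived from crops consumed, crops
#' sold, livestock products consumed, livestock products sold and off-farm
#' income, per stratum and round. Within each stratum the five mean shares
#' sum to 1. Households with zero TVA have no defined composition and are
#' excluded.
#'
#' @param indicators `povdyn_indicators` table.
#' @param assignments output of [assign_strata()].
#' @return data.frame, one row per round x stratum, share columns
#'   `crops_consumed`, `crops_sold`, `livestock_consumed`,
#'   `livestock_sold`, `off_farm`.
#' @export
tva_composition <- function(indicators, assignments) {
  key_a <- paste(assignments$household_id, assignments$round)
  key_i <- paste(indicators$household_id, indicators$round)
  idx <- match(key_a, key_i)
  comp_cols <- c(crops_consumed = "value_consumed_crops",
                 crops_sold = "value_sold_crops",
                 livestock_consumed = "value_consumed_livestock",
                 livestock_sold = "value_sold_livestock",
                 off_farm = "off_farm_income")
  out <- NULL
  for (r in sort(unique(assignments$round))) {
    for (s in stratum_levels()) {
      g <- which(assignments$round == r & assignments$stratum == s)
      rows <- idx[g]
      tva <- indicators$tva[rows]
      rows <- rows[tva > 0]; tva <- tva[tva > 0]
      if (length(rows) == 0) next
      shares <- vapply(comp_cols, function(cc)
        mean(indicators[[cc]][rows] / tva), numeric(1))
      out <- rbind(out, data.frame(round = r, stratum = s, n = length(rows),
                                   as.list(shares), stringsAsFactors = FALSE))
    }
  }
  out
}
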
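#' Male adult equivalents of a household roster
#'
#' Sums the age/sex energy-demand factor of every member, so that households
#' of different size and composition are comparable on a per-consumer basis.
#' An adult male contributes exactly 1.0.
#'
#' @param roster data.frame with columns `age` (years) and `sex`
#'   (`"M"`/`"F"`).
#' @param mae_factors factor table, see [default_mae_factors()].
#' @return MAE persons (positive scalar).
#' @export
compute_mae <- function(roster, mae_factors = default_mae_factors()) {
  if (is.null(roster) || nrow(roster) == 0) stop("roster is empty")
  bad <- roster$age < 0
  if (any(bad)) {
    warning(sprintf("rejecting %d roster member(s) with negative age",
                    sum(bad)))
    roster <- roster[!bad, , drop = FALSE]
    if (nrow(roster) == 0) stop("roster is empty after rejecting members")
  }
  f <- mae_member_factors(roster$age, roster$sex, mae_factors)
  sum(f)
}

# Vectorised factor lookup: first matching band wins, sex-specific bands
# take precedence over "any" only through table order.
mae_member_factors <- function(age, sex, mae_factors) {
  out <- numeric(length(age))
  for (i in seq_along(age)) {
    hit <- which(mae_factors$age_min <= age[i] & age[i] <= mae_factors$age_max &
                   (mae_factors$sex == "any" | mae_factors$sex == sex[i]))
    if (length(hit) == 0) {
      stop(sprintf("no MAE factor for age %s, sex %s", age[i], sex[i]))
    }
    out[i] <- mae_factors$factor[hit[1]]
  }
  out
}

#' Tropical livestock units of a herd
#'
#' Weighted head count with 1 TLU equal to one 250 kg cow; five goats
#' (weight 0.2) also make one TLU.
#'
#' @param livestock_counts named numeric, head counts by species.
#' @param tlu_weights named numeric, TLU per head by species.
#' @return TLU (non-negative scalar).
#' @export
compute_tlu <- function(livestock_counts, tlu_weights = default_tlu_weights()) {
  if (length(livestock_counts) == 0) return(0)
  if (any(livestock_counts < 0)) stop("negative livestock counts")
  unknown <- setdiff(names(livestock_counts), names(tlu_weights))
  if (length(unknown) > 0) {
    stop(sprintf("no TLU weight for species: %s",
                 paste(unknown, collapse = ", ")))
  }
  sum(livestock_counts * tlu_weights[names(livestock_counts)])
}

# Local-currency value of one product table (crops or livestock products)
# for all households at once. Reported sale income takes precedence over
# quantity x price; consumption is always valued at the local price.
value_rows <- function(tab, prod_col, hh, conv) {
  if (nrow(tab) == 0) {
    return(data.frame(household_id = character(), round = integer(),
                      consumed_value = numeric(), sold_value = numeric(),
                      consumed_kcal = numeric(), stringsAsFactors = FALSE))
  }
  site <- hh$site[match(paste(tab$household_id, tab$round),
                        paste(hh$household_id, hh$round))]
  pk <- paste(site, tab$round, tab[[prod_col]])
  price <- conv$prices$price[match(pk, with(conv$prices,
                                            paste(site, round, product)))]
  if (anyNA(price)) {
    miss <- unique(pk[is.na(price)])
    stop(sprintf("unpriced product(s): %s", paste(miss, collapse = "; ")),
         call. = FALSE)
  }
  maize_p <- conv$maize_price$price[match(paste(site, tab$round),
                                          with(conv$maize_price, paste(site, round)))]
  if (anyNA(maize_p)) stop("missing maize price for some site/round",
                           call. = FALSE)
  consumed_value <- tab$consumed_kg * price
  sold_value <- ifelse(!is.na(tab$sale_income) & tab$sale_income > 0,
                       tab$sale_income, tab$sold_kg * price)
  kcal_direct <- if (is.null(conv$kcal_per_kg)) rep(NA_real_, nrow(tab)) else
    conv$kcal_per_kg[tab[[prod_col]]]
  consumed_kcal <- ifelse(!is.na(kcal_direct),
                          tab$consumed_kg * kcal_direct,
                          consumed_value * conv$maize_energy / maize_p)
  data.frame(household_id = tab$household_id, round = tab$round,
             consumed_value = consumed_value, sold_value = sold_value,
             consumed_kcal = consumed_kcal, stringsAsFactors = FALSE)
}

sum_by_household <- function(vals, hh_key, col) {
  if (nrow(vals) == 0) return(numeric(length(hh_key)))
  agg <- tapply(vals[[col]], paste(vals$household_id, vals$round), sum)
  out <- as.numeric(agg[hh_key])
  out[is.na(out)] <- 0
  out
}

#' Per-household indicator set for a two-round panel
#'
#' Computes, for every household and round: MAE, TLU, the five value
#' components in PPP dollars per year (crops consumed, crops sold, livestock
#' products consumed, livestock products sold, off-farm income), their sum
#' the Total Value of Activities (TVA), TVA per MAE per day, Food
#' Availability (FA, kcal per MAE per day), and the three intensity metrics
#' (crop value per hectare, livestock value per TLU, off-farm income per
#' MAE).
#'
#' FA counts the calories of all consumed farm produce plus the calories
#' purchasable with cash income (sales plus off-farm) at the local staple
#' (maize) price. Consumed produce with an entry in the conversion table's
#' `kcal_per_kg` is counted at its own energy density; everything else is
#' valued at the local price and converted through the maize route.
#'
#' Intensities with a zero denominator are 0 when the numerator is also 0
#' and `NA` (excluded from group summaries) otherwise.
#'
#' @param panel a `povdyn_panel`.
#' @param conv a `povdyn_conversion`.
#' @param per denominator for the daily value threshold: `"mae"` (default)
#'   or `"capita"`.
#' @return data.frame, one row per household x round, of class
#'   `povdyn_indicators`.
#' @export
compute_indicators <- function(panel, conv, per = c("mae", "capita")) {
  stopifnot(inherits(panel, "povdyn_panel"), inherits(conv, "povdyn_conversion"))
  per <- match.arg(per)
  hh <- panel$households
  hh_key <- paste(hh$household_id, hh$round)

  ros <- panel$roster
  ros_f <- mae_member_factors(ros$age, ros$sex, conv$mae_factors)
  mae_agg <- tapply(ros_f, paste(ros$household_id, ros$round), sum)
  size_agg <- tapply(ros_f, paste(ros$household_id, ros$round), length)
  mae <- as.numeric(mae_agg[hh_key])
  hh_size <- as.integer(size_agg[hh_key])
  if (anyNA(mae) || any(mae <= 0)) stop("every household needs a non-empty roster")

  ls <- panel$livestock
  tlu <- numeric(nrow(hh))
  if (nrow(ls) > 0) {
    unknown <- setdiff(unique(ls$species), names(conv$tlu_weights))
    if (length(unknown) > 0) {
      stop(sprintf("no TLU weight for species: %s",
                   paste(unknown, collapse = ", ")))
    }
    tlu_agg <- tapply(ls$count * conv$tlu_weights[ls$species],
                      paste(ls$household_id, ls$round), sum)
    tlu <- as.numeric(tlu_agg[hh_key])
    tlu[is.na(tlu)] <- 0
  }

  crop_vals <- value_rows(panel$crops, "crop", hh, conv)
  lsp_vals <- value_rows(panel$livestock_products, "product", hh, conv)

  ppp <- conv$ppp$factor[match(hh$site, conv$ppp$site)]
  if (anyNA(ppp)) stop("missing PPP factor for some site")
  maize_p <- conv$maize_price$price[match(paste(hh$site, hh$round),
                                          with(conv$maize_price, paste(site, round)))]
  if (anyNA(maize_p)) stop("missing maize price for some site/round")

  cc_local <- sum_by_household(crop_vals, hh_key, "consumed_value")
  cs_local <- sum_by_household(crop_vals, hh_key, "sold_value")
  lc_local <- sum_by_household(lsp_vals, hh_key, "consumed_value")
  lsold_local <- sum_by_household(lsp_vals, hh_key, "sold_value")
  kcal_cons <- sum_by_household(crop_vals, hh_key, "consumed_kcal") +
    sum_by_household(lsp_vals, hh_key, "consumed_kcal")

  off_local <- hh$off_farm_income
  cash_local <- cs_local + lsold_local + off_local
  fa <- (kcal_cons + cash_local * conv$maize_energy / maize_p) / (mae * 365)

  value_consumed_crops <- cc_local / ppp
  value_sold_crops <- cs_local / ppp
  value_consumed_livestock <- lc_local / ppp
  value_sold_livestock <- lsold_local / ppp
  off_farm <- off_local / ppp
  crop_value <- value_consumed_crops + value_sold_crops
  livestock_value <- value_consumed_livestock + value_sold_livestock
  tva <- crop_value + livestock_value + off_farm
  denom <- if (per == "mae") mae else hh_size
  tva_per_mae_day <- tva / (denom * 365)

  land <- hh$land_cultivated
  out <- data.frame(
    household_id = hh$household_id, site = hh$site, round = hh$round,
    hh_size = hh_size, mae = mae, tlu = tlu, land = land,
    value_consumed_crops = value_consumed_crops,
    value_sold_crops = value_sold_crops,
    value_consumed_livestock = value_consumed_livestock,
    value_sold_livestock = value_sold_livestock,
    off_farm_income = off_farm,
    crop_value = crop_value, livestock_value = livestock_value,
    tva = tva, tva_per_mae_day = tva_per_mae_day, fa = fa,
    stringsAsFactors = FALSE)
  ints <- compute_intensities(crop_value, livestock_value, off_farm,
                              land, tlu, mae)
  out <- cbind(out, ints)
  class(out) <- c("povdyn_indicators", "data.frame")
  out
}

#' Value-production intensity metrics
#'
#' Crop value per hectare cultivated, livestock-product value per TLU, and
#' off-farm income per MAE. A ratio with both numerator and denominator zero
#' is 0; a positive numerator over a zero denominator is `NA` and flagged
#' for exclusion from group summaries.
#'
#' @param crop_value,livestock_value,off_farm value components, PPP $/yr.
#' @param land hectares cultivated.
#' @param tlu tropical livestock units.
#' @param mae male adult equivalents (must be positive).
#' @return data.frame with columns `crop_intensity`, `livestock_intensity`,
#'   `offfarm_intensity`.
#' @export
compute_intensities <- function(crop_value, livestock_value, off_farm,
                                land, tlu, mae) {
  if (any(mae <= 0)) stop("mae must be positive")
  ratio0 <- function(num, den) {
    ifelse(den > 0, num / den, ifelse(num == 0, 0, NA_real_))
  }
  data.frame(crop_intensity = ratio0(crop_value, land),
             livestock_intensity = ratio0(livestock_value, tlu),
             offfarm_intensity = off_farm / mae)
}

#' Food availability of a single household
#'
#' Scalar form of the FA computation in [compute_indicators()], mostly
#' useful for worked examples and checks: calories of consumed produce plus
#' cash converted at the maize price, per MAE per day.
#'
#' @param consumed_kcal total calories of consumed farm produce (kcal/yr).
#' @param cash_income cash from produce sales plus off-farm income, local
#'   currency per year.
#' @param mae male adult equivalents.
#' @param maize_price local maize price, currency/kg (must be positive).
#' @param maize_energy staple energy density, kcal/kg.
#' @return FA in kcal/MAE/day.
#' @export
compute_fa <- function(consumed_kcal, cash_income, mae,
                       maize_price, maize_energy = 3580) {
  if (maize_price <= 0) stop("maize price must be positive")
  if (mae <= 0) stop("mae must be positive")
  (consumed_kcal + cash_income * maize_energy / maize_price) / (mae * 365)
}
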
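#' Default dietary-diversity food groups
#'
#' The ten food groups used for the household dietary diversity score,
#' recorded once for the post-harvest (flush) season and once for the lean
#' season.
#'
#' @return Character vector of group names.
#' @export
hdds_groups <- function() {
  c("cereals", "roots_tubers", "legumes", "nuts_seeds", "vegetables",
    "fruits", "meat_fish", "eggs", "dairy", "oils_fats")
}

panel_tables <- c("households", "roster", "livestock", "crops",
                  "livestock_products")

required_cols <- list(
  households = c("household_id", "site", "round", "land_cultivated",
                 "off_farm_income", "months_food_shortage"),
  roster = c("household_id", "round", "age", "sex"),
  livestock = c("household_id", "round", "species", "count"),
  crops = c("household_id", "round", "crop", "produced_kg", "consumed_kg",
            "sold_kg", "sale_income"),
  livestock_products = c("household_id", "round", "product", "produced_kg",
                         "consumed_kg", "sold_kg", "sale_income"))

#' Assemble a two-round household panel
#'
#' The panel is a set of five linked long-format tables keyed by
#' `household_id` and `round` (1 or 2): one row per household in
#' `households` (land, off-farm income and the welfare response block), one
#' row per member in `roster`, per species in `livestock`, per crop in
#' `crops` and per animal product in `livestock_products`.
#'
#' @param households,roster,livestock,crops,livestock_products data.frames;
#'   see [read_household_table()] for the column contract.
#' @return An object of class `povdyn_panel`.
#' @export
household_panel <- function(households, roster, livestock, crops,
                            livestock_products) {
  tabs <- list(households = households, roster = roster,
               livestock = livestock, crops = crops,
               livestock_products = livestock_products)
  for (nm in names(tabs)) {
    missing <- setdiff(required_cols[[nm]], names(tabs[[nm]]))
    if (length(missing) > 0) {
      stop(sprintf("table '%s' is missing mandatory column(s): %s",
                   nm, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  if (nrow(households) > 0) {
    if (!all(households$round %in% c(1L, 2L)))
      stop("round must be 1 or 2", call. = FALSE)
    key <- paste(households$household_id, households$round)
    if (anyDuplicated(key))
      stop("duplicate household_id within a round", call. = FALSE)
  }
  structure(tabs, class = "povdyn_panel")
}

#' @export
print.povdyn_panel <- function(x, ...) {
  n1 <- sum(x$households$round == 1)
  n2 <- sum(x$households$round == 2)
  cat(sprintf("Household panel: %d households in round 1, %d in round 2\n",
              n1, n2))
  cat(sprintf("  sites: %s\n",
              paste(sort(unique(x$households$site)), collapse = ", ")))
  errs <- attr(x, "errors")
  if (!is.null(errs) && nrow(errs) > 0)
    cat(sprintf("  %d row-level validation findings (attr 'errors')\n",
                nrow(errs)))
  invisible(x)
}

# Row-level invariant screen. Offending crop / product rows are excluded
# (consumption + sales may exceed production only within the recall
# tolerance); households with an empty roster are dropped entirely.
screen_panel <- function(panel, tolerance = 0.05) {
  errors <- data.frame(household_id = character(), round = integer(),
                       table = character(), problem = character(),
                       stringsAsFactors = FALSE)
  note <- function(id, round, table, problem) {
    rbind(errors, data.frame(household_id = as.character(id),
                             round = as.integer(round), table = table,
                             problem = problem, stringsAsFactors = FALSE))
  }
  for (nm in c("crops", "livestock_products")) {
    tab <- panel[[nm]]
    if (nrow(tab) == 0) next
    qty <- c("produced_kg", "consumed_kg", "sold_kg")
    bad_neg <- rowSums(sapply(tab[qty], function(v) v < 0)) > 0
    over <- (tab$consumed_kg + tab$sold_kg) >
      tab$produced_kg * (1 + tolerance) + 1e-9
    for (i in which(bad_neg)) {
      errors <- note(tab$household_id[i], tab$round[i], nm,
                     "negative quantity")
    }
    for (i in which(over & !bad_neg)) {
      errors <- note(tab$household_id[i], tab$round[i], nm,
                     sprintf("consumed+sold exceeds produced by more than %g%%",
                             100 * tolerance))
    }
    panel[[nm]] <- tab[!(bad_neg | over), , drop = FALSE]
  }
  hh <- panel$households
  if (nrow(hh) > 0) {
    roster_key <- paste(panel$roster$household_id, panel$roster$round)
    hh_key <- paste(hh$household_id, hh$round)
    no_roster <- !(hh_key %in% roster_key)
    for (i in which(no_roster)) {
      errors <- note(hh$household_id[i], hh$round[i], "roster",
                     "empty roster")
    }
    if (any(no_roster)) {
      drop_key <- hh_key[no_roster]
      panel$households <- hh[!no_roster, , drop = FALSE]
      for (nm in setdiff(panel_tables, "households")) {
        tkey <- paste(panel[[nm]]$household_id, panel[[nm]]$round)
        panel[[nm]] <- panel[[nm]][!(tkey %in% drop_key), , drop = FALSE]
      }
    }
    neg_land <- panel$households$land_cultivated < 0 |
      panel$households$off_farm_income < 0
    for (i in which(neg_land)) {
      errors <- note(panel$households$household_id[i],
                     panel$households$round[i], "households",
                     "negative land or off-farm income")
    }
    panel$households <- panel$households[!neg_land, , drop = FALSE]
  }
  attr(panel, "errors") <- errors
  panel
}

#' Read a household panel from a directory of CSV files
#'
#' Expects `households.csv`, `roster.csv`, `livestock.csv`, `crops.csv` and
#' `livestock_products.csv` (comma-separated, UTF-8, "." decimal). Missing
#' numeric cells are read as 0 for quantities and incomes but kept missing
#' for welfare items, whose scores require complete responses. Rows that
#' violate the quantity invariants (negative amounts, or consumed + sold
#' exceeding production by more than `tolerance`) are excluded and reported
#' in the `errors` attribute of the result; a missing mandatory column is a
#' hard failure naming the column.
#'
#' @param dir directory containing the five CSV files.
#' @param tolerance relative recall tolerance for consumed + sold vs
#'   produced (default 5%).
#' @return A `povdyn_panel` with attribute `errors` (data.frame of excluded
#'   rows and the violated invariant).
#' @export
read_household_table <- function(dir, tolerance = 0.05) {
  tabs <- list()
  for (nm in panel_tables) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop(sprintf("missing file: %s", path),
                                 call. = FALSE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
    missing <- setdiff(required_cols[[nm]], names(tab))
    if (length(missing) > 0) {
      stop(sprintf("%s.csv is missing mandatory column(s): %s",
                   nm, paste(missing, collapse = ", ")), call. = FALSE)
    }
    qty_cols <- intersect(
      c("land_cultivated", "off_farm_income", "count",
        "produced_kg", "consumed_kg", "sold_kg", "sale_income"),
      names(tab))
    for (cc in qty_cols) tab[[cc]][is.na(tab[[cc]])] <- 0
    if ("round" %in% names(tab)) tab$round <- as.integer(tab$round)
    tabs[[nm]] <- tab
  }
  panel <- do.call(household_panel, tabs)
  screen_panel(panel, tolerance = tolerance)
}

#' Write a household panel to a directory of CSV files
#'
#' Inverse of [read_household_table()]: writing then reading a conforming
#' panel returns the same records.
#'
#' @param panel a `povdyn_panel`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_household_table <- function(panel, dir) {
  stopifnot(inherits(panel, "povdyn_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in panel_tables) {
    utils::write.csv(panel[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Cross-check a panel against a conversion table
#'
#' Report-only consistency screen: products that have no price for their
#' site and round, livestock species without a TLU weight, and households
#' that appear in round 2 without a round-1 record. Inputs are not modified.
#'
#' @param panel a `povdyn_panel`.
#' @param conv a `povdyn_conversion`.
#' @return data.frame with columns `type`, `household_id`, `detail`; zero
#'   rows when the dataset is fully consistent.
#' @export
validate_dataset <- function(panel, conv) {
  stopifnot(inherits(panel, "povdyn_panel"), inherits(conv, "povdyn_conversion"))
  findings <- list()
  add <- function(type, id, detail) {
    findings[[length(findings) + 1]] <<- data.frame(
      type = type, household_id = as.character(id), detail = detail,
      stringsAsFactors = FALSE)
  }
  priced <- with(conv$prices, paste(site, round, product))
  for (nm in c("crops", "livestock_products")) {
    tab <- panel[[nm]]
    prod_col <- if (nm == "crops") "crop" else "product"
    if (nrow(tab) == 0) next
    key <- paste(tab$household_id, tab$round, tab[[prod_col]])
    pkey <- with(tab, paste(panel$households$site[
      match(paste(household_id, round),
            paste(panel$households$household_id, panel$households$round))],
      round, tab[[prod_col]]))
    bad <- !(pkey %in% priced)
    for (i in which(bad)) {
      add("unpriced_product", tab$household_id[i],
          sprintf("%s '%s' has no price entry", nm, tab[[prod_col]][i]))
    }
  }
  ls <- panel$livestock
  if (nrow(ls) > 0) {
    unknown <- !(ls$species %in% names(conv$tlu_weights))
    for (i in which(unknown)) {
      add("unknown_species", ls$household_id[i],
          sprintf("species '%s' has no TLU weight", ls$species[i]))
    }
  }
  hh <- panel$households
  ids1 <- hh$household_id[hh$round == 1]
  orphans <- setdiff(hh$household_id[hh$round == 2], ids1)
  for (id in orphans) add("unmatched_panel_id", id,
                          "household present in round 2 but not round 1")
  if (length(findings) == 0) {
    return(data.frame(type = character(), household_id = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Panel retention bookkeeping
#'
#' Number of households per site in each round and the resurvey retention
#' percentage (round-2 households as a share of round 1, reported as an
#' integer percentage with halves rounding down) — e.g. 147 resurveyed of
#' 200 (73.5%) reports 73%.
#'
#' @param panel a `povdyn_panel`.
#' @return data.frame with columns `site`, `n_round1`, `n_round2`,
#'   `retention_pct`.
#' @export
panel_retention <- function(panel) {
  stopifnot(inherits(panel, "povdyn_panel"))
  hh <- panel$households
  sites <- sort(unique(hh$site))
  out <- data.frame(site = sites,
                    n_round1 = NA_integer_, n_round2 = NA_integer_,
                    retention_pct = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(sites)) {
    n1 <- sum(hh$site == sites[i] & hh$round == 1)
    n2 <- sum(hh$site == sites[i] & hh$round == 2)
    out$n_round1[i] <- n1
    out$n_round2[i] <- n2
    out$retention_pct[i] <- if (n1 > 0) ceiling(100 * n2 / n1 - 0.5) else NA_real_
  }
  out
}
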
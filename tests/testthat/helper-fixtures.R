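# Hand-sized fixtures shared across test files. Everything is built in
# code; nothing is read from disk except in the explicit IO round-trips.

# One-site conversion table with round-invariant unit-friendly prices.
tiny_conv <- function(ppp = 1, maize_price = 0.5) {
  products <- c("maize", "beans", "milk")
  prices <- expand.grid(site = "A", round = 1:2, product = products,
                        stringsAsFactors = FALSE)
  prices$price <- c(maize = maize_price, beans = 1.0,
                    milk = 0.8)[prices$product]
  maize <- prices[prices$product == "maize", c("site", "round", "price")]
  conversion_table(prices = prices, maize_price = maize,
                   ppp = data.frame(site = "A", factor = ppp),
                   maize_energy = 3580)
}

# Minimal single-household panel builder: quantities in kg, incomes in
# local currency; adults is the number of adult males on the roster.
tiny_panel <- function(id = "h1", round = 1, adults = 2,
                       crops = NULL, products = NULL,
                       off_farm = 0, land = 1, livestock = NULL) {
  hh <- data.frame(household_id = id, site = "A", round = round,
                   land_cultivated = land, off_farm_income = off_farm,
                   months_food_shortage = NA_real_,
                   stringsAsFactors = FALSE)
  roster <- data.frame(household_id = id, round = round,
                       age = rep(30, adults), sex = rep("M", adults),
                       stringsAsFactors = FALSE)
  empty_rows <- data.frame(household_id = character(), round = integer(),
                           crop = character(), produced_kg = numeric(),
                           consumed_kg = numeric(), sold_kg = numeric(),
                           sale_income = numeric(), stringsAsFactors = FALSE)
  if (is.null(crops)) crops <- empty_rows
  if (is.null(products)) {
    products <- empty_rows
    names(products)[3] <- "product"
  }
  if (is.null(livestock)) {
    livestock <- data.frame(household_id = character(), round = integer(),
                            species = character(), count = numeric(),
                            stringsAsFactors = FALSE)
  }
  household_panel(hh, roster, livestock, crops, products)
}

crop_row <- function(id, round, crop, produced, consumed, sold,
                     sale_income = 0) {
  data.frame(household_id = id, round = round, crop = crop,
             produced_kg = produced, consumed_kg = consumed, sold_kg = sold,
             sale_income = sale_income, stringsAsFactors = FALSE)
}

# A small but full synthetic study, generated once and reused.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sites <- list(
        site_config("S1", n_villages = 3, households_per_village = 15,
                    retention_fraction = 0.8, country = "Kenya",
                    ppp_factor = 43),
        site_config("S2", n_villages = 3, households_per_village = 15,
                    retention_fraction = 0.7, country = "Uganda",
                    ppp_factor = 1100, crops = c("banana", "beans")))
      cache <<- generate_panel(sites, default_design(), seed = 7)
    }
    cache
  }
})
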
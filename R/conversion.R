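#' Default male-adult-equivalent (MAE) factors
#'
#' Age/sex factors expressing each household member's energy demand relative
#' to an adult male (factor 1.0). Household MAE is the sum of member factors,
#' so a household of two adult men counts as 2 MAE. The table approximates
#' relative energy requirements by age band and sex and is deliberately
#' coarse; supply your own table via [conversion_table()] to change it.
#'
#' @return A data.frame with columns `age_min`, `age_max`, `sex`
#'   (`"M"`, `"F"` or `"any"`) and `factor`.
#' @seealso [compute_mae()]
#' @export
default_mae_factors <- function() {
  data.frame(
    age_min = c(0, 5, 11, 15, 15, 60, 60),
    age_max = c(4, 10, 14, 59, 59, Inf, Inf),
    sex     = c("any", "any", "any", "M", "F", "M", "F"),
    factor  = c(0.50, 0.75, 0.85, 1.00, 0.80, 0.80, 0.65),
    stringsAsFactors = FALSE
  )
}

#' Default tropical livestock unit (TLU) weights
#'
#' One TLU is the metabolic equivalent of a 250 kg cow, so cattle carry
#' weight 1.0 and five goats make one TLU (weight 0.2). Other species use
#' standard reference weights and can be overridden in the conversion table.
#'
#' @return Named numeric vector of TLU per head by species.
#' @seealso [compute_tlu()]
#' @export
default_tlu_weights <- function() {
  c(cattle = 1.0, cow = 1.0, goat = 0.2, sheep = 0.2, pig = 0.3,
    donkey = 0.5, horse = 0.8, camel = 1.4, poultry = 0.01, chicken = 0.01)
}

#' Build a site/round conversion table
#'
#' Bundles everything needed to turn raw survey quantities into comparable
#' indicators: local product prices per site and survey round, the staple
#' (maize) price and energy density used to convert cash into calorie
#' equivalents, purchasing-power-parity factors to express local currency in
#' international dollars, TLU weights and MAE factors.
#'
#' @param prices data.frame with columns `site`, `round`, `product`, `price`
#'   (local currency per kg).
#' @param maize_price data.frame with columns `site`, `round`, `price`
#'   (local currency per kg of staple maize).
#' @param ppp data.frame with columns `site`, `factor`: local currency units
#'   per international (PPP) dollar for the country the site belongs to.
#' @param tlu_weights named numeric, TLU per head by species.
#' @param mae_factors data.frame as returned by [default_mae_factors()].
#' @param maize_energy energy density of the staple, kcal per kg.
#' @param kcal_per_kg optional named numeric giving direct energy densities
#'   for specific products; products absent from it are converted to calories
#'   through their cash value at the local maize price.
#' @return An object of class `povdyn_conversion`.
#' @export
conversion_table <- function(prices, maize_price, ppp,
                             tlu_weights = default_tlu_weights(),
                             mae_factors = default_mae_factors(),
                             maize_energy = 3580,
                             kcal_per_kg = NULL) {
  stopifnot(is.data.frame(prices),
            all(c("site", "round", "product", "price") %in% names(prices)),
            is.data.frame(maize_price),
            all(c("site", "round", "price") %in% names(maize_price)),
            is.data.frame(ppp), all(c("site", "factor") %in% names(ppp)))
  if (any(prices$price <= 0)) stop("all product prices must be > 0")
  if (any(maize_price$price <= 0)) stop("maize prices must be > 0")
  if (any(ppp$factor <= 0)) stop("PPP factors must be > 0")
  if (maize_energy <= 0) stop("maize energy density must be > 0")
  if (any(tlu_weights <= 0)) stop("TLU weights must be > 0")
  if (any(mae_factors$factor <= 0)) stop("MAE factors must be > 0")
  if (!is.null(kcal_per_kg) && any(kcal_per_kg <= 0))
    stop("kcal_per_kg entries must be > 0")
  structure(
    list(prices = prices, maize_price = maize_price, ppp = ppp,
         tlu_weights = tlu_weights, mae_factors = mae_factors,
         maize_energy = maize_energy, kcal_per_kg = kcal_per_kg),
    class = "povdyn_conversion")
}

#' @export
print.povdyn_conversion <- function(x, ...) {
  cat("Conversion table\n")
  cat(sprintf("  %d product prices over %d site(s), round(s) %s\n",
              nrow(x$prices), length(unique(x$prices$site)),
              paste(sort(unique(x$prices$round)), collapse = ", ")))
  cat(sprintf("  staple energy density: %g kcal/kg\n", x$maize_energy))
  cat(sprintf("  species with TLU weights: %d; MAE factor rows: %d\n",
              length(x$tlu_weights), nrow(x$mae_factors)))
  invisible(x)
}

lookup_price <- function(conv, site, round, product) {
  p <- conv$prices
  i <- which(p$site == site & p$round == round & p$product == product)
  if (length(i) == 0) {
    stop(sprintf("no price for product '%s' at site '%s', round %s",
                 product, site, round), call. = FALSE)
  }
  p$price[i[1]]
}

lookup_maize_price <- function(conv, site, round) {
  m <- conv$maize_price
  i <- which(m$site == site & m$round == round)
  if (length(i) == 0 || m$price[i[1]] <= 0) {
    stop(sprintf("no positive maize price for site '%s', round %s", site, round),
         call. = FALSE)
  }
  m$price[i[1]]
}

lookup_ppp <- function(conv, site) {
  i <- which(conv$ppp$site == site)
  if (length(i) == 0) stop(sprintf("no PPP factor for site '%s'", site),
                           call. = FALSE)
  conv$ppp$factor[i[1]]
}

#' Write / read a conversion table as YAML
#'
#' @param conv a `povdyn_conversion` object.
#' @param path file path.
#' @return `read_conversion_table()` returns a `povdyn_conversion`;
#'   `write_conversion_table()` returns `path` invisibly.
#' @export
write_conversion_table <- function(conv, path) {
  stopifnot(inherits(conv, "povdyn_conversion"))
  obj <- list(
    prices = conv$prices, maize_price = conv$maize_price, ppp = conv$ppp,
    tlu_weights = as.list(conv$tlu_weights),
    mae_factors = conv$mae_factors,
    maize_energy = conv$maize_energy,
    kcal_per_kg = if (is.null(conv$kcal_per_kg)) NULL else as.list(conv$kcal_per_kg))
  yaml::write_yaml(obj, path, column.major = FALSE)
  invisible(path)
}

#' @rdname write_conversion_table
#' @export
read_conversion_table <- function(path) {
  obj <- yaml::read_yaml(path)
  as_df <- function(x) do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  mf <- as_df(obj$mae_factors)
  mf$age_max[is.na(mf$age_max) | mf$age_max == ".inf"] <- Inf
  mf$age_max <- as.numeric(mf$age_max)
  conversion_table(
    prices = as_df(obj$prices),
    maize_price = as_df(obj$maize_price),
    ppp = as_df(obj$ppp),
    tlu_weights = unlist(obj$tlu_weights),
    mae_factors = mf,
    maize_energy = obj$maize_energy,
    kcal_per_kg = if (is.null(obj$kcal_per_kg)) NULL else unlist(obj$kcal_per_kg))
}
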
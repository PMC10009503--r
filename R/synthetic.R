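#' Configuration of one synthetic survey site
#'
#' Describes the sampling frame and distributional scales of one site:
#' villages times households-per-village sampled in round 1, the fraction
#' randomly resurveyed in round 2, lognormal scales for land and herd size,
#' the household size range, and the price environment (country, PPP
#' factor, non-staple crops grown).
#'
#' @param site_name site label.
#' @param n_villages number of villages sampled (>= 1).
#' @param households_per_village households sampled per village.
#' @param retention_fraction fraction of round-1 households resurveyed, in
#'   (0, 1].
#' @param land_lognormal c(meanlog, sdlog) of cultivated hectares.
#' @param tlu_lognormal c(meanlog, sdlog) of herd size in TLU.
#' @param household_size_range integer range of household sizes.
#' @param country country label (PPP key).
#' @param ppp_factor local currency units per PPP dollar.
#' @param crops non-staple crops grown at the site (maize is always grown).
#' @return list of class `povdyn_site_config`.
#' @export
site_config <- function(site_name, n_villages = 7, households_per_village = 20,
                        retention_fraction = 0.8,
                        land_lognormal = c(meanlog = log(1.2), sdlog = 0.6),
                        tlu_lognormal = c(meanlog = log(2), sdlog = 0.8),
                        household_size_range = c(4L, 7L),
                        country = "Kenya", ppp_factor = 43,
                        crops = c("beans", "vegetables")) {
  stopifnot(n_villages >= 1, households_per_village >= 1)
  if (retention_fraction <= 0 || retention_fraction > 1)
    stop("retention_fraction must be in (0, 1]")
  if (land_lognormal[2] <= 0 || tlu_lognormal[2] <= 0 || ppp_factor <= 0)
    stop("all scale parameters must be > 0")
  structure(list(site_name = site_name, n_villages = n_villages,
                 households_per_village = households_per_village,
                 retention_fraction = retention_fraction,
                 land_lognormal = land_lognormal,
                 tlu_lognormal = tlu_lognormal,
                 household_size_range = as.integer(household_size_range),
                 country = country, ppp_factor = ppp_factor, crops = crops),
            class = "povdyn_site_config")
}

#' Default four-site study configuration
#'
#' Four sites emulating the study conditions: 7 villages of 20 households
#' each in round 1 (560 households) with site retention fractions 0.735,
#' 0.675, 0.80 and 0.80, median land 1-2 ha, median herd 1-5 TLU and
#' household sizes 4-7.
#'
#' @return list of [site_config()] objects.
#' @export
default_sites <- function() {
  list(
    site_config("Lushoto", retention_fraction = 0.735, country = "Tanzania",
                ppp_factor = 585, crops = c("beans", "vegetables")),
    site_config("Rakai", retention_fraction = 0.675, country = "Uganda",
                ppp_factor = 1100, crops = c("banana", "beans")),
    site_config("Wote", retention_fraction = 0.80, country = "Kenya",
                ppp_factor = 43, crops = c("sorghum", "beans")),
    site_config("Nyando", retention_fraction = 0.80, country = "Kenya",
                ppp_factor = 43, crops = c("sorghum", "beans")))
}

#' Designed strata proportions and transition structure
#'
#' @param first_round_proportions length-3 vector (Low, Medium, High)
#'   summing to 1.
#' @param transition_matrix 3x3 row-stochastic matrix of
#'   stratum-to-stratum probabilities between rounds (rows = round-1
#'   stratum).
#' @return list of class `povdyn_trajectory_design`.
#' @export
trajectory_design <- function(first_round_proportions, transition_matrix) {
  p <- as.numeric(first_round_proportions)
  m <- as.matrix(transition_matrix)
  if (length(p) != 3 || abs(sum(p) - 1) > 1e-9 || any(p < 0))
    stop("first-round proportions must be 3 non-negative values summing to 1")
  if (!all(dim(m) == c(3, 3)) || any(m < 0) ||
      any(abs(rowSums(m) - 1) > 1e-9))
    stop("transition matrix must be 3x3 row-stochastic")
  dimnames(m) <- list(stratum_levels(), stratum_levels())
  structure(list(first_round_proportions = stats::setNames(p, stratum_levels()),
                 transition_matrix = m),
            class = "povdyn_trajectory_design")
}

#' Default trajectory design
#'
#' First-round strata proportions (0.30, 0.33, 0.37) and a transition
#' matrix whose implied second-round marginals are approximately
#' (0.27, 0.33, 0.41), with a majority of households changing stratum.
#'
#' @return a `povdyn_trajectory_design`.
#' @export
default_design <- function() {
  trajectory_design(
    c(0.30, 0.33, 0.37),
    rbind(c(0.34, 0.33, 0.33),
          c(0.30, 0.32, 0.38),
          c(0.18, 0.32, 0.50)))
}

# Independent per-site pseudo-random stream: adding a site leaves the
# draws of the other sites unchanged.
site_seed <- function(seed, index, offset = 0) {
  (as.integer(seed) %% 100000L) * 10000L + index * 101L + offset
}

# PPP-dollar reference prices per kg; local prices are these times the
# site's PPP factor times a small lognormal market jitter per round.
reference_prices_ppp <- c(maize = 0.65, beans = 1.2, sorghum = 0.5,
                          vegetables = 0.8, banana = 0.4,
                          milk = 0.8, eggs = 3.0, meat = 5.0)

#' Generate a site-by-round price and conversion table
#'
#' Builds positive local-currency prices for every product, site and round
#' (reference PPP prices scaled by the site's PPP factor with mild market
#' jitter), the staple maize price, PPP factors, and the default TLU and
#' MAE tables. Deterministic given the seed.
#'
#' @param sites list of [site_config()] objects.
#' @param seed integer seed.
#' @return a `povdyn_conversion`.
#' @export
generate_price_table <- function(sites, seed = 1) {
  products <- names(reference_prices_ppp)
  prices <- NULL
  ppp <- NULL
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    set.seed(site_seed(seed, i, offset = 50L))
    for (r in 1:2) {
      jitter <- stats::rlnorm(length(products), 0, 0.08)
      prices <- rbind(prices, data.frame(
        site = s$site_name, round = r, product = products,
        price = reference_prices_ppp * s$ppp_factor * jitter,
        stringsAsFactors = FALSE))
    }
    ppp <- rbind(ppp, data.frame(site = s$site_name, factor = s$ppp_factor,
                                 country = s$country,
                                 stringsAsFactors = FALSE))
  }
  maize <- prices[prices$product == "maize", c("site", "round", "price")]
  conversion_table(prices = prices, maize_price = maize, ppp = ppp)
}

# Latent prosperity targets on the food-availability axis (kcal/MAE/day).
# Low and Medium are placed around 1500 and 3500 kcal; High is placed in
# value terms at 2.5 x the $1.90/day line and mapped onto the FA axis
# through the staple price (kcal purchasable per PPP dollar).
draw_fa_target <- function(stratum, kcal_per_ppp) {
  n <- length(stratum)
  fa <- numeric(n)
  low <- stratum == 1; med <- stratum == 2; high <- stratum == 3
  fa[low] <- stats::rnorm(sum(low), 1500, 450)
  fa[med] <- stats::rnorm(sum(med), 3500, 300)
  fa[high] <- stats::rnorm(sum(high), 2.5 * 1.90, 1.2)[seq_len(sum(high))] *
    kcal_per_ppp[high]
  pmax(fa, 200)
}

# Stratum-dependent mean shares of TVA over (crops consumed, crops sold,
# livestock consumed, livestock sold, off-farm): more sales and off-farm
# income with rising prosperity.
component_share_means <- rbind(
  Low    = c(0.40, 0.18, 0.12, 0.05, 0.25),
  Medium = c(0.32, 0.22, 0.10, 0.10, 0.26),
  High   = c(0.22, 0.24, 0.06, 0.14, 0.34))

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

education_levels <- c("none", "primary", "secondary", "post_secondary")
education_probs <- rbind(
  Low    = c(0.24, 0.60, 0.12, 0.04),
  Medium = c(0.15, 0.55, 0.22, 0.08),
  High   = c(0.08, 0.48, 0.28, 0.16))

hfias_item_probs <- rbind(
  Low    = c(0.25, 0.30, 0.25, 0.20),
  Medium = c(0.50, 0.25, 0.15, 0.10),
  High   = c(0.75, 0.15, 0.07, 0.03))

ppi_option_probs <- rbind(
  Low    = c(0.50, 0.30, 0.15, 0.05),
  Medium = c(0.25, 0.35, 0.25, 0.15),
  High   = c(0.08, 0.22, 0.35, 0.35))

hdds_flush_prob <- c(Low = 0.55, Medium = 0.70, High = 0.85)
hungry_lambda <- c(Low = 3.5, Medium = 2.0, High = 0.8)

#' Generate a two-round synthetic household panel
#'
#' Latent-first generation: each household's round-1 stratum is drawn from
#' the designed first-round proportions and its round-2 stratum from the
#' designed transition matrix; observable records (roster, land, herd,
#' per-crop and per-product quantities, sale incomes, off-farm income,
#' welfare responses) are then drawn so that the indicator pipeline
#' classifies the household back into its latent stratum with high
#' probability. Round-2 households are a simple random subsample of round-1
#' households of size `round(retention_fraction * n)` per site. Welfare
#' responses are generated for round 2 only, with stratum-dependent shifts
#' (better scores in higher strata). Identical seeds give identical output;
#' each site has its own pseudo-random stream.
#'
#' @param sites list of [site_config()]s (default [default_sites()]).
#' @param design a [trajectory_design()] (default [default_design()]).
#' @param seed integer master seed.
#' @return list with `panel` (a `povdyn_panel`), `conversion`
#'   (a `povdyn_conversion`) and `truth` (data.frame of latent strata per
#'   household x round).
#' @export
generate_panel <- function(sites = default_sites(), design = default_design(),
                           seed = 1) {
  stopifnot(inherits(design, "povdyn_trajectory_design"))
  conv <- generate_price_table(sites, seed)
  hh_all <- NULL; roster_all <- NULL; ls_all <- NULL
  crops_all <- NULL; lsp_all <- NULL; truth_all <- NULL
  welfare_template <- welfare_columns()
  for (si in seq_along(sites)) {
    s <- sites[[si]]
    set.seed(site_seed(seed, si))
    n1 <- s$n_villages * s$households_per_village
    ids <- sprintf("%s_v%02d_h%02d", s$site_name,
                   rep(seq_len(s$n_villages), each = s$households_per_village),
                   rep(seq_len(s$households_per_village), s$n_villages))
    str1 <- sample.int(3, n1, replace = TRUE,
                       prob = design$first_round_proportions)
    n2 <- round(s$retention_fraction * n1)
    retained <- sort(sample.int(n1, n2))
    str2 <- integer(n1)
    for (k in 1:3) {
      sel <- which(str1 == k)
      str2[sel] <- sample.int(3, length(sel), replace = TRUE,
                              prob = design$transition_matrix[k, ])
    }
    sizes <- sample(seq(s$household_size_range[1], s$household_size_range[2]),
                    n1, replace = TRUE)
    land_base <- stats::rlnorm(n1, s$land_lognormal[1], s$land_lognormal[2]) *
      c(0.7, 1.0, 1.3)[str1]
    tlu_base <- stats::rlnorm(n1, s$tlu_lognormal[1], s$tlu_lognormal[2]) *
      c(0.6, 1.0, 2.0)[str1]
    education <- apply(education_probs[str1, , drop = FALSE], 1, function(p)
      sample(education_levels, 1, prob = p))

    roster <- make_rosters(ids, sizes)
    for (r in 1:2) {
      idx <- if (r == 1) seq_len(n1) else retained
      strat <- if (r == 1) str1[idx] else str2[idx]
      ros_r <- roster[roster$household_id %in% ids[idx], ]
      if (r == 2) ros_r$age <- ros_r$age + 4
      ros_r$round <- r
      roster_all <- rbind(roster_all, ros_r)

      mae <- as.numeric(tapply(
        mae_member_factors(ros_r$age, ros_r$sex, default_mae_factors()),
        ros_r$household_id, sum)[ids[idx]])
      maize_p <- lookup_maize_price(conv, s$site_name, r)
      kcal_per_ppp <- conv$maize_energy / maize_p * s$ppp_factor
      fa <- draw_fa_target(strat, rep(kcal_per_ppp, length(strat)))
      tva_local <- fa * mae * 365 * maize_p / conv$maize_energy

      shares <- t(vapply(strat, function(k)
        rdirichlet1(30 * component_share_means[k, ]), numeric(5)))
      land <- land_base[idx] * if (r == 1) 1 else stats::rlnorm(length(idx), 0, 0.15)
      tlu_t <- tlu_base[idx] * if (r == 1) 1 else stats::rlnorm(length(idx), 0, 0.2)

      crops_all <- rbind(crops_all,
                         make_crop_rows(ids[idx], r, s, conv,
                                        cons_val = tva_local * shares[, 1],
                                        sold_val = tva_local * shares[, 2]))
      lsp_all <- rbind(lsp_all,
                       make_product_rows(ids[idx], r, s, conv,
                                         cons_val = tva_local * shares[, 3],
                                         sold_val = tva_local * shares[, 4]))
      ls_all <- rbind(ls_all, make_herds(ids[idx], r, tlu_t))

      hh <- data.frame(household_id = ids[idx], site = s$site_name, round = r,
                       land_cultivated = land,
                       off_farm_income = tva_local * shares[, 5],
                       education = education[idx],
                       stringsAsFactors = FALSE)
      hh <- cbind(hh, if (r == 2) draw_welfare(strat) else
        welfare_template[rep(1, length(idx)), , drop = FALSE])
      hh_all <- rbind(hh_all, hh)
      truth_all <- rbind(truth_all, data.frame(
        household_id = ids[idx], round = r,
        stratum = stratum_levels()[strat], stringsAsFactors = FALSE))
    }
  }
  rownames(hh_all) <- NULL
  panel <- household_panel(hh_all, roster_all, ls_all, crops_all, lsp_all)
  list(panel = panel, conversion = conv, truth = truth_all)
}

welfare_columns <- function() {
  out <- data.frame(months_food_shortage = NA_real_)
  for (i in 1:9) out[[paste0("hfias_", i)]] <- NA_real_
  for (g in hdds_groups()) out[[paste0("hdds_flush_", g)]] <- NA
  for (g in hdds_groups()) out[[paste0("hdds_lean_", g)]] <- NA
  for (q in 1:10) out[[paste0("ppi_q", q)]] <- NA_real_
  out
}

draw_welfare <- function(strat) {
  n <- length(strat)
  lv <- stratum_levels()[strat]
  out <- data.frame(months_food_shortage =
                      pmin(stats::rpois(n, hungry_lambda[lv]), 12))
  for (i in 1:9) {
    out[[paste0("hfias_", i)]] <- vapply(lv, function(g)
      sample(0:3, 1, prob = hfias_item_probs[g, ]), numeric(1))
  }
  for (g in hdds_groups()) {
    out[[paste0("hdds_flush_", g)]] <-
      stats::runif(n) < hdds_flush_prob[lv]
  }
  for (g in hdds_groups()) {
    out[[paste0("hdds_lean_", g)]] <-
      stats::runif(n) < (hdds_flush_prob[lv] - 0.15)
  }
  for (q in 1:10) {
    out[[paste0("ppi_q", q)]] <- vapply(lv, function(g)
      sample(1:4, 1, prob = ppi_option_probs[g, ]), numeric(1))
  }
  rownames(out) <- NULL
  out
}

make_rosters <- function(ids, sizes) {
  n <- length(ids)
  total <- sum(sizes)
  hh_id <- rep(ids, sizes)
  age <- numeric(total); sex <- character(total)
  pos <- 1
  head_age <- sample(25:60, n, replace = TRUE)
  spouse_age <- pmax(18, head_age - sample(0:8, n, replace = TRUE))
  for (i in seq_len(n)) {
    k <- sizes[i]
    ages_i <- c(head_age[i], spouse_age[i],
                if (k > 2) sample(1:18, k - 2, replace = TRUE))
    sexes_i <- c("M", "F",
                 if (k > 2) sample(c("M", "F"), k - 2, replace = TRUE))
    age[pos:(pos + k - 1)] <- ages_i
    sex[pos:(pos + k - 1)] <- sexes_i
    pos <- pos + k
  }
  data.frame(household_id = hh_id, round = 1L, age = age, sex = sex,
             stringsAsFactors = FALSE)
}

make_herds <- function(ids, round, tlu_target) {
  cattle <- floor(tlu_target)
  goats <- pmax(0, round((tlu_target - cattle) / 0.2))
  poultry <- sample(0:10, length(ids), replace = TRUE)
  out <- rbind(
    data.frame(household_id = ids, round = round, species = "cattle",
               count = cattle, stringsAsFactors = FALSE),
    data.frame(household_id = ids, round = round, species = "goat",
               count = goats, stringsAsFactors = FALSE),
    data.frame(household_id = ids, round = round, species = "poultry",
               count = poultry, stringsAsFactors = FALSE))
  out[out$count > 0, ]
}

# Spread a local-currency consumption and sales value over the site's
# crops; reported sale income equals the sales value, quantities follow
# from local prices, and production exceeds consumption + sales by a small
# unsold remainder within the recall tolerance.
make_crop_rows <- function(ids, round, site, conv, cons_val, sold_val) {
  crops <- c("maize", site$crops)
  w <- c(0.6, 0.25, 0.15)[seq_along(crops)]
  w <- w / sum(w)
  n <- length(ids)
  split_cons <- t(vapply(seq_len(n), function(i) rdirichlet1(50 * w),
                         numeric(length(crops))))
  split_sold <- t(vapply(seq_len(n), function(i) rdirichlet1(50 * w),
                         numeric(length(crops))))
  price <- vapply(crops, function(cr)
    lookup_price(conv, site$site_name, round, cr), numeric(1))
  out <- NULL
  for (j in seq_along(crops)) {
    cv <- cons_val * split_cons[, j]
    sv <- sold_val * split_sold[, j]
    consumed <- cv / price[j]
    sold <- sv / price[j]
    produced <- (consumed + sold) * (1 + stats::runif(n, 0, 0.03))
    out <- rbind(out, data.frame(
      household_id = ids, round = round, crop = crops[j],
      produced_kg = produced, consumed_kg = consumed, sold_kg = sold,
      sale_income = sv, stringsAsFactors = FALSE))
  }
  out[out$produced_kg > 0, ]
}

make_product_rows <- function(ids, round, site, conv, cons_val, sold_val) {
  prods <- c("milk", "eggs")
  w <- c(0.7, 0.3)
  n <- length(ids)
  split_cons <- t(vapply(seq_len(n), function(i) rdirichlet1(50 * w),
                         numeric(2)))
  split_sold <- t(vapply(seq_len(n), function(i) rdirichlet1(50 * w),
                         numeric(2)))
  price <- vapply(prods, function(p)
    lookup_price(conv, site$site_name, round, p), numeric(1))
  out <- NULL
  for (j in seq_along(prods)) {
    cv <- cons_val * split_cons[, j]
    sv <- sold_val * split_sold[, j]
    consumed <- cv / price[j]
    sold <- sv / price[j]
    produced <- (consumed + sold) * (1 + stats::runif(n, 0, 0.03))
    out <- rbind(out, data.frame(
      household_id = ids, round = round, product = prods[j],
      produced_kg = produced, consumed_kg = consumed, sold_kg = sold,
      sale_income = sv, stringsAsFactors = FALSE))
  }
  out[out$produced_kg > 0, ]
}

#' Write / read a panel design (sites + trajectory design) as YAML
#'
#' @param sites list of [site_config()]s.
#' @param design a [trajectory_design()].
#' @param path file path.
#' @return `read_panel_design()` returns `list(sites, design)`.
#' @export
write_panel_design <- function(sites, design, path) {
  obj <- list(
    sites = lapply(sites, function(s) {
      s <- unclass(s)
      s$land_lognormal <- as.numeric(s$land_lognormal)
      s$tlu_lognormal <- as.numeric(s$tlu_lognormal)
      s
    }),
    design = list(
      first_round_proportions = as.numeric(design$first_round_proportions),
      transition_matrix = lapply(1:3, function(i)
        as.numeric(design$transition_matrix[i, ]))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_panel_design
#' @export
read_panel_design <- function(path) {
  obj <- yaml::read_yaml(path)
  sites <- lapply(obj$sites, function(s) {
    site_config(s$site_name, s$n_villages, s$households_per_village,
                s$retention_fraction,
                land_lognormal = unlist(s$land_lognormal),
                tlu_lognormal = unlist(s$tlu_lognormal),
                household_size_range = unlist(s$household_size_range),
                country = s$country, ppp_factor = s$ppp_factor,
                crops = unlist(s$crops))
  })
  design <- trajectory_design(
    unlist(obj$design$first_round_proportions),
    do.call(rbind, obj$design$transition_matrix))
  list(sites = sites, design = design)
}
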
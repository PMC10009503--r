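test_that("classification boundaries: value line dominates, >= on both", {
  expect_equal(as.character(classify_stratum(0, 0)), "Low")
  expect_equal(as.character(classify_stratum(3500, 1.00)), "Medium")
  expect_equal(as.character(classify_stratum(2999.99, 1.899)), "Low")
  expect_equal(as.character(classify_stratum(3000, 1.90)), "High")
  # above the poverty line but below the calorie line is still High,
  # counted as discordant
  s <- classify_stratum(c(2000, 4000), c(2.5, 2.5))
  expect_equal(as.character(s), c("High", "High"))
  expect_equal(attr(s, "discordant"), 1)
  expect_error(classify_stratum(-1, 0), "non-negative")
})

test_that("classification equals a brute-force three-predicate oracle", {
  # independent oracle: each class predicate evaluated separately
  oracle <- function(fa, tva) {
    is_high <- tva >= 1.90
    is_medium <- !is_high & fa >= 3000
    is_low <- !is_high & fa < 3000
    stopifnot(is_high + is_medium + is_low == 1)
    c("Low", "Medium", "High")[which(c(is_low, is_medium, is_high))]
  }
  set.seed(1)
  n <- 10000
  fa <- c(stats::runif(n - 8, 0, 6000),
          2999.999, 3000, 3000.001, 0, 1e6, 2999, 3001, 3000)
  tva <- c(stats::runif(n - 8, 0, 4),
           1.899, 1.90, 1.901, 0, 1e3, 1.9, 1.9, 1.89)
  got <- as.character(classify_stratum(fa, tva))
  want <- vapply(seq_along(fa), function(i) oracle(fa[i], tva[i]), "")
  expect_identical(got, want)
})

test_that("classification is monotone in income", {
  set.seed(2)
  lv <- stratum_levels()
  for (i in 1:200) {
    fa <- stats::runif(1, 0, 5000); tva <- stats::runif(1, 0, 3)
    dfa <- stats::runif(1, 0, 2000); dtva <- stats::runif(1, 0, 1)
    s0 <- match(as.character(classify_stratum(fa, tva)), lv)
    s1 <- match(as.character(classify_stratum(fa + dfa, tva + dtva)), lv)
    expect_gte(s1, s0)
  }
})

test_that("all nine ordered stratum pairs give distinct trajectories", {
  lv <- stratum_levels()
  grid <- expand.grid(from = lv, to = lv, stringsAsFactors = FALSE)
  labs <- character(nrow(grid)); dirs <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    t <- trajectory_label(grid$from[i], grid$to[i])
    labs[i] <- t$label; dirs[i] <- t$direction
  }
  expect_equal(length(unique(labs)), 9)
  expect_equal(sum(dirs == "rising"), 3)
  expect_equal(sum(dirs == "steady"), 3)
  expect_equal(sum(dirs == "falling"), 3)
  expect_equal(trajectory_label("Low", "High"),
               list(label = "Low to High", direction = "rising"))
  expect_equal(trajectory_label("Medium", "Medium")$direction, "steady")
})

test_that("strata proportions sum to one and ignore household order", {
  asg <- data.frame(
    household_id = sprintf("h%03d", 1:100), round = 1,
    stratum = rep(c("Low", "Medium", "High"), c(30, 33, 37)),
    stringsAsFactors = FALSE)
  p <- strata_proportions(asg)
  expect_equal(as.numeric(p), c(0.30, 0.33, 0.37))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  p2 <- strata_proportions(asg[sample(nrow(asg)), ])
  expect_equal(p, p2)
  one <- data.frame(household_id = paste0("h", 1:10), round = 1,
                    stratum = "Low", stringsAsFactors = FALSE)
  expect_equal(as.numeric(strata_proportions(one)), c(1, 0, 0))
})

test_that("flow matrix conserves counts and marginals", {
  # identity transitions -> diagonal matrix
  trj <- data.frame(household_id = paste0("h", 1:30),
                    from_stratum = rep(stratum_levels(), 10),
                    to_stratum = rep(stratum_levels(), 10),
                    label = "x", direction = "steady",
                    stringsAsFactors = FALSE)
  fm <- flow_matrix(trj)
  expect_true(all(fm$counts[row(fm$counts) != col(fm$counts)] == 0))
  expect_equal(sum(fm$shares), 1)

  # constructed fixture: 9 groups of 50 plus 100 extra in two High rows
  lv <- stratum_levels()
  grid <- expand.grid(from = lv, to = lv, stringsAsFactors = FALSE)
  n_per <- ifelse(grid$from == "High" & grid$to %in% c("Medium", "High"),
                  150, 50)
  from <- rep(grid$from, n_per); to <- rep(grid$to, n_per)
  i <- match(from, lv); j <- match(to, lv)
  trj2 <- data.frame(household_id = paste0("h", seq_along(from)),
                     from_stratum = from, to_stratum = to,
                     label = paste(from, "to", to),
                     direction = ifelse(j > i, "rising",
                                        ifelse(j < i, "falling", "steady")),
                     stringsAsFactors = FALSE)
  fm2 <- flow_matrix(trj2)
  expect_equal(sum(fm2$counts), 650)
  expect_equal(as.numeric(rowSums(fm2$counts)), c(150, 150, 350))
  expect_equal(fm2$counts["High", "High"], 150)
  expect_equal(sum(fm2$shares), 1)

  # on a generated study the marginals match the per-round strata counts
  st <- small_study()
  ind <- compute_indicators(st$panel, st$conversion)
  asg <- assign_strata(ind)
  trj3 <- assign_trajectories(asg)
  fm3 <- flow_matrix(trj3)
  matched <- trj3$household_id
  a1 <- asg[asg$round == 1 & asg$household_id %in% matched, ]
  a2 <- asg[asg$round == 2 & asg$household_id %in% matched, ]
  expect_equal(as.numeric(rowSums(fm3$counts)),
               as.numeric(table(factor(a1$stratum, stratum_levels()))))
  expect_equal(as.numeric(colSums(fm3$counts)),
               as.numeric(table(factor(a2$stratum, stratum_levels()))))
  expect_equal(fm3$n, nrow(trj3))
})

test_that("share table: shares sum to 100 and ratios follow the shares", {
  st <- small_study()
  ind <- compute_indicators(st$panel, st$conversion)
  asg <- assign_strata(ind)
  tab <- share_table(asg, ind)
  for (r in unique(tab$round)) {
    sel <- tab$round == r
    expect_equal(sum(tab$pop_pct[sel]), 100, tolerance = 1e-9)
    expect_equal(sum(tab$land_pct[sel]), 100, tolerance = 1e-9)
    expect_equal(sum(tab$value_pct[sel]), 100, tolerance = 1e-9)
  }
  expect_equal(tab$ratio,
               round(tab$value_pct / tab$land_pct, 2))
})

test_that("single-stratum population gives 100% shares and ratio 1", {
  conv <- tiny_conv()
  rows <- rbind(crop_row("h1", 1, "maize", 100, 60, 40),
                crop_row("h2", 1, "maize", 200, 120, 80))
  hh <- data.frame(household_id = c("h1", "h2"), site = "A", round = 1,
                   land_cultivated = c(1, 2), off_farm_income = 0,
                   months_food_shortage = NA_real_, stringsAsFactors = FALSE)
  ros <- data.frame(household_id = c("h1", "h2"), round = 1, age = 30,
                    sex = "M", stringsAsFactors = FALSE)
  p <- household_panel(hh, ros, tiny_panel()$livestock,
                       rows, tiny_panel()$livestock_products)
  ind <- compute_indicators(p, conv)
  asg <- assign_strata(ind)
  expect_equal(length(unique(asg$stratum)), 1)
  tab <- share_table(asg, ind)
  s <- as.character(unique(asg$stratum))
  expect_equal(tab$pop_pct[tab$stratum == s], 100)
  expect_equal(tab$ratio[tab$stratum == s], 1.00)
})

test_that("net change by trajectory subtracts round 1 from round 2", {
  st <- small_study()
  ind <- compute_indicators(st$panel, st$conversion)
  asg <- assign_strata(ind)
  trj <- assign_trajectories(asg)

  # identical rounds -> all deltas zero
  ind_same <- ind
  i1 <- ind[ind$round == 1, ]
  ind_same[ind_same$round == 2, ] <-
    transform(i1[i1$household_id %in% trj$household_id, ], round = 2)
  nc0 <- net_change_by_trajectory(ind_same, trj)
  expect_true(all(abs(nc0$deltas$d_crop_value) < 1e-12))
  expect_true(all(nc0$medians$median_delta[
    nc0$medians$metric == "crop_value"] == 0))

  # a single constructed household: crop value 300 -> 800 gives +500
  ind1 <- data.frame(household_id = "h1", site = "A", round = 1:2,
                     crop_value = c(300, 800), livestock_value = 0,
                     off_farm_income = 0, crop_intensity = 0,
                     livestock_intensity = 0, offfarm_intensity = 0,
                     stringsAsFactors = FALSE)
  trj1 <- data.frame(household_id = "h1", from_stratum = "Low",
                     to_stratum = "Medium", label = "Low to Medium",
                     direction = "rising", stringsAsFactors = FALSE)
  nc1 <- net_change_by_trajectory(ind1, trj1)
  expect_equal(nc1$deltas$d_crop_value, 500)

  # medians invariant to household order
  nc <- net_change_by_trajectory(ind, trj)
  shuffled <- trj[sample(nrow(trj)), ]
  nc_b <- net_change_by_trajectory(ind, shuffled)
  a <- nc$medians[order(nc$medians$label, nc$medians$metric), ]
  b <- nc_b$medians[order(nc_b$medians$label, nc_b$medians$metric), ]
  expect_equal(a$median_delta, b$median_delta)
})
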
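test_that("MAE sums age/sex factors with the adult male as reference", {
  expect_equal(compute_mae(data.frame(age = 30, sex = "M")), 1.0)
  # two adult males plus two small children with factor 0.5
  roster <- data.frame(age = c(30, 40, 2, 3), sex = c("M", "M", "F", "M"))
  expect_equal(compute_mae(roster), 3.0)
  expect_error(compute_mae(data.frame(age = numeric(), sex = character())),
               "empty")
  expect_warning(
    m <- compute_mae(data.frame(age = c(30, -1), sex = c("M", "F"))),
    "negative age")
  expect_equal(m, 1.0)
})

test_that("TLU is the weighted head count (five goats = one cow = 1 TLU)", {
  expect_equal(compute_tlu(c(goat = 5)), 1.0)
  expect_equal(compute_tlu(numeric(0)), 0)
  expect_equal(compute_tlu(c(cattle = 2, goat = 5)), 2.2 + 0.8)
  expect_equal(compute_tlu(c(cattle = 2, goat = 5),
                           c(cattle = 1, goat = 0.2)), 3.0)
  expect_error(compute_tlu(c(dragon = 1)), "dragon")
  expect_error(compute_tlu(c(goat = -1)), "negative")
})

test_that("production valuation: prices, PPP and sale-income precedence", {
  conv <- tiny_conv(ppp = 1)
  # 100 kg beans consumed at 1.0/kg -> 100 $PPP; maize 100 kg at 0.5 -> 50
  p <- tiny_panel(crops = crop_row("h1", 1, "maize", 100, 100, 0))
  ind <- compute_indicators(p, conv)
  expect_equal(ind$value_consumed_crops, 50)
  expect_equal(ind$value_sold_crops, 0)
  expect_equal(ind$tva, 50)

  # zero quantities and incomes -> all components zero
  p0 <- tiny_panel(crops = crop_row("h1", 1, "maize", 0, 0, 0))
  ind0 <- compute_indicators(p0, conv)
  expect_equal(ind0$tva, 0)
  expect_equal(ind0$fa, 0)

  # reported sale income differs from sold x price: reported income wins
  p2 <- tiny_panel(crops = crop_row("h1", 1, "maize", 100, 0, 100,
                                    sale_income = 77))
  ind2 <- compute_indicators(p2, conv)
  expect_equal(ind2$value_sold_crops, 77)
  # without a reported income the quantity route is used
  p3 <- tiny_panel(crops = crop_row("h1", 1, "maize", 100, 0, 100))
  expect_equal(compute_indicators(p3, conv)$value_sold_crops, 50)

  # PPP conversion divides local values
  conv10 <- tiny_conv(ppp = 10)
  expect_equal(compute_indicators(p2, conv10)$value_sold_crops, 7.7)

  # unpriced product is a hard error naming it
  p4 <- tiny_panel(crops = crop_row("h1", 1, "quinoa", 10, 10, 0))
  expect_error(compute_indicators(p4, conv), "quinoa")
})

test_that("FA: 500 kg maize consumed, mae 2 gives ~2452 kcal/MAE/day", {
  # hand arithmetic: 500 * 3580 / (2 * 365) = 2452.05; below the 3000 line
  expect_equal(compute_fa(500 * 3580, 0, mae = 2, maize_price = 0.5),
               500 * 3580 / 730)
  conv <- tiny_conv()
  p <- tiny_panel(adults = 2,
                  crops = crop_row("h1", 1, "maize", 500, 500, 0))
  ind <- compute_indicators(p, conv)
  expect_equal(ind$fa, 2452.0548, tolerance = 1e-6)
  expect_lt(ind$fa, 3000)
  expect_equal(compute_fa(0, 0, 2, 0.5), 0)
  expect_error(compute_fa(100, 0, 2, 0), "maize price")
})

test_that("consumed maize calories equal kg times energy density exactly", {
  conv <- tiny_conv()
  kg <- c(1, 10, 123.45)
  for (k in kg) {
    p <- tiny_panel(adults = 1, crops = crop_row("h1", 1, "maize", k, k, 0))
    ind <- compute_indicators(p, conv)
    expect_equal(ind$fa * 1 * 365, k * 3580)
  }
})

test_that("doubling the maize price strictly decreases FA when cash > 0", {
  fa1 <- compute_fa(1000, cash_income = 500, mae = 2, maize_price = 0.5)
  fa2 <- compute_fa(1000, cash_income = 500, mae = 2, maize_price = 1.0)
  expect_lt(fa2, fa1)
  # with no cash the consumed-calorie term is unaffected
  expect_equal(compute_fa(1000, 0, 2, 0.5), compute_fa(1000, 0, 2, 1.0))
})

test_that("intensity metrics handle zero denominators as documented", {
  out <- compute_intensities(crop_value = 1000, livestock_value = 0,
                             off_farm = 0, land = 2, tlu = 0, mae = 1)
  expect_equal(out$crop_intensity, 500)
  expect_equal(out$livestock_intensity, 0)  # 0/0 -> 0
  out2 <- compute_intensities(0, livestock_value = 10, 0, land = 0,
                              tlu = 0, mae = 1)
  expect_true(is.na(out2$livestock_intensity))  # >0 over 0 -> missing
  expect_equal(out2$crop_intensity, 0)
  expect_error(compute_intensities(1, 1, 1, 1, 1, mae = 0), "mae")
})

test_that("TVA decomposition identity holds on every generated household", {
  st <- small_study()
  ind <- compute_indicators(st$panel, st$conversion)
  recomputed <- ind$value_consumed_crops + ind$value_sold_crops +
    ind$value_consumed_livestock + ind$value_sold_livestock +
    ind$off_farm_income
  expect_equal(ind$tva, recomputed, tolerance = 1e-9)
  expect_true(all(ind$mae > 0))
  expect_true(all(ind[c("value_consumed_crops", "value_sold_crops",
                        "value_consumed_livestock", "value_sold_livestock",
                        "off_farm_income")] >= 0))
})

test_that("currency invariance: rescaling prices, incomes and PPP together", {
  st <- small_study()
  ind <- compute_indicators(st$panel, st$conversion)
  k <- 7.3
  conv2 <- st$conversion
  conv2$prices$price <- conv2$prices$price * k
  conv2$maize_price$price <- conv2$maize_price$price * k
  conv2$ppp$factor <- conv2$ppp$factor * k
  panel2 <- st$panel
  panel2$households$off_farm_income <- panel2$households$off_farm_income * k
  panel2$crops$sale_income <- panel2$crops$sale_income * k
  panel2$livestock_products$sale_income <-
    panel2$livestock_products$sale_income * k
  ind2 <- compute_indicators(panel2, conv2)
  expect_equal(ind2$tva, ind$tva, tolerance = 1e-9)
  expect_equal(ind2$fa, ind$fa, tolerance = 1e-9)
  expect_equal(ind2$crop_intensity, ind$crop_intensity, tolerance = 1e-9)
})

test_that("FA and TVA are monotone in every quantity and income component", {
  conv <- tiny_conv()
  base <- tiny_panel(crops = crop_row("h1", 1, "maize", 100, 60, 40),
                     off_farm = 50)
  ind0 <- compute_indicators(base, conv)
  bump <- function(field, where = c("crops", "households")) {
    where <- match.arg(where)
    p <- base
    p[[where]][[field]] <- p[[where]][[field]] + 10
    compute_indicators(p, conv)
  }
  for (f in c("consumed_kg", "sold_kg")) {
    ind1 <- bump(f, "crops")
    expect_gte(ind1$tva, ind0$tva)
    expect_gte(ind1$fa, ind0$fa)
  }
  ind1 <- bump("off_farm_income", "households")
  expect_gt(ind1$tva, ind0$tva)
  expect_gt(ind1$fa, ind0$fa)
})
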
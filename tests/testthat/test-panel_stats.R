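test_that("McNemar: symmetry, closed form, and agreement with stats::", {
  # b = c -> statistic 0, exact p = 1
  before <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 10))
  after <- c(rep(FALSE, 5), rep(TRUE, 5), rep(TRUE, 10))
  r <- mcnemar_paired(before, after)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # b = 10, c = 2 -> chi-squared = 64/12
  b <- 10; cc <- 2
  before2 <- c(rep(TRUE, b), rep(FALSE, cc), rep(TRUE, 20))
  after2 <- c(rep(FALSE, b), rep(TRUE, cc), rep(TRUE, 20))
  r2 <- mcnemar_paired(before2, after2, method = "chisq")
  expect_equal(r2$statistic, 64 / 12)
  ref <- stats::mcnemar.test(table(before2, after2), correct = FALSE)
  expect_equal(r2$statistic, unname(ref$statistic))
  expect_equal(r2$p_value, ref$p.value)

  # no discordant pairs -> degenerate, p = 1
  r3 <- mcnemar_paired(rep(TRUE, 10), rep(TRUE, 10))
  expect_equal(r3$p_value, 1)
  expect_true(r3$details$degenerate)
})

test_that("exact McNemar equals brute-force binomial tails for n <= 12", {
  # oracle: two-sided binomial tail by direct summation over the exact
  # null, P(X = k) = choose(n, k) / 2^n
  oracle <- function(b, n) {
    pk <- choose(n, 0:n) / 2^n
    sum(pk[pk <= pk[b + 1] + 1e-12])
  }
  for (n in 1:12) {
    for (b in 0:n) {
      cc <- n - b
      before <- c(rep(TRUE, b), rep(FALSE, cc))
      after <- c(rep(FALSE, b), rep(TRUE, cc))
      r <- mcnemar_paired(before, after, method = "exact")
      expect_equal(r$p_value, oracle(b, n), tolerance = 1e-12,
                   info = sprintf("b=%d c=%d", b, cc))
    }
  }
})

test_that("Wilcoxon signed rank: symmetric movement and extreme movement", {
  # perfectly symmetric moves -> p = 1
  c1 <- c(1, 1, 2, 2, 3, 3, 2, 2)
  c2 <- c(2, 2, 1, 1, 2, 2, 3, 3)
  r <- wilcoxon_strata_movement(c1, c2)
  expect_gte(r$p_value, 0.99)

  # 20 households all moving up one stratum: the one-tailed p is the
  # smallest attainable for n = 20, i.e. 2^-20
  r_up <- wilcoxon_strata_movement(rep(1, 20), rep(2, 20),
                                   alternative = "greater")
  expect_equal(r_up$p_value, 2^-20, tolerance = 1e-12)

  # no movement at all -> degenerate p = 1
  r0 <- wilcoxon_strata_movement(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$p_value, 1)
  expect_true(r0$details$degenerate)
})

test_that("exact signed-rank p matches full 2^n enumeration for n <= 12", {
  # oracle: enumerate every sign assignment of the |d| ranks
  enum_oracle <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- signs %*% r
    p_low <- mean(vs <= v_obs + 1e-9)
    p_high <- mean(vs >= v_obs - 1e-9)
    min(1, 2 * min(p_low, p_high))
  }
  set.seed(9)
  for (rep_i in 1:20) {
    n <- sample(3:12, 1)
    c1 <- sample(1:3, n, replace = TRUE)
    c2 <- pmin(3, pmax(1, c1 + sample(-2:2, n, replace = TRUE)))
    if (all(c1 == c2)) next
    got <- wilcoxon_strata_movement(c1, c2)
    expect_equal(got$p_value, enum_oracle(c2 - c1), tolerance = 1e-9,
                 info = paste(c2 - c1, collapse = ","))
  }
})

test_that("exact signed rank agrees with wilcox.test on tie-free data", {
  set.seed(10)
  for (i in 1:10) {
    d <- sample(c(-1, 1), 10, TRUE) * sample(seq(0.1, 5, by = 0.17), 10)
    got <- wilcoxon_strata_movement(rep(0, 10), d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("large-sample signed rank uses the tie-corrected normal tail", {
  set.seed(12)
  c1 <- sample(1:3, 80, replace = TRUE)
  c2 <- sample(1:3, 80, replace = TRUE)
  got <- wilcoxon_strata_movement(c1, c2)
  expect_equal(got$details$variant, "normal_tie_corrected")
  ref <- stats::wilcox.test(c2, c1, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("ANOVA F equals the definitional sum-of-squares ratio", {
  # 3 x 5 fixture, F computed by direct sums as the oracle
  y <- c(4.1, 5.0, 4.4, 4.8, 4.6,
         6.1, 5.8, 6.4, 6.0, 6.3,
         5.1, 4.9, 5.6, 5.2, 5.4)
  g <- rep(c("a", "b", "c"), each = 5)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ss_between <- sum(5 * (means - gm)^2)
  ss_within <- sum((y - means[g])^2)
  f_oracle <- (ss_between / 2) / (ss_within / 12)
  cmp <- anova_posthoc(y, g, method = "tukey_hsd")
  expect_equal(cmp$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(cmp$n, 15)
})

test_that("Tukey-Kramer pairwise p-values match stats::TukeyHSD", {
  set.seed(13)
  y <- c(rnorm(8, 0), rnorm(12, 0.8), rnorm(6, 1.6))
  g <- rep(c("Low", "Medium", "High"), c(8, 12, 6))
  cmp <- anova_posthoc(y, g, method = "tukey_hsd")
  ref <- stats::TukeyHSD(stats::aov(y ~ factor(g)))[[1]]
  got <- cmp$details$pairs
  for (i in seq_len(nrow(got))) {
    nm1 <- paste0(got$group_j[i], "-", got$group_i[i])
    nm2 <- paste0(got$group_i[i], "-", got$group_j[i])
    nm <- if (nm1 %in% rownames(ref)) nm1 else nm2
    expect_equal(got$p_value[i], ref[nm, "p adj"], tolerance = 1e-8)
  }
})

test_that("Fisher LSD flags at least every pair Tukey flags", {
  set.seed(14)
  for (i in 1:200) {
    k <- sample(3:5, 1)
    n <- sample(4:10, 1)
    y <- rnorm(k * n) + rep(runif(k, 0, 1.5), each = n)
    g <- rep(letters[1:k], each = n)
    tuk <- anova_posthoc(y, g, method = "tukey_hsd")$details$pairs
    lsd <- anova_posthoc(y, g, method = "fisher_lsd")$details$pairs
    expect_true(all(lsd$p_value <= tuk$p_value + 1e-12))
  }
})

test_that("letter displays are valid coverings consistent with the pairs", {
  set.seed(15)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    y <- rnorm(k * 8) + rep(runif(k, 0, 2), each = 8)
    g <- rep(letters[1:k], each = 8)
    cmp <- anova_posthoc(y, g, method = "fisher_lsd", alpha = 0.05)
    expect_true(all(nchar(cmp$letters) >= 1))
    pairs <- cmp$details$pairs
    share <- function(a, b) {
      any(strsplit(cmp$letters[a], "")[[1]] %in%
            strsplit(cmp$letters[b], "")[[1]])
    }
    for (p in seq_len(nrow(pairs))) {
      shared <- share(pairs$group_i[p], pairs$group_j[p])
      if (pairs$p_value[p] <= 0.05) {
        expect_false(shared)
      } else {
        expect_true(shared)
      }
    }
  }
})

test_that("three identical groups all share one letter", {
  y <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("x", "y", "z"), each = 4)
  cmp <- anova_posthoc(y, g)
  expect_equal(unname(cmp$letters), rep("a", 3))
})

test_that("tests consume untrimmed data even with extreme outliers", {
  y <- c(rnorm(10), 1e6, rnorm(11, 1))
  g <- rep(c("a", "b"), each = 11)
  cmp <- anova_posthoc(y, g)
  expect_equal(cmp$n, 22)
  expect_equal(sum(cmp$estimates$n), 22)
})

test_that("asset regression: exact recovery, collinearity, permutation", {
  set.seed(16)
  land <- rlnorm(100)
  tlu <- rlnorm(100)
  off <- rgamma(100, 2, 0.01)
  # a perfect fit makes summary.lm warn about zero residual variance
  fit <- suppressWarnings(asset_income_regression(2 * land, land, tlu, off))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "land"], 2, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "tlu"], 0, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "off_farm"], 0, tolerance = 1e-6)

  expect_error(asset_income_regression(rnorm(50), land[1:50], 2 * land[1:50],
                                       off[1:50]),
               "collinear")

  # permuting the outcome destroys the association
  y <- 400 * land + rnorm(100, sd = 100)
  ps <- replicate(50, {
    f <- asset_income_regression(sample(y), land, tlu, off)
    f$coefficients$p[f$coefficients$term == "land"]
  })
  expect_gt(stats::median(ps), 0.05)
})

test_that("education analysis separates a designed monotone effect", {
  set.seed(17)
  lev <- c("none", "primary", "secondary", "post_secondary")
  edu <- rep(lev, each = 100)
  off <- rnorm(400, mean = rep(c(100, 300, 600, 1000), each = 100), sd = 150)
  farm <- rep(rnorm(100, 500, 100), 4)  # identical across levels
  res <- education_income_analysis(edu, farm, off)
  # off-farm: extreme levels must not share a letter
  lo <- res$off_farm$letters[["none"]]
  hi <- res$off_farm$letters[["post_secondary"]]
  expect_false(any(strsplit(lo, "")[[1]] %in% strsplit(hi, "")[[1]]))
  # identical farm-income distributions: all levels share a letter
  expect_true(length(unique(res$farm$letters)) == 1)
  # relabelling that preserves order does not change the p-value
  edu2 <- c(none = "e0", primary = "e1", secondary = "e2",
            post_secondary = "e3")[edu]
  res2 <- education_income_analysis(edu2, farm, off)
  expect_equal(res2$off_farm$p_value, res$off_farm$p_value)
  # single level is skipped
  expect_null(education_income_analysis(rep("primary", 10), rnorm(10),
                                        rnorm(10))$farm)
})
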
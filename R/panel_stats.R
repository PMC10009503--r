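#' Container for a statistical comparison
#'
#' @param test test name.
#' @param statistic test statistic.
#' @param p_value p-value in [0, 1] (or NA for degenerate cases).
#' @param groups optional group labels.
#' @param letters optional compact letter display.
#' @param estimates optional per-group summaries (data.frame).
#' @param n sample size(s).
#' @param details free-form list (method flags, degeneracy, etc.).
#' @return object of class `povdyn_comparison`.
#' @export
comparison_result <- function(test, statistic, p_value, groups = NULL,
                              letters = NULL, estimates = NULL, n = NULL,
                              details = list()) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]")
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 groups = groups, letters = letters, estimates = estimates,
                 n = n, details = details),
            class = "povdyn_comparison")
}

#' @export
print.povdyn_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %s\n", x$test,
              format(x$statistic, digits = 4),
              format.pval(x$p_value, digits = 3)))
  if (!is.null(x$estimates)) {
    est <- x$estimates
    if (!is.null(x$letters)) est$letters <- x$letters[est$group]
    print(est, row.names = FALSE)
  }
  if (isTRUE(x$details$degenerate)) cat("  (degenerate case)\n")
  invisible(x)
}

#' McNemar's test for paired binary status
#'
#' Tests whether the marginal frequency of a binary status (e.g. above vs
#' below the poverty line) changed between the two panel rounds, using only
#' the discordant pairs. The chi-squared statistic is (b - c)^2 / (b + c)
#' without continuity correction, where b and c count the two discordant
#' cells; with fewer than 25 discordant pairs the exact two-sided binomial
#' test on b out of b + c at probability 1/2 is used instead.
#'
#' @param before,after logical vectors of equal length (round 1, round 2).
#' @param method `"auto"` (exact below 25 discordant pairs), `"chisq"` or
#'   `"exact"`.
#' @return `povdyn_comparison` with discordant counts in `details`.
#' @export
mcnemar_paired <- function(before, after, method = c("auto", "chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(length(before) == length(after))
  ok <- !is.na(before) & !is.na(after)
  before <- as.logical(before)[ok]; after <- as.logical(after)[ok]
  b <- sum(before & !after)
  cc <- sum(!before & after)
  nd <- b + cc
  if (nd == 0) {
    return(comparison_result("McNemar", 0, 1, n = length(before),
                             details = list(b = b, c = cc, degenerate = TRUE,
                                            variant = "degenerate")))
  }
  stat <- (b - cc)^2 / nd
  use_exact <- method == "exact" || (method == "auto" && nd < 25)
  if (use_exact) {
    p <- stats::binom.test(b, nd, 0.5)$p.value
    variant <- "exact_binomial"
  } else {
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    variant <- "chisq"
  }
  comparison_result("McNemar", stat, p, n = length(before),
                    details = list(b = b, c = cc, variant = variant))
}

# Exact null distribution of the signed-rank sum with (possibly tied,
# averaged) ranks: dynamic-programming convolution over the doubled ranks,
# which are integers. Returns P(V <= v) and P(V >= v).
signed_rank_exact_tails <- function(ranks, v) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (w in r2) {
    shifted <- c(numeric(w), counts[seq_len(total + 1 - w)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(ranks)
  v2 <- round(2 * v)
  sums <- 0:total
  c(lower = sum(counts[sums <= v2]), upper = sum(counts[sums >= v2]))
}

#' Wilcoxon signed-rank test for movement between strata
#'
#' Paired test on ordinal stratum codes (Low = 1, Medium = 2, High = 3)
#' across the two rounds: do households move up more than down? Zero
#' differences are dropped (Wilcoxon's original treatment), tied absolute
#' differences receive average ranks. With at most `exact_max` non-zero
#' differences the exact null distribution of the rank sum is computed by
#' enumeration (a convolution that handles ties exactly); beyond that a
#' normal approximation with tie correction is used.
#'
#' @param codes1,codes2 paired numeric/ordinal codes (round 1, round 2), or
#'   any paired ordinal measurements.
#' @param exact_max largest number of non-zero differences for which the
#'   exact distribution is used (default 25).
#' @param alternative `"two.sided"` (default), `"greater"` (movement up) or
#'   `"less"`.
#' @return `povdyn_comparison`; statistic is V, the sum of ranks of
#'   positive differences.
#' @export
wilcoxon_strata_movement <- function(codes1, codes2, exact_max = 25,
                                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(codes1) == length(codes2))
  d <- as.numeric(codes2) - as.numeric(codes1)
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(comparison_result("Wilcoxon signed rank", 0, 1, n = 0,
                             details = list(degenerate = TRUE)))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    tails <- signed_rank_exact_tails(r, v)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(tails)),
                greater = tails[["upper"]],
                less = tails[["lower"]])
    variant <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    variant <- "normal_tie_corrected"
  }
  comparison_result("Wilcoxon signed rank", v, p, n = n,
                    details = list(variant = variant,
                                   n_zero_dropped = sum(codes2 == codes1, na.rm = TRUE)))
}

# Compact letter display by insert-and-absorb: start from one column
# containing every group; each significant pair splits the columns that
# contain both; subset columns are absorbed; columns become letters.
cld_letters <- function(group_names, sig_pairs) {
  k <- length(group_names)
  cols <- list(rep(TRUE, k))
  if (nrow(sig_pairs) > 0) {
    for (p in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs$i[p]; j <- sig_pairs$j[p]
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          newcols <- c(newcols, list(c1, c2))
        } else newcols <- c(newcols, list(col))
      }
      # absorb: drop columns whose member set is contained in another's
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) {
        for (b in seq_along(newcols)) {
          if (a != b && keep[a] &&
              all(!newcols[[a]] | newcols[[b]]) &&
              !identical(newcols[[a]], newcols[[b]])) {
            keep[a] <- FALSE
            break
          }
        }
      }
      # deduplicate identical columns
      cols <- unique(newcols[keep])
    }
  }
  ord <- order(vapply(cols, function(col) which(col)[1], numeric(1)))
  cols <- cols[ord]
  letters_out <- character(k)
  for (ci in seq_along(cols)) {
    sym <- letters[ci]
    letters_out[cols[[ci]]] <- paste0(letters_out[cols[[ci]]], sym)
  }
  names(letters_out) <- group_names
  letters_out
}

#' One-way ANOVA with post-hoc letters
#'
#' Compares a numeric outcome across groups with one-way ANOVA, then runs
#' the chosen pairwise post-hoc procedure and summarises it as a compact
#' letter display: groups sharing a letter are not significantly different
#' at `alpha`. Tukey's HSD uses the studentized range with the
#' Tukey–Kramer unequal-n adjustment; Fisher's LSD uses unadjusted pairwise
#' t tests on the pooled within-group mean square.
#'
#' @param values numeric outcome.
#' @param groups group labels (coerced to factor).
#' @param method `"tukey_hsd"` or `"fisher_lsd"`.
#' @param alpha significance level for the letter display.
#' @return `povdyn_comparison`: statistic is the ANOVA F; `estimates` holds
#'   per-group n, mean and median; `details$pairs` the pairwise p-values.
#' @export
anova_posthoc <- function(values, groups, method = c("tukey_hsd", "fisher_lsd"),
                          alpha = 0.05) {
  method <- match.arg(method)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  g <- droplevels(factor(groups[ok]))
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("need at least 2 values per group")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  fp <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]
  lv <- levels(g)
  nn <- as.integer(table(g))
  means <- tapply(values, g, mean)
  medians <- tapply(values, g, stats::median)
  degenerate <- !is.finite(mse) || mse <= 0
  pairs <- NULL
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (degenerate) {
        p <- if (means[i] == means[j]) 1 else 0
      } else if (method == "tukey_hsd") {
        se <- sqrt(mse / 2 * (1 / nn[i] + 1 / nn[j]))
        q <- abs(means[i] - means[j]) / se
        p <- stats::ptukey(q, nmeans = k, df = dfe, lower.tail = FALSE)
      } else {
        se <- sqrt(mse * (1 / nn[i] + 1 / nn[j]))
        tstat <- (means[i] - means[j]) / se
        p <- 2 * stats::pt(-abs(tstat), df = dfe)
      }
      pairs <- rbind(pairs, data.frame(i = i, j = j, group_i = lv[i],
                                       group_j = lv[j], p_value = p,
                                       stringsAsFactors = FALSE))
    }
  }
  sig <- pairs[pairs$p_value <= alpha, c("i", "j"), drop = FALSE]
  letts <- cld_letters(lv, sig)
  est <- data.frame(group = lv, n = nn, mean = as.numeric(means),
                    median = as.numeric(medians), stringsAsFactors = FALSE)
  comparison_result(
    test = sprintf("one-way ANOVA + %s", method),
    statistic = fstat, p_value = if (degenerate) NA_real_ else fp,
    groups = lv, letters = letts, estimates = est, n = length(values),
    details = list(pairs = pairs, method = method, alpha = alpha,
                   mse = mse, df_error = dfe, degenerate = degenerate))
}

#' Regression of round-2 farm income on round-1 productive assets
#'
#' Ordinary least squares of farm income in the second panel on land, TLU
#' and off-farm income measured in the first panel, testing whether
#' baseline productive assets predict later farm income.
#'
#' @param farm_income round-2 farm income (value of crop + livestock
#'   production), $/yr.
#' @param land round-1 land cultivated, ha.
#' @param tlu round-1 tropical livestock units.
#' @param off_farm round-1 off-farm income, $/yr.
#' @param log1p_transform if TRUE, log1p is applied to outcome and income
#'   predictors before fitting.
#' @return list with `coefficients` (term, estimate, se, t, p, ci_lower,
#'   ci_upper), `r_squared`, `n`, and the underlying `lm` fit.
#' @export
asset_income_regression <- function(farm_income, land, tlu, off_farm,
                                    log1p_transform = FALSE) {
  df <- data.frame(farm_income = farm_income, land = land, tlu = tlu,
                   off_farm = off_farm)
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 5) stop("need more observations than parameters")
  if (log1p_transform) {
    df$farm_income <- log1p(df$farm_income)
    df$off_farm <- log1p(df$off_farm)
  }
  fit <- stats::lm(farm_income ~ land + tlu + off_farm, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- stats::confint(fit)
  coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      t = co[, 3], p = co[, 4],
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(coefficients = coefs, r_squared = sm$r.squared, n = nrow(df),
       fit = fit)
}

#' Education level versus farm and off-farm income
#'
#' One-way ANOVA with Fisher LSD letters of income across ordered education
#' levels, run separately for farm and off-farm income.
#'
#' @param education education level labels (ordered categories).
#' @param farm_income,off_farm_income $/yr.
#' @param alpha significance level.
#' @return list of two `povdyn_comparison` objects (`farm`, `off_farm`), or
#'   `NULL` entries when fewer than two levels are represented.
#' @export
education_income_analysis <- function(education, farm_income,
                                      off_farm_income, alpha = 0.05) {
  run1 <- function(y) {
    ok <- !is.na(y) & !is.na(education)
    if (length(unique(education[ok])) < 2) return(NULL)
    anova_posthoc(y[ok], education[ok], method = "fisher_lsd", alpha = alpha)
  }
  list(farm = run1(farm_income), off_farm = run1(off_farm_income))
}
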
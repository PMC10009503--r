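#' Full poverty-dynamics analysis of a two-round panel
#'
#' Runs the whole analysis on a household panel: per-household indicators
#' (MAE, TLU, value components, TVA, FA, intensities), three-stratum
#' classification per round, nine-group trajectories, flow matrix and
#' rising/steady/falling shares, per-stratum shares of population, land and
#' produce value, TVA composition, net change by trajectory group, paired
#' tests on poverty status (McNemar at the poverty line and at the calorie
#' line, Wilcoxon signed rank on stratum codes), per-stratum performance
#' tables with post-hoc letters, welfare scoring and stratum validation,
#' and the asset-to-income regression.
#'
#' @param panel a `povdyn_panel`.
#' @param conversion a `povdyn_conversion`.
#' @param calorie_line FA threshold, kcal/MAE/day (default 3000).
#' @param poverty_line value threshold, PPP $/MAE/day (default 1.90).
#' @param per `"mae"` or `"capita"` denominator for the value threshold.
#' @param alpha significance level for post-hoc letters.
#' @param scorecard PPI scorecard for welfare scoring.
#' @return object of class `povdyn`; see Details for components.
#' @details Components: `indicators`, `assignments`, `trajectories`,
#'   `proportions`, `flow`, `shares`, `composition`, `net_change`,
#'   `tests` (mcnemar_poverty, mcnemar_calorie, wilcoxon), `tables`
#'   (strata_description, performance), `welfare` (scores, validation),
#'   `regression`, `education`, `retention`, `config`.
#' @export
poverty_dynamics <- function(panel, conversion, calorie_line = 3000,
                             poverty_line = 1.90, per = c("mae", "capita"),
                             alpha = 0.05,
                             scorecard = example_ppi_scorecard()) {
  per <- match.arg(per)
  ind <- compute_indicators(panel, conversion, per = per)
  asg <- assign_strata(ind, calorie_line, poverty_line)
  trj <- assign_trajectories(asg)
  flow <- flow_matrix(trj)
  props <- strata_proportions(asg)
  shares <- share_table(asg, ind)
  comp <- tva_composition(ind, asg)
  nets <- net_change_by_trajectory(ind, trj)

  # paired tests on the matched subsample, both dichotomizations
  i1 <- ind[ind$round == 1, ]; i2 <- ind[ind$round == 2, ]
  common <- intersect(i1$household_id, i2$household_id)
  m1 <- match(common, i1$household_id); m2 <- match(common, i2$household_id)
  lv <- stratum_levels()
  tests <- list(
    mcnemar_poverty = mcnemar_paired(i1$tva_per_mae_day[m1] >= poverty_line,
                                     i2$tva_per_mae_day[m2] >= poverty_line),
    mcnemar_calorie = mcnemar_paired(i1$fa[m1] >= calorie_line,
                                     i2$fa[m2] >= calorie_line),
    wilcoxon = {
      a1 <- asg[asg$round == 1, ]; a2 <- asg[asg$round == 2, ]
      wilcoxon_strata_movement(
        match(a1$stratum[match(common, a1$household_id)], lv),
        match(a2$stratum[match(common, a2$household_id)], lv))
    })

  tables <- list(
    strata_description = stratum_metric_table(
      ind, asg, c(hh_size = "Household members", land = "Land (ha)",
                  tlu = "Livestock (TLU)"), alpha = alpha),
    performance = stratum_metric_table(
      ind, asg, c(crop_value = "Crop value ($/yr)",
                  crop_intensity = "Crop intensity ($/ha/yr)",
                  livestock_value = "Livestock value ($/yr)",
                  livestock_intensity = "Livestock intensity ($/TLU/yr)",
                  off_farm_income = "Off-farm income ($/yr)",
                  offfarm_intensity = "Off-farm intensity ($/MAE/yr)"),
      alpha = alpha))

  welfare <- tryCatch({
    scores <- score_welfare(panel, scorecard = scorecard, round = 2)
    list(scores = scores,
         validation = validate_strata(scores, asg[asg$round == 2, ],
                                      alpha = alpha))
  }, error = function(e) list(scores = NULL, validation = NULL,
                              error = conditionMessage(e)))

  regression <- if (length(common) >= 5) {
    farm2 <- i2$crop_value[m2] + i2$livestock_value[m2]
    asset_income_regression(farm2, i1$land[m1], i1$tlu[m1],
                            i1$off_farm_income[m1])
  } else NULL

  education <- NULL
  if ("education" %in% names(panel$households)) {
    hh2 <- panel$households[panel$households$round == 2, ]
    e2 <- hh2$education[match(i2$household_id, hh2$household_id)]
    education <- education_income_analysis(
      e2, i2$crop_value + i2$livestock_value, i2$off_farm_income,
      alpha = alpha)
  }

  structure(list(indicators = ind, assignments = asg, trajectories = trj,
                 proportions = props, flow = flow, shares = shares,
                 composition = comp, net_change = nets, tests = tests,
                 tables = tables, welfare = welfare, regression = regression,
                 education = education, retention = panel_retention(panel),
                 config = list(calorie_line = calorie_line,
                               poverty_line = poverty_line, per = per,
                               alpha = alpha)),
            class = "povdyn")
}

# Medians with within-round post-hoc letters for a set of metrics: the
# shape of the farm-description and performance tables. No cross-round
# comparison is ever computed.
stratum_metric_table <- function(indicators, assignments, metrics,
                                 method = "tukey_hsd", alpha = 0.05) {
  key_i <- paste(indicators$household_id, indicators$round)
  key_a <- paste(assignments$household_id, assignments$round)
  stratum <- assignments$stratum[match(key_i, key_a)]
  out <- NULL
  for (r in sort(unique(indicators$round))) {
    rows <- data.frame(round = r, stratum = stratum_levels(),
                       stringsAsFactors = FALSE)
    for (m in names(metrics)) {
      sel <- indicators$round == r & !is.na(indicators[[m]])
      med <- tapply(indicators[[m]][sel],
                    factor(as.character(stratum[sel]),
                           levels = stratum_levels()), stats::median)
      letts <- rep(NA_character_, 3)
      counts <- table(factor(as.character(stratum[sel]),
                             levels = stratum_levels()))
      if (all(counts >= 2)) {
        cmp <- anova_posthoc(indicators[[m]][sel], stratum[sel],
                             method = method, alpha = alpha)
        letts <- cmp$letters[stratum_levels()]
      }
      rows[[m]] <- as.numeric(med)
      rows[[paste0(m, "_letters")]] <- letts
    }
    out <- rbind(out, rows)
  }
  attr(out, "labels") <- metrics
  out
}

#' @export
print.povdyn <- function(x, ...) {
  cat("Poverty-dynamics analysis\n")
  n1 <- sum(x$indicators$round == 1); n2 <- sum(x$indicators$round == 2)
  cat(sprintf("  households: %d (round 1), %d (round 2), %d matched\n",
              n1, n2, x$flow$n))
  cat(sprintf("  thresholds: %g kcal/%s/day, $%g/%s/day\n",
              x$config$calorie_line, toupper(x$config$per),
              x$config$poverty_line, toupper(x$config$per)))
  p <- round(100 * x$proportions)
  for (r in rownames(p)) {
    cat(sprintf("  round %s strata: Low %d%%, Medium %d%%, High %d%%\n",
                r, p[r, "Low"], p[r, "Medium"], p[r, "High"]))
  }
  s <- round(100 * x$flow$shares)
  cat(sprintf("  trajectories: %d%% rising, %d%% steady, %d%% falling\n",
              s[["rising"]], s[["steady"]], s[["falling"]]))
  invisible(x)
}

#' @export
summary.povdyn <- function(object, ...) {
  print(object)
  cat("\nPaired tests (matched panel households):\n")
  for (nm in names(object$tests)) {
    t <- object$tests[[nm]]
    cat(sprintf("  %s: statistic = %.3f, p = %.4g\n", nm, t$statistic,
                t$p_value))
  }
  if (!is.null(object$regression)) {
    cat("\nRound-2 farm income on round-1 assets:\n")
    print(object$regression$coefficients, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Format one of the headline tables
#'
#' @param kind `"strata_description"` (median household members, land, TLU
#'   per stratum with letters), `"shares"` (population/land/value shares
#'   and value:land ratios) or `"performance"` (median value and intensity
#'   metrics with letters).
#' @param fit a `povdyn` object.
#' @return data.frame shaped like the corresponding published table.
#' @export
make_table <- function(kind = c("strata_description", "shares", "performance"),
                       fit) {
  kind <- match.arg(kind)
  stopifnot(inherits(fit, "povdyn"))
  switch(kind,
         strata_description = fit$tables$strata_description,
         shares = fit$shares,
         performance = fit$tables$performance)
}

#' Run the pipeline end-to-end and write all outputs
#'
#' Reads (or receives) a panel and conversion table, runs
#' [poverty_dynamics()], and writes the output bundle to a directory:
#' indicator, strata, trajectory, share, composition, net-change,
#' description and performance CSVs, the flow matrix as JSON, welfare
#' validation, and a manifest recording the configuration and seed. The
#' run is deterministic given the same inputs and configuration.
#'
#' @param panel a `povdyn_panel`, or a directory path readable by
#'   [read_household_table()].
#' @param conversion a `povdyn_conversion`, or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @param calorie_line,poverty_line,per,alpha see [poverty_dynamics()].
#' @param seed integer recorded in the manifest (and used for any
#'   downstream simulation).
#' @return the `povdyn` object, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(panel, conversion, out_dir,
                         calorie_line = 3000, poverty_line = 1.90,
                         per = "mae", alpha = 0.05, seed = 1) {
  if (is.character(panel)) panel <- read_household_table(panel)
  if (is.character(conversion)) conversion <- read_conversion_table(conversion)
  fit <- poverty_dynamics(panel, conversion, calorie_line = calorie_line,
                          poverty_line = poverty_line, per = per,
                          alpha = alpha)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(fit$indicators, "indicators.csv")
  wcsv(fit$assignments, "strata.csv")
  wcsv(fit$trajectories, "trajectories.csv")
  wcsv(fit$shares, "share_table.csv")
  wcsv(fit$composition, "tva_composition.csv")
  wcsv(fit$net_change$medians, "net_change.csv")
  wcsv(fit$tables$strata_description, "strata_description.csv")
  wcsv(fit$tables$performance, "performance_table.csv")
  jsonlite::write_json(
    list(counts = fit$flow$counts, proportions = fit$flow$proportions,
         shares = as.list(fit$flow$shares), n = fit$flow$n),
    file.path(out_dir, "flow_matrix.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(fit$welfare$validation)) {
    wv <- do.call(rbind, lapply(names(fit$welfare$validation), function(nm) {
      v <- fit$welfare$validation[[nm]]
      data.frame(indicator = nm, skipped = isTRUE(v$skipped),
                 f_statistic = if (is.null(v$comparison)) NA else v$comparison$statistic,
                 p_value = if (is.null(v$comparison)) NA else v$comparison$p_value,
                 expected_direction_ok = v$expected_direction_ok,
                 stringsAsFactors = FALSE)
    }))
    wcsv(wv, "welfare_validation.csv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("povdyn")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = fit$config,
    n_round1 = sum(fit$indicators$round == 1),
    n_round2 = sum(fit$indicators$round == 2),
    outputs = union(list.files(out_dir), "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}
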
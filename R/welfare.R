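#' HFIAS score and severity category
#'
#' The Household Food Insecurity of Access Scale asks nine occurrence
#' questions about the past period, each answered with a frequency 0
#' (never), 1 (rarely), 2 (sometimes) or 3 (often). The score is the plain
#' sum (0-27). The severity category follows the standard four-class
#' algorithm over the item/frequency pattern, taking the most severe class
#' triggered: severe if the household cut meal sizes or meal numbers often,
#' or ran out of food, went to sleep hungry, or passed a whole day without
#' eating at any frequency; moderate if it sacrificed diet quality often or
#' cut quantity rarely/sometimes; mild if it worried or ate undesired foods
#' occasionally; food secure otherwise.
#'
#' @param items numeric vector of the 9 item frequencies (0-3), in the
#'   standard item order: worry; unable to eat preferred foods; limited
#'   variety; undesired foods; smaller meals; fewer meals; no food in
#'   house; sleep hungry; whole day without eating.
#' @return list with `score` (0-27) and `category` (factor: food_secure,
#'   mild, moderate, severe); both NA when any item is missing.
#' @export
score_hfias <- function(items) {
  cats <- c("food_secure", "mild", "moderate", "severe")
  if (length(items) != 9) stop("HFIAS needs exactly 9 items")
  if (anyNA(items)) {
    return(list(score = NA_real_,
                category = factor(NA, levels = cats, ordered = TRUE)))
  }
  if (any(items < 0 | items > 3)) stop("HFIAS frequencies must be in 0..3")
  q <- as.numeric(items)
  category <-
    if (q[5] == 3 || q[6] == 3 || q[7] > 0 || q[8] > 0 || q[9] > 0) "severe"
    else if (q[3] >= 2 || q[4] >= 2 || q[5] %in% 1:2 || q[6] %in% 1:2) "moderate"
    else if (q[1] >= 2 || q[2] >= 1 || q[3] == 1 || q[4] == 1) "mild"
    else "food_secure"
  list(score = sum(q), category = factor(category, levels = cats,
                                         ordered = TRUE))
}

#' Household dietary diversity score
#'
#' Count of food groups consumed during the reference season.
#'
#' @param consumed logical (or 0/1) vector, one flag per food group.
#' @return integer count; NA if any flag is missing.
#' @export
score_hdds <- function(consumed) {
  if (anyNA(consumed)) return(NA_integer_)
  sum(as.logical(consumed))
}

#' Example PPI-style scorecard
#'
#' A synthetic ten-question asset-based scorecard in the shape of the
#' published Poverty Probability Index instruments: each question has
#' options worth fixed points (total 0-100) and the point total maps to a
#' poverty likelihood through a monotone non-increasing step lookup. The
#' published country scorecards are data and can be supplied in the same
#' structure; this fixture exists so the engine is usable and testable
#' without them.
#'
#' @return list with `questions` (each a named numeric vector of option
#'   points) and `lookup` (data.frame `min_points`, `likelihood`).
#' @export
example_ppi_scorecard <- function() {
  qnames <- paste0("q", 1:10)
  questions <- stats::setNames(lapply(1:10, function(i) {
    c(none = 0, some = if (i %% 2) 4 else 6, good = if (i %% 2) 7 else 8,
      best = 10)
  }), qnames)
  lookup <- data.frame(min_points = seq(0, 90, by = 10),
                       likelihood = c(0.92, 0.85, 0.74, 0.60, 0.45,
                                      0.31, 0.20, 0.12, 0.06, 0.02))
  list(questions = questions, lookup = lookup)
}

#' Read / write a PPI scorecard (YAML)
#' @param path file path.
#' @param scorecard scorecard list as in [example_ppi_scorecard()].
#' @return `read_ppi_scorecard()` returns the scorecard list.
#' @export
read_ppi_scorecard <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$questions <- lapply(obj$questions, unlist)
  obj$lookup <- if (is.null(obj$lookup$min_points)) {
    do.call(rbind, lapply(obj$lookup, as.data.frame))
  } else {
    as.data.frame(lapply(obj$lookup, unlist))
  }
  obj
}

#' @rdname read_ppi_scorecard
#' @export
write_ppi_scorecard <- function(scorecard, path) {
  obj <- scorecard
  obj$questions <- lapply(obj$questions, as.list)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Score a PPI scorecard response
#'
#' Sums the option points of the chosen answers and maps the total to a
#' poverty likelihood via the scorecard's step lookup (the row with the
#' largest `min_points` not exceeding the total).
#'
#' @param answers named (or positional) vector of chosen option indices,
#'   one per scorecard question.
#' @param scorecard scorecard list, see [example_ppi_scorecard()].
#' @return list with `points` and `likelihood`; both NA if any question is
#'   unanswered.
#' @export
score_ppi <- function(answers, scorecard) {
  qs <- scorecard$questions
  if (length(answers) != length(qs)) stop("one answer per question required")
  if (anyNA(answers)) return(list(points = NA_real_, likelihood = NA_real_))
  pts <- 0
  for (i in seq_along(qs)) {
    opts <- qs[[i]]
    a <- answers[[i]]
    if (a < 1 || a > length(opts)) stop(sprintf("answer %d out of range", i))
    pts <- pts + opts[[a]]
  }
  lk <- scorecard$lookup[order(scorecard$lookup$min_points), ]
  row <- findInterval(pts, lk$min_points)
  list(points = pts, likelihood = lk$likelihood[row])
}

#' Score all welfare instruments for a panel round
#'
#' Computes HFIAS score and category, HDDS for flush and lean seasons, PPI
#' points and likelihood, and hungry months for every household in the
#' requested round. Households with incomplete responses for an instrument
#' get NA for that instrument (welfare scores require completeness).
#'
#' @param panel a `povdyn_panel`.
#' @param scorecard PPI scorecard; default [example_ppi_scorecard()].
#' @param round which survey round to score (welfare instruments were
#'   collected in the second round; default 2).
#' @return data.frame, one row per household.
#' @export
score_welfare <- function(panel, scorecard = example_ppi_scorecard(),
                          round = 2) {
  hh <- panel$households[panel$households$round == round, , drop = FALSE]
  hf_cols <- paste0("hfias_", 1:9)
  groups <- hdds_groups()
  fl_cols <- paste0("hdds_flush_", groups)
  le_cols <- paste0("hdds_lean_", groups)
  ppi_cols <- paste0("ppi_", names(scorecard$questions))
  out <- data.frame(household_id = hh$household_id, site = hh$site,
                    round = round, stringsAsFactors = FALSE)
  n <- nrow(hh)
  out$hfias_score <- rep(NA_real_, n)
  out$hfias_category <- rep(NA_character_, n)
  out$hdds_flush <- rep(NA_integer_, n)
  out$hdds_lean <- rep(NA_integer_, n)
  out$ppi_score <- rep(NA_real_, n)
  out$ppi_likelihood <- rep(NA_real_, n)
  out$hungry_months <- hh$months_food_shortage
  for (i in seq_len(n)) {
    if (all(hf_cols %in% names(hh))) {
      hf <- score_hfias(as.numeric(hh[i, hf_cols]))
      out$hfias_score[i] <- hf$score
      out$hfias_category[i] <- as.character(hf$category)
    }
    if (all(fl_cols %in% names(hh)))
      out$hdds_flush[i] <- score_hdds(as.logical(hh[i, fl_cols]))
    if (all(le_cols %in% names(hh)))
      out$hdds_lean[i] <- score_hdds(as.logical(hh[i, le_cols]))
    if (all(ppi_cols %in% names(hh))) {
      pp <- score_ppi(as.numeric(hh[i, ppi_cols]), scorecard)
      out$ppi_score[i] <- pp$points
      out$ppi_likelihood[i] <- pp$likelihood
    }
  }
  out
}

#' Validate the poverty strata against independent welfare indicators
#'
#' The strata are built from production values only; here they are checked
#' against the welfare instruments, which use independent data. For each
#' indicator the three strata are compared by one-way ANOVA with Tukey HSD
#' letters, and the direction of the stratum medians is checked against the
#' expectation that higher strata score better (lower HFIAS, PPI
#' likelihood and hungry months; higher HDDS).
#'
#' @param scores output of [score_welfare()].
#' @param assignments output of [assign_strata()] (round matching `scores`).
#' @param alpha significance level.
#' @return list, one entry per indicator, each with the
#'   `povdyn_comparison` (`comparison`), `expected_direction_ok` (logical)
#'   and `skipped` flag when a stratum has fewer than 2 households.
#' @export
validate_strata <- function(scores, assignments, alpha = 0.05) {
  idx <- match(paste(scores$household_id, scores$round),
               paste(assignments$household_id, assignments$round))
  stratum <- assignments$stratum[idx]
  indicators <- c(hfias_score = -1, hdds_flush = 1, hdds_lean = 1,
                  ppi_likelihood = -1, hungry_months = -1)
  out <- list()
  for (ind in names(indicators)) {
    y <- scores[[ind]]
    ok <- !is.na(y) & !is.na(stratum)
    counts <- table(factor(stratum[ok], levels = stratum_levels()))
    if (any(counts < 2)) {
      out[[ind]] <- list(comparison = NULL, expected_direction_ok = NA,
                         skipped = TRUE,
                         reason = "a stratum has fewer than 2 households")
      next
    }
    cmp <- anova_posthoc(y[ok], factor(stratum[ok], levels = stratum_levels()),
                         method = "tukey_hsd", alpha = alpha)
    med <- cmp$estimates$median[match(stratum_levels(), cmp$estimates$group)]
    better <- if (indicators[[ind]] > 0) !is.unsorted(med) else !is.unsorted(rev(med))
    out[[ind]] <- list(comparison = cmp, expected_direction_ok = better,
                       skipped = FALSE)
  }
  out
}
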
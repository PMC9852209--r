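# Cohort-level statistics: odds ratios with Woolf intervals, one-way
# ANOVA of survival by group, and descriptive summaries.

#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table (`a` = exposure and outcome, `b` = exposure only,
#' `c` = outcome only, `d` = neither): `OR = a d / (b c)`, with the
#' Woolf (log) interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. No continuity
#' correction is applied by default; the Haldane-Anscombe +0.5
#' correction is available for tables with zero cells.
#'
#' @param a,b,c,d Nonnegative counts; `b * c > 0` for the point
#'   estimate, all cells positive for the interval.
#' @param confidence Coverage (default 0.95, `z = 1.959964`).
#' @param correction If `TRUE`, add 0.5 to every cell.
#' @return A list: `or`, `ci_low`, `ci_high`, `defined` (FALSE when a
#'   zero cell leaves the interval undefined).
#' @export
odds_ratio <- function(a, b, c, d, confidence = 0.95, correction = FALSE) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (correction) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  if (b * c == 0) stop("odds ratio undefined: b*c = 0", call. = FALSE)
  or <- (a * d) / (b * c)
  if (min(a, b, c, d) > 0) {
    z <- stats::qnorm(1 - (1 - confidence) / 2)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
         defined = TRUE)
  } else {
    list(or = or, ci_low = NA_real_, ci_high = NA_real_, defined = FALSE)
  }
}

#' King's stage by survival profile odds-ratio table
#'
#' For every (stage, profile) pair, the exposure is membership in the
#' stage and the outcome membership in the profile; the cross-product
#' odds ratio and Woolf interval are computed, with a significance flag
#' when the interval excludes 1. Entries with undefined estimates
#' (empty margins or zero cells) are flagged rather than dropped.
#'
#' @param cohort Cohort data frame with a `kings_stage` column.
#' @param labels Survival profile per subject.
#' @param stages Stages to tabulate (default 1:4).
#' @param confidence Interval coverage.
#' @return A data frame: `stage`, `class`, cell counts `a`-`d`, `or`,
#'   `ci_low`, `ci_high`, `significant`, `defined`.
#' @export
stage_class_or_table <- function(cohort, labels, stages = 1:4,
                                 confidence = 0.95) {
  stopifnot(length(labels) == nrow(cohort))
  classes <- sort(unique(labels))
  rows <- list()
  for (s in stages) for (cl in classes) {
    e <- cohort$kings_stage == s
    o <- labels == cl
    a <- sum(e & o); b <- sum(e & !o); c <- sum(!e & o); d <- sum(!e & !o)
    if (b * c == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        stage = s, class = cl, a = a, b = b, c = c, d = d,
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        significant = NA, defined = FALSE)
      next
    }
    orr <- odds_ratio(a, b, c, d, confidence)
    rows[[length(rows) + 1]] <- data.frame(
      stage = s, class = cl, a = a, b = b, c = c, d = d,
      or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
      significant = if (orr$defined) orr$ci_low > 1 | orr$ci_high < 1 else NA,
      defined = orr$defined)
  }
  do.call(rbind, rows)
}

#' One-way ANOVA of survival time by group
#'
#' Classic between/within decomposition with
#' `F = (SSB/(g-1)) / (SSW/(n-g))` and the p-value from the F
#' distribution, via [stats::oneway.test()] with equal variances.
#'
#' @param values Continuous response (survival time in years).
#' @param groups Grouping factor; at least two groups with two or more
#'   members each.
#' @return A list: `f`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  counts <- table(groups)
  if (length(counts) < 2 || any(counts < 2))
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(f = unname(fit$statistic), p = unname(fit$p.value),
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]))
}

#' Descriptive cohort summary
#'
#' Medians and interquartile ranges (inclusive-quartile convention,
#' [stats::quantile()] type 7) of survival and age, and category
#' percentages rounded to one decimal, overall and per survival
#' profile.
#'
#' @param cohort Cohort data frame (`survival_years`, `sex`,
#'   `age_years`, `onset` columns used when present).
#' @param labels Optional survival profile per subject; adds per-class
#'   blocks.
#' @return A list with an `overall` block (and `per_class` list when
#'   `labels` is given). Each block reports `n`, `median_survival`,
#'   `iqr_survival`, `pct_female`, `pct_spinal`, `median_age`,
#'   `iqr_age` (fields present when the column exists).
#' @export
descriptive_summary <- function(cohort, labels = NULL) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  block <- function(d) {
    out <- list(n = nrow(d))
    if (!is.null(d$survival_years)) {
      q <- stats::quantile(d$survival_years, c(0.25, 0.5, 0.75), type = 7)
      out$median_survival <- unname(q[2])
      out$iqr_survival <- unname(q[c(1, 3)])
    }
    if (!is.null(d$sex))
      out$pct_female <- round(100 * mean(d$sex == "F"), 1)
    if (!is.null(d$onset))
      out$pct_spinal <- round(100 * mean(d$onset == "spinal"), 1)
    if (!is.null(d$age_years)) {
      q <- stats::quantile(d$age_years, c(0.25, 0.5, 0.75), type = 7)
      out$median_age <- unname(q[2])
      out$iqr_age <- unname(q[c(1, 3)])
    }
    out
  }
  res <- list(overall = block(cohort))
  if (!is.null(labels)) {
    res$per_class <- lapply(sort(unique(labels)),
                            function(cl) block(cohort[labels == cl, , drop = FALSE]))
    names(res$per_class) <- paste0("class_", sort(unique(labels)))
  }
  res
}
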
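#' IHC percentage-of-positive-cells category score
#'
#' Bins the percentage of positively stained cells into the five-level
#' semiquantitative score: <= 5% -> 0 (absent), 6-25% -> 1, 26-50% -> 2,
#' 51-75% -> 3, > 75% -> 4. Percentages are rounded to the nearest integer
#' (half-up) before binning, so fractional readings at bin boundaries resolve
#' the way pathologists conventionally report them.
#'
#' @param percent_positive percentage in `[0, 100]` (vectorized).
#' @return Integer score(s) in 0..4.
#' @export
percentage_score <- function(percent_positive) {
  if (any(is.na(percent_positive)) ||
      any(percent_positive < 0 | percent_positive > 100))
    stop("percent_positive must be within [0, 100]")
  p <- floor(percent_positive + 0.5)  # half-up
  as.integer(cut(p, breaks = c(-1, 5, 25, 50, 75, 100),
                 labels = FALSE)) - 1L
}

#' IHC staining score
#'
#' Total staining score = percentage-category score (0..4) times staining
#' intensity (0 negative, 1 weak, 2 moderate, 3 strong); range 0..12, with 0
#' absorbing (absent staining or negative intensity forces a zero total).
#'
#' @param percent_positive percentage in `[0, 100]` (vectorized).
#' @param intensity intensity score(s) in `{0, 1, 2, 3}`.
#' @return Integer total score(s) in 0..12.
#' @export
staining_score <- function(percent_positive, intensity) {
  if (any(is.na(intensity)) || any(!intensity %in% 0:3))
    stop("intensity must be 0, 1, 2 or 3")
  percentage_score(percent_positive) * as.integer(intensity)
}

#' Compare mean staining scores between groups
#'
#' Unpaired two-sided Student's t-test with pooled variance. When both groups
#' are constant with equal means the statistic is 0 and p = 1; constant groups
#' with different means give p = 0.
#'
#' @param a,b numeric score vectors, each of length >= 2.
#' @return A list: `t`, `df`, `p`, group means.
#' @export
compare_scores <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least two observations")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1,
                                        mean_a = mean(a), mean_b = mean(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' Kaplan-Meier overall-survival estimate
#'
#' Product-limit estimator (via the survival package) with right censoring.
#' The q-th quartile survival time is read off the curve as the earliest time
#' at which S(t) drops to `1 - q` or below (`NA` when the curve never falls
#' that far); "third-quartile survival" therefore means the time at which 75%
#' of patients are still alive.
#'
#' @param times follow-up in months (>= 0).
#' @param events event flags (1 = death, 0 = censored).
#' @return A list of class `vb_km`: `table` (time, n_risk, n_event, surv step
#'   function), `quartiles` (named times at S <= 0.75 / 0.50 / 0.25),
#'   `survival_at` (a function t -> S(t)), `n`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (any(times < 0)) stop("survival times must be >= 0")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, surv = sf$surv)
  step <- stats::stepfun(tab$time, c(1, tab$surv), right = FALSE)
  quart <- vapply(c(q25 = 0.25, q50 = 0.5, q75 = 0.75), function(q) {
    hit <- which(tab$surv <= 1 - q + 1e-12)
    if (length(hit) == 0L) NA_real_ else tab$time[hit[1]]
  }, numeric(1))
  structure(list(table = tab, quartiles = quart,
                 survival_at = function(t) step(t), n = length(times)),
            class = "vb_km")
}

#' @export
print.vb_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate, n = %d, %d event(s)\n",
              x$n, sum(x$table$n_event)))
  q <- x$quartiles
  cat(sprintf("  survival quartiles (S<=0.75/0.50/0.25): %s / %s / %s months\n",
              format(q[1]), format(q[2]), format(q[3])))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic on 1 degree of freedom, the conventional
#' companion of the Kaplan-Meier comparison.
#'
#' @param times follow-up in months.
#' @param events event flags (1 = death, 0 = censored).
#' @param groups two-level group labels.
#' @return A list: `chisq`, `df`, `p`, per-group observed/expected events.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("log-rank comparison needs exactly two non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(chisq = sd$chisq, df = 1L,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Survival and IHC analysis of a cohort table
#'
#' Convenience wrapper: overall KM curve, per-group KM curves with 5-year OS,
#' the log-rank group comparison, and (when IHC columns are present) the
#' per-marker staining-score group comparison by unpaired t-test.
#'
#' @param cohort a cohort table (see [read_cohort_table]).
#' @param markers IHC marker prefixes to analyze (default `c("cd68", "il1b")`).
#' @return A list: `km_all`, `km_group` (per-level [km_estimate]),
#'   `os5yr_pct` (per-group S(60) in percent), `logrank`, `ihc` (per marker:
#'   group means and t-test).
#' @export
survival_ihc_analysis <- function(cohort, markers = c("cd68", "il1b")) {
  km_all <- km_estimate(cohort$survival_months, cohort$event)
  km_group <- lapply(split(cohort, cohort$group), function(g)
    km_estimate(g$survival_months, g$event))
  os5 <- vapply(km_group, function(k) 100 * k$survival_at(60), numeric(1))
  lr <- logrank_test(cohort$survival_months, cohort$event, cohort$group)

  ihc <- list()
  for (m in markers) {
    pc <- paste0(m, "_percent"); ic <- paste0(m, "_intensity")
    if (!all(c(pc, ic) %in% names(cohort))) next
    ok <- !is.na(cohort[[pc]]) & !is.na(cohort[[ic]])
    if (!any(ok)) next
    sc <- staining_score(cohort[[pc]][ok], cohort[[ic]][ok])
    grp <- cohort$group[ok]
    ihc[[m]] <- c(list(scores = stats::setNames(sc, cohort$patient_id[ok])),
                  compare_scores(sc[grp == "long"], sc[grp == "short"]))
  }
  list(km_all = km_all, km_group = km_group, os5yr_pct = os5,
       logrank = lr, ihc = ihc)
}
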
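# cache of split-enumeration index matrices, keyed by "n,n1"
.vb_combn_cache <- new.env(parent = emptyenv())

group_splits <- function(n, n1) {
  key <- paste(n, n1, sep = ",")
  if (is.null(.vb_combn_cache[[key]]))
    .vb_combn_cache[[key]] <- utils::combn(n, n1)
  .vb_combn_cache[[key]]
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Computes the two-sided Mann-Whitney U test. For pooled sizes
#' `n1 + n2 <= 16` the p-value is exact: all `choose(n1+n2, n1)` assignments
#' of the observed pooled values (midranks, so ties are handled by
#' construction) are enumerated and the two-sided p is `min(1, 2 * one-sided)`
#' with the one-sided tail taken as the smaller of the two tail probabilities
#' of the observed U. For larger samples the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b numeric vectors, the two groups (both non-empty).
#' @return A list of class `vb_utest`: `U` (for group `a`), `p`, `method`
#'   (`"exact"` or `"normal-tie-corrected"`), `n1`, `n2`.
#' @export
mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (n <= 16L) {
    splits <- group_splits(n, n1)
    Rsums <- colSums(matrix(r[splits], nrow = n1))
    Uall <- Rsums - n1 * (n1 + 1) / 2
    eps <- 1e-9
    one_sided <- min(mean(Uall <= U_obs + eps), mean(Uall >= U_obs - eps))
    p <- min(1, 2 * one_sided)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U_obs - mu
      z <- z - sign(z) * 0.5  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    }
    method <- "normal-tie-corrected"
  }
  structure(list(U = U_obs, p = p, method = method, n1 = n1, n2 = n2),
            class = "vb_utest")
}

#' @export
print.vb_utest <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p, x$method))
  invisible(x)
}

#' Muscle-sphere noise-control filter
#'
#' The control sphere sits in muscle, which carries no outcome information: a
#' feature whose muscle-VOI values separate the outcome groups is driven by
#' image noise or scanner differences and is excluded from selection. The
#' default reading compares muscle values between outcome groups within each
#' observer set and excludes a feature significant in either set
#' (`"between-groups"`); the alternative reading compares the two observers'
#' muscle spheres directly, pooling patients (`"between-observers"`).
#'
#' @param features feature table: a data.frame with columns `patient_id`,
#'   `observer`, `role` plus one column per feature; only `role == "control"`
#'   rows are used.
#' @param cohort cohort table with `patient_id` and `group` (see
#'   [read_cohort_table]).
#' @param alpha significance level (default 0.05); `alpha = 0` disables
#'   exclusion.
#' @param feature_ids features to screen (default: all numeric feature
#'   columns).
#' @param mode noise-comparison reading, see above.
#' @return A data.frame with one row per feature: the per-observer muscle
#'   p-values and the `excluded` flag; the mode is recorded as an attribute.
#' @export
noise_control_filter <- function(features, cohort, alpha = 0.05,
                                 feature_ids = NULL,
                                 mode = c("between-groups", "between-observers")) {
  mode <- match.arg(mode)
  muscle <- features[features$role == "control", , drop = FALSE]
  if (is.null(feature_ids))
    feature_ids <- setdiff(names(features),
                           c("patient_id", "observer", "role"))
  observers <- sort(unique(features$observer))
  missing <- character(0)
  for (obs in observers) {
    have <- unique(muscle$patient_id[muscle$observer == obs])
    lack <- setdiff(cohort$patient_id, have)
    if (length(lack) > 0)
      missing <- c(missing, paste0(lack, " (", obs, ")"))
  }
  if (length(missing) > 0)
    stop("missing muscle-sphere data for patient(s): ",
         paste(missing, collapse = ", "))
  muscle$group <- cohort$group[match(muscle$patient_id, cohort$patient_id)]

  pmat <- matrix(NA_real_, nrow = length(feature_ids), ncol = length(observers),
                 dimnames = list(feature_ids, observers))
  if (mode == "between-groups") {
    for (obs in observers) {
      mo <- muscle[muscle$observer == obs, , drop = FALSE]
      for (f in feature_ids)
        pmat[f, obs] <- mann_whitney(mo[[f]][mo$group == "long"],
                                     mo[[f]][mo$group == "short"])$p
    }
    excluded <- apply(pmat, 1, function(p) alpha > 0 && any(p <= alpha))
  } else {
    if (length(observers) != 2L)
      stop("between-observers mode needs exactly two observers")
    m1 <- muscle[muscle$observer == observers[1], , drop = FALSE]
    m2 <- muscle[muscle$observer == observers[2], , drop = FALSE]
    for (f in feature_ids) {
      p <- mann_whitney(m1[[f]], m2[[f]])$p
      pmat[f, ] <- p
    }
    excluded <- pmat[, 1] <= alpha & alpha > 0
  }
  out <- data.frame(feature = feature_ids,
                    muscle_p_obs1 = pmat[, 1],
                    muscle_p_obs2 = pmat[, 2],
                    excluded = unname(excluded),
                    row.names = NULL)
  attr(out, "mode") <- mode
  attr(out, "observers") <- observers
  out
}

#' Dual-observer intersection selection
#'
#' A feature is selected when its group-difference p-value is `<= alpha` in
#' BOTH observers' analyses (the boundary value counts) and it is not
#' noise-excluded.
#'
#' @param p_obs1,p_obs2 named numeric vectors of per-feature p-values, one per
#'   observer; the feature sets must match.
#' @param alpha significance level (default 0.05).
#' @param noise_excluded character vector of noise-excluded feature ids.
#' @return A data.frame with columns `feature`, `p_obs1`, `p_obs2`,
#'   `noise_excluded`, `selected`.
#' @export
dual_set_intersection <- function(p_obs1, p_obs2, alpha = 0.05,
                                  noise_excluded = character(0)) {
  if (!setequal(names(p_obs1), names(p_obs2)))
    stop("the two observer result sets cover different features")
  feats <- names(p_obs1)
  p2 <- p_obs2[feats]
  excl <- feats %in% noise_excluded
  data.frame(
    feature = feats,
    p_obs1 = unname(p_obs1),
    p_obs2 = unname(p2),
    noise_excluded = excl,
    selected = unname(p_obs1) <= alpha & unname(p2) <= alpha & !excl,
    row.names = NULL
  )
}

#' Empirical ROC analysis
#'
#' AUC by the rank formula (equivalent to `U / (n1 * n2)`, ties counted half)
#' with the empirical ROC evaluated at every distinct observed value. Both
#' orientations are considered and the one with AUC >= 0.5 is reported: with
#' direction `"greater"` a case is called positive when its value is `>=` the
#' cutoff, with `"less"` when it is `<=` the cutoff.
#'
#' @param values numeric feature values.
#' @param labels class labels (two classes present).
#' @param positive the positive-class label (default `"short"`, the
#'   poor-outcome group).
#' @return A list of class `vb_roc`: `auc`, `direction`, `cutoffs` (data.frame
#'   of cutoff/sensitivity/specificity), class sizes.
#' @export
roc_analysis <- function(values, labels, positive = "short") {
  labels <- as.character(labels)
  if (!positive %in% labels) stop("positive class '", positive, "' absent")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(values)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  direction <- if (auc >= 0.5) "greater" else "less"
  if (direction == "less") auc <- 1 - auc
  v <- if (direction == "greater") values else -values
  cut_v <- sort(unique(v))
  sens <- vapply(cut_v, function(cc) mean(v[pos] >= cc), numeric(1))
  spec <- vapply(cut_v, function(cc) mean(v[!pos] < cc), numeric(1))
  cutoffs <- data.frame(
    cutoff = if (direction == "greater") cut_v else -cut_v,
    sensitivity = sens, specificity = spec)
  structure(list(auc = auc, direction = direction, cutoffs = cutoffs,
                 n_pos = n_pos, n_neg = n_neg, positive = positive),
            class = "vb_roc")
}

#' @export
print.vb_roc <- function(x, ...) {
  y <- youden_cutoff(x)
  cat(sprintf(
    "ROC: AUC = %.3f (%s), Youden cutoff %.4g (sens %.0f%%, spec %.0f%%)\n",
    x$auc, x$direction, y$cutoff, 100 * y$sensitivity, 100 * y$specificity))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Maximizes `J = sensitivity + specificity - 1` over the ROC cutoffs; ties
#' are broken by the highest sensitivity, then the lowest cutoff value.
#'
#' @param roc a `vb_roc` from [roc_analysis].
#' @return A list: `cutoff`, `sensitivity`, `specificity`, `youden`,
#'   `direction`.
#' @export
youden_cutoff <- function(roc) {
  tab <- roc$cutoffs
  J <- tab$sensitivity + tab$specificity - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[order(-tab$sensitivity[best], tab$cutoff[best])][1]
  list(cutoff = tab$cutoff[best],
       sensitivity = tab$sensitivity[best],
       specificity = tab$specificity[best],
       youden = J[best],
       direction = roc$direction)
}

#' Run the full selection pipeline on a cohort feature table
#'
#' Per observer, each patient's tumor value for a feature is the mean of the
#' axial and coronal biopsy-sphere values (configurable), compared between the
#' long- and short-survival groups with the exact Mann-Whitney test. Features
#' failing the muscle-sphere noise filter are excluded; the remaining features
#' significant at `alpha` in both observer sets are selected and characterized
#' by ROC/Youden analysis per observer.
#'
#' @param features feature table (see [noise_control_filter] for the layout).
#' @param cohort cohort table with `patient_id` and `group`.
#' @param alpha significance level (default 0.05).
#' @param combine_vois how to reduce the two biopsy spheres to one tumor value
#'   per patient: `"mean"` (default), `"axial"`, or `"coronal"`.
#' @param noise_mode muscle-filter reading (see [noise_control_filter]).
#' @param adjust optional Benjamini-Hochberg correction of each observer's
#'   p-values before intersection (`"none"`, the default, mirrors the original
#'   procedure, whose robustness device is the dual-observer intersection).
#' @return A list of class `vb_selection`: `report` (per-feature p-values,
#'   exclusion and selection flags), `roc` (per selected feature, per
#'   observer: AUC, Youden cutoff, sensitivity, specificity), `alpha`,
#'   `noise`, `observers`.
#' @export
select_features <- function(features, cohort, alpha = 0.05,
                            combine_vois = c("mean", "axial", "coronal"),
                            noise_mode = c("between-groups", "between-observers"),
                            adjust = c("none", "BH")) {
  combine_vois <- match.arg(combine_vois)
  adjust <- match.arg(adjust)
  observers <- sort(unique(features$observer))
  if (length(observers) != 2L)
    stop("selection requires exactly two observer sets, found: ",
         paste(observers, collapse = ", "))
  feature_ids <- setdiff(names(features), c("patient_id", "observer", "role"))

  tumor_value <- function(obs, f) {
    tf <- features[features$observer == obs & features$role != "control", ,
                   drop = FALSE]
    if (combine_vois != "mean")
      tf <- tf[tf$role == combine_vois, , drop = FALSE]
    v <- tapply(tf[[f]], tf$patient_id, mean)
    v[as.character(cohort$patient_id)]
  }

  pvals <- list()
  vals <- list()
  for (obs in observers) {
    p <- numeric(0)
    vlist <- list()
    for (f in feature_ids) {
      v <- tumor_value(obs, f)
      p[f] <- mann_whitney(v[cohort$group == "long"],
                           v[cohort$group == "short"])$p
      vlist[[f]] <- v
    }
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    pvals[[obs]] <- p
    vals[[obs]] <- vlist
  }

  noise <- noise_control_filter(features, cohort, alpha = alpha,
                                feature_ids = feature_ids, mode = noise_mode)
  report <- dual_set_intersection(pvals[[1]], pvals[[2]], alpha = alpha,
                                  noise_excluded = noise$feature[noise$excluded])
  report$muscle_p_obs1 <- noise$muscle_p_obs1[match(report$feature, noise$feature)]
  report$muscle_p_obs2 <- noise$muscle_p_obs2[match(report$feature, noise$feature)]

  roc <- list()
  for (f in report$feature[report$selected]) {
    roc[[f]] <- lapply(stats::setNames(observers, observers), function(obs) {
      rr <- roc_analysis(vals[[obs]][[f]], cohort$group, positive = "short")
      yy <- youden_cutoff(rr)
      list(auc = rr$auc, direction = rr$direction, cutoff = yy$cutoff,
           sensitivity = yy$sensitivity, specificity = yy$specificity,
           youden = yy$youden)
    })
  }
  structure(list(report = report, roc = roc, alpha = alpha,
                 noise = noise, observers = observers,
                 combine_vois = combine_vois, adjust = adjust),
            class = "vb_selection")
}

#' @export
print.vb_selection <- function(x, ...) {
  sel <- x$report$feature[x$report$selected]
  cat(sprintf("Dual-observer selection at alpha = %g:\n", x$alpha))
  cat(sprintf("  %d candidate feature(s), %d noise-excluded, %d selected\n",
              nrow(x$report), sum(x$report$noise_excluded), length(sel)))
  if (length(sel) > 0) {
    for (f in sel) {
      aucs <- vapply(x$roc[[f]], `[[`, numeric(1), "auc")
      cat(sprintf("  %-26s AUC %s\n", f,
                  paste(sprintf("%.3f", aucs), collapse = " / ")))
    }
  }
  invisible(x)
}

#' Write a selection report to JSON and CSV
#'
#' @param selection a `vb_selection`.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @return The selection object, invisibly.
#' @export
write_selection_report <- function(selection, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- list(
      alpha = selection$alpha,
      noise_mode = attr(selection$noise, "mode"),
      combine_vois = selection$combine_vois,
      report = selection$report,
      roc = selection$roc
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    flat <- selection$report
    for (col in c("auc_obs1", "auc_obs2", "cutoff_obs1", "cutoff_obs2",
                  "sens_obs1", "spec_obs1", "sens_obs2", "spec_obs2"))
      flat[[col]] <- NA_real_
    for (f in names(selection$roc)) {
      i <- match(f, flat$feature)
      r <- selection$roc[[f]]
      flat$auc_obs1[i] <- r[[1]]$auc; flat$auc_obs2[i] <- r[[2]]$auc
      flat$cutoff_obs1[i] <- r[[1]]$cutoff; flat$cutoff_obs2[i] <- r[[2]]$cutoff
      flat$sens_obs1[i] <- r[[1]]$sensitivity; flat$spec_obs1[i] <- r[[1]]$specificity
      flat$sens_obs2[i] <- r[[2]]$sensitivity; flat$spec_obs2[i] <- r[[2]]$specificity
    }
    utils::write.csv(flat, csv_path, row.names = FALSE)
  }
  invisible(selection)
}
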
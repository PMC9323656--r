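test_that("exact Mann-Whitney p-values match enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 of the 20 assignments are as extreme
  expect_identical(r$method, "exact")

  expect_equal(mann_whitney(c(5, 5, 5, 5), c(5, 5, 5))$p, 1)

  set.seed(19)
  for (i in 1:10) {
    a <- round(rnorm(8, 0, 10)); b <- round(rnorm(7, 5, 10))
    got <- mann_whitney(a, b)
    expect_equal(got$p, bf_mw_exact_p(a, b))
    expect_equal(got$U, bf_mw_u(a, b))
  }
  # tie-free case agrees with the reference exact implementation
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(7)
    expect_equal(mann_whitney(a, b)$p,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(29)
  a <- round(rnorm(12, 0, 5)); b <- round(rnorm(10, 2, 5))
  got <- mann_whitney(a, b)
  expect_identical(got$method, "normal-tie-corrected")
  ref <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$U, unname(ref$statistic))
})

test_that("AUC obeys the rank-formula identity with the U statistic", {
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1)
    vals <- c(round(rnorm(n1, 1, 2)), round(rnorm(n2, 0, 2)))
    labs <- rep(c("short", "long"), c(n1, n2))
    roc <- roc_analysis(vals, labs, positive = "short")
    raw_auc <- bf_auc(vals, labs, "short")
    expect_equal(roc$auc, max(raw_auc, 1 - raw_auc))
    expect_equal(raw_auc,
                 mann_whitney(vals[labs == "short"], vals[labs == "long"])$U /
                   (n1 * n2))
  }
  # perfect separation
  expect_equal(roc_analysis(c(1, 2, 3, 10, 11, 12),
                            rep(c("long", "short"), each = 3))$auc, 1)
  # orientation symmetry: negating values flips the raw AUC
  vals <- c(3, 1, 4, 1, 5, 9, 2, 6)
  labs <- rep(c("short", "long"), each = 4)
  expect_equal(bf_auc(vals, labs, "short"), 1 - bf_auc(-vals, labs, "short"))
})

test_that("Youden cutoff maximizes J with deterministic tie-breaks", {
  roc <- roc_analysis(c(1, 2, 3, 10, 11, 12),
                      rep(c("long", "short"), each = 3))
  y <- youden_cutoff(roc)
  expect_equal(y$youden, 1)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)

  set.seed(37)
  for (i in 1:10) {
    vals <- round(rnorm(14, 0, 3))
    labs <- rep(c("short", "long"), 7)
    roc <- roc_analysis(vals, labs)
    expect_equal(youden_cutoff(roc)$youden, bf_youden(vals, labs, "short"),
                 tolerance = 1e-12)
  }

  const <- roc_analysis(rep(5, 10), rep(c("short", "long"), 5))
  expect_equal(youden_cutoff(const)$youden, 0)
})

test_that("ROC results agree with an independent ROC implementation", {
  requireNamespace("pROC", quietly = TRUE)
  set.seed(71)
  for (i in 1:8) {
    vals <- round(rnorm(15, 0, 4)) + c(rep(0, 8), rep(i %% 4, 7))
    labs <- rep(c("long", "short"), c(8, 7))
    mine <- roc_analysis(vals, labs, positive = "short")
    # pROC's "auto" direction is median-based; evaluate both directions and
    # keep the better one, matching the AUC >= 0.5 orientation rule
    refs <- lapply(c("<", ">"), function(d) suppressMessages(
      pROC::roc(labs, vals, levels = c("long", "short"), direction = d)))
    aucs <- vapply(refs, function(r) as.numeric(pROC::auc(r)), numeric(1))
    ref <- refs[[which.max(aucs)]]
    expect_equal(mine$auc, max(aucs))
    y <- youden_cutoff(mine)
    best <- pROC::coords(ref, "best", best.method = "youden",
                         ret = c("sensitivity", "specificity"))
    expect_equal(y$sensitivity + y$specificity,
                 max(best$sensitivity + best$specificity))
  }
})

make_feature_table <- function(values_by_feature, cohort,
                               roles = c("axial", "coronal", "control")) {
  rows <- list()
  for (obs in c("obs1", "obs2")) for (role in roles) {
    df <- data.frame(patient_id = cohort$patient_id, observer = obs,
                     role = role, stringsAsFactors = FALSE)
    for (f in names(values_by_feature))
      df[[f]] <- values_by_feature[[f]][[obs]][[role]]
    rows[[length(rows) + 1L]] <- df
  }
  do.call(rbind, rows)
}

toy_cohort <- function(n_long = 8, n_short = 7) {
  data.frame(patient_id = sprintf("P%02d", seq_len(n_long + n_short)),
             group = factor(rep(c("long", "short"), c(n_long, n_short)),
                            levels = c("long", "short")),
             stringsAsFactors = FALSE)
}

test_that("noise filter excludes muscle-significant features and honors alpha", {
  cohort <- toy_cohort()
  set.seed(43)
  mk <- function(tumor_shift, muscle_shift) {
    shift <- function(base_shift)
      c(rnorm(8), rnorm(7) + base_shift)
    lapply(stats::setNames(c("obs1", "obs2"), c("obs1", "obs2")), function(o)
      list(axial = shift(tumor_shift), coronal = shift(tumor_shift),
           control = shift(muscle_shift)))
  }
  feats <- list(CLEAN = mk(5, 0), NOISY = mk(5, 10))  # 10 SD muscle shift
  tab <- make_feature_table(feats, cohort)
  nf <- noise_control_filter(tab, cohort, alpha = 0.05)
  expect_false(nf$excluded[nf$feature == "CLEAN"])
  expect_true(nf$excluded[nf$feature == "NOISY"])

  nf0 <- noise_control_filter(tab, cohort, alpha = 0)
  expect_false(any(nf0$excluded))

  # missing muscle rows are reported by patient
  broken <- tab[!(tab$patient_id == "P03" & tab$role == "control"), ]
  expect_error(noise_control_filter(broken, cohort), "P03")
})

test_that("null muscle features are excluded at about the alpha rate", {
  cohort <- toy_cohort()
  set.seed(47)
  n_feat <- 200
  alpha <- 0.05
  hits <- logical(n_feat)
  for (i in seq_len(n_feat)) {
    v <- rnorm(15)
    feats <- list(F = list(obs1 = list(axial = v, coronal = v, control = v),
                           obs2 = list(axial = v, coronal = v, control = v)))
    names(feats) <- "F1"
    tab <- make_feature_table(feats, cohort)
    hits[i] <- noise_control_filter(tab, cohort, alpha = alpha)$excluded
  }
  # identical VOIs across observers: exclusion rate ~ P(p <= .05) ~ 4%;
  # binomial 99% bounds around alpha for 200 draws
  expect_gt(mean(hits), alpha - 2.58 * sqrt(alpha * (1 - alpha) / n_feat))
  expect_lt(mean(hits), alpha + 2.58 * sqrt(alpha * (1 - alpha) / n_feat))
})

test_that("dual-observer intersection respects the boundary and monotonicity", {
  p1 <- c(A = 0.04, B = 0.05, C = 0.2)
  p2 <- c(A = 0.06, B = 0.05, C = 0.01)
  rep05 <- dual_set_intersection(p1, p2, alpha = 0.05)
  expect_false(rep05$selected[rep05$feature == "A"])  # 0.06 fails
  expect_true(rep05$selected[rep05$feature == "B"])   # boundary counts
  expect_false(rep05$selected[rep05$feature == "C"])

  # monotone in alpha
  set.seed(53)
  pa <- stats::setNames(runif(20), paste0("f", 1:20))
  pb <- stats::setNames(runif(20), paste0("f", 1:20))
  alphas <- sort(runif(5))
  prev <- character(0)
  for (a in alphas) {
    cur <- with(dual_set_intersection(pa, pb, alpha = a), feature[selected])
    expect_true(all(prev %in% cur))
    prev <- cur
  }

  # noise exclusion wins over significance
  repx <- dual_set_intersection(p1, p2, alpha = 0.5, noise_excluded = "C")
  expect_false(repx$selected[repx$feature == "C"])

  expect_error(dual_set_intersection(p1, p2[1:2]), "different features")
})

test_that("select_features ties the pieces together on constructed data", {
  cohort <- toy_cohort()
  set.seed(59)
  mk <- function(tumor_shift, muscle_shift = 0) {
    lapply(stats::setNames(c("obs1", "obs2"), c("obs1", "obs2")), function(o)
      list(axial = c(rnorm(8), rnorm(7) + tumor_shift),
           coronal = c(rnorm(8), rnorm(7) + tumor_shift),
           control = c(rnorm(8), rnorm(7) + muscle_shift)))
  }
  feats <- list(STRONG = mk(8), NULLF = mk(0), TAINTED = mk(8, 12))
  tab <- make_feature_table(feats, cohort)
  sel <- select_features(tab, cohort, alpha = 0.05)
  rep <- sel$report
  expect_true(rep$selected[rep$feature == "STRONG"])
  expect_false(rep$selected[rep$feature == "NULLF"])
  expect_false(rep$selected[rep$feature == "TAINTED"])
  expect_true(rep$noise_excluded[rep$feature == "TAINTED"])
  expect_named(sel$roc["STRONG"], "STRONG")
  expect_gte(sel$roc$STRONG$obs1$auc, 0.9)

  # alpha = 1: everything not noise-excluded is selected
  sel1 <- select_features(tab, cohort, alpha = 1)
  expect_true(all(sel1$report$selected[!sel1$report$noise_excluded]))
})
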
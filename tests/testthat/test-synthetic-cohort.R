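# a reduced grid keeps phantom mechanics tests quick; the statistical
# recovery suites run at the default 96^3 study conditions elsewhere
small_config <- function(seed = 1, ...) {
  cohort_config(grid_dim = c(64, 64, 64), lesion_radii_mm = c(6, 8),
                rim_thickness_mm = 5, seed = seed, ...)
}

test_that("phantom generation is bit-stable per (seed, patient)", {
  cfg <- small_config(seed = 9)
  p1 <- generate_phantom(cfg, 3, "short")
  p2 <- generate_phantom(cfg, 3, "short")
  expect_identical(p1$volume$intensities, p2$volume$intensities)
  expect_identical(p1$lesion, p2$lesion)
  p3 <- generate_phantom(cfg, 4, "short")
  expect_false(identical(p1$volume$intensities, p3$volume$intensities))
})

test_that("rim density offset is recoverable from the phantoms", {
  cfg <- small_config(seed = 17)
  diffs <- replicate(6, {
    i <- sample.int(1000, 1)
    ph_l <- generate_phantom(cfg, i, "long")
    ph_s <- generate_phantom(cfg, i + 1000, "short")
    mean(ph_s$volume$intensities[ph_s$rim]) -
      mean(ph_l$volume$intensities[ph_l$rim])
  })
  expect_equal(mean(diffs), unname(cfg$rim_offset["short"]), tolerance = 0.05)

  # with the offset disabled the group difference is sampling noise around 0
  cfg0 <- small_config(seed = 18, rim_offset = c(long = 0, short = 0))
  diffs0 <- replicate(6, {
    i <- sample.int(1000, 1)
    ph_s <- generate_phantom(cfg0, i, "short")
    ph_l <- generate_phantom(cfg0, i + 1000, "long")
    mean(ph_s$volume$intensities[ph_s$rim]) -
      mean(ph_l$volume$intensities[ph_l$rim])
  })
  expect_lt(abs(mean(diffs0)), 5)
})

test_that("the muscle control sphere sees the configured noise variance", {
  cfg <- small_config(seed = 21)
  ph <- generate_phantom(cfg, 1, "long")
  ctl <- place_control_sphere(ph$muscle_seed, ph$volume,
                              diameter = cfg$diameter_mm)
  s <- voxelize_sphere(ph$volume, ctl)
  # the sphere mean includes the patient-level density offset (SD 8 HU)
  expect_lt(abs(mean(s$intensities) - cfg$muscle_mean),
            4 * cfg$muscle_patient_sd)
  # the within-sphere variance is the block's voxel-noise variance
  expect_equal(stats::var(s$intensities), cfg$muscle_sd^2, tolerance = 0.35)
})

test_that("muscle features are exchangeable between outcome groups", {
  cfg <- small_config(seed = 25)
  muscle_mean <- function(i, group) {
    ph <- generate_phantom(cfg, i, group)
    ctl <- place_control_sphere(ph$muscle_seed, ph$volume,
                                diameter = cfg$diameter_mm)
    mean(voxelize_sphere(ph$volume, ctl)$intensities)
  }
  long_vals <- vapply(1:12, muscle_mean, numeric(1), group = "long")
  short_vals <- vapply(13:24, muscle_mean, numeric(1), group = "short")
  ks <- suppressWarnings(stats::ks.test(long_vals, short_vals))
  expect_gt(ks$p.value, 0.01)
})

test_that("second-observer jitter respects its contract", {
  cfg <- small_config(seed = 33)
  ph <- generate_phantom(cfg, 1, "long")
  vois <- place_biopsy_spheres(ph$lesion, ph$volume,
                               diameter = cfg$diameter_mm)
  same <- simulate_second_observer(vois, 0, ph$volume, seed = 1)
  expect_equal(same$axial$center, vois$axial$center)
  expect_equal(same$coronal$center, vois$coronal$center)
  expect_identical(same$axial$observer, "obs2")

  jit <- simulate_second_observer(vois, 1, ph$volume, seed = 2)
  expect_true(all(abs(jit$axial$center - vois$axial$center) <= 1 + 1e-9))
  expect_identical(jit$axial$role, "axial")
  expect_equal(jit$axial$diameter, vois$axial$diameter)

  expect_error(simulate_second_observer(vois, 500, ph$volume, seed = 3),
               "10 attempts")
})

test_that("generated cohorts have the study's group structure", {
  cfg <- small_config(seed = 77)
  b1 <- generate_cohort(cfg, keep_volumes = FALSE)
  expect_equal(nrow(b1$cohort), 15)
  expect_equal(as.integer(table(b1$cohort$group)), c(8, 7))
  expect_true(all(b1$cohort$event[b1$cohort$group == "short"] == 1))
  expect_true(all(b1$cohort$event[b1$cohort$group == "long"] == 0))
  expect_true(all(b1$cohort$survival_months[b1$cohort$group == "short"] <= 24))
  expect_true(all(b1$cohort$survival_months[b1$cohort$group == "long"] > 60))

  # short group carries the pro-inflammatory IHC profile for both markers
  sc <- function(m) tapply(staining_score(b1$cohort[[paste0(m, "_percent")]],
                                          b1$cohort[[paste0(m, "_intensity")]]),
                           b1$cohort$group, mean)
  expect_gt(sc("cd68")["short"], sc("cd68")["long"])
  expect_gt(sc("il1b")["short"], sc("il1b")["long"])

  # same master seed -> identical tables; VOIs straddle the lesion boundary
  b2 <- generate_cohort(cfg, keep_volumes = FALSE)
  expect_identical(b1$cohort, b2$cohort)
  frac <- mean(b1$patients[[1]]$phantom$lesion[
    voxelize_sphere(generate_phantom(cfg, 1, "long")$volume,
                    b1$patients[[1]]$vois$obs1$axial)$indices1])
  expect_gt(frac, 0); expect_lt(frac, 1)
})

test_that("observer jitter moves features less than the group effect", {
  # averaged over seeds: per-cohort, per-feature mean |obs1 - obs2| versus
  # the long/short group contrast (the robustness premise of the dual-
  # observer design)
  seeds <- 1:6
  js <- ge <- matrix(0, 6, length(seeds),
                     dimnames = list(core_feature_ids(), NULL))
  for (k in seq_along(seeds)) {
    tab <- cohort_feature_table(cohort_config(seed = seeds[k]))
    tf <- tab$features[tab$features$role != "control", ]
    agg <- aggregate(tf[core_feature_ids()],
                     by = list(pid = tf$patient_id, obs = tf$observer), mean)
    o1 <- agg[agg$obs == "obs1", ]; o2 <- agg[agg$obs == "obs2", ]
    o2 <- o2[match(o1$pid, o2$pid), ]
    grp <- tab$cohort$group[match(o1$pid, tab$cohort$patient_id)]
    for (f in core_feature_ids()) {
      js[f, k] <- mean(abs(o1[[f]] - o2[[f]]))
      ge[f, k] <- abs(mean(o1[[f]][grp == "long"]) -
                      mean(o1[[f]][grp == "short"]))
    }
  }
  for (f in core_feature_ids())
    expect_lt(mean(js[f, ]), mean(ge[f, ]))
})

test_that("cohort directory layout round-trips through the readers", {
  cfg <- small_config(seed = 55, n_long = 2, n_short = 2)
  dir <- withr::local_tempdir()
  generate_cohort(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  cohort <- read_cohort_table(file.path(dir, "cohort.csv"))
  expect_equal(nrow(cohort), 4)
  v <- read_volume(file.path(dir, "patients", "P01", "volume.nii.gz"))
  m <- read_mask(file.path(dir, "patients", "P01", "lesion.nii.gz"), v)
  expect_identical(dim(v$intensities), c(64L, 64L, 64L))
  expect_true(any(m))
  vois <- read_voi_json(file.path(dir, "patients", "P01", "vois_obs1.json"))
  expect_equal(length(vois), 3)
})

test_that("cohort summaries reproduce printed-table percentages", {
  records <- data.frame(
    patient_id = seq_len(35),
    sex = rep(c("male", "female"), c(27, 8)),
    histology = rep(c("adenocarcinoma", "squamous"), c(20, 15)),
    age = c(seq(42, 84, length.out = 35)))
  s <- cohort_summary(records)
  cat_tab <- s$categorical
  expect_equal(cat_tab$percent[cat_tab$level == "adenocarcinoma"], 57.1)
  expect_equal(cat_tab$percent[cat_tab$level == "male"], 77.1)
  expect_equal(cat_tab$percent[cat_tab$level == "squamous"], 42.9)
  expect_equal(s$numeric$min[s$numeric$variable == "age"], 42)
  expect_equal(s$numeric$max[s$numeric$variable == "age"], 84)

  single <- cohort_summary(data.frame(patient_id = 1, sex = "female"))
  expect_equal(single$categorical$percent, 100)
})
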
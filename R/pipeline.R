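#' Pipeline configuration
#'
#' @param synthetic a [cohort_config] to simulate from, or `NULL` when reading
#'   an existing cohort directory.
#' @param input_dir cohort directory (layout of [generate_cohort]); ignored
#'   when `synthetic` is given.
#' @param alpha selection significance level, in (0, 1).
#' @param features a [feature_config].
#' @param diameter sampling-sphere diameter in mm.
#' @param noise_mode muscle-filter reading (see [noise_control_filter]).
#' @param out_dir optional output directory for reports.
#' @param seed master seed (overrides the synthetic config's seed).
#' @return A list of class `vb_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = cohort_config(), input_dir = NULL,
                            alpha = 0.05, features = feature_config(),
                            diameter = 10,
                            noise_mode = c("between-groups", "between-observers"),
                            out_dir = NULL, seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (diameter <= 0) stop("diameter must be > 0")
  if (is.null(synthetic) && is.null(input_dir))
    stop("either a synthetic cohort config or an input directory is required")
  if (!is.null(synthetic) && !is.null(seed)) synthetic$seed <- seed
  if (!is.null(synthetic)) synthetic$diameter_mm <- diameter
  structure(list(synthetic = synthetic, input_dir = input_dir, alpha = alpha,
                 features = features, diameter = diameter,
                 noise_mode = noise_mode, out_dir = out_dir,
                 seed = if (is.null(seed) && !is.null(synthetic))
                   synthetic$seed else seed),
            class = "vb_pipeline_config")
}

load_cohort_features <- function(input_dir, fconfig, diameter) {
  cohort <- read_cohort_table(file.path(input_dir, "cohort.csv"))
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$patient_id[i]
    pdir <- file.path(input_dir, "patients", id)
    volume <- read_volume(file.path(pdir, "volume.nii.gz"))
    lesion <- read_mask(file.path(pdir, "lesion.nii.gz"), volume)
    for (obs in c("obs1", "obs2")) {
      vpath <- file.path(pdir, paste0("vois_", obs, ".json"))
      if (file.exists(vpath)) {
        vois <- read_voi_json(vpath)
        names(vois) <- vapply(vois, `[[`, character(1), "role")
      } else {
        seed_cols <- c("muscle_z", "muscle_y", "muscle_x")
        if (!all(seed_cols %in% names(cohort)))
          stop("no VOI JSON for ", id, "/", obs,
               " and no muscle seed columns in cohort.csv to place spheres")
        vois <- place_biopsy_spheres(lesion, volume, diameter = diameter,
                                     observer = obs)
        vois$control <- place_control_sphere(
          unlist(cohort[i, seed_cols]), volume, diameter = diameter,
          observer = obs, axial_sphere = vois$axial)
      }
      for (role in names(vois)) {
        fv <- extract_feature_vector(volume, vois[[role]], fconfig)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(patient_id = id, observer = obs, role = role,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
      }
    }
  }
  list(features = do.call(rbind, rows), cohort = cohort)
}

#' Run the virtual-biopsy pipeline end to end
#'
#' Stages, in fixed order: simulate (or load) the cohort; extract the feature
#' vector of every patient x observer x VOI; apply the muscle-sphere noise
#' filter; dual-observer Mann-Whitney intersection selection with ROC/Youden
#' characterization; Kaplan-Meier survival and IHC staining-score analyses.
#' Each stage logs its in/out counts; any failure aborts with the stage name.
#'
#' @param config a [pipeline_config].
#' @param quiet suppress stage logging.
#' @return A list of class `vb_report`: `features`, `cohort`, `selection`,
#'   `survival`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[virtualbiopsy] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("stage extract: building feature table")
  tab <- stage("extract", {
    if (!is.null(config$synthetic))
      cohort_feature_table(config$synthetic, config$features)
    else
      load_cohort_features(config$input_dir, config$features, config$diameter)
  })
  say(sprintf("  %d patients -> %d feature vectors x %d features",
              nrow(tab$cohort), nrow(tab$features),
              length(setdiff(names(tab$features),
                             c("patient_id", "observer", "role")))))

  say("stage select: noise filter + dual-observer selection at alpha = ",
      config$alpha)
  selection <- stage("select",
    select_features(tab$features, tab$cohort, alpha = config$alpha,
                    noise_mode = config$noise_mode))
  say(sprintf("  %d candidates, %d noise-excluded, %d selected",
              nrow(selection$report), sum(selection$report$noise_excluded),
              sum(selection$report$selected)))

  say("stage survive: Kaplan-Meier + IHC comparison")
  surv <- stage("survive", survival_ihc_analysis(tab$cohort))

  summary <- stage("summary", cohort_summary(tab$cohort))

  manifest <- list(
    package = "virtualbiopsy",
    version = as.character(utils::packageVersion("virtualbiopsy")),
    seed = config$seed,
    alpha = config$alpha,
    noise_mode = config$noise_mode,
    bin_width = config$features$bin_width,
    lower_bound = config$features$lower_bound,
    diameter_mm = config$diameter,
    n_patients = nrow(tab$cohort),
    n_feature_vectors = nrow(tab$features),
    synthetic = !is.null(config$synthetic),
    config = if (!is.null(config$synthetic))
      unclass(config$synthetic) else list(input_dir = config$input_dir)
  )

  report <- structure(
    list(features = tab$features, cohort = tab$cohort, selection = selection,
         survival = surv, summary = summary, manifest = manifest),
    class = "vb_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    utils::write.csv(tab$features, file.path(od, "features.csv"),
                     row.names = FALSE)
    write_selection_report(selection,
                           json_path = file.path(od, "selection.json"),
                           csv_path = file.path(od, "selection.csv"))
    km_tab <- do.call(rbind, lapply(names(surv$km_group), function(g)
      cbind(group = g, surv$km_group[[g]]$table)))
    utils::write.csv(km_tab, file.path(od, "km_groups.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    say("reports written to ", od)
  }
  report
}

#' @export
print.vb_report <- function(x, ...) {
  cat(sprintf("<vb_report> %d patients, %d feature vectors\n",
              nrow(x$cohort), nrow(x$features)))
  print(x$selection)
  os <- x$survival$os5yr_pct
  cat(sprintf("5-year OS: long %.1f%%, short %.1f%% (log-rank p = %.3g)\n",
              os[["long"]], os[["short"]], x$survival$logrank$p))
  invisible(x)
}
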
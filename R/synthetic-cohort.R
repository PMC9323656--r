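#' Synthetic cohort configuration
#'
#' Defines the study conditions emulated by the phantom generator: a lung-window
#' CT grid holding an ellipsoidal soft-tissue lesion, a peritumoral rim whose
#' mean density (HU offset) and run-length texture (fragmentation probability)
#' depend on the outcome group, a homogeneous muscle block whose statistics are
#' group-independent, two observers related by small placement jitter, and
#' survival/IHC distributions that separate at 24 versus >60 months.
#'
#' The group effect is encoded where the biology suggests: the denser,
#' inflammation-infiltrated rim of poor-outcome patients raises the intensity
#' features and the GLCM autocorrelation, while spatially fragmenting the rim
#' texture lowers the run concentration seen by GLRLM gray-level
#' non-uniformity.
#'
#' @param n_long,n_short group sizes (defaults 8 and 7).
#' @param grid_dim grid shape (z, y, x) in voxels.
#' @param spacing voxel spacing (dz, dy, dx) in mm.
#' @param lung_mean,lung_sd background lung parenchyma HU.
#' @param lesion_mean,lesion_sd soft-tissue lesion HU.
#' @param lesion_radii_mm range the per-patient ellipsoid semi-axes are drawn
#'   from (uniform), in mm.
#' @param rim_thickness_mm peritumoral rim shell thickness.
#' @param rim_mean,rim_sd rim HU before the group offset.
#' @param rim_offset named group offsets added to the rim mean (HU).
#' @param rim_fragmentation named per-group probability that a rim voxel's
#'   value is re-drawn independently, breaking the smooth rim texture.
#' @param muscle_mean,muscle_sd homogeneous muscle block HU
#'   (group-independent).
#' @param muscle_patient_sd SD of the per-patient muscle density offset (HU),
#'   modelling inter-patient variability in muscle attenuation; group-
#'   independent.
#' @param jitter_voxels maximum per-axis displacement of the second observer's
#'   sphere centres, in voxels.
#' @param diameter_mm sampling-sphere diameter.
#' @param survival_short_months,survival_long_censor_months uniform ranges for
#'   the short group's event times and the long group's censoring times.
#' @param seed master seed; every random draw derives from it.
#' @return A list of class `vb_cohort_config`.
#' @export
cohort_config <- function(n_long = 8, n_short = 7,
                          grid_dim = c(96, 96, 96), spacing = c(1, 1, 1),
                          lung_mean = -800, lung_sd = 50,
                          lesion_mean = 30, lesion_sd = 30,
                          lesion_radii_mm = c(8, 11),
                          rim_thickness_mm = 7,
                          rim_mean = -420, rim_sd = 30,
                          rim_offset = c(long = 0, short = 500),
                          rim_fragmentation = c(long = 0, short = 0.7),
                          muscle_mean = 50, muscle_sd = 15,
                          muscle_patient_sd = 8,
                          jitter_voxels = 1, diameter_mm = 10,
                          survival_short_months = c(6, 24),
                          survival_long_censor_months = c(61, 72),
                          seed = 1) {
  stopifnot(n_long >= 1, n_short >= 1, all(spacing > 0),
            rim_thickness_mm > 0, lung_sd >= 0, lesion_sd >= 0,
            rim_sd >= 0, muscle_sd >= 0, jitter_voxels >= 0)
  structure(as.list(environment()), class = "vb_cohort_config")
}

# derive a per-patient, per-purpose 32-bit seed from the master seed
derive_seed <- function(master, i, purpose = 0L) {
  as.integer((as.numeric(master) * 100003 + i * 7919 + purpose * 104729) %%
               2147483647)
}

# separable 3x3x3 box smoothing with edge replication; rescaled to keep an
# approximately unit-variance field away from the edges
smooth3 <- function(arr) {
  for (axis in 1:3) {
    d <- dim(arr)
    n <- d[axis]
    if (n < 2) next
    idx <- function(shift) pmin(pmax(seq_len(n) + shift, 1L), n)
    pick <- function(sh) {
      ii <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ii[[axis]] <- idx(sh)
      arr[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
    }
    arr <- (pick(-1L) + pick(0L) + pick(1L)) / 3
  }
  arr * sqrt(27)
}

#' Generate one synthetic CT phantom
#'
#' Deterministic per `(config$seed, patient_index)`: a lung-density background,
#' an ellipsoidal lesion at the grid centre, a peritumoral rim shell with the
#' patient's group-specific density offset and texture fragmentation, and a
#' homogeneous muscle slab near the x-low edge of the grid. HU values are
#' rounded to integers, as a CT export would store them.
#'
#' @param config a [cohort_config].
#' @param patient_index integer (drives the derived seed).
#' @param group `"long"` or `"short"`.
#' @return A list: `volume` ([vb_volume]), `lesion` (logical mask),
#'   `muscle_seed` (world mm, z/y/x), `lesion_radii_mm`.
#' @export
generate_phantom <- function(config, patient_index, group = c("long", "short")) {
  group <- match.arg(group)
  d <- config$grid_dim
  sp <- config$spacing
  set.seed(derive_seed(config$seed, patient_index, 1L))

  vol <- array(stats::rnorm(prod(d), config$lung_mean, config$lung_sd), dim = d)

  # world coordinates of voxel centres along each axis (origin at 0)
  zc <- (seq_len(d[1]) - 1) * sp[1]
  yc <- (seq_len(d[2]) - 1) * sp[2]
  xc <- (seq_len(d[3]) - 1) * sp[3]
  center <- c(mean(range(zc)), mean(range(yc)), mean(range(xc)))

  radii <- stats::runif(3, config$lesion_radii_mm[1], config$lesion_radii_mm[2])
  outer_radii <- radii + config$rim_thickness_mm
  if (any(center - outer_radii < 0) || any(center + outer_radii >
                                           c(max(zc), max(yc), max(xc))))
    stop("lesion plus rim exceed the grid; enlarge grid_dim or shrink the lesion")

  # ellipsoid membership evaluated on the enclosing bounding box only and
  # re-embedded (pure arithmetic, no RNG involved)
  bz <- which(abs(zc - center[1]) <= outer_radii[1])
  by <- which(abs(yc - center[2]) <= outer_radii[2])
  bx <- which(abs(xc - center[3]) <= outer_radii[3])
  ell <- function(r) {
    sub <- outer(outer(((zc[bz] - center[1]) / r[1])^2,
                       ((yc[by] - center[2]) / r[2])^2, `+`),
                 ((xc[bx] - center[3]) / r[3])^2, `+`) <= 1
    full <- array(FALSE, dim = d)
    full[bz, by, bx] <- sub
    full
  }
  lesion <- ell(radii)
  rim <- ell(outer_radii) & !lesion

  vol[lesion] <- stats::rnorm(sum(lesion), config$lesion_mean, config$lesion_sd)

  # spatially smooth rim field (long coherent runs), then fragment a
  # group-dependent fraction of voxels with independent re-draws
  rim_idx <- which(rim, arr.ind = TRUE)
  blo <- apply(rim_idx, 2, min); bhi <- apply(rim_idx, 2, max)
  noise <- smooth3(smooth3(array(stats::rnorm(prod(bhi - blo + 1)),
                                 dim = bhi - blo + 1)))
  noise <- noise / stats::sd(noise)  # unit marginal variance after smoothing
  rim_mu <- config$rim_mean + config$rim_offset[[group]]
  local_idx <- sweep(rim_idx, 2, blo - 1L)
  vol[rim] <- rim_mu + config$rim_sd * noise[local_idx]
  n_rim <- nrow(rim_idx)
  n_frag <- round(config$rim_fragmentation[[group]] * n_rim)
  if (n_frag > 0) {
    frag <- sample.int(n_rim, n_frag)
    vol[rim_idx[frag, , drop = FALSE]] <-
      stats::rnorm(n_frag, rim_mu, config$rim_sd)
  }

  # muscle slab along the x-low edge (chest-wall analogue), full z extent.
  # One smoothing pass emulates the spatial noise correlation a reconstruction
  # kernel leaves in homogeneous soft tissue; the per-patient density offset
  # models inter-patient variability in muscle attenuation (myosteatosis),
  # which dominates the between-patient spread of muscle-sphere statistics
  # exactly as it does on real CT
  xr <- xc >= 0.06 * max(xc) & xc < 0.27 * max(xc)
  yr <- yc >= 0.25 * max(yc) & yc <= 0.75 * max(yc)
  mus <- smooth3(array(stats::rnorm(d[1] * sum(yr) * sum(xr)),
                       dim = c(d[1], sum(yr), sum(xr))))
  mus <- mus / stats::sd(mus)
  patient_offset <- stats::rnorm(1, 0, config$muscle_patient_sd)
  vol[, yr, xr] <- config$muscle_mean + patient_offset +
    config$muscle_sd * mus
  muscle_seed <- c(center[1], mean(yc[yr]), mean(xc[xr]))

  volume <- vb_volume(round(vol), spacing = sp, origin = c(0, 0, 0))
  list(volume = volume, lesion = lesion, rim = rim,
       muscle_seed = muscle_seed, lesion_radii_mm = radii)
}

#' Jitter an observer's sphere placements
#'
#' Displaces each sphere centre by an independent uniform integer offset of at
#' most `jitter_voxels` voxels per axis, emulating a second observer repeating
#' the placement; roles and diameters are unchanged. A sphere jittered off the
#' grid is re-drawn up to 10 times before erroring.
#'
#' @param vois list of [vb_sphere] objects.
#' @param jitter_voxels maximum per-axis displacement (voxels, >= 0).
#' @param volume the [vb_volume] the spheres live on.
#' @param seed integer seed.
#' @param observer observer id recorded on the jittered spheres.
#' @return A list of jittered [vb_sphere] objects (same names).
#' @export
simulate_second_observer <- function(vois, jitter_voxels, volume, seed,
                                     observer = "obs2") {
  set.seed(as.integer(seed))
  d <- dim(volume$intensities)
  jitter_one <- function(voi) {
    if (jitter_voxels == 0)
      return(vb_sphere(voi$center, voi$diameter, voi$role, observer))
    for (try in 1:10) {
      off <- sample(seq(-jitter_voxels, jitter_voxels), 3, replace = TRUE)
      center <- voi$center + off * volume$spacing
      idx0 <- world_to_index0(volume, center)
      r <- voi$diameter / 2
      inside <- if (voi$role == "control") {
        all(world_to_index0(volume, center - r) >= -0.5) &&
          all(world_to_index0(volume, center + r) <= d - 0.5)
      } else {
        all(idx0 >= -0.5) && all(idx0 <= d - 0.5)
      }
      if (inside)
        return(vb_sphere(center, voi$diameter, voi$role, observer))
    }
    stop("could not jitter the ", voi$role,
         " sphere onto the grid after 10 attempts")
  }
  lapply(vois, jitter_one)
}

generate_patient <- function(config, i) {
  group <- if (i <= config$n_long) "long" else "short"
  id <- sprintf("P%02d", i)
  ph <- generate_phantom(config, i, group)
  obs1 <- place_biopsy_spheres(ph$lesion, ph$volume,
                               diameter = config$diameter_mm,
                               observer = "obs1")
  obs1$control <- place_control_sphere(ph$muscle_seed, ph$volume,
                                       diameter = config$diameter_mm,
                                       observer = "obs1",
                                       axial_sphere = obs1$axial)
  obs2 <- simulate_second_observer(obs1, config$jitter_voxels, ph$volume,
                                   seed = derive_seed(config$seed, i, 2L),
                                   observer = "obs2")

  set.seed(derive_seed(config$seed, i, 3L))
  if (group == "short") {
    months <- stats::runif(1, config$survival_short_months[1],
                           config$survival_short_months[2])
    event <- 1L
    cd68_percent <- stats::runif(1, 55, 95)
    cd68_intensity <- sample(2:3, 1)
    il1b_percent <- stats::runif(1, 50, 90)
    il1b_intensity <- sample(2:3, 1)
  } else {
    months <- stats::runif(1, config$survival_long_censor_months[1],
                           config$survival_long_censor_months[2])
    event <- 0L
    cd68_percent <- stats::runif(1, 0, 20)
    cd68_intensity <- sample(0:2, 1, prob = c(0.3, 0.5, 0.2))
    il1b_percent <- stats::runif(1, 0, 20)
    il1b_intensity <- sample(0:2, 1, prob = c(0.3, 0.5, 0.2))
  }
  record <- data.frame(
    patient_id = id, group = group,
    survival_months = round(months, 1), event = event,
    cd68_percent = round(cd68_percent, 1), cd68_intensity = cd68_intensity,
    il1b_percent = round(il1b_percent, 1), il1b_intensity = il1b_intensity,
    stringsAsFactors = FALSE)
  list(id = id, group = group, phantom = ph,
       vois = list(obs1 = obs1, obs2 = obs2), record = record)
}

#' Generate a full synthetic cohort
#'
#' `n_long + n_short` patients with phantoms, dual-observer sphere placements,
#' survival and IHC tables. With `dir` set, a directory layout consumable by
#' [run_pipeline] is written: per-patient NIfTI volume and lesion mask, VOI
#' JSONs per observer, `cohort.csv` and `config.json`. Two runs with the same
#' master seed produce identical output.
#'
#' @param config a [cohort_config].
#' @param dir optional output directory.
#' @param keep_volumes keep the phantom volumes in the returned bundle
#'   (default: only when not writing to disk).
#' @return A list of class `vb_cohort`: `config`, `cohort` (validated table),
#'   `patients` (per-patient phantoms and VOIs).
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL,
                            keep_volumes = is.null(dir)) {
  n <- config$n_long + config$n_short
  patients <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    p <- generate_patient(config, i)
    records[[i]] <- p$record
    if (!is.null(dir)) {
      pdir <- file.path(dir, "patients", p$id)
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      write_volume(p$phantom$volume, file.path(pdir, "volume.nii.gz"))
      write_volume(p$phantom$lesion, file.path(pdir, "lesion.nii.gz"),
                   geometry_from = p$phantom$volume)
      write_voi_json(p$vois$obs1, file.path(pdir, "vois_obs1.json"))
      write_voi_json(p$vois$obs2, file.path(pdir, "vois_obs2.json"))
    }
    if (!keep_volumes) p$phantom$volume <- NULL
    patients[[i]] <- p
  }
  cohort <- validate_cohort_table(do.call(rbind, records))
  if (!is.null(dir)) {
    utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(config = config, cohort = cohort, patients = patients),
            class = "vb_cohort")
}

#' Extract the cohort feature table, one patient at a time
#'
#' Generates (or takes) each patient, extracts the feature vector of all six
#' VOIs (2 observers x axial/coronal/control) and discards the phantom volume
#' before moving on, keeping memory flat. This is the path the pipeline and
#' the simulation studies use.
#'
#' @param config a [cohort_config].
#' @param fconfig a [feature_config].
#' @return A list: `features` (data.frame, one row per patient x observer x
#'   VOI role), `cohort` (cohort table).
#' @export
cohort_feature_table <- function(config = cohort_config(),
                                 fconfig = feature_config()) {
  n <- config$n_long + config$n_short
  rows <- list()
  records <- vector("list", n)
  for (i in seq_len(n)) {
    p <- generate_patient(config, i)
    records[[i]] <- p$record
    for (obs in names(p$vois)) {
      for (role in names(p$vois[[obs]])) {
        fv <- extract_feature_vector(p$phantom$volume, p$vois[[obs]][[role]],
                                     fconfig)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(patient_id = p$id, observer = obs, role = role,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
      }
    }
  }
  list(features = do.call(rbind, rows),
       cohort = validate_cohort_table(do.call(rbind, records)))
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Descriptive cohort summary
#'
#' Counts and percentages (one decimal, half-up rounding) for categorical
#' fields, mean and range for continuous fields. A numeric column is treated
#' as continuous when it takes more than six distinct values (age, survival),
#' otherwise as categorical (event flags, scores).
#'
#' @param records a cohort-like data.frame; `patient_id` is ignored.
#' @return A list: `n`, `categorical` (variable, level, n, percent), `numeric`
#'   (variable, mean, min, max).
#' @export
cohort_summary <- function(records) {
  if (nrow(records) == 0L) stop("empty cohort")
  cols <- setdiff(names(records), "patient_id")
  cat_rows <- list(); num_rows <- list()
  for (col in cols) {
    v <- records[[col]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    if (is.numeric(v) && length(unique(v)) > 6L) {
      num_rows[[col]] <- data.frame(variable = col, mean = mean(v),
                                    min = min(v), max = max(v))
    } else {
      tab <- table(as.character(v))
      cat_rows[[col]] <- data.frame(
        variable = col, level = names(tab), n = as.integer(tab),
        percent = round_half_up(100 * as.integer(tab) / length(v), 1),
        row.names = NULL)
    }
  }
  list(n = nrow(records),
       categorical = if (length(cat_rows)) do.call(rbind, c(cat_rows, list(make.row.names = FALSE))) else NULL,
       numeric = if (length(num_rows)) do.call(rbind, c(num_rows, list(make.row.names = FALSE))) else NULL)
}
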
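#' Fixed-bin-size gray-level discretization
#'
#' Maps HU values to gray-level bins `floor((x - lower_bound) / bin_width) + 1`,
#' clamped to be at least 1 — the fixed-bin-size scheme recommended for CT.
#' Intensity features are always computed on raw HU; only the texture features
#' (GLCM, GLRLM) see the binned values.
#'
#' @param sample a `vb_sample` from [voxelize_sphere].
#' @param bin_width bin width in HU (> 0; default 25).
#' @param lower_bound lowest bin edge in HU (default -1000, air).
#' @return A `vb_discrete`: the sample plus per-voxel bin indices, a binned
#'   local array (`NA` outside the VOI) for adjacency-aware texture features,
#'   and `Ng`, the largest bin index present.
#' @export
discretize <- function(sample, bin_width = 25, lower_bound = -1000) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  bins <- pmax(1L, as.integer(floor((sample$intensities - lower_bound) / bin_width)) + 1L)
  bin_arr <- array(NA_integer_, dim = dim(sample$mask))
  bin_arr[which(sample$mask)] <- bins
  structure(list(sample = sample, bins = bins, bin_arr = bin_arr,
                 Ng = max(bins), bin_width = bin_width,
                 lower_bound = lower_bound),
            class = "vb_discrete")
}

#' Intensity-based features on raw HU values
#'
#' Computes the first-order features: intensity-based energy (sum of squared
#' HU values), maximum, median (mean of the middle two for even n), and the
#' 90th intensity percentile, defined as the lowest sample value strictly
#' greater than at least `ceiling(0.9 * N)` of the sample values (the maximum
#' when no value qualifies, e.g. a constant sample).
#'
#' @param sample a `vb_sample`.
#' @param extras character vector of optional extra feature ids among
#'   `"MEAN_HU"`, `"MIN_HU"`, `"IQR_HU"`.
#' @return Named numeric vector.
#' @export
intensity_features <- function(sample, extras = character(0)) {
  x <- sample$intensities
  if (length(x) == 0L) stop("empty voxel sample")
  out <- c(
    ENERGY_VOXELS = sum(x^2),
    MAX_HU = max(x),
    MEDIAN_VOXELS = stats::median(x),
    PERCENTILE_90_HU = percentile90(x)
  )
  for (f in extras) {
    out[[f]] <- switch(f,
      MEAN_HU = mean(x),
      MIN_HU = min(x),
      IQR_HU = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
      stop("unknown extra feature id: ", f))
  }
  out
}

percentile90 <- function(x) {
  n <- length(x)
  threshold <- ceiling(0.9 * n)
  u <- sort(unique(x))
  counts <- tabulate(match(x, u), nbins = length(u))
  below <- cumsum(c(0, counts[-length(counts)]))  # values strictly less than u[k]
  ok <- which(below >= threshold)
  if (length(ok) == 0L) max(x) else u[ok[1]]
}

# the 13 unique 3D offsets at Chebyshev distance 1 (up to sign)
glcm_directions_3d <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(0, 1, 1), c(0, 1, -1), c(1, 0, 1), c(1, 0, -1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

# gray-level values of all voxel pairs inside the mask at a given offset;
# returns a two-column matrix of ordered pairs (one orientation only)
offset_pairs <- function(bin_arr, off) {
  d <- dim(bin_arr)
  rng <- vector("list", 3)
  for (a in 1:3) {
    lo <- max(1, 1 - off[a]); hi <- min(d[a], d[a] - off[a])
    if (lo > hi) return(matrix(integer(0), ncol = 2))
    rng[[a]] <- lo:hi
  }
  a <- bin_arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- bin_arr[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  cbind(a[keep], b[keep])
}

#' GLCM autocorrelation, averaged over the 13 3D directions
#'
#' For each 3D direction at Chebyshev distance 1, the co-occurrence matrix over
#' voxel pairs lying wholly inside the VOI is formed, symmetrized and
#' normalized to probabilities, and the autocorrelation
#' \eqn{\sum_i \sum_j i\, j\, p(i,j)} is computed; the feature is the mean over
#' directions that contribute at least one pair (empty directions are excluded
#' from the average rather than diluting it).
#'
#' @param d a `vb_discrete` from [discretize].
#' @param per_direction return the per-direction values instead of their mean.
#' @return A single value (or a 13-vector with `NA` for empty directions).
#' @export
glcm_autocorrelation <- function(d, per_direction = FALSE) {
  dirs <- glcm_directions_3d()
  vals <- rep(NA_real_, nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    pr <- offset_pairs(d$bin_arr, dirs[k, ])
    if (nrow(pr) > 0L) {
      # i*j is symmetric, so the symmetrized normalized matrix gives the
      # same expectation as the mean over one orientation of each pair
      vals[k] <- mean(as.numeric(pr[, 1]) * as.numeric(pr[, 2]))
    }
  }
  if (per_direction) return(vals)
  if (all(is.na(vals)))
    stop("no direction has a co-occurring voxel pair (sample too fragmented)")
  mean(vals, na.rm = TRUE)
}

# cache of per-(nrow, ncol, direction) line-scan templates
.vb_line_cache <- new.env(parent = emptyenv())

# indices that read a 2D slice line by line along a direction, with the
# out-of-range index n+1 inserted between lines so that runs cannot span them
glrlm_line_template <- function(nr, nc, direction) {
  key <- paste(nr, nc, direction, sep = ",")
  tpl <- .vb_line_cache[[key]]
  if (!is.null(tpl)) return(tpl)
  n <- nr * nc
  cells <- seq_len(n)
  rowi <- (cells - 1L) %% nr + 1L
  colj <- (cells - 1L) %/% nr + 1L
  line_key <- switch(direction,
    "0" = rowi, "90" = colj, "45" = colj - rowi, "135" = colj + rowi,
    stop("direction must be one of 0, 45, 90, 135"))
  ord <- order(line_key, if (direction == "0") colj else rowi)
  ks <- line_key[ord]
  newline <- c(FALSE, ks[-1] != ks[-n])
  tpl <- rep.int(n + 1L, n + sum(newline))
  tpl[seq_len(n) + cumsum(newline)] <- cells[ord]
  .vb_line_cache[[key]] <- tpl
  tpl
}

# run gray levels of a masked slice (NA = outside VOI) along one direction;
# rle treats each NA as unequal to everything, so runs break at mask gaps
# and at the inter-line separators
slice_run_levels <- function(slice, direction) {
  tpl <- glrlm_line_template(nrow(slice), ncol(slice), direction)
  v <- c(slice, NA_integer_)[tpl]
  r <- rle(v)
  r$values[!is.na(r$values)]
}

#' GLRLM gray-level non-uniformity, averaged over 2D directions and slices
#'
#' For every axial slice intersecting the VOI and each of the four in-plane
#' directions (0, 45, 90, 135 degrees), runs are the maximal collinear
#' segments of equal gray level lying entirely inside the VOI mask; with
#' \eqn{r(i,j)} counting runs of level i and length j, the per-matrix value is
#' \eqn{\sum_i (\sum_j r(i,j))^2 / N_{runs}}. The feature is the mean over all
#' (slice, direction) matrices with at least one run.
#'
#' @param d a `vb_discrete`.
#' @param per_matrix return a data.frame of per-(slice, direction) values.
#' @return A single value (or a data.frame with columns `slice`, `direction`,
#'   `gln`, `n_runs`).
#' @export
glrlm_gln <- function(d, per_matrix = FALSE) {
  arr <- d$bin_arr
  nz <- dim(arr)[1]
  slice_id <- integer(0); dir_id <- character(0)
  gln <- numeric(0); nrun <- integer(0)
  for (z in seq_len(nz)) {
    slice <- matrix(arr[z, , ], nrow = dim(arr)[2])
    if (all(is.na(slice))) next
    for (dir in c("0", "45", "90", "135")) {
      lev <- slice_run_levels(slice, dir)
      if (length(lev) == 0L) next
      counts <- tabulate(lev, nbins = d$Ng)
      slice_id <- c(slice_id, z); dir_id <- c(dir_id, dir)
      gln <- c(gln, sum(as.numeric(counts)^2) / length(lev))
      nrun <- c(nrun, length(lev))
    }
  }
  if (length(gln) == 0L) stop("sample intersects no axial slice")
  if (per_matrix)
    data.frame(slice = slice_id, direction = dir_id, gln = gln, n_runs = nrun)
  else mean(gln)
}

#' Feature extraction configuration
#'
#' @param bin_width,lower_bound discretization settings in HU (see
#'   [discretize]).
#' @param extras extra intensity feature ids (see [intensity_features]).
#' @return A list of class `vb_feature_config`.
#' @export
feature_config <- function(bin_width = 25, lower_bound = -1000,
                           extras = c("MEAN_HU", "MIN_HU", "IQR_HU")) {
  structure(list(bin_width = bin_width, lower_bound = lower_bound,
                 extras = extras),
            class = "vb_feature_config")
}

#' Required feature ids
#' @return Character vector of the six always-computed feature ids.
#' @export
core_feature_ids <- function() {
  c("ENERGY_VOXELS", "MAX_HU", "MEDIAN_VOXELS", "PERCENTILE_90_HU",
    "GLCM_AUTOCORR_3DF", "GLRLM_GLNONUNIFORMITY_2DF")
}

#' Extract the feature vector of one VOI
#'
#' Voxelizes the sphere, computes the intensity features on raw HU, discretizes
#' per the configuration and computes the two texture features on the bin
#' indices. Texture values are reported on the bin scale (a label choice, not
#' a unit conversion: autocorrelation in raw HU squared would be ill-defined
#' with negative HU).
#'
#' @param volume a [vb_volume].
#' @param voi a [vb_sphere].
#' @param config a [feature_config].
#' @return Named numeric vector with a `provenance` attribute recording the
#'   VOI role/observer, sphere geometry and discretization settings.
#' @export
extract_feature_vector <- function(volume, voi, config = feature_config()) {
  s <- voxelize_sphere(volume, voi)
  disc <- discretize(s, config$bin_width, config$lower_bound)
  intens <- intensity_features(s, extras = config$extras)
  fv <- c(
    intens[c("ENERGY_VOXELS", "MAX_HU", "MEDIAN_VOXELS", "PERCENTILE_90_HU")],
    GLCM_AUTOCORR_3DF = glcm_autocorrelation(disc),
    GLRLM_GLNONUNIFORMITY_2DF = glrlm_gln(disc)
  )
  if (length(config$extras) > 0)
    fv <- c(fv, intens[config$extras])
  if (!all(is.finite(fv))) stop("non-finite feature value computed")
  attr(fv, "provenance") <- list(
    role = voi$role, observer = voi$observer,
    center_mm = voi$center, diameter_mm = voi$diameter,
    n_voxels = nrow(s$indices1),
    bin_width = config$bin_width, lower_bound = config$lower_bound)
  fv
}
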
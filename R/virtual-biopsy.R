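#' Sampling-sphere VOI
#'
#' A "virtual biopsy" volume of interest: a sphere of fixed diameter (10 mm by
#' default) in world coordinates. Biopsy spheres are centred on the lesion
#' boundary so that they straddle tumor and peritumoral tissue; the control
#' sphere sits in homogeneous muscle and carries no outcome signal.
#'
#' @param center world coordinates (mm) of the sphere centre, (z, y, x) order.
#' @param diameter sphere diameter in mm (default 10, i.e. 1 cm).
#' @param role one of `"axial"`, `"coronal"`, `"control"`.
#' @param observer observer identifier (e.g. `"obs1"`).
#' @return An object of class `vb_sphere`.
#' @export
vb_sphere <- function(center, diameter = 10, role, observer = "obs1") {
  role <- match.arg(role, c("axial", "coronal", "control"))
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0)
    stop("diameter must be a positive scalar (mm)")
  if (length(center) != 3L) stop("center must be (z, y, x) in mm")
  structure(list(center = as.numeric(center), diameter = diameter,
                 role = role, observer = as.character(observer)),
            class = "vb_sphere")
}

#' @export
print.vb_sphere <- function(x, ...) {
  cat(sprintf("<vb_sphere> %s/%s, %g mm diameter at (%.2f, %.2f, %.2f) mm\n",
              x$role, x$observer, x$diameter,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# 6-connectivity surface: foreground voxels with at least one background
# 6-neighbour; voxels beyond the grid edge count as background. Computed on
# the foreground bounding box (padded by one voxel) and re-embedded, so large
# mostly-empty grids cost little.
lesion_boundary <- function(mask) {
  d_full <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(array(FALSE, dim = d_full))
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, d_full)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  bsub <- lesion_boundary_dense(sub)
  out <- array(FALSE, dim = d_full)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- bsub
  out
}

lesion_boundary_dense <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_and <- function(m, axis, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by == 1L) { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    else { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    if (d[axis] == 1L) { interior[] <- FALSE; next }
    interior <- interior & shift_and(mask, axis, by)
  }
  mask & !interior
}

# pick the boundary voxel in a given plane closest (in mm) to the centroid of
# that plane's boundary points; ties broken by lowest (z,y,x) index
pick_anchor <- function(boundary_idx, spacing) {
  if (nrow(boundary_idx) == 0L) return(NULL)
  mm <- sweep(boundary_idx, 2, spacing, `*`)
  centroid <- colMeans(mm)
  d2 <- rowSums(sweep(mm, 2, centroid, `-`)^2)
  cand <- which(d2 <= min(d2) + 1e-9)
  ord <- order(boundary_idx[cand, 1], boundary_idx[cand, 2], boundary_idx[cand, 3])
  boundary_idx[cand[ord[1]], ]
}

#' Place the axial and coronal biopsy spheres on the lesion boundary
#'
#' Both spheres are centred on the tumor contour (6-connectivity surface
#' voxels of the lesion mask): the axial sphere in the axial slice through the
#' lesion centroid, the coronal sphere in the coronal plane through the
#' centroid. The default anchor is the boundary voxel of the plane nearest to
#' the centroid of that plane's boundary points (deterministic tie-break by
#' lowest (z,y,x) index); pass `anchor_axial`/`anchor_coronal` (world mm) to
#' override, mimicking a manually chosen contour point. Each returned sphere is
#' verified to contain both tumor and non-tumor voxels.
#'
#' @param lesion logical 3D lesion mask on the volume grid (see [read_mask]).
#' @param volume a [vb_volume].
#' @param diameter sphere diameter in mm.
#' @param observer observer identifier recorded in the VOIs.
#' @param anchor_axial,anchor_coronal optional world-coordinate overrides.
#' @return A list with elements `axial` and `coronal`, both [vb_sphere].
#' @export
place_biopsy_spheres <- function(lesion, volume, diameter = 10,
                                 observer = "obs1",
                                 anchor_axial = NULL, anchor_coronal = NULL) {
  lesion <- as_mask(lesion, volume)
  idx <- which(lesion, arr.ind = TRUE) - 1L  # 0-based (z,y,x)
  centroid <- colMeans(idx)
  boundary <- lesion_boundary(lesion)
  bidx <- which(boundary, arr.ind = TRUE) - 1L

  make_sphere <- function(role, override) {
    if (!is.null(override)) {
      return(vb_sphere(override, diameter, role, observer))
    }
    axis <- if (role == "axial") 1L else 2L
    plane <- round(centroid[axis])
    in_plane <- bidx[bidx[, axis] == plane, , drop = FALSE]
    if (nrow(in_plane) == 0L) {
      # centroid plane misses the boundary (can happen for 1-voxel-thick
      # lesions); fall back to the nearest populated plane
      nearest <- bidx[abs(bidx[, axis] - plane) == min(abs(bidx[, axis] - plane)),
                      , drop = FALSE]
      in_plane <- nearest[nearest[, axis] == nearest[1, axis], , drop = FALSE]
    }
    anchor <- pick_anchor(in_plane, volume$spacing)
    vb_sphere(index0_to_world(volume, anchor), diameter, role, observer)
  }

  axial <- make_sphere("axial", anchor_axial)
  coronal <- make_sphere("coronal", anchor_coronal)

  for (voi in list(axial, coronal)) {
    s <- voxelize_sphere(volume, voi)
    inside <- lesion[s$indices1]
    if (!any(inside) || all(inside))
      stop("the ", voi$role, " biopsy sphere does not straddle the lesion ",
           "boundary (lesion too small or too close to the grid edge); ",
           "review the mask or reduce the sphere diameter")
  }
  list(axial = axial, coronal = coronal)
}

#' Place the muscle control sphere
#'
#' The control sphere is centred at a user-supplied seed point inside muscle
#' tissue, on the same axial slice as the observer's axial biopsy sphere: when
#' the seed lies on a different slice its z coordinate is replaced by the
#' axial sphere's z and a note is emitted.
#'
#' @param muscle_seed world coordinates (mm), (z, y, x) order.
#' @param volume a [vb_volume].
#' @param diameter sphere diameter in mm.
#' @param observer observer identifier.
#' @param axial_sphere the observer's axial [vb_sphere] (optional; when given,
#'   enforces the same-slice constraint).
#' @return A [vb_sphere] with role `"control"`.
#' @export
place_control_sphere <- function(muscle_seed, volume, diameter = 10,
                                 observer = "obs1", axial_sphere = NULL) {
  d <- dim(volume$intensities)
  idx0 <- world_to_index0(volume, muscle_seed)
  if (any(idx0 < -0.5) || any(idx0 > d - 0.5))
    stop("muscle seed point lies outside the volume grid")
  center <- as.numeric(muscle_seed)
  if (!is.null(axial_sphere)) {
    z_axial <- axial_sphere$center[1]
    seed_slice <- round(world_to_index0(volume, center)[1])
    axial_slice <- round(world_to_index0(volume, axial_sphere$center)[1])
    if (seed_slice != axial_slice) {
      message("control sphere seed moved from slice ", seed_slice,
              " to the axial sphere's slice ", axial_slice)
      center[1] <- z_axial
    }
  }
  r <- diameter / 2
  lo <- world_to_index0(volume, center - r)
  hi <- world_to_index0(volume, center + r)
  if (any(lo < -0.5) || any(hi > d - 0.5))
    stop("control sphere of diameter ", diameter, " mm exceeds the grid bounds")
  vb_sphere(center, diameter, "control", observer)
}

#' Voxelize a sphere VOI against a volume
#'
#' Membership is by voxel centre: a voxel belongs to the sample when the
#' Euclidean distance (in mm, using the anisotropic spacing) from its centre
#' to the sphere centre is at most `diameter / 2`. The 3D membership mask over
#' the sample's bounding box is retained so texture features can see voxel
#' adjacency.
#'
#' @param volume a [vb_volume].
#' @param voi a [vb_sphere].
#' @return An object of class `vb_sample` with fields `indices1` (1-based
#'   (z,y,x) index matrix), `intensities` (HU), `mask` and `bbox_lo` (local
#'   adjacency mask and its grid offset), `spacing`, and the originating `voi`.
#' @export
voxelize_sphere <- function(volume, voi) {
  d <- dim(volume$intensities)
  sp <- volume$spacing
  c0 <- world_to_index0(volume, voi$center)
  r <- voi$diameter / 2
  lo <- pmax(ceiling(c0 - r / sp), 0)
  hi <- pmin(floor(c0 + r / sp), d - 1)
  if (any(lo > hi)) stop("sphere does not intersect the volume grid")
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz2 <- ((zi - c0[1]) * sp[1])^2
  dy2 <- ((yi - c0[2]) * sp[2])^2
  dx2 <- ((xi - c0[3]) * sp[3])^2
  dist2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
  mask <- dist2 <= r^2 + 1e-9
  if (!any(mask)) stop("sphere VOI contains no voxel centres")
  local <- which(mask, arr.ind = TRUE)
  idx1 <- cbind(local[, 1] + lo[1], local[, 2] + lo[2], local[, 3] + lo[3])
  structure(list(
    indices1 = idx1,
    intensities = volume$intensities[idx1],
    mask = mask,
    bbox_lo = lo + 1L,
    spacing = sp,
    voi = voi
  ), class = "vb_sample")
}

#' @export
print.vb_sample <- function(x, ...) {
  cat(sprintf("<vb_sample> %d voxels (%s/%s), HU range [%.1f, %.1f]\n",
              nrow(x$indices1), x$voi$role, x$voi$observer,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Full-grid mask of a voxelized VOI (for NIfTI export / inspection)
#'
#' @param volume a [vb_volume].
#' @param voi a [vb_sphere].
#' @return A logical array on the volume grid.
#' @export
voi_mask <- function(volume, voi) {
  s <- voxelize_sphere(volume, voi)
  m <- array(FALSE, dim = dim(volume$intensities))
  m[s$indices1] <- TRUE
  m
}

#' Serialize / restore sphere VOIs
#'
#' @param vois a list of [vb_sphere] objects.
#' @param path JSON file path.
#' @return `path` invisibly; `read_voi_json` returns a list of [vb_sphere].
#' @export
write_voi_json <- function(vois, path) {
  payload <- lapply(vois, function(v)
    list(center_mm = v$center, diameter_mm = v$diameter,
         role = v$role, observer = v$observer))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_voi_json
#' @export
read_voi_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(payload, function(v)
    vb_sphere(unlist(v$center_mm), v$diameter_mm, v$role, v$observer))
}
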
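#' CT volume container
#'
#' A `vb_volume` stores a 3D grid of Hounsfield Unit values together with its
#' voxel geometry. The internal axis order is fixed as (slice z, row y,
#' column x); world coordinates are in millimetres in an axis-aligned LPS-like
#' frame, and a voxel is treated as a point sample at its centre. The world
#' position of voxel `(i, j, k)` (0-based) is `origin + (i*dz, j*dy, k*dx)`.
#'
#' @param intensities 3D numeric array, axis order (z, y, x), values in HU.
#' @param spacing numeric length-3, voxel spacing `(dz, dy, dx)` in mm.
#' @param origin numeric length-3, world coordinates (mm) of the centre of
#'   voxel (0, 0, 0), in (z, y, x) order.
#' @return An object of class `vb_volume`.
#' @export
vb_volume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (length(intensities) == 0L) stop("volume grid is empty")
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive numbers (dz, dy, dx)")
  if (length(origin) != 3L) stop("origin must have three components")
  structure(
    list(intensities = intensities, spacing = spacing, origin = origin),
    class = "vb_volume"
  )
}

#' @export
print.vb_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<vb_volume> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.1f, %.1f, %.1f) mm\n",
              min(x$intensities), max(x$intensities),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.vb_volume <- function(x) dim(x$intensities)

# world (mm, z/y/x order) -> 0-based continuous voxel index
world_to_index0 <- function(volume, world) {
  (as.numeric(world) - volume$origin) / volume$spacing
}

index0_to_world <- function(volume, index0) {
  volume$origin + as.numeric(index0) * volume$spacing
}

#' Read a CT volume
#'
#' Reads a NIfTI file (`.nii`/`.nii.gz`) or a DICOM series directory into a
#' [vb_volume]. NIfTI images whose stored orientation differs from the
#' canonical axis-aligned frame are reoriented on load, so downstream sphere
#' placement always sees the (z, y, x) convention. DICOM stored values are
#' converted to HU with the rescale slope/intercept and slices are sorted by
#' position along the stack normal.
#'
#' @param path path to a NIfTI file or a directory containing one DICOM series.
#' @return A [vb_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) read_dicom_series(path) else read_nifti_volume(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(orient) && !identical(orient, "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  pd <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  org_xyz <- if (is.matrix(xf)) xf[1:3, 4] else c(0, 0, 0)
  # stored (x,y,z) -> internal (z,y,x)
  vb_volume(aperm(arr, c(3, 2, 1)),
            spacing = rev(pd),
            origin = rev(org_xyz))
}

#' Write a volume or mask to NIfTI
#'
#' @param volume a [vb_volume], or a logical/0-1 array paired with
#'   `geometry_from`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param geometry_from optional [vb_volume] supplying spacing/origin when
#'   `volume` is a bare array (e.g. a mask).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, geometry_from = NULL) {
  if (!inherits(volume, "vb_volume")) {
    if (is.null(geometry_from))
      stop("geometry_from is required when writing a bare array")
    volume <- vb_volume(array(as.numeric(volume), dim = dim(volume)),
                        spacing = geometry_from$spacing,
                        origin = geometry_from$origin)
  }
  arr <- aperm(volume$intensities, c(3, 2, 1))  # internal (z,y,x) -> (x,y,z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing)
  xf <- diag(c(rev(volume$spacing), 1))
  xf[1:3, 4] <- rev(volume$origin)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary lesion/region mask
#'
#' The mask must live on the same grid as its paired volume; a lesion mask must
#' contain at least one foreground voxel.
#'
#' @param path NIfTI file with 0/1 voxel values.
#' @param volume the paired [vb_volume] (grid consistency is checked).
#' @param require_foreground error when the mask is empty (default `TRUE`).
#' @return A logical 3D array in (z, y, x) order.
#' @export
read_mask <- function(path, volume, require_foreground = TRUE) {
  m <- read_volume(path)
  as_mask(m$intensities != 0, volume,
          spacing = m$spacing, require_foreground = require_foreground)
}

as_mask <- function(mask, volume, spacing = NULL, require_foreground = TRUE) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), dim(volume$intensities)))
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match volume grid ",
         paste(dim(volume$intensities), collapse = "x"))
  if (!is.null(spacing) && any(abs(spacing - volume$spacing) > 1e-6))
    stop("mask voxel spacing does not match the volume")
  if (require_foreground && !any(mask))
    stop("mask has no foreground voxels")
  mask
}

# ---- minimal DICOM series support -----------------------------------------
#
# No DICOM reader ships with the installed R stack, so a minimal parser for
# uncompressed explicit-VR little-endian series is provided: enough for
# axial CT exports (and the synthetic series written by write_dicom_series).

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

read_dicom_element <- function(con) {
  hdr <- readBin(con, "integer", n = 2, size = 2, signed = FALSE, endian = "little")
  if (length(hdr) < 2) return(NULL)
  vr <- rawToChar(readBin(con, "raw", n = 2))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    readBin(con, "raw", n = 2)  # reserved
    len <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  } else {
    len <- readBin(con, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
  }
  value <- readBin(con, "raw", n = len)
  list(tag = dcm_tag(hdr[1], hdr[2]), vr = vr, bytes = value)
}

dcm_string <- function(el) trimws(rawToChar(el$bytes))
dcm_numbers <- function(el) as.numeric(strsplit(dcm_string(el), "\\\\")[[1]])
dcm_uint16 <- function(el) readBin(el$bytes, "integer", size = 2, signed = FALSE,
                                   endian = "little")

read_dicom_slice <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", n = 132)
  if (length(preamble) < 132 || rawToChar(preamble[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  out <- list()
  repeat {
    el <- read_dicom_element(con)
    if (is.null(el)) break
    out[[el$tag]] <- el
    if (el$tag == "7FE0,0010") break
  }
  rows <- dcm_uint16(out[["0028,0010"]])
  cols <- dcm_uint16(out[["0028,0011"]])
  bits <- dcm_uint16(out[["0028,0100"]])
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported: ", path)
  signed <- dcm_uint16(out[["0028,0103"]]) == 1L
  px <- readBin(out[["7FE0,0010"]]$bytes, "integer", n = rows * cols,
                size = 2, signed = signed, endian = "little")
  slope <- if (!is.null(out[["0028,1053"]])) dcm_numbers(out[["0028,1053"]]) else 1
  inter <- if (!is.null(out[["0028,1052"]])) dcm_numbers(out[["0028,1052"]]) else 0
  orient <- if (!is.null(out[["0020,0037"]])) dcm_numbers(out[["0020,0037"]])
            else c(1, 0, 0, 0, 1, 0)
  list(
    modality = if (!is.null(out[["0008,0060"]])) dcm_string(out[["0008,0060"]]) else "",
    position = dcm_numbers(out[["0020,0032"]]),
    orientation = orient,
    pixel_spacing = dcm_numbers(out[["0028,0030"]]),  # (row, col) = (dy, dx)
    hu = matrix(px * slope + inter, nrow = cols, ncol = rows)  # [x, y]
  )
}

read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) == 0L)
    files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no DICOM files found in ", dir)
  slices <- lapply(files, read_dicom_slice)

  modality <- slices[[1]]$modality
  if (nzchar(modality) && modality != "CT")
    warning("DICOM series modality is '", modality, "', not CT")
  ori <- slices[[1]]$orientation
  if (max(abs(ori - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("only axial identity-orientation DICOM series are supported")

  normal <- c(ori[2] * ori[6] - ori[3] * ori[5],
              ori[3] * ori[4] - ori[1] * ori[6],
              ori[1] * ori[5] - ori[2] * ori[4])
  pos <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]
  files <- files[ord]
  pos <- pos[ord]

  if (length(slices) > 1L) {
    dz <- diff(pos)
    if (any(dz <= 0)) stop("duplicate DICOM slice positions in ", dir)
    if ((max(dz) - min(dz)) / mean(dz) > 0.01) {
      bad <- which(abs(dz - stats::median(dz)) > 0.01 * stats::median(dz))
      stop("inconsistent DICOM slice spacing (> 1% variation) between slices: ",
           paste(basename(files[bad]), basename(files[bad + 1]),
                 sep = " -> ", collapse = ", "))
    }
    dz <- mean(dz)
  } else {
    dz <- 1
  }
  ps <- slices[[1]]$pixel_spacing
  nx <- nrow(slices[[1]]$hu); ny <- ncol(slices[[1]]$hu)
  arr <- array(0, dim = c(length(slices), ny, nx))
  for (i in seq_along(slices)) arr[i, , ] <- t(slices[[i]]$hu)
  p0 <- slices[[1]]$position  # (x, y, z) of first voxel centre
  vb_volume(arr, spacing = c(dz, ps[1], ps[2]), origin = rev(p0))
}

#' Write a minimal synthetic DICOM series
#'
#' Writes one uncompressed explicit-VR little-endian CT file per axial slice,
#' with identity orientation and signed 16-bit stored values
#' (`HU = slope * stored + intercept`). Intended for generating test series and
#' for exporting synthetic volumes; it is not a general DICOM exporter.
#'
#' @param volume a [vb_volume].
#' @param dir output directory (created if needed).
#' @param slope,intercept rescale applied when reading back
#'   (`stored = (HU - intercept) / slope`, must be integral).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(volume, dir, slope = 1, intercept = -1024,
                               modality = "CT") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume$intensities)
  stored <- (volume$intensities - intercept) / slope
  if (max(abs(stored - round(stored))) > 1e-6)
    stop("HU values are not representable as integer stored values with this slope/intercept")
  stored <- round(stored)
  if (min(stored) < -32768 || max(stored) > 32767)
    stop("stored values exceed the signed 16-bit range")
  for (i in seq_len(d[1])) {
    z <- volume$origin[1] + (i - 1) * volume$spacing[1]
    slab <- stored[i, , ]  # [y, x]
    path <- file.path(dir, sprintf("slice_%04d.dcm", i))
    write_dicom_file(path, slab, rows = d[2], cols = d[3],
                     pixel_spacing = c(volume$spacing[2], volume$spacing[3]),
                     position = c(volume$origin[3], volume$origin[2], z),
                     slope = slope, intercept = intercept,
                     instance = i, modality = modality)
  }
  invisible(dir)
}

dcm_element_raw <- function(group, element, vr, bytes) {
  if (length(bytes) %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  hdr <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                  endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(bytes), raw(), size = 4, endian = "little"), bytes)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(bytes), raw(), size = 2, endian = "little"), bytes)
  }
}

dcm_str_element <- function(group, element, vr, value) {
  dcm_element_raw(as.integer(group), as.integer(element), vr, charToRaw(value))
}

write_dicom_file <- function(path, slab, rows, cols, pixel_spacing, position,
                             slope, intercept, instance, modality = "CT") {
  num <- function(x) paste(formatC(x, format = "fg", digits = 10), collapse = "\\")
  px <- writeBin(as.integer(t(slab)), raw(), size = 2, endian = "little")
  meta <- c(
    dcm_str_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_str_element(0x0002, 0x0003, "UI", sprintf("1.2.826.0.1.999999.1.%d", instance)),
    dcm_str_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  body <- c(
    dcm_str_element(0x0008, 0x0060, "CS", modality),
    dcm_str_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_str_element(0x0020, 0x0032, "DS", num(position)),
    dcm_str_element(0x0020, 0x0037, "DS", num(c(1, 0, 0, 0, 1, 0))),
    dcm_element_raw(0x0028, 0x0010, "US",
                    writeBin(as.integer(rows), raw(), size = 2, endian = "little")),
    dcm_element_raw(0x0028, 0x0011, "US",
                    writeBin(as.integer(cols), raw(), size = 2, endian = "little")),
    dcm_str_element(0x0028, 0x0030, "DS", num(pixel_spacing)),
    dcm_element_raw(0x0028, 0x0100, "US",
                    writeBin(16L, raw(), size = 2, endian = "little")),
    dcm_element_raw(0x0028, 0x0101, "US",
                    writeBin(16L, raw(), size = 2, endian = "little")),
    dcm_element_raw(0x0028, 0x0102, "US",
                    writeBin(15L, raw(), size = 2, endian = "little")),
    dcm_element_raw(0x0028, 0x0103, "US",
                    writeBin(1L, raw(), size = 2, endian = "little")),
    dcm_str_element(0x0028, 0x1052, "DS", num(intercept)),
    dcm_str_element(0x0028, 0x1053, "DS", num(slope)),
    dcm_element_raw(0x7FE0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

# ---- cohort tables ---------------------------------------------------------

#' Read and validate a cohort table
#'
#' The CSV must contain `patient_id`, `group`, `survival_months` and `event`
#' columns; any further columns (IHC percentages/intensities, file references,
#' clinical covariates) are preserved as-is. Group labels must be `long` or
#' `short`, survival must be non-negative and patient ids unique.
#'
#' @param path CSV file.
#' @return A `data.frame`, one row per patient, with `group` as a factor with
#'   levels `c("long", "short")`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(df)
}

validate_cohort_table <- function(df) {
  required <- c("patient_id", "group", "survival_months", "event")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  bad_group <- which(!df$group %in% c("long", "short"))
  if (length(bad_group) > 0)
    stop("unknown group label(s) '",
         paste(unique(df$group[bad_group]), collapse = "', '"),
         "' in row(s) ", paste(bad_group, collapse = ", "),
         " (expected 'long' or 'short')")
  neg <- which(df$survival_months < 0)
  if (length(neg) > 0)
    stop("negative survival_months in row(s) ", paste(neg, collapse = ", "))
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup) > 0)
    stop("duplicate patient id(s): ", paste(unique(dup), collapse = ", "))
  if (!all(df$event %in% c(0, 1, TRUE, FALSE)))
    stop("event must be 0/1")
  df$group <- factor(df$group, levels = c("long", "short"))
  df$event <- as.integer(df$event)
  df
}

#' Does a cohort row carry IHC scores for a marker?
#'
#' @param record one row of a cohort table.
#' @param marker marker name, e.g. `"cd68"` (columns `<marker>_percent` and
#'   `<marker>_intensity`).
#' @return `TRUE` when both IHC fields are present and non-missing.
#' @export
has_ihc <- function(record, marker) {
  pc <- paste0(marker, "_percent"); ic <- paste0(marker, "_intensity")
  all(c(pc, ic) %in% names(record)) &&
    !is.na(record[[pc]]) && !is.na(record[[ic]])
}
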
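# S3 containers for the T1rho pipeline. Conventions used throughout:
# 0-based physical reasoning but 1-based R indexing; axis order (x, y, z[, TSL]);
# every container carries voxel_size_mm so physical units never depend on
# header guessing; invalid voxels in derived maps are NaN (never zero).

#' Multi-TSL image series
#'
#' The central pipeline currency: a 4D stack of magnitude image volumes, one
#' per spin-lock time (TSL), plus the acquisition metadata needed to fit and
#' simulate the series.
#'
#' @param volumes 4D numeric array, dimensions (x, y, z, TSL index); magnitude
#'   signal in arbitrary units, all values >= 0.
#' @param tsl_ms numeric vector of spin-lock durations in milliseconds,
#'   strictly increasing, first element >= 0; length must equal `dim(volumes)[4]`.
#' @param voxel_size_mm length-3 numeric vector of voxel edge lengths (mm).
#' @param field_T main field strength in Tesla.
#' @param b1sl_hz spin-lock amplitude in Hz.
#' @return An object of class `tsl_series`.
#' @export
tsl_series <- function(volumes, tsl_ms, voxel_size_mm = c(1, 1, 1),
                       field_T = 7, b1sl_hz = 500) {
  volumes <- as_array4d(volumes)
  tsl_ms <- as.numeric(tsl_ms)
  if (dim(volumes)[4] != length(tsl_ms)) {
    stop("number of volumes (", dim(volumes)[4], ") must equal length of tsl_ms (",
         length(tsl_ms), ")", call. = FALSE)
  }
  if (length(tsl_ms) && (any(diff(tsl_ms) <= 0) || tsl_ms[1] < 0)) {
    stop("tsl_ms must be strictly increasing with first element >= 0", call. = FALSE)
  }
  if (any(volumes < 0, na.rm = TRUE)) {
    stop("magnitude signal must be >= 0 everywhere", call. = FALSE)
  }
  structure(
    list(volumes = volumes, tsl_ms = tsl_ms,
         voxel_size_mm = check_voxel_size(voxel_size_mm),
         field_T = as.numeric(field_T), b1sl_hz = as.numeric(b1sl_hz)),
    class = "tsl_series"
  )
}

#' Scalar per-voxel field map
#'
#' @param values 3D numeric array: B0 offset in Hz (`kind = "b0_hz"`) or
#'   relative transmit field (`kind = "b1rel"`, actual/nominal flip ratio).
#'   Undefined voxels are NaN.
#' @param kind `"b0_hz"` or `"b1rel"`.
#' @param voxel_size_mm length-3 numeric vector (mm).
#' @return An object of class `field_map`.
#' @export
field_map <- function(values, kind = c("b0_hz", "b1rel"), voxel_size_mm = c(1, 1, 1)) {
  kind <- match.arg(kind)
  values <- as_array3d(values)
  finite <- values[is.finite(values)]
  if (kind == "b1rel" && any(finite <= 0)) {
    stop("b1rel values must be > 0 where defined", call. = FALSE)
  }
  structure(
    list(values = values, kind = kind, voxel_size_mm = check_voxel_size(voxel_size_mm)),
    class = "field_map"
  )
}

#' Region label codes
#'
#' Integer codes used in [region_mask()] `labels`: background 0, deep 1,
#' middle 2, superficial 3, fluid 4, bone 5. `side` codes: none 0, medial 1,
#' lateral 2.
#' @export
REGION_CODES <- c(background = 0L, deep = 1L, middle = 2L, superficial = 3L,
                  fluid = 4L, bone = 5L)

#' @rdname REGION_CODES
#' @export
SIDE_CODES <- c(none = 0L, medial = 1L, lateral = 2L)

#' Cartilage region mask
#'
#' Labelled segmentation volume: tissue class per voxel plus a medial/lateral
#' side code. Zone codes (deep/middle/superficial) are only meaningful inside
#' cartilage; every cartilage voxel carries exactly one zone and one side.
#'
#' @param labels 3D integer array with codes from [REGION_CODES].
#' @param side 3D integer array of [SIDE_CODES], same shape; defaults to all 0.
#' @param voxel_size_mm length-3 numeric vector (mm).
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(labels, side = NULL, voxel_size_mm = c(1, 1, 1)) {
  labels <- as_array3d(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% REGION_CODES)) {
    stop("labels must use only the codes in REGION_CODES", call. = FALSE)
  }
  if (is.null(side)) side <- array(0L, dim(labels))
  side <- as_array3d(side)
  storage.mode(side) <- "integer"
  if (!identical(dim(side), dim(labels))) {
    stop("side array shape must match labels", call. = FALSE)
  }
  if (!all(side %in% SIDE_CODES)) {
    stop("side must use only the codes in SIDE_CODES", call. = FALSE)
  }
  structure(
    list(labels = labels, side = side, voxel_size_mm = check_voxel_size(voxel_size_mm)),
    class = "region_mask"
  )
}

#' Logical cartilage selection from a region mask
#'
#' @param mask a [region_mask()].
#' @param zones character vector of zone names to select (default: the three
#'   cartilage zones).
#' @param sides optional character vector (`"medial"`, `"lateral"`); `NULL`
#'   selects both.
#' @return logical 3D array.
#' @export
mask_select <- function(mask, zones = c("deep", "middle", "superficial"), sides = NULL) {
  stopifnot(inherits(mask, "region_mask"))
  sel <- mask$labels %in% REGION_CODES[zones]
  dim(sel) <- dim(mask$labels)
  if (!is.null(sides)) {
    sel <- sel & (mask$side %in% SIDE_CODES[sides])
    dim(sel) <- dim(mask$labels)
  }
  sel
}

#' Acquisition protocol description
#'
#' Counts and timings of the segmented spin-lock-prepared GRE protocol, used
#' for the scan-time and resolution arithmetic. Defaults mirror a 7T knee
#' protocol: 5 TSLs, 10 slice encodes, 2 shots per slice encode, shot TR 5 s,
#' FOV 140x140 mm, matrix 448x224, and the named session segments (localizer,
#' shim/frequency, structural, two localized SVS calibrations, two 3D-T1rho
#' scans).
#'
#' @param n_tsl number of spin-lock times.
#' @param n_slice_encodes number of slice (partition) encodes.
#' @param shots_per_slice_encode shots per slice encode.
#' @param shot_tr_s shot repetition time, seconds.
#' @param segment_minutes named numeric vector of protocol segment durations
#'   in minutes.
#' @param fov_mm in-plane field of view, length-2 (mm).
#' @param matrix_size in-plane acquisition matrix, length-2 integers.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_tsl = 5L, n_slice_encodes = 10L,
                          shots_per_slice_encode = 2L, shot_tr_s = 5,
                          segment_minutes = c(localizer = 0.5, shim = 1,
                                              structural = 4, svs_patellar = 2,
                                              t1rho_axial = 25 / 3,
                                              svs_femorotibial = 2,
                                              t1rho_coronal = 25 / 3),
                          fov_mm = c(140, 140), matrix_size = c(448L, 224L)) {
  counts <- c(n_tsl, n_slice_encodes, shots_per_slice_encode)
  if (any(counts < 1)) stop("all protocol counts must be >= 1", call. = FALSE)
  if (shot_tr_s <= 0) stop("shot_tr_s must be > 0", call. = FALSE)
  if (length(segment_minutes) && any(segment_minutes <= 0)) {
    stop("all segment durations must be > 0", call. = FALSE)
  }
  structure(
    list(n_tsl = as.integer(n_tsl), n_slice_encodes = as.integer(n_slice_encodes),
         shots_per_slice_encode = as.integer(shots_per_slice_encode),
         shot_tr_s = as.numeric(shot_tr_s),
         segment_minutes = segment_minutes,
         fov_mm = as.numeric(fov_mm), matrix_size = as.integer(matrix_size)),
    class = "protocol_spec"
  )
}

#' @export
print.tsl_series <- function(x, ...) {
  d <- dim(x$volumes)
  cat("<tsl_series> ", paste(d[1:3], collapse = "x"), " voxels, ",
      d[4], " TSLs (", paste(x$tsl_ms, collapse = ", "), " ms), B1sl ",
      x$b1sl_hz, " Hz at ", x$field_T, "T\n", sep = "")
  invisible(x)
}

#' @export
print.field_map <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  cat("<field_map:", x$kind, "> ", paste(dim(x$values), collapse = "x"),
      sprintf(", finite %d/%d, range [%.3g, %.3g]\n", length(fin),
              length(x$values), min(fin), max(fin)), sep = "")
  invisible(x)
}

#' @export
print.region_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = REGION_CODES, labels = names(REGION_CODES)))
  cat("<region_mask> ", paste(dim(x$labels), collapse = "x"), " voxels\n", sep = "")
  print(tab)
  invisible(x)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec> ", x$n_tsl, " TSLs x ", x$n_slice_encodes,
      " slice encodes x ", x$shots_per_slice_encode, " shots, shot TR ",
      x$shot_tr_s, " s\n", sep = "")
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

as_array3d <- function(x) {
  x <- as.array(x)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected a 3D array", call. = FALSE)
  x
}

as_array4d <- function(x) {
  x <- as.array(x)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("expected a 4D array", call. = FALSE)
  x
}

check_voxel_size <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0)) {
    stop("voxel_size_mm must be 3 positive numbers", call. = FALSE)
  }
  v
}

# restore the caller's RNG state after locally seeded generation
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
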
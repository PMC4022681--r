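# Protocol arithmetic: scan time, session length, in-plane resolution.

#' Scan time for one 3D-T1rho set
#'
#' Total acquisition time of one multi-TSL 3D set under segmented readout:
#' `n_tsl * n_slice_encodes * shots_per_slice_encode * shot_tr_s` seconds.
#' With the default protocol (5 TSLs, 10 slice encodes, 2 shots, shot TR 5 s)
#' this is 500 s, i.e. about 8.3 minutes.
#'
#' @param p a [protocol_spec()].
#' @return scan time in seconds.
#' @export
scan_time_s <- function(p) {
  stopifnot(inherits(p, "protocol_spec"))
  p$n_tsl * p$n_slice_encodes * p$shots_per_slice_encode * p$shot_tr_s
}

#' Total protocol duration
#'
#' Sum of the named session segment durations (localizer, shimming and
#' frequency setting, structural scan, localized SVS calibrations, T1rho
#' acquisitions).
#'
#' @param p a [protocol_spec()].
#' @return total duration in minutes.
#' @export
protocol_total_minutes <- function(p) {
  stopifnot(inherits(p, "protocol_spec"))
  if (length(p$segment_minutes) == 0L) {
    stop("segment_minutes is empty", call. = FALSE)
  }
  sum(p$segment_minutes)
}

#' In-plane voxel area
#'
#' `(fov_x/matrix_x) * (fov_y/matrix_y)` in mm^2; with FOV 140x140 mm and
#' matrix 448x224 this is 0.195 mm^2 (the nominal "0.2 mm^2" resolution).
#'
#' @param p a [protocol_spec()].
#' @return voxel area in mm^2.
#' @export
inplane_voxel_area_mm2 <- function(p) {
  stopifnot(inherits(p, "protocol_spec"))
  if (any(p$matrix_size == 0)) stop("matrix dimension is zero", call. = FALSE)
  (p$fov_mm[1] / p$matrix_size[1]) * (p$fov_mm[2] / p$matrix_size[2])
}
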
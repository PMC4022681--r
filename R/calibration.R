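# Field calibration: WASSR z-spectrum B0 mapping, double-angle B1 mapping,
# and STEAM two-spectrum flip-angle / reference-voltage computation.

#' WASSR z-spectrum series
#'
#' Image volumes acquired at a ladder of saturation frequency offsets; the
#' per-voxel minimum of the (direct-saturation) z-spectrum locates the water
#' resonance, i.e. the B0 offset.
#'
#' @param volumes 4D array (x, y, z, offset index).
#' @param offsets_ppm strictly increasing saturation offsets, ppm.
#' @param sat_b1_hz saturation amplitude, Hz (metadata).
#' @param sat_dur_ms saturation duration, ms (metadata).
#' @param field_T main field, Tesla (for the ppm-to-Hz conversion).
#' @param voxel_size_mm length-3 voxel size, mm.
#' @return An object of class `zspectrum_series`.
#' @export
zspectrum_series <- function(volumes, offsets_ppm, sat_b1_hz = 20,
                             sat_dur_ms = 200, field_T = 7,
                             voxel_size_mm = c(1, 1, 1)) {
  volumes <- as_array4d(volumes)
  offsets_ppm <- as.numeric(offsets_ppm)
  if (dim(volumes)[4] != length(offsets_ppm)) {
    stop("number of volumes must equal number of offsets", call. = FALSE)
  }
  if (any(diff(offsets_ppm) <= 0)) {
    stop("offsets_ppm must be strictly increasing", call. = FALSE)
  }
  structure(list(volumes = volumes, offsets_ppm = offsets_ppm,
                 sat_b1_hz = sat_b1_hz, sat_dur_ms = sat_dur_ms,
                 field_T = field_T, voxel_size_mm = check_voxel_size(voxel_size_mm)),
            class = "zspectrum_series")
}

#' B0 map from WASSR data
#'
#' Per masked voxel: the ppm offset grid is converted to Hz, the z-spectrum is
#' upsampled by cubic-spline interpolation to a 1 Hz grid, and the offset
#' minimizing the interpolated signal is returned. Voxels whose minimum falls
#' on the boundary of the sampled range (dip not bracketed) and all-constant
#' spectra are flagged NaN.
#'
#' @param z a [zspectrum_series()].
#' @param mask logical 3D array or [region_mask()] (all non-background voxels
#'   are mapped).
#' @return A [field_map()] of kind `"b0_hz"` (NaN outside the mask).
#' @export
wassr_b0_map <- function(z, mask) {
  stopifnot(inherits(z, "zspectrum_series"))
  sel <- mask_as_logical(mask, dim(z$volumes)[1:3])
  off_hz <- ppm_to_hz(z$offsets_ppm, z$field_T)
  if (length(off_hz) < 5) stop("need at least 5 saturation offsets", call. = FALSE)
  fine <- seq(off_hz[1], off_hz[length(off_hz)], by = 1)
  out <- array(NaN, dim(z$volumes)[1:3])
  idx <- which(sel)
  nvol <- prod(dim(z$volumes)[1:3])
  for (i in idx) {
    spec <- z$volumes[i + (seq_along(off_hz) - 1L) * nvol]
    if (!all(is.finite(spec)) || diff(range(spec)) == 0) next
    sf <- stats::splinefun(off_hz, spec, method = "fmm")
    vals <- sf(fine)
    j <- which.min(vals)
    if (j == 1L || j == length(fine)) next  # dip on grid boundary: censored
    out[i] <- fine[j]
  }
  field_map(out, "b0_hz", voxel_size_mm = z$voxel_size_mm)
}

#' B1 map by the double-angle method
#'
#' From magnitude volumes at nominal flips `alpha0` and `2*alpha0` under the
#' long-TR (full-relaxation) regime, the actual flip is
#' `acos(s_high / (2 * s_low))` and B1rel is actual/nominal. Voxels with
#' `s_low = 0` or a ratio outside (0, 2) (arccos domain / unphysical) are NaN.
#'
#' @param s_low 3D magnitude volume at nominal flip `alpha0_deg`.
#' @param s_high 3D magnitude volume at nominal flip `2 * alpha0_deg`.
#' @param alpha0_deg the lower nominal flip angle, degrees (protocol: 30).
#' @param mask logical 3D array or [region_mask()].
#' @param voxel_size_mm length-3 voxel size, mm.
#' @return A [field_map()] of kind `"b1rel"`.
#' @export
double_angle_b1_map <- function(s_low, s_high, alpha0_deg = 30, mask = NULL,
                                voxel_size_mm = c(1, 1, 1)) {
  s_low <- as_array3d(s_low); s_high <- as_array3d(s_high)
  stopifnot(identical(dim(s_low), dim(s_high)))
  sel <- if (is.null(mask)) array(TRUE, dim(s_low)) else mask_as_logical(mask, dim(s_low))
  ratio <- ifelse(s_low > 0, s_high / (2 * s_low), NaN)
  ratio[!sel] <- NaN
  ratio[!is.na(ratio) & (ratio <= 0 | ratio >= 1)] <- NaN
  alpha <- acos(ratio) * 180 / pi
  field_map(alpha / alpha0_deg, "b1rel", voxel_size_mm = voxel_size_mm)
}

#' STEAM two-spectrum pair
#'
#' Peak water signals of two single-voxel STEAM spectra acquired at transmit
#' reference voltages `x` and `2x`. With three identical pulses of flip alpha
#' the STEAM signal is proportional to `sin(alpha)^3`, so the pair determines
#' alpha and hence the true 90-degree reference voltage.
#'
#' @param s1 peak water signal at voltage `x` (> 0).
#' @param s2 peak water signal at voltage `2x` (>= 0).
#' @param x_volts the preset reference voltage (> 0).
#' @return An object of class `steam_pair`.
#' @export
steam_pair <- function(s1, s2, x_volts) {
  if (s1 <= 0) stop("s1 must be > 0", call. = FALSE)
  if (s2 < 0) stop("s2 must be >= 0", call. = FALSE)
  if (x_volts <= 0) stop("x_volts must be > 0", call. = FALSE)
  structure(list(s1 = s1, s2 = s2, x_volts = x_volts), class = "steam_pair")
}

#' Flip angle from a STEAM pair
#'
#' With S proportional to `sin(alpha)^3` and the voltage-to-flip linearity,
#' doubling the voltage doubles the flip, so `s2/s1 = sin(2a)^3 / sin(a)^3
#' = 8 cos(a)^3` and `alpha = acos((s2 / (8 s1))^(1/3))`.
#'
#' @param pair a [steam_pair()].
#' @return flip angle in degrees, in (0, 90].
#' @export
steam_flip_angle <- function(pair) {
  stopifnot(inherits(pair, "steam_pair"))
  u <- pair$s2 / (8 * pair$s1)
  if (u > 1) {
    stop("inconsistent STEAM pair: s2/(8*s1) = ", signif(u, 4), " exceeds 1",
         call. = FALSE)
  }
  acos(u^(1 / 3)) * 180 / pi
}

#' Reference voltage from a STEAM pair
#'
#' The voltage at which the same pulse produces exactly 90 degrees, under the
#' linear voltage-to-flip assumption: `V = x * 90 / alpha`.
#'
#' @param pair a [steam_pair()].
#' @return reference voltage in volts.
#' @export
reference_voltage <- function(pair) {
  alpha <- steam_flip_angle(pair)
  pair$x_volts * 90 / alpha
}

#' Mean and s.d. of a B0 map over a mask
#'
#' @param b0 a [field_map()] of kind `"b0_hz"`.
#' @param mask logical 3D array or [region_mask()].
#' @return tibble with columns `mean_hz`, `sd_hz`, `n`.
#' @export
frequency_offset_summary <- function(b0, mask) {
  stopifnot(inherits(b0, "field_map"), b0$kind == "b0_hz")
  sel <- mask_as_logical(mask, dim(b0$values))
  v <- b0$values[sel]
  v <- v[is.finite(v)]
  if (length(v) < 2) stop("need at least 2 masked finite voxels", call. = FALSE)
  tibble::tibble(mean_hz = mean(v), sd_hz = stats::sd(v), n = length(v))
}

# mask argument normalization: logical array, region_mask, or NULL
mask_as_logical <- function(mask, dims) {
  if (inherits(mask, "region_mask")) {
    sel <- mask$labels != REGION_CODES[["background"]]
    dim(sel) <- dim(mask$labels)
  } else {
    sel <- mask
    if (is.numeric(sel)) sel <- sel != 0
    sel <- as_array3d(sel)
  }
  if (!identical(as.integer(dim(sel)), as.integer(dims))) {
    stop("mask shape does not match volume shape", call. = FALSE)
  }
  sel & !is.na(sel)
}
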
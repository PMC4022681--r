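# Synthetic knee phantom: an annular cartilage band (patellar-like curved
# slab) over bone, with adjacent fluid, zone-dependent T1rho, smooth B0/B1rel
# fields with per-voxel jitter, and Rician noise at a configurable base SNR.

#' Gyromagnetic ratio of 1H, MHz/T
#' @export
GAMMA_MHZ_PER_T <- 42.5764

#' Convert chemical-shift offsets to Hz
#'
#' @param ppm offset in parts per million.
#' @param field_T main field strength, Tesla.
#' @return offset in Hz (`ppm * 1e-6 * gamma * field_T`, gamma in Hz/T).
#' @export
ppm_to_hz <- function(ppm, field_T) ppm * GAMMA_MHZ_PER_T * field_T

#' Synthetic cartilage phantom description
#'
#' Geometry and physics of the synthetic scene. The cartilage is an annular
#' band (angular sector of an annulus, extruded through the slices) wrapped
#' around a bone disc, with a thin fluid layer outside it. Zone T1rho defaults
#' (deep 35, middle 45, superficial 55 ms) respect the deep-to-superficial
#' increase and the healthy sub-60 ms range; they are configuration values,
#' not measured ground truth. Field defaults emulate the post-localized-
#' calibration regime: B0 residuals 0 +/- 30 Hz, B1rel 1.0 +/- 0.1, base
#' (TSL = 0) SNR 240.
#'
#' @param grid_dim length-3 integer grid size (x, y, z).
#' @param voxel_size_mm length-3 voxel size (mm); default 0.3 x 0.6 x 3
#'   mirrors a high in-plane / coarse through-plane acquisition.
#' @param center_vox annulus center (x, y), voxels; default grid center.
#' @param bone_radius_vox inner (bone) radius, voxels.
#' @param thickness_vox cartilage band thickness, voxels.
#' @param angle_deg angular extent of the band, degrees, centered on +y.
#' @param fluid_thickness_vox fluid layer thickness outside the cartilage.
#' @param zone_t1rho_ms named numeric: deep, middle, superficial T1rho (ms).
#' @param zone_fractions thickness fractions (deep, middle, superficial),
#'   summing to 1.
#' @param fluid_t1rho_ms fluid T1rho (ms), long relative to cartilage.
#' @param amp_cartilage,amp_fluid,amp_bone,amp_background tissue base signal
#'   amplitudes (arbitrary units).
#' @param b0_bulk_hz bulk B0 offset (Hz); 0 emulates localized frequency
#'   setting, ~139 emulates a patellar scanner-prescan offset.
#' @param b0_gradient_hz_per_fov linear B0 change across the x FOV (Hz).
#' @param b0_jitter_sd_hz per-voxel Gaussian B0 jitter s.d. (Hz).
#' @param b1_mean,b1_gradient_per_fov,b1_jitter_sd B1rel field model.
#' @param base_snr SNR of the cartilage at TSL = 0 (signal amplitude over
#'   per-channel noise sigma).
#' @param seed RNG seed making the phantom deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(96L, 96L, 4L),
                         voxel_size_mm = c(0.3, 0.6, 3),
                         center_vox = NULL,
                         bone_radius_vox = 28,
                         thickness_vox = 9,
                         angle_deg = 180,
                         fluid_thickness_vox = 2,
                         zone_t1rho_ms = c(deep = 35, middle = 45, superficial = 55),
                         zone_fractions = c(deep = 1/3, middle = 1/3, superficial = 1/3),
                         fluid_t1rho_ms = 150,
                         amp_cartilage = 1, amp_fluid = 1.2, amp_bone = 0.25,
                         amp_background = 0,
                         b0_bulk_hz = 0, b0_gradient_hz_per_fov = 0,
                         b0_jitter_sd_hz = 30,
                         b1_mean = 1, b1_gradient_per_fov = 0, b1_jitter_sd = 0.1,
                         base_snr = 240, seed = 1L) {
  if (is.null(center_vox)) center_vox <- (grid_dim[1:2] + 1) / 2
  outer <- bone_radius_vox + thickness_vox + fluid_thickness_vox
  if (outer > min(center_vox[1] - 1, center_vox[2] - 1,
                  grid_dim[1] - center_vox[1], grid_dim[2] - center_vox[2])) {
    stop("phantom geometry does not fit inside the grid", call. = FALSE)
  }
  if (any(zone_t1rho_ms <= 0) || fluid_t1rho_ms <= 0) {
    stop("T1rho values must be positive", call. = FALSE)
  }
  if (abs(sum(zone_fractions) - 1) > 1e-8) {
    stop("zone_fractions must sum to 1", call. = FALSE)
  }
  if (base_snr <= 0) stop("base_snr must be > 0", call. = FALSE)
  structure(
    list(grid_dim = as.integer(grid_dim), voxel_size_mm = check_voxel_size(voxel_size_mm),
         center_vox = as.numeric(center_vox), bone_radius_vox = bone_radius_vox,
         thickness_vox = thickness_vox, angle_deg = angle_deg,
         fluid_thickness_vox = fluid_thickness_vox,
         zone_t1rho_ms = zone_t1rho_ms, zone_fractions = zone_fractions,
         fluid_t1rho_ms = fluid_t1rho_ms,
         amp_cartilage = amp_cartilage, amp_fluid = amp_fluid,
         amp_bone = amp_bone, amp_background = amp_background,
         b0_bulk_hz = b0_bulk_hz, b0_gradient_hz_per_fov = b0_gradient_hz_per_fov,
         b0_jitter_sd_hz = b0_jitter_sd_hz,
         b1_mean = b1_mean, b1_gradient_per_fov = b1_gradient_per_fov,
         b1_jitter_sd = b1_jitter_sd,
         base_snr = base_snr, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Build the synthetic phantom scene
#'
#' Deterministic given `spec$seed`. The cartilage band is split into deep /
#' middle / superficial zones along its thickness by the cumulative zone
#' fractions, measured radially from the bone-facing (inner) surface; fluid
#' sits outside the superficial surface. B0 (Hz) and B1rel fields are bulk +
#' linear-gradient + per-voxel Gaussian jitter.
#'
#' @param spec a [phantom_spec()].
#' @return list with components `mask` ([region_mask()]), `t1rho_true`
#'   (3D map, ms; NaN outside tissue with defined T1rho), `amplitude`
#'   (3D base-signal map), `b0` and `b1` ([field_map()]s).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dim
  cx <- spec$center_vox[1]; cy <- spec$center_vox[2]
  x <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  ang <- atan2(y - cy, x - cx) * 180 / pi  # 90 = +y
  half <- spec$angle_deg / 2
  in_sector <- abs(((ang - 90 + 180) %% 360) - 180) <= half

  r0 <- spec$bone_radius_vox
  r1 <- r0 + spec$thickness_vox
  r2 <- r1 + spec$fluid_thickness_vox
  labels <- array(REGION_CODES[["background"]], d)
  labels[r <= r0 & in_sector] <- REGION_CODES[["bone"]]
  cart <- r > r0 & r <= r1 & in_sector
  labels[r > r1 & r <= r2 & in_sector] <- REGION_CODES[["fluid"]]

  # normalized radial depth from the bone-facing surface
  depth <- (r - r0) / spec$thickness_vox
  cuts <- cumsum(spec$zone_fractions)
  labels[cart & depth <= cuts[1]] <- REGION_CODES[["deep"]]
  labels[cart & depth > cuts[1] & depth <= cuts[2]] <- REGION_CODES[["middle"]]
  labels[cart & depth > cuts[2]] <- REGION_CODES[["superficial"]]

  side <- array(SIDE_CODES[["none"]], d)
  side[labels != REGION_CODES[["background"]] & x <= cx] <- SIDE_CODES[["medial"]]
  side[labels != REGION_CODES[["background"]] & x > cx] <- SIDE_CODES[["lateral"]]

  t1rho <- array(NaN, d)
  t1rho[labels == REGION_CODES[["deep"]]] <- spec$zone_t1rho_ms[["deep"]]
  t1rho[labels == REGION_CODES[["middle"]]] <- spec$zone_t1rho_ms[["middle"]]
  t1rho[labels == REGION_CODES[["superficial"]]] <- spec$zone_t1rho_ms[["superficial"]]
  t1rho[labels == REGION_CODES[["fluid"]]] <- spec$fluid_t1rho_ms

  amp <- array(spec$amp_background, d)
  amp[labels %in% REGION_CODES[c("deep", "middle", "superficial")]] <- spec$amp_cartilage
  amp[labels == REGION_CODES[["fluid"]]] <- spec$amp_fluid
  amp[labels == REGION_CODES[["bone"]]] <- spec$amp_bone

  xfrac <- (x - 1) / max(d[1] - 1, 1)
  fields <- local_seed(spec$seed, {
    b0 <- spec$b0_bulk_hz + spec$b0_gradient_hz_per_fov * (xfrac - 0.5) +
      array(stats::rnorm(prod(d), 0, spec$b0_jitter_sd_hz), d)
    b1 <- spec$b1_mean + spec$b1_gradient_per_fov * (xfrac - 0.5) +
      array(stats::rnorm(prod(d), 0, spec$b1_jitter_sd), d)
    list(b0 = b0, b1 = pmax(b1, 0.05))
  })

  list(mask = region_mask(labels, side, spec$voxel_size_mm),
       t1rho_true = t1rho, amplitude = amp,
       b0 = field_map(fields$b0, "b0_hz", spec$voxel_size_mm),
       b1 = field_map(fields$b1, "b1rel", spec$voxel_size_mm))
}

#' Add Rician noise to magnitude signal
#'
#' Adds independent Gaussian noise of standard deviation `sigma` to two
#' quadrature channels (the noiseless signal on the real channel, zero on the
#' imaginary) and returns the magnitude. On zero signal this yields
#' Rayleigh-distributed background whose s.d. is `sigma * sqrt(2 - pi/2)`
#' (about 0.655 sigma) and whose mean is `sigma * sqrt(pi/2)`.
#'
#' @param signal numeric vector/array of noiseless magnitude signal.
#' @param sigma per-channel Gaussian noise s.d.
#' @return noisy magnitude values, same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (is.array(signal)) dim(out) <- dim(signal)
  out
}

#' Simulate a multi-TSL series from a phantom
#'
#' For every voxel and TSL, the signal is the tissue base amplitude times the
#' preparation-cluster signal at that voxel's (B0 offset, B1rel, T1rho);
#' voxels without a defined T1rho (bone, background) keep their base
#' amplitude at every TSL. Rician noise with per-channel sigma =
#' `amp_cartilage / base_snr` is then applied. Deterministic given
#' `spec$seed` (noise stream seeded at `seed + 1` so the phantom fields and
#' the noise are independent).
#'
#' @param spec a [phantom_spec()].
#' @param prep a [prep_cluster()]; its `tsl_ms` field is ignored in favour of
#'   `tsl_list_ms`.
#' @param tsl_list_ms spin-lock times of the series, ms.
#' @param noise logical; disable to obtain the noiseless series.
#' @return list with the [tsl_series()] (`series`) plus the `make_phantom()`
#'   components (`mask`, `t1rho_true`, `amplitude`, `b0`, `b1`).
#' @export
simulate_tsl_series <- function(spec, prep = prep_cluster(b1sl_hz = 500),
                                tsl_list_ms = c(0, 10, 20, 30, 40),
                                noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(prep, "prep_cluster"))
  ph <- make_phantom(spec)
  d <- spec$grid_dim
  has_t1 <- is.finite(ph$t1rho_true)
  t1 <- ph$t1rho_true[has_t1]
  dw <- ph$b0$values[has_t1]
  b1 <- ph$b1$values[has_t1]
  t2 <- if (is.null(prep$t2rho_ms)) t1 else rep_len(prep$t2rho_ms, length(t1))
  # T2rho defaults to T1rho per-voxel unless the cluster configures it
  if (identical(prep$t2rho_ms, prep$t1rho_ms)) t2 <- t1

  vols <- array(0, c(d, length(tsl_list_ms)))
  for (k in seq_along(tsl_list_ms)) {
    v <- ph$amplitude
    sig <- cluster_signal_vec(prep$mode, prep$b1sl_hz, tsl_list_ms[k],
                              t1, t2, dw, b1)
    v[has_t1] <- ph$amplitude[has_t1] * sig
    vols[, , , k] <- v
  }
  if (noise) {
    sigma <- spec$amp_cartilage / spec$base_snr
    vols <- local_seed(spec$seed + 1L, add_rician_noise(vols, sigma))
  }
  series <- tsl_series(vols, tsl_list_ms, voxel_size_mm = spec$voxel_size_mm,
                       b1sl_hz = prep$b1sl_hz)
  c(list(series = series), ph)
}
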
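# Pre-processing and voxel-wise T1rho mapping: integer-shift registration to
# the TSL = 0 volume, mono-exponential fitting (linearized and nonlinear),
# native-scale R^2 quality maps, and the display thresholds used on final
# maps.

#' Register a TSL series to a reference volume
#'
#' Aligns every volume to the reference (by default the first, TSL = 0) with
#' an integer-voxel translation chosen to maximize normalized
#' cross-correlation over a search window, evaluated on the overlapping
#' region. Sub-voxel motion is out of scope; simulated inter-TSL motion is
#' integer by construction.
#'
#' @param series a [tsl_series()] with at least 2 volumes.
#' @param reference_index index of the reference volume (default 1).
#' @param max_shift_vox length-3 search half-window in voxels.
#' @return list with `series` (registered [tsl_series()]) and `shifts`
#'   (n_volumes x 3 integer matrix of applied shifts).
#' @export
register_series <- function(series, reference_index = 1L,
                            max_shift_vox = c(5L, 5L, 1L)) {
  stopifnot(inherits(series, "tsl_series"))
  d <- dim(series$volumes)
  if (d[4] < 2) stop("need at least 2 volumes to register", call. = FALSE)
  ref <- series$volumes[, , , reference_index]
  out <- series$volumes
  shifts <- matrix(0L, d[4], 3, dimnames = list(NULL, c("x", "y", "z")))
  for (k in seq_len(d[4])) {
    if (k == reference_index) next
    vol <- series$volumes[, , , k]
    if (stats::sd(vol) == 0) {
      warning("volume ", k, " is constant; applying zero shift")
      next
    }
    best <- c(0L, 0L, 0L); best_cc <- -Inf
    for (sx in -max_shift_vox[1]:max_shift_vox[1])
      for (sy in -max_shift_vox[2]:max_shift_vox[2])
        for (sz in -max_shift_vox[3]:max_shift_vox[3]) {
          cc <- overlap_ncc(ref, vol, c(sx, sy, sz))
          if (!is.na(cc) && cc > best_cc) {
            best_cc <- cc
            best <- c(sx, sy, sz)
          }
        }
    out[, , , k] <- translate_volume(vol, best)
    shifts[k, ] <- as.integer(best)
  }
  list(series = tsl_series(out, series$tsl_ms, series$voxel_size_mm,
                           series$field_T, series$b1sl_hz),
       shifts = shifts)
}

# NCC between ref and vol translated by s, on the overlap region
overlap_ncc <- function(ref, vol, s) {
  d <- dim(ref)
  rx <- seq(max(1, 1 + s[1]), min(d[1], d[1] + s[1]))
  ry <- seq(max(1, 1 + s[2]), min(d[2], d[2] + s[2]))
  rz <- seq(max(1, 1 + s[3]), min(d[3], d[3] + s[3]))
  if (!length(rx) || !length(ry) || !length(rz)) return(NA_real_)
  a <- ref[rx, ry, rz, drop = FALSE]
  b <- vol[rx - s[1], ry - s[2], rz - s[3], drop = FALSE]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(as.vector(a), as.vector(b))
}

# integer translation, zero fill
translate_volume <- function(vol, s) {
  d <- dim(vol)
  out <- array(0, d)
  rx <- seq(max(1, 1 + s[1]), min(d[1], d[1] + s[1]))
  ry <- seq(max(1, 1 + s[2]), min(d[2], d[2] + s[2]))
  rz <- seq(max(1, 1 + s[3]), min(d[3], d[3] + s[3]))
  out[rx, ry, rz] <- vol[rx - s[1], ry - s[2], rz - s[3]]
  out
}

#' Voxel-wise mono-exponential T1rho fit
#'
#' Fits `S(TSL) = S0 * exp(-TSL / T1rho)` per masked voxel. The linearized
#' method is ordinary least squares on `log(S)` against TSL (all points
#' weighted equally); the nonlinear method is Levenberg-Marquardt least
#' squares on the exponential itself, initialized from the linearized
#' estimate. R^2 is computed on the native signal scale against the fitted
#' curve for both methods, so a quality threshold means the same thing under
#' either. Voxels with fewer than 3 usable points, nonpositive signal (for
#' the log fit), or a non-decaying fit are marked invalid (NaN in the maps),
#' never an error.
#'
#' @param series a [tsl_series()] with >= 3 distinct TSLs.
#' @param mask logical 3D array or [region_mask()]; voxels to fit.
#' @param method `"linearized"` or `"nonlinear"`.
#' @return An object of class `t1rho_result`: list with 3D maps `t1rho_ms`,
#'   `s0`, `r2` (NaN where invalid) and logical `valid`, plus `method` and
#'   `tsl_ms`.
#' @export
fit_t1rho <- function(series, mask, method = c("linearized", "nonlinear")) {
  stopifnot(inherits(series, "tsl_series"))
  method <- match.arg(method)
  d <- dim(series$volumes)
  if (length(unique(series$tsl_ms)) < 3) {
    stop("need at least 3 distinct TSLs", call. = FALSE)
  }
  sel <- mask_as_logical(mask, d[1:3])
  nvox <- prod(d[1:3])
  idx <- which(sel)
  tsl <- series$tsl_ms
  nt <- length(tsl)
  # signals as nt x nvox_masked matrix
  sig <- vapply(seq_len(nt), function(k) series$volumes[idx + (k - 1L) * nvox],
                numeric(length(idx)))
  sig <- t(sig)

  t1rho <- s0 <- r2 <- array(NaN, d[1:3])
  valid <- array(FALSE, d[1:3])

  ok <- colSums(sig > 0 & is.finite(sig)) == nt
  if (any(ok)) {
    y <- log(sig[, ok, drop = FALSE])
    xc <- tsl - mean(tsl)
    slope <- colSums(xc * y) / sum(xc^2)
    inter <- colMeans(y) - slope * mean(tsl)
    t1_lin <- -1 / slope
    s0_lin <- exp(inter)
    good <- is.finite(t1_lin) & t1_lin > 0
    est_t1 <- t1_lin
    est_s0 <- s0_lin
    if (method == "nonlinear") {
      cols <- which(good)
      for (j in cols) {
        yj <- sig[, j]
        fit <- tryCatch(
          minpack.lm::nlsLM(yj ~ a * exp(-tsl / b),
                            start = list(a = s0_lin[j], b = t1_lin[j]),
                            lower = c(0, 1e-3),
                            control = minpack.lm::nls.lm.control(maxiter = 100)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          cf <- stats::coef(fit)
          est_s0[j] <- cf[["a"]]
          est_t1[j] <- cf[["b"]]
        }
      }
      good <- good & is.finite(est_t1) & est_t1 > 0
    }
    fitted <- outer(-tsl, 1 / est_t1) # nt x n
    fitted <- exp(sweep(fitted, 2, log(est_s0), `+`))
    ss_res <- colSums((sig[, ok, drop = FALSE] - fitted)^2)
    ss_tot <- colSums(sweep(sig[, ok, drop = FALSE], 2,
                            colMeans(sig[, ok, drop = FALSE]))^2)
    r2v <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NaN)
    vox <- idx[ok]
    t1rho[vox[good]] <- est_t1[good]
    s0[vox[good]] <- est_s0[good]
    r2[vox[good]] <- r2v[good]
    valid[vox[good]] <- TRUE
  }
  structure(list(t1rho_ms = t1rho, s0 = s0, r2 = r2, valid = valid,
                 method = method, tsl_ms = tsl,
                 voxel_size_mm = series$voxel_size_mm),
            class = "t1rho_result")
}

#' @export
print.t1rho_result <- function(x, ...) {
  v <- x$t1rho_ms[x$valid]
  cat("<t1rho_result> ", sum(x$valid), " valid voxels (", x$method, " fit), ",
      sprintf("median T1rho %.1f ms, median R^2 %.3f\n",
              stats::median(v), stats::median(x$r2[x$valid])), sep = "")
  invisible(x)
}

#' Apply display thresholds to a fitted map
#'
#' Reproduces the display conventions used on final maps: voxels with R^2
#' below `r2_floor` are removed (NaN), and T1rho values above
#' `t1rho_ceiling_ms` are set to zero. The underlying result is untouched;
#' this returns a display copy only.
#'
#' @param result a [fit_t1rho()] result.
#' @param r2_floor minimum R^2 shown (default 0.8).
#' @param t1rho_ceiling_ms values above this are zeroed (default 300 ms).
#' @return 3D display map (ms; NaN where hidden).
#' @export
apply_display_rules <- function(result, r2_floor = 0.8, t1rho_ceiling_ms = 300) {
  stopifnot(inherits(result, "t1rho_result"))
  disp <- result$t1rho_ms
  disp[!result$valid] <- NaN
  disp[is.finite(result$r2) & result$r2 < r2_floor] <- NaN
  disp[is.finite(disp) & disp > t1rho_ceiling_ms] <- 0
  disp
}

#' ROI summary of fitted T1rho
#'
#' Mean, s.d. and voxel count of valid fitted T1rho over a region of
#' interest.
#'
#' @param result a [fit_t1rho()] result.
#' @param roi logical 3D array, or a [region_mask()] combined with `zones` /
#'   `sides` selectors.
#' @param zones,sides forwarded to [mask_select()] when `roi` is a
#'   [region_mask()].
#' @return tibble with columns `mean_ms`, `sd_ms`, `n`.
#' @export
roi_mean_t1rho <- function(result, roi, zones = c("deep", "middle", "superficial"),
                           sides = NULL) {
  stopifnot(inherits(result, "t1rho_result"))
  sel <- if (inherits(roi, "region_mask")) mask_select(roi, zones, sides)
         else mask_as_logical(roi, dim(result$t1rho_ms))
  v <- result$t1rho_ms[sel & result$valid]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no valid fitted voxels in ROI", call. = FALSE)
  tibble::tibble(mean_ms = mean(v), sd_ms = if (length(v) > 1) stats::sd(v) else NA_real_,
                 n = length(v))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a voxel-wise fit into a tibble
#'
#' One row per fitted (valid) voxel with its grid coordinates, estimates and
#' fit quality.
#'
#' @param x a `t1rho_result`.
#' @param ... unused.
#' @return tibble with columns `x`, `y`, `z`, `t1rho_ms`, `s0`, `r2`.
#' @method tidy t1rho_result
#' @export
tidy.t1rho_result <- function(x, ...) {
  idx <- which(x$valid, arr.ind = TRUE)
  t1 <- x$t1rho_ms[x$valid]
  s0 <- x$s0[x$valid]
  r2 <- x$r2[x$valid]
  tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                 t1rho_ms = t1, s0 = s0, r2 = r2)
}

#' One-row summary of a voxel-wise fit
#'
#' @param x a `t1rho_result`.
#' @param ... unused.
#' @return tibble with voxel counts and median/mean estimates.
#' @method glance t1rho_result
#' @export
glance.t1rho_result <- function(x, ...) {
  v <- x$t1rho_ms[x$valid]
  tibble::tibble(n_valid = sum(x$valid),
                 median_t1rho_ms = stats::median(v),
                 mean_t1rho_ms = mean(v),
                 median_r2 = stats::median(x$r2[x$valid]),
                 method = x$method)
}

#' Plot one slice of a fitted T1rho map
#'
#' ggplot2 raster view of the display-thresholded map for a chosen slice.
#'
#' @param result a [fit_t1rho()] result.
#' @param slice z index (default middle slice).
#' @param r2_floor,t1rho_ceiling_ms forwarded to [apply_display_rules()].
#' @return a ggplot object.
#' @export
plot_t1rho_map <- function(result, slice = NULL, r2_floor = 0.8,
                           t1rho_ceiling_ms = 300) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  disp <- apply_display_rules(result, r2_floor, t1rho_ceiling_ms)
  if (is.null(slice)) slice <- ceiling(dim(disp)[3] / 2)
  sl <- disp[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$t1rho_ms <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$t1rho_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = "T1ρ (ms)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("T1ρ map, slice %d", slice))
}
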
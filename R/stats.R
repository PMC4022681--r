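# Reliability and image-quality statistics: Rician-corrected SNR, ICC with
# F-based 95% CI (two-way random, absolute agreement, single measures),
# Pearson correlation, test-retest coefficient of variation, Welch's t from
# summary statistics, and the SNR decay projection.

#' Rician magnitude-noise s.d. factor
#'
#' For complex Gaussian noise of per-channel s.d. sigma, the background of a
#' magnitude image is Rayleigh distributed with s.d.
#' `sigma * sqrt(2 - pi/2) ~= 0.655 sigma`; dividing a signal/background-s.d.
#' ratio by that factor is equivalent to multiplying the apparent SNR by
#' 0.655 to express it against the true per-channel sigma.
#' @export
RICIAN_SD_FACTOR <- sqrt(2 - pi / 2)

#' Rician-corrected SNR
#'
#' SNR of a magnitude image computed as the mean of a signal ROI over the
#' s.d. of each background-noise ROI, multiplied by 0.655 to account for the
#' Rician distribution of magnitude noise, and averaged over the noise ROIs
#' (protocol: four).
#'
#' @param signal_roi numeric vector of signal-ROI voxel values.
#' @param noise_roi_sds numeric vector of background-ROI standard deviations
#'   (one per noise ROI).
#' @param rician_factor the correction factor (default 0.655).
#' @return scalar SNR.
#' @export
snr <- function(signal_roi, noise_roi_sds, rician_factor = 0.655) {
  if (!length(signal_roi)) stop("empty signal ROI", call. = FALSE)
  if (!length(noise_roi_sds)) stop("no noise ROI s.d. given", call. = FALSE)
  if (any(noise_roi_sds <= 0)) stop("noise ROI s.d. must be > 0", call. = FALSE)
  mean(rician_factor * mean(signal_roi) / noise_roi_sds)
}

#' Projected SNR after spin-lock decay
#'
#' `base_snr * exp(-tsl/t1rho)`: the SNR expected of a T1rho-weighted image
#' at spin-lock time `tsl_ms` given the SNR of the TSL = 0 base image.
#'
#' @param base_snr SNR at TSL = 0.
#' @param t1rho_ms tissue T1rho, ms.
#' @param tsl_ms spin-lock time, ms.
#' @return projected SNR.
#' @export
snr_decay_projection <- function(base_snr, t1rho_ms, tsl_ms) {
  stopifnot(base_snr > 0, t1rho_ms > 0, tsl_ms >= 0)
  base_snr * exp(-tsl_ms / t1rho_ms)
}

#' Test-retest ICC (two-way random, absolute agreement, single measures)
#'
#' McGraw & Wong's ICC(A,1) from paired measurements: with between-subject,
#' between-session and residual mean squares MSR, MSC, MSE (k = 2 sessions,
#' n subjects), `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The 95% CI uses the F-based interval with Satterthwaite degrees of
#' freedom; the p-value tests ICC = 0 via `F = MSR/MSE` on
#' `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param test numeric vector, first-session values per subject.
#' @param retest numeric vector, second-session values (paired).
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `icc_fit` (use [tidy()]/[glance()] or access
#'   `$icc`, `$ci_low`, `$ci_high`, `$p`).
#' @export
icc_absolute <- function(test, retest, conf_level = 0.95) {
  stopifnot(length(test) == length(retest))
  ok <- is.finite(test) & is.finite(retest)
  test <- test[ok]; retest <- retest[ok]
  n <- length(test)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  x <- cbind(test, retest)
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot <= 0) stop("zero total variance; ICC undefined", call. = FALSE)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  nu <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, nu)
  f_u <- stats::qf(1 - alpha / 2, nu, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  f0 <- msr / mse
  p <- stats::pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high, p = p,
                 n = n, k = k, msr = msr, msc = msc, mse = mse,
                 conf_level = conf_level),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f, %d%% CI [%.3f, %.3f], p = %.3g (n = %d)\n",
              x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' @rdname icc_absolute
#' @param x an `icc_fit`.
#' @param ... unused.
#' @method tidy icc_fit
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 p.value = x$p, n = x$n)
}

#' @rdname icc_absolute
#' @method glance icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 p.value = x$p, msr = x$msr, msc = x$msc, mse = x$mse,
                 n = x$n, conf_level = x$conf_level)
}

#' Pearson correlation of paired sessions
#'
#' Product-moment correlation with a two-sided p-value. Note the documented
#' contrast with [icc_absolute()]: a perfect linear relation with offset or
#' slope (e.g. `retest = 2*test + 1`) gives r = 1 but ICC < 1, because ICC
#' measures absolute agreement.
#'
#' @param test,retest paired numeric vectors, n >= 3.
#' @return tibble with columns `r`, `p.value`, `n`.
#' @export
pearson_testretest <- function(test, retest) {
  stopifnot(length(test) == length(retest), length(test) >= 3)
  ct <- stats::cor.test(test, retest, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p.value = ct$p.value, n = length(test))
}

#' Test-retest coefficient of variation
#'
#' Per subject, `CV = sd(pair) / mean(pair) * 100` using the two-measurement
#' (n-1 denominator) s.d.; the summary is the mean and s.d. of the per-subject
#' CVs.
#'
#' @param test,retest paired positive numeric vectors.
#' @return list with `cv_percent` (per-subject vector) and `summary`
#'   (tibble: `cv_mean`, `cv_sd`, `n`).
#' @export
cv_testretest <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  if (any(test <= 0) || any(retest <= 0)) {
    stop("CV requires positive measurements", call. = FALSE)
  }
  cv <- vapply(seq_along(test), function(i) {
    pair <- c(test[i], retest[i])
    stats::sd(pair) / mean(pair) * 100
  }, numeric(1))
  list(cv_percent = cv,
       summary = tibble::tibble(cv_mean = mean(cv), cv_sd = stats::sd(cv),
                                n = length(cv)))
}

#' Group summary (mean, s.d., n)
#'
#' @param mean group mean.
#' @param sd group s.d. (>= 0).
#' @param n group size (>= 2).
#' @return An object of class `summary_group`.
#' @export
summary_group <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = as.integer(n)), class = "summary_group")
}

#' Welch's t-test from summary statistics
#'
#' Unequal-variance two-sample t-test computed from (mean, s.d., n) summaries
#' with Satterthwaite degrees of freedom and a two-sided p-value. When both
#' s.d.s are zero and the means equal, p = 1 by convention.
#'
#' @param a,b [summary_group()] objects (or lists with mean/sd/n).
#' @return tibble with columns `t`, `df`, `p.value`, `mean_diff`.
#' @export
welch_t_from_summary <- function(a, b) {
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (va + vb == 0) {
    same <- a$mean == b$mean
    return(tibble::tibble(t = if (same) 0 else Inf * sign(a$mean - b$mean),
                          df = a$n + b$n - 2, p.value = if (same) 1 else 0,
                          mean_diff = a$mean - b$mean))
  }
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  tibble::tibble(t = t, df = df, p.value = p, mean_diff = a$mean - b$mean)
}

#' Test-retest reliability report by region
#'
#' Runs the full reliability panel (ICC with CI, Pearson r, CV) per group of
#' a long data frame of paired session measurements.
#'
#' @param data data frame with one row per subject x region.
#' @param test,retest names of the two session-value columns.
#' @param by character vector of grouping columns (e.g. facet, side).
#' @return tibble, one row per group: `n`, `icc`, `ci_low`, `ci_high`,
#'   `icc_p`, `pearson_r`, `pearson_p`, `cv_mean`, `cv_sd`.
#' @export
reliability_report <- function(data, test = "test", retest = "retest",
                               by = character()) {
  data <- as.data.frame(data)
  groups <- if (length(by)) split(data, data[by], drop = TRUE) else list(all = data)
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    ic <- icc_absolute(d[[test]], d[[retest]])
    pr <- pearson_testretest(d[[test]], d[[retest]])
    cv <- cv_testretest(d[[test]], d[[retest]])
    out <- tibble::tibble(n = ic$n, icc = ic$icc, ci_low = ic$ci_low,
                          ci_high = ic$ci_high, icc_p = ic$p,
                          pearson_r = pr$r, pearson_p = pr$p.value,
                          cv_mean = cv$summary$cv_mean, cv_sd = cv$summary$cv_sd)
    if (length(by)) {
      key <- d[1, by, drop = FALSE]
      rownames(key) <- NULL
      out <- tibble::as_tibble(cbind(key, out))
    }
    out
  })
  do.call(rbind, rows)
}
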
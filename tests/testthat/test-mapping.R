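# Registration, voxel-wise fitting, display rules, ROI statistics.

# small noiseless series with known T1rho
exp_series <- function(t1rho = 40, s0 = 100, tsl = c(0, 10, 20, 30, 40),
                       dims = c(4, 4, 1)) {
  vols <- array(0, c(dims, length(tsl)))
  for (k in seq_along(tsl)) vols[, , , k] <- s0 * exp(-tsl[k] / t1rho)
  tsl_series(vols, tsl)
}

test_that("integer-shift registration recovers constructed translations", {
  set.seed(4)
  base <- array(0, c(24, 24, 3))
  base[8:16, 6:14, 2] <- 5
  base <- base + array(abs(rnorm(length(base), 1, 0.1)), dim(base))
  shifted <- rotaframe:::translate_volume(base, c(2, 3, 0))
  vols <- array(0, c(dim(base), 2))
  vols[, , , 1] <- base
  vols[, , , 2] <- shifted
  reg <- register_series(tsl_series(vols, c(0, 10)))
  expect_equal(reg$shifts[2, ], c(x = -2L, y = -3L, z = 0L))
  expect_equal(reg$series$volumes[5:20, 5:20, , 2], base[5:20, 5:20, ],
               tolerance = 1e-12)

  # identical volumes give zero shifts
  vols[, , , 2] <- base
  reg <- register_series(tsl_series(vols, c(0, 10)))
  expect_equal(unname(reg$shifts), matrix(0L, 2, 3))

  # constant volume: zero shift with a warning
  vols[, , , 2] <- 1
  expect_warning(reg <- register_series(tsl_series(vols, c(0, 10))), "constant")
  expect_equal(unname(reg$shifts[2, ]), c(0L, 0L, 0L))
})

test_that("shift recovery stays exact on a noisy phantom", {
  spec <- test_phantom_spec(base_snr = 90)
  sim <- simulate_tsl_series(spec, tsl_list_ms = c(0, 20, 40))
  vols <- sim$series$volumes
  true_shift <- c(4, -5, 0)
  vols[, , , 3] <- rotaframe:::translate_volume(vols[, , , 3], true_shift)
  # in-plane search: the extruded phantom is ambiguous through-plane
  reg <- register_series(tsl_series(vols, c(0, 20, 40)),
                         max_shift_vox = c(5L, 5L, 0L))
  expect_equal(unname(reg$shifts[3, ]), -true_shift)
})

test_that("noiseless mono-exponential fits are exact for both methods", {
  s <- exp_series(t1rho = 40, s0 = 100)
  mask <- array(TRUE, c(4, 4, 1))
  for (m in c("linearized", "nonlinear")) {
    fit <- fit_t1rho(s, mask, method = m)
    expect_true(all(fit$valid))
    expect_equal(fit$t1rho_ms[1, 1, 1], 40, tolerance = 1e-6)
    expect_equal(fit$s0[1, 1, 1], 100, tolerance = 1e-4)
    expect_equal(fit$r2[1, 1, 1], 1, tolerance = 1e-10)
  }
})

test_that("degenerate voxels are flagged invalid, not fatal", {
  s <- exp_series()
  vols <- s$volumes
  vols[2, 2, 1, 3:5] <- 0   # only two usable points
  s2 <- tsl_series(vols, s$tsl_ms)
  fit <- fit_t1rho(s2, array(TRUE, c(4, 4, 1)))
  expect_false(fit$valid[2, 2, 1])
  expect_true(is.nan(fit$t1rho_ms[2, 2, 1]))
  expect_true(fit$valid[1, 1, 1])
  expect_error(fit_t1rho(exp_series(tsl = c(0, 20), dims = c(2, 2, 1)),
                         array(TRUE, c(2, 2, 1))), "3 distinct")
})

test_that("fit is scale-invariant and TSL-permutation-invariant", {
  s <- exp_series(t1rho = 35, s0 = 10)
  mask <- array(TRUE, c(4, 4, 1))
  f1 <- fit_t1rho(s, mask)
  s_scaled <- tsl_series(s$volumes * 7.3, s$tsl_ms)
  f2 <- fit_t1rho(s_scaled, mask)
  expect_equal(f2$t1rho_ms, f1$t1rho_ms, tolerance = 1e-8)
  expect_equal(f2$s0, f1$s0 * 7.3, tolerance = 1e-8)

  perm <- c(3, 1, 5, 2, 4)
  # permuting acquisition order with matching volumes changes nothing once
  # the series is expressed in increasing-TSL order again
  vols_perm <- s$volumes[, , , perm, drop = FALSE][, , , order(perm), drop = FALSE]
  f3 <- fit_t1rho(tsl_series(vols_perm, s$tsl_ms), mask)
  expect_equal(f3$t1rho_ms, f1$t1rho_ms)
})

test_that("linearized and nonlinear agree within 1% at SNR 90", {
  set.seed(31)
  n <- 2000
  tsl <- c(0, 10, 20, 30, 40)
  truth <- 45
  sig <- sapply(tsl, function(t) {
    add_rician_noise(rep(exp(-t / truth), n), 1 / 90)
  })
  vols <- array(t(sig), c(length(tsl), n, 1, 1))
  vols <- aperm(vols, c(2, 3, 4, 1))
  s <- tsl_series(vols, tsl)
  mask <- array(TRUE, c(n, 1, 1))
  lin <- fit_t1rho(s, mask, "linearized")
  nl <- fit_t1rho(s, mask, "nonlinear")
  m_lin <- median(lin$t1rho_ms[lin$valid])
  m_nl <- median(nl$t1rho_ms[nl$valid])
  expect_lt(abs(m_lin - m_nl) / m_nl, 0.01)
  expect_lt(abs(m_nl - truth) / truth, 0.03)
})

test_that("display rules hide low-R2 voxels and zero implausible values", {
  s <- exp_series()
  fit <- fit_t1rho(s, array(TRUE, c(4, 4, 1)))
  fit$r2[1, 1, 1] <- 0.75
  fit$t1rho_ms[2, 1, 1] <- 350
  disp <- apply_display_rules(fit, r2_floor = 0.8, t1rho_ceiling_ms = 300)
  expect_true(is.nan(disp[1, 1, 1]))       # below the R2 floor: not displayed
  expect_equal(disp[2, 1, 1], 0)           # above the ceiling: zeroed
  expect_equal(disp[3, 3, 1], fit$t1rho_ms[3, 3, 1])
  # untouched underlying result
  expect_equal(fit$t1rho_ms[2, 1, 1], 350)
  # all-clean result displays unchanged
  fit2 <- fit_t1rho(s, array(TRUE, c(4, 4, 1)))
  expect_equal(apply_display_rules(fit2), fit2$t1rho_ms)
})

test_that("ROI means recover a focal lesion at 113 ms", {
  spec <- test_phantom_spec(base_snr = 90)
  sim <- simulate_tsl_series(spec)
  # implant a focal lesion in the superficial zone: T1rho 113 ms
  lesion <- mask_select(sim$mask, "superficial")
  lesion <- lesion & slice.index(lesion, 1) <= 32
  t1 <- sim$t1rho_true
  t1[lesion] <- 113
  spec113 <- spec
  sim2 <- simulate_tsl_series(spec, noise = FALSE)
  # rebuild signals with the lesion and renoise
  vols <- sim2$series$volumes
  prep <- prep_cluster("compensated", 500)
  nvox <- prod(dim(t1)[1:3])
  idx <- which(lesion)
  for (k in seq_along(sim2$series$tsl_ms)) {
    sig <- rotaframe:::cluster_signal_vec("compensated", 500,
                                          sim2$series$tsl_ms[k],
                                          t1[idx], t1[idx],
                                          sim2$b0$values[idx], sim2$b1$values[idx])
    vols[idx + (k - 1) * nvox] <- sim2$amplitude[idx] * sig
  }
  set.seed(77)
  vols <- add_rician_noise(vols, spec$amp_cartilage / 90)
  s <- tsl_series(vols, sim2$series$tsl_ms)
  fit <- fit_t1rho(s, lesion)
  res <- roi_mean_t1rho(fit, lesion)
  expect_equal(res$mean_ms, 113, tolerance = 2 / 113 * 113)  # within ~2 ms
  expect_gt(res$n, 10)
  # uniform ROI sanity and empty-ROI error
  su <- exp_series(t1rho = 44)
  fu <- fit_t1rho(su, array(TRUE, c(4, 4, 1)))
  expect_equal(roi_mean_t1rho(fu, array(TRUE, c(4, 4, 1)))$mean_ms, 44,
               tolerance = 1e-6)
  expect_error(roi_mean_t1rho(fu, array(FALSE, c(4, 4, 1))), "no valid")
})

test_that("per-zone median recovery within 3% under study conditions, and
           the uncompensated cluster at 139 Hz biases deep/middle zones", {
  spec <- phantom_spec(base_snr = 90, seed = 17L)
  sim <- simulate_tsl_series(spec, prep_cluster("compensated", 500))
  fit <- fit_t1rho(sim$series, mask_select(sim$mask))
  truth <- spec$zone_t1rho_ms
  for (z in names(truth)) {
    est <- median(fit$t1rho_ms[mask_select(sim$mask, z) & fit$valid])
    expect_lt(abs(est - truth[[z]]) / truth[[z]], 0.03)
  }

  # scanner-prescan regime: bulk 139 Hz offset, simple cluster
  spec_off <- phantom_spec(base_snr = 90, seed = 17L, b0_bulk_hz = 139)
  sim_s <- simulate_tsl_series(spec_off, prep_cluster("simple", 500))
  fit_s <- fit_t1rho(sim_s$series, mask_select(sim_s$mask))
  sim_c <- simulate_tsl_series(spec_off, prep_cluster("compensated", 500))
  fit_c <- fit_t1rho(sim_c$series, mask_select(sim_c$mask))
  for (z in c("deep", "middle")) {
    sel <- function(f, s) median(f$t1rho_ms[mask_select(s$mask, z) & f$valid])
    bias_simple <- abs(sel(fit_s, sim_s) - truth[[z]])
    bias_comp <- abs(sel(fit_c, sim_c) - truth[[z]])
    expect_gt(bias_simple, bias_comp)
  }
})

test_that("tidy and glance summarize fits as tibbles", {
  fit <- fit_t1rho(exp_series(), array(TRUE, c(4, 4, 1)))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("x", "y", "z", "t1rho_ms", "s0", "r2"))
  expect_equal(nrow(td), 16)
  gl <- glance(fit)
  expect_equal(gl$n_valid, 16)
  expect_equal(gl$median_t1rho_ms, 40, tolerance = 1e-6)
})
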
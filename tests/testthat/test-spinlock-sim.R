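# Rotating-frame Bloch simulation and the synthetic phantom.

test_that("hard pulses rotate as expected and conserve |m|", {
  m0 <- c(0, 0, 1)
  expect_equal(hard_pulse_rotation(m0, 90, 0), c(0, -1, 0), tolerance = 1e-12)
  expect_equal(hard_pulse_rotation(m0, 360, 0), m0, tolerance = 1e-12)
  m <- hard_pulse_rotation(m0, 90, 0, b1rel = 0.9)  # effective flip 81 deg
  expect_equal(m[3], cos(81 * pi / 180), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:50) {
    m <- rnorm(3); m <- m / sqrt(sum(m^2))
    out <- hard_pulse_rotation(m, runif(1, 0, 360), runif(1, 0, 360),
                               runif(1, 0.5, 1.5))
    expect_equal(sqrt(sum(out^2)), 1, tolerance = 1e-9)
  }
})

test_that("spin-lock evolution matches the closed forms", {
  prep <- prep_cluster("compensated", b1sl_hz = 500, t1rho_ms = 40)
  # m along lock axis, on resonance: pure mono-exponential decay
  m <- spinlock_evolve(c(1, 0, 0), prep, dw_hz = 0, b1rel = 1,
                       lock_phase_deg = 0, duration_ms = 40)
  expect_equal(m, c(exp(-1), 0, 0), tolerance = 1e-12)
  # zero duration is the identity
  expect_equal(spinlock_evolve(c(0.3, -0.4, 0.5), prep, 25, 0.9, 45, 0),
               c(0.3, -0.4, 0.5))
  # relaxation strictly decreases the locked component
  locked <- 1
  for (t in c(5, 10, 20)) {
    mt <- spinlock_evolve(c(1, 0, 0), prep, 0, 1, 0, t)
    expect_lt(mt[1], locked)
    locked <- mt[1]
  }
})

test_that("closed-form evolution equals brute-force 1-us Bloch integration", {
  prep <- prep_cluster("compensated", b1sl_hz = 500, t1rho_ms = 40,
                       t2rho_ms = 30)
  cases <- expand.grid(dw = c(0, 50, 139, -139), b1rel = c(0.85, 1, 1.1),
                       t = c(10, 40))
  set.seed(3)
  for (i in seq_len(nrow(cases))) {
    m0 <- rnorm(3); m0 <- m0 / sqrt(sum(m0^2))
    fast <- spinlock_evolve(m0, prep, cases$dw[i], cases$b1rel[i],
                            lock_phase_deg = 90, duration_ms = cases$t[i])
    slow <- bloch_integrate_oracle(m0, 500, cases$b1rel[i], cases$dw[i],
                                   90, cases$t[i], 40, 30)
    expect_equal(fast, slow, tolerance = 1e-4)
  }
  # effective-field tilt at a patellar-scale bulk offset
  expect_equal(atan(139 / 500) * 180 / pi, 15.54, tolerance = 0.01)
})

test_that("preparation cluster reduces to exp(-TSL/T1rho) on resonance", {
  for (mode in c("compensated", "simple")) {
    p <- prep_cluster(mode, b1sl_hz = 500, tsl_ms = 20, t1rho_ms = 40)
    expect_equal(prep_cluster_signal(p, 0, 1), exp(-0.5), tolerance = 1e-12)
  }
  p0 <- prep_cluster("compensated", tsl_ms = 0, t1rho_ms = 40)
  expect_equal(prep_cluster_signal(p0, 0, 1), 1)
  # convergence to the exponential as (dw, |1 - b1rel|) -> 0
  p <- prep_cluster("compensated", 500, 20, 40)
  errs <- vapply(c(1, 0.1, 0.01), function(s) {
    max(abs(prep_cluster_signal(p, 50 * s, 1 + 0.1 * s) - exp(-0.5)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("compensated mode beats simple mode off resonance", {
  g <- expand.grid(dw = seq(-200, 200, by = 10), b1 = seq(0.85, 1.15, by = 0.05))
  pc <- prep_cluster("compensated", 500, 20, 40)
  ps <- prep_cluster("simple", 500, 20, 40)
  err_c <- max(abs(prep_cluster_signal(pc, g$dw, g$b1) - exp(-0.5)))
  err_s <- max(abs(prep_cluster_signal(ps, g$dw, g$b1) - exp(-0.5)))
  expect_lt(err_c, err_s)
})

test_that("phantom is deterministic, zoned and fits its field statistics", {
  spec <- phantom_spec(seed = 9L)
  ph1 <- make_phantom(spec)
  ph2 <- make_phantom(spec)
  expect_identical(ph1$mask$labels, ph2$mask$labels)
  expect_identical(ph1$b0$values, ph2$b0$values)

  # equal zone fractions on a 9-voxel-thick band: equal radial layers
  spec3 <- phantom_spec(zone_fractions = c(deep = 1/3, middle = 1/3,
                                           superficial = 1/3), seed = 9L)
  ph <- make_phantom(spec3)
  lab <- ph$mask$labels
  # along the central (+y) thickness profile each zone spans 3 voxels
  cx <- round(spec3$center_vox[1])
  profile <- lab[cx, , 1]
  zones <- profile[profile %in% REGION_CODES[c("deep", "middle", "superficial")]]
  expect_equal(as.vector(table(zones)), c(3, 3, 3))

  # every cartilage voxel has exactly one zone and one side
  cart <- mask_select(ph$mask)
  expect_true(all(ph$mask$side[cart] %in% SIDE_CODES[c("medial", "lateral")]))

  # b0 jitter sd 30 Hz recovered over >= 3000 cartilage voxels
  expect_gte(sum(cart), 3000)
  s <- sd(ph$b0$values[cart])
  expect_lt(abs(s - 30), 3)
  # geometry that does not fit is rejected
  expect_error(phantom_spec(grid_dim = c(32L, 32L, 2L), bone_radius_vox = 28),
               "fit")
})

test_that("noiseless simulation is the exact exponential at dw = 0", {
  spec <- test_phantom_spec(b0_jitter_sd_hz = 0, b1_jitter_sd = 0)
  sim <- simulate_tsl_series(spec, prep_cluster("compensated", 500),
                             tsl_list_ms = c(0, 10, 20, 30, 40), noise = FALSE)
  cart <- mask_select(sim$mask)
  idx <- which(cart)[1:50]
  nvox <- prod(dim(sim$series$volumes)[1:3])
  for (k in 1:5) {
    tslk <- sim$series$tsl_ms[k]
    got <- sim$series$volumes[idx + (k - 1) * nvox]
    want <- sim$amplitude[idx] * exp(-tslk / sim$t1rho_true[idx])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Rician background statistics match the Rayleigh closed forms", {
  spec <- test_phantom_spec(base_snr = 90)
  sim <- simulate_tsl_series(spec, tsl_list_ms = c(0, 10, 20, 30, 40))
  bg <- sim$mask$labels == REGION_CODES[["background"]]
  sigma <- spec$amp_cartilage / spec$base_snr
  bgvals <- sim$series$volumes[, , , 1][bg]
  expect_equal(mean(bgvals), sigma * sqrt(pi / 2), tolerance = 0.05)
  expect_equal(sd(bgvals) / sigma, sqrt(2 - pi / 2), tolerance = 0.05)
})

test_that("base SNR 240 decays to ~97 at TSL 40 for T1rho 44.1 ms", {
  spec <- phantom_spec(zone_t1rho_ms = c(deep = 44.1, middle = 44.1,
                                         superficial = 44.1),
                       base_snr = 240, b0_jitter_sd_hz = 0, b1_jitter_sd = 0,
                       seed = 5L)
  sim <- simulate_tsl_series(spec, tsl_list_ms = c(0, 10, 20, 30, 40))
  cart <- mask_select(sim$mask)
  bg <- sim$mask$labels == REGION_CODES[["background"]]
  v40 <- sim$series$volumes[, , , 5]
  # the 0.655 factor turns the background-magnitude s.d. back into the
  # per-channel sigma, so the corrected SNR is mean(signal)/sigma
  measured <- snr(v40[cart], sd(v40[bg]))
  expect_equal(measured, 240 * exp(-40 / 44.1), tolerance = 0.05 * 97)
})
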
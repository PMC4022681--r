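# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form code paths: brute-force time stepping for the Bloch
# evolution, aov()-based variance components for the ICC, and closed-form
# textbook formulas elsewhere.

# Brute-force Bloch integration during a lock segment: explicit small-step
# rotation about the instantaneous effective field plus first-order
# relaxation, default 1 microsecond steps.
bloch_integrate_oracle <- function(m, b1sl_hz, b1rel, dw_hz, lock_phase_deg,
                                   duration_ms, t1rho_ms, t2rho_ms,
                                   dt_us = 1) {
  phi <- lock_phase_deg * pi / 180
  fvec <- c(b1sl_hz * b1rel * cos(phi), b1sl_hz * b1rel * sin(phi), dw_hz)
  f <- sqrt(sum(fvec^2))
  e <- if (f > 0) fvec / f else c(cos(phi), sin(phi), 0)
  dt_ms <- dt_us / 1000
  nstep <- round(duration_ms / dt_ms)
  theta <- 2 * pi * f * dt_ms / 1000  # dt in seconds
  ct <- cos(theta); st <- sin(theta)
  d1 <- exp(-dt_ms / t1rho_ms)
  d2 <- exp(-dt_ms / t2rho_ms)
  for (i in seq_len(nstep)) {
    # rotate about e (Rodrigues)
    m <- m * ct + pracma_cross(e, m) * st + e * sum(e * m) * (1 - ct)
    # relax: parallel toward 0 with T1rho, perpendicular with T2rho
    par <- sum(m * e)
    perp <- m - par * e
    m <- par * d1 * e + perp * d2
  }
  m
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ICC(A,1) oracle from aov() variance components (random subjects and
# sessions): sigma2_r from MS_subject, sigma2_c from MS_session, sigma2_e
# residual; ICC = s2r / (s2r + s2c + s2e).
icc_oracle_aov <- function(test, retest) {
  n <- length(test)
  df <- data.frame(y = c(test, retest),
                   subj = factor(rep(seq_len(n), 2)),
                   sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  s2r <- (msr - mse) / k
  s2c <- (msc - mse) / n
  s2e <- mse
  s2r / (s2r + s2c + s2e)
}

# forward STEAM model: signals proportional to sin^3 of the flip
steam_forward <- function(alpha_deg, x_volts = 100, scale = 1) {
  s1 <- scale * sin(alpha_deg * pi / 180)^3
  s2 <- scale * sin(2 * alpha_deg * pi / 180)^3
  steam_pair(s1, max(s2, 0), x_volts)
}

# small default phantom kept cheap for unit tests
test_phantom_spec <- function(...) {
  phantom_spec(grid_dim = c(64L, 64L, 2L), bone_radius_vox = 16,
               thickness_vox = 9, fluid_thickness_vox = 2, seed = 42L, ...)
}
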
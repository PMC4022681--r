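# Rotating-frame Bloch model of the spin-lock preparation cluster.
#
# All magnetization states are dimensionless 3-vectors with equilibrium
# magnitude 1, expressed in the rotating frame: x/y transverse, z along B0.
# Rotation convention (fixed here, used consistently by the simulator and the
# test oracles): an RF field at phase phi applies a right-handed rotation
# about the axis (cos phi, sin phi, 0) via the Rodrigues formula, so a 90
# degree pulse at phase 0 takes (0,0,1) to (0,-1,0).
#
# During the spin lock the effective field is the vector sum of the RF
# amplitude b1sl*b1rel (Hz) along the lock phase and the B0 offset dw (Hz)
# along z. The magnetization component parallel to the effective field
# relaxes toward 0 with T1rho; the perpendicular component precesses at the
# effective-field frequency and relaxes with T2rho. Equilibrium regrowth
# during the (short) lock is neglected, and the hard pulses are treated as
# instantaneous rotations (no relaxation or off-resonance during pulses) --
# the standard preparation-cluster approximations.

#' Spin-lock preparation cluster parameters
#'
#' @param mode `"compensated"` (rotary echo plus 180-degree refocusing,
#'   cancelling first-order B0 and B1 errors) or `"simple"` (single lock
#'   phase, the uncompensated failure mode).
#' @param b1sl_hz spin-lock amplitude in Hz (nominal, scaled by b1rel).
#' @param tsl_ms spin-lock duration in ms.
#' @param t1rho_ms relaxation time of the component along the effective field.
#' @param t2rho_ms relaxation time of the perpendicular component; defaults to
#'   `t1rho_ms` (the on-resonance signal is insensitive to this choice).
#' @return An object of class `prep_cluster`.
#' @export
prep_cluster <- function(mode = c("compensated", "simple"), b1sl_hz = 500,
                         tsl_ms = 40, t1rho_ms = 45, t2rho_ms = t1rho_ms) {
  mode <- match.arg(mode)
  if (b1sl_hz <= 0) stop("b1sl_hz must be > 0", call. = FALSE)
  if (tsl_ms < 0) stop("tsl_ms must be >= 0", call. = FALSE)
  if (t1rho_ms <= 0 || t2rho_ms <= 0) stop("relaxation times must be > 0", call. = FALSE)
  structure(list(mode = mode, b1sl_hz = b1sl_hz, tsl_ms = tsl_ms,
                 t1rho_ms = t1rho_ms, t2rho_ms = t2rho_ms),
            class = "prep_cluster")
}

# Vectorized Rodrigues rotation of a 3 x n state matrix about a transverse
# axis at phase_deg, by flip_deg * b1rel (b1rel may be length n).
rotate_state <- function(m, flip_deg, phase_deg, b1rel = 1) {
  theta <- flip_deg * b1rel * pi / 180
  phi <- phase_deg * pi / 180
  nx <- cos(phi); ny <- sin(phi)
  ct <- cos(theta); st <- sin(theta)
  mx <- m[1, ]; my <- m[2, ]; mz <- m[3, ]
  # n x m with n = (nx, ny, 0)
  cx <- ny * mz
  cy <- -nx * mz
  cz <- nx * my - ny * mx
  ndm <- nx * mx + ny * my
  rbind(mx * ct + cx * st + nx * ndm * (1 - ct),
        my * ct + cy * st + ny * ndm * (1 - ct),
        mz * ct + cz * st)
}

# Closed-form evolution during a lock segment: decompose about the effective
# field (w1 at lock phase in-plane, dw along z), relax parallel with T1rho,
# precess + relax perpendicular with T2rho. Vectorized over columns of m;
# dw_hz, b1rel, t1rho/t2rho may be length n.
evolve_state <- function(m, b1sl_hz, b1rel, dw_hz, lock_phase_deg, duration_ms,
                         t1rho_ms, t2rho_ms) {
  if (duration_ms == 0) return(m)
  w1 <- b1sl_hz * b1rel
  phi <- lock_phase_deg * pi / 180
  fx <- w1 * cos(phi); fy <- w1 * sin(phi); fz <- dw_hz + 0 * w1
  f <- sqrt(fx^2 + fy^2 + fz^2)
  # degenerate zero effective field: keep the nominal lock axis
  zero <- f < 1e-12
  ex <- ifelse(zero, cos(phi), fx / pmax(f, 1e-12))
  ey <- ifelse(zero, sin(phi), fy / pmax(f, 1e-12))
  ez <- ifelse(zero, 0, fz / pmax(f, 1e-12))
  t_s <- duration_ms / 1000
  mx <- m[1, ]; my <- m[2, ]; mz <- m[3, ]
  par <- mx * ex + my * ey + mz * ez
  px <- mx - par * ex; py <- my - par * ey; pz <- mz - par * ez
  theta <- 2 * pi * f * t_s
  ct <- cos(theta); st <- sin(theta)
  # e x p
  cx <- ey * pz - ez * py
  cy <- ez * px - ex * pz
  cz <- ex * py - ey * px
  e1 <- exp(-duration_ms / t1rho_ms)
  e2 <- exp(-duration_ms / t2rho_ms)
  rbind(par * e1 * ex + (px * ct + cx * st) * e2,
        par * e1 * ey + (py * ct + cy * st) * e2,
        par * e1 * ez + (pz * ct + cz * st) * e2)
}

#' Instantaneous hard-pulse rotation
#'
#' Rotates a magnetization vector by `flip_deg * b1rel` degrees about the
#' transverse axis at `phase_deg`, preserving its norm. With the package's
#' sign convention a 90-degree pulse at phase 0 takes (0,0,1) to (0,-1,0).
#'
#' @param m numeric length-3 magnetization vector.
#' @param flip_deg nominal flip angle, degrees.
#' @param phase_deg RF phase, degrees (0 = x axis, 90 = y axis).
#' @param b1rel relative transmit field scaling the flip.
#' @return rotated length-3 vector.
#' @export
hard_pulse_rotation <- function(m, flip_deg, phase_deg = 0, b1rel = 1) {
  stopifnot(length(m) == 3, all(is.finite(m)))
  as.numeric(rotate_state(matrix(m, 3), flip_deg, phase_deg, b1rel))
}

#' Evolution during a spin-lock segment
#'
#' Evolves a magnetization vector about the effective field formed by the
#' (b1rel-scaled) spin-lock amplitude at `lock_phase_deg` and the B0 offset
#' `dw_hz` along z: the parallel component relaxes with T1rho, the
#' perpendicular component precesses at the effective-field frequency and
#' relaxes with T2rho. At `dw_hz = 0`, `b1rel = 1`, with `m` along the lock
#' axis, this is a pure mono-exponential decay `exp(-t/T1rho)`.
#'
#' @param m numeric length-3 magnetization vector.
#' @param prep a [prep_cluster()] (supplies b1sl and relaxation times).
#' @param dw_hz B0 offset, Hz.
#' @param b1rel relative transmit field.
#' @param lock_phase_deg lock RF phase, degrees.
#' @param duration_ms segment duration, ms (>= 0).
#' @return evolved length-3 vector.
#' @export
spinlock_evolve <- function(m, prep, dw_hz = 0, b1rel = 1, lock_phase_deg = 0,
                            duration_ms = prep$tsl_ms) {
  stopifnot(inherits(prep, "prep_cluster"), length(m) == 3, duration_ms >= 0)
  as.numeric(evolve_state(matrix(m, 3), prep$b1sl_hz, b1rel, dw_hz,
                          lock_phase_deg, duration_ms,
                          prep$t1rho_ms, prep$t2rho_ms))
}

# Vectorized full cluster from equilibrium; dw_hz, b1rel, t1rho_ms, t2rho_ms
# may be length n. Returns the retained longitudinal magnitude per element.
cluster_signal_vec <- function(mode, b1sl_hz, tsl_ms, t1rho_ms, t2rho_ms,
                               dw_hz, b1rel) {
  n <- max(length(dw_hz), length(b1rel), length(t1rho_ms))
  dw_hz <- rep_len(dw_hz, n); b1rel <- rep_len(b1rel, n)
  t1rho_ms <- rep_len(t1rho_ms, n); t2rho_ms <- rep_len(t2rho_ms, n)
  m <- rbind(numeric(n), numeric(n), rep(1, n))
  m <- rotate_state(m, 90, 0, b1rel)              # tip-down about x -> -y
  if (mode == "simple") {
    # lock along the tipped magnetization (-y, phase 270)
    m <- evolve_state(m, b1sl_hz, b1rel, dw_hz, 270, tsl_ms, t1rho_ms, t2rho_ms)
    m <- rotate_state(m, 90, 180, b1rel)          # tip-up about -x
  } else {
    # rotary echo with a central 180-degree refocusing rotation about the
    # lock axis: lock TSL/2 at +90, 180 at +90, lock TSL/2 at 270, tip-up at
    # the tip-down phase (returns the locked component to -z; the magnitude
    # readout is sign-insensitive)
    m <- evolve_state(m, b1sl_hz, b1rel, dw_hz, 90, tsl_ms / 2, t1rho_ms, t2rho_ms)
    m <- rotate_state(m, 180, 90, b1rel)
    m <- evolve_state(m, b1sl_hz, b1rel, dw_hz, 270, tsl_ms / 2, t1rho_ms, t2rho_ms)
    m <- rotate_state(m, 90, 0, b1rel)
  }
  # crusher: transverse components are spoiled; magnitude readout samples |Mz|
  abs(m[3, ])
}

#' Signal retained by the full preparation cluster
#'
#' Composes the cluster from equilibrium m = (0,0,1): tip-down, spin lock for
#' TSL (in one segment for `mode = "simple"`; as a rotary echo with a central
#' 180-degree refocusing rotation about the lock axis for
#' `mode = "compensated"`), tip-up, then a crusher that spoils the remaining
#' transverse magnetization. Returns the retained longitudinal magnitude, the
#' quantity a magnitude readout samples. On resonance with nominal B1 both
#' modes reduce to `exp(-TSL/T1rho)`; off resonance the rotary echo plus
#' refocusing cancels the first-order B0 and B1 errors that the simple mode
#' accumulates.
#'
#' @param prep a [prep_cluster()].
#' @param dw_hz B0 offset, Hz.
#' @param b1rel relative transmit field.
#' @return normalized signal in `[0, 1 + eps]`; vectorized over `dw_hz`/`b1rel`.
#' @export
prep_cluster_signal <- function(prep, dw_hz = 0, b1rel = 1) {
  stopifnot(inherits(prep, "prep_cluster"))
  cluster_signal_vec(prep$mode, prep$b1sl_hz, prep$tsl_ms,
                     prep$t1rho_ms, prep$t2rho_ms, dw_hz, b1rel)
}
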
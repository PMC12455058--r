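#' Double-rotation gradient waveform generator
#'
#' Generates self-refocusing gradient waveforms whose dephasing vector
#' q(t) is swept on a cone while its magnitude follows a smooth envelope,
#' realizing a prescribed b-tensor anisotropy b_delta and b-value. The
#' cone half-angle beta satisfies P2(cos beta) = b_delta, the second
#' Legendre polynomial, so that the time-averaged outer product of the
#' sweep direction has the requested shape: beta = 0 gives linear
#' (b_delta = 1), the magic angle gives spherical (b_delta = 0), and
#' beta = pi/2 a planar sweep (b_delta = -0.5). The q-vector magnitude
#' envelope is sin(pi t / tau), vanishing at both ends (self-refocusing),
#' and the azimuth advances by `n_osc + 2` full turns so that the first
#' and second azimuthal harmonics average to zero under the squared
#' envelope, making the realized b_delta exact up to discretization.
#' For the linear shape the direction is fixed and the oscillation count
#' instead multiplies the envelope frequency, q_z = q0 sin((2 n_osc + 1)
#' pi t / tau). Increasing `n_osc` shifts the centroid frequency
#' omega_cent upward for every shape.
#'
#' The realized b-value is fixed by rescaling the amplitude to the
#' time-domain integral of |q(t)|^2, which equals the trace of the
#' integrated b-tensor.
#'
#' @param n_osc number of extra oscillations (integer >= 0).
#' @param duration waveform duration tau in seconds.
#' @param b_delta_target target anisotropy in \[-0.5, 1\].
#' @param b_target target b-value (trace), s m^-2.
#' @param dt sampling interval, seconds.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @param g_max maximum allowed gradient amplitude, T m^-1; exceeding it
#'   is an error reporting the required amplitude.
#' @return a [gradient_waveform()] with attribute `meta` recording the
#'   generation parameters.
#' @export
double_rotation_waveform <- function(n_osc, duration, b_delta_target,
                                     b_target, dt = 1e-6,
                                     gamma = GAMMA_1H, g_max = 3) {
  if (n_osc < 0 || n_osc != round(n_osc)) stop("n_osc must be a non-negative integer")
  if (duration <= 0 || duration > 1) stop("duration outside plausible bounds (0, 1] s")
  if (b_delta_target < -0.5 || b_delta_target > 1)
    stop("b_delta_target must be in [-0.5, 1]")
  if (b_target <= 0) stop("b_target must be positive")
  tau <- duration
  n <- round(tau / dt) + 1L
  t <- (seq_len(n) - 1L) * dt
  q0 <- sqrt(2 * b_target / tau)
  if (b_delta_target >= 1 - 1e-12) {
    m <- 2 * n_osc + 1
    # q_z = q0 sin(m pi t / tau); g = dq/dt / gamma
    g <- cbind(0, 0, q0 * (m * pi / tau) * cos(m * pi * t / tau)) / gamma
    qfun <- function(tt) cbind(0, 0, q0 * sin(m * pi * tt / tau))
  } else {
    cb2 <- (2 * b_delta_target + 1) / 3
    beta <- acos(sqrt(cb2))
    k <- n_osc + 2
    wk <- 2 * pi * k / tau
    s <- sin(pi * t / tau)
    sp <- (pi / tau) * cos(pi * t / tau)
    psi <- wk * t
    sb <- sin(beta); cb <- cos(beta)
    gx <- q0 * (sp * sb * cos(psi) - s * wk * sb * sin(psi))
    gy <- q0 * (sp * sb * sin(psi) + s * wk * sb * cos(psi))
    gz <- q0 * sp * cb
    g <- cbind(gx, gy, gz) / gamma
    qfun <- function(tt) {
      ss <- sin(pi * tt / tau); ps <- wk * tt
      q0 * cbind(ss * sb * cos(ps), ss * sb * sin(ps), ss * cb)
    }
  }
  # rescale amplitude so the realized b (= int |q|^2 dt) hits the target
  qs <- qfun(t)
  w <- trapz_weights(t)
  b_real <- sum(rowSums(qs^2) * w)
  scale <- sqrt(b_target / b_real)
  g <- g * scale
  amp <- max(sqrt(rowSums(g^2)))
  if (amp > g_max)
    stop(sprintf(
      "gradient amplitude %.4g T/m exceeds g_max = %.4g T/m for the requested encoding",
      amp, g_max))
  wf <- gradient_waveform(g, dt = dt, gamma = gamma)
  attr(wf, "meta") <- list(n_osc = n_osc, duration = duration,
                           b_delta_target = b_delta_target,
                           b_target = b_target, g_amp = amp)
  wf
}

#' Maximum b-value reachable by a double-rotation waveform
#'
#' Scales from the unit-amplitude waveform: b is proportional to the
#' squared gradient amplitude, so b_max = b_ref * (g_max / g_ref)^2.
#'
#' @inheritParams double_rotation_waveform
#' @return maximum trace b-value in s m^-2.
#' @export
double_rotation_b_max <- function(n_osc, duration, b_delta_target,
                                  dt = 1e-6, gamma = GAMMA_1H, g_max = 3) {
  b_ref <- 1e6  # small reference b; amplitude scales as sqrt(b)
  wf <- double_rotation_waveform(n_osc, duration, b_delta_target, b_ref,
                                 dt = dt, gamma = gamma, g_max = Inf)
  amp <- attr(wf, "meta")$g_amp
  b_ref * (g_max / amp)^2
}
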
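# Synthetic acquisition protocols emulating the two published designs:
# a wide-frequency microimaging protocol (double-rotation waveforms,
# 0-5 oscillations, 4.5-22 ms durations, b up to 4.25e9 s m^-2, linear /
# planar / spherical shapes, variable recovery and echo times) and a
# narrow-frequency protocol in which all waveforms share one duration
# and oscillation count. These are synthetic stand-ins built from the
# published design parameters, not the published tables themselves.

# orientation sets per shape: linear encodes direction strongly, so it
# gets the most rotations; spherical is isotropic and gets one
shape_rotations <- function(b_delta) {
  if (b_delta >= 1 - 1e-9) {
    list(c(0, 0), c(pi / 2, 0), c(pi / 2, pi / 2))
  } else if (b_delta <= -0.5 + 1e-9) {
    list(c(0, 0), c(pi / 2, pi / 4))
  } else {
    list(c(0, 0))
  }
}

build_protocol_grid <- function(durations, n_oscs, b_deltas, n_b,
                                b_min, b_max_protocol, g_max, dt,
                                tau_r_diff, tau_e_offset,
                                relax_block = NULL, n_pad = 8) {
  waveforms <- list()
  rows <- list()
  for (tau in durations) {
    for (nosc in n_oscs) {
      for (bd in b_deltas) {
        b_hw <- 0.95 * double_rotation_b_max(nosc, tau, bd, dt = dt,
                                             g_max = g_max)
        b_hi <- min(b_max_protocol, b_hw)
        b_lo <- min(b_min, b_hi / 10)
        bvals <- exp(seq(log(b_lo), log(b_hi), length.out = n_b))
        id <- sprintf("wf_t%04.1fms_n%d_bd%+.1f", tau * 1e3, nosc, bd)
        waveforms[[id]] <- double_rotation_waveform(
          nosc, tau, bd, b_hi, dt = dt, g_max = g_max)
        tau_e <- max(tau_e_offset, tau + 0.004)
        for (rot in shape_rotations(bd)) {
          for (b in bvals) {
            rows[[length(rows) + 1L]] <- data.frame(
              waveform_id = id, theta = rot[1L], phi = rot[2L], psi = 0,
              b = b, tau_r = tau_r_diff, tau_e = tau_e)
          }
        }
      }
    }
  }
  tb <- do.call(rbind, rows)
  if (!is.null(relax_block)) {
    id0 <- names(waveforms)[1L]
    rb <- expand.grid(tau_r = relax_block$tau_r, tau_e = relax_block$tau_e)
    tb <- rbind(tb, data.frame(waveform_id = id0, theta = 0, phi = 0,
                               psi = 0, b = relax_block$b,
                               tau_r = rb$tau_r, tau_e = rb$tau_e))
  }
  tb$n_acq <- seq_len(nrow(tb))
  protocol(tb, waveforms = waveforms, n_pad = n_pad)
}

#' Synthetic wide-frequency microimaging protocol
#'
#' Emulates a 1491-acquisition wide-frequency design: 6 waveform
#' durations (4.5-22 ms) x 6 oscillation counts (0-5) x linear, planar
#' and spherical shapes, each with a geometric b-ramp from 0.033e9 up to
#' 4.25e9 s m^-2 (capped by the 3 T/m gradient amplitude, so the highest
#' centroid frequencies are reached at low b only), plus a 13 x 15
#' relaxation-encoding block with tau_r in 0.8-3.5 s and tau_e in
#' 13-49 ms. This is a synthetic emulation built from the published
#' design parameters; it is not the published table.
#'
#' @param dt waveform sampling interval, seconds.
#' @param g_max maximum gradient amplitude, T m^-1.
#' @param n_pad spectral zero-padding factor.
#' @return a `dr_protocol` with 1491 acquisitions.
#' @export
protocol_preclinical_like <- function(dt = 2e-6, g_max = 3, n_pad = 8) {
  build_protocol_grid(
    durations = c(4.5, 8, 11.5, 15, 18.5, 22) * 1e-3,
    n_oscs = 0:5, b_deltas = c(1, -0.5, 0), n_b = 6,
    b_min = 0.033e9, b_max_protocol = 4.25e9, g_max = g_max, dt = dt,
    tau_r_diff = 3.5, tau_e_offset = 0.013,
    relax_block = list(tau_r = seq(0.8, 3.5, length.out = 13),
                       tau_e = seq(0.013, 0.049, length.out = 15),
                       b = 0.033e9),
    n_pad = n_pad)
}

#' Reduced wide-frequency protocol for simulation studies
#'
#' A scaled-down version of the wide-frequency design (3 durations x 3
#' oscillation counts x 3 shapes x 4 b-values plus a small relaxation
#' block; about 230 acquisitions) covering the same centroid-frequency
#' and b-value ranges. Suitable for minutes-scale simulation studies.
#'
#' @inheritParams protocol_preclinical_like
#' @return a `dr_protocol`.
#' @export
protocol_wide_reduced <- function(dt = 2e-6, g_max = 3, n_pad = 8) {
  build_protocol_grid(
    durations = c(4.5, 11.5, 22) * 1e-3,
    n_oscs = c(0, 2, 5), b_deltas = c(1, -0.5, 0), n_b = 4,
    b_min = 0.033e9, b_max_protocol = 4.25e9, g_max = g_max, dt = dt,
    tau_r_diff = 3.5, tau_e_offset = 0.013,
    relax_block = list(tau_r = seq(0.8, 3.5, length.out = 4),
                       tau_e = seq(0.013, 0.049, length.out = 3),
                       b = 0.033e9),
    n_pad = n_pad)
}

#' Narrow-frequency protocol emulation
#'
#' All waveforms share one duration and zero extra oscillations, so the
#' centroid-frequency spread comes only from the shape differences — the
#' narrow-window situation of clinical tensor-valued encoding, at
#' whole-body b-values (up to 3e9 s m^-2) and relaxation times.
#'
#' @param duration shared waveform duration, seconds.
#' @inheritParams protocol_preclinical_like
#' @return a `dr_protocol`.
#' @export
protocol_narrow <- function(duration = 60e-3, dt = 2e-6, g_max = 0.3,
                            n_pad = 8) {
  build_protocol_grid(
    durations = duration, n_oscs = 0, b_deltas = c(1, -0.5, 0), n_b = 6,
    b_min = 0.1e9, b_max_protocol = 3e9, g_max = g_max, dt = dt,
    tau_r_diff = 5, tau_e_offset = 0.08,
    relax_block = list(tau_r = seq(0.5, 7.6, length.out = 4),
                       tau_e = seq(0.033, 0.15, length.out = 3),
                       b = 0.1e9),
    n_pad = n_pad)
}
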
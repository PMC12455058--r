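#' Discrete diffusion-relaxation distribution components
#'
#' A component set is a data.frame with one row per discrete component of
#' a D(omega)-R1-R2 distribution, columns in the canonical parameter
#' order: `w` (signal weight), `d_a`, `d_r` (low-frequency axial/radial
#' diffusivities, m^2 s^-1), `theta`, `phi` (symmetry-axis orientation,
#' radians), `d_0` (high-frequency isotropic diffusivity, m^2 s^-1),
#' `gamma_a`, `gamma_r` (Lorentzian transition mid-point angular
#' frequencies, rad s^-1), `r_1`, `r_2` (relaxation rates, s^-1).
#' Frequency-independent (static) components are encoded with
#' `d_0 = NA` and `gamma_a = gamma_r = Inf`, making D(omega) constant.
#'
#' @param w,d_a,d_r,theta,phi,d_0,gamma_a,gamma_r,r_1,r_2 component
#'   parameters, recycled to a common length.
#' @return data.frame of class `component_set`.
#' @export
component_set <- function(w, d_a, d_r, theta = 0, phi = 0,
                          d_0 = NA_real_, gamma_a = Inf, gamma_r = Inf,
                          r_1 = 1, r_2 = 10) {
  df <- data.frame(w = w, d_a = d_a, d_r = d_r, theta = theta, phi = phi,
                   d_0 = d_0, gamma_a = gamma_a, gamma_r = gamma_r,
                   r_1 = r_1, r_2 = r_2)
  if (any(df$w < 0)) stop("component weights must be non-negative")
  if (any(df$d_a < 0 | df$d_r < 0)) stop("diffusivities must be non-negative")
  if (any(df$gamma_a <= 0 | df$gamma_r <= 0)) stop("gamma must be positive")
  disp <- !is.na(df$d_0)
  if (any(disp & df$d_0 < pmax(df$d_a, df$d_r) * (1 - 1e-12)))
    stop("d_0 must be >= max(d_a, d_r): restriction lowers the low-frequency diffusivity")
  if (any(df$r_1 <= 0 | df$r_2 < 0)) stop("invalid relaxation rates")
  class(df) <- c("component_set", "data.frame")
  df
}

#' Is a component dispersion-free?
#'
#' TRUE when D(omega) is constant: static encoding (d_0 missing /
#' infinite gamma) or d_0 equal to both low-frequency diffusivities.
#' @param components a `component_set`.
#' @return logical vector.
#' @export
is_dispersion_free <- function(components) {
  is.na(components$d_0) |
    (is.infinite(components$gamma_a) & is.infinite(components$gamma_r)) |
    (components$d_0 == components$d_a & components$d_0 == components$d_r)
}

#' Axial and radial eigenvalue spectra of one component
#'
#' Lorentzian interpolation between the low-frequency values (d_a, d_r)
#' and the common high-frequency isotropic diffusivity d_0:
#' D_R(omega) = d_0 - (d_0 - d_r) / (1 + omega^2 / gamma_r^2) and the
#' analogous expression for D_A. Both are even in omega. Static
#' components return the constant low-frequency values.
#'
#' @param component one-row `component_set` (or list with the fields).
#' @param omega angular frequencies, rad s^-1.
#' @return list with vectors `d_a` and `d_r` (m^2 s^-1).
#' @export
eigenvalue_spectra <- function(component, omega) {
  d0 <- component$d_0
  if (is.na(d0)) {
    return(list(d_a = rep(component$d_a, length(omega)),
                d_r = rep(component$d_r, length(omega))))
  }
  # written as d + (d0 - d) * omega^2/(gamma^2 + omega^2) so that the
  # omega = 0 limit returns the low-frequency value exactly
  lor <- function(gam) if (is.infinite(gam)) rep(0, length(omega)) else
    omega^2 / (gam^2 + omega^2)
  list(
    d_a = component$d_a + (d0 - component$d_a) * lor(component$gamma_a),
    d_r = component$d_r + (d0 - component$d_r) * lor(component$gamma_r))
}

#' Diffusion tensor spectrum of one component
#'
#' D(omega) = R(theta, phi) diag(D_R, D_R, D_A) R^-1(theta, phi): an
#' axisymmetric tensor with symmetry axis
#' (sin theta cos phi, sin theta sin phi, cos theta).
#'
#' @param component one-row `component_set`.
#' @param omega a single angular frequency, rad s^-1.
#' @return symmetric 3x3 matrix.
#' @export
tensor_spectrum <- function(component, omega) {
  stopifnot(length(omega) == 1L)
  ev <- eigenvalue_spectra(component, omega)
  nvec <- c(sin(component$theta) * cos(component$phi),
            sin(component$theta) * sin(component$phi),
            cos(component$theta))
  diag(rep(ev$d_r, 3L)) + (ev$d_a - ev$d_r) * tcrossprod(nvec)
}

#' Diffusion attenuation of one component under one encoding
#'
#' Evaluates exp(-integral of b(omega) : D(omega) d omega) by the
#' trapezoid rule on the encoding's frequency grid, using the real part
#' of b(omega) (D(omega) is real, symmetric and even in omega, so the
#' imaginary part integrates to zero). For a dispersion-free component
#' this reduces exactly to exp(-b : D).
#'
#' @param encoding an `acquisition_encoding` (from
#'   [acquisition_encoding()]) or an `encoding_spectrum`.
#' @param component one-row `component_set`.
#' @return attenuation factor in (0, 1].
#' @export
attenuation <- function(encoding, component) {
  spec <- if (inherits(encoding, "acquisition_encoding")) encoding$spectrum
          else encoding
  stopifnot(inherits(spec, "encoding_spectrum"))
  ev <- eigenvalue_spectra(component, spec$omega)
  nvec <- c(sin(component$theta) * cos(component$phi),
            sin(component$theta) * sin(component$phi),
            cos(component$theta))
  bn <- as.numeric(spec$density %*% orient6(nvec))
  integrand <- ev$d_r * spec$trace + (ev$d_a - ev$d_r) * bn
  beta <- sum(integrand * trapz_weights(spec$omega))
  if (beta < -1e-10 * max(1, abs(beta)))
    stop("negative attenuation exponent: unphysical encoding/component pair")
  exp(-max(beta, 0))
}

#' Relaxation weighting factor
#'
#' \[1 - exp(-tau_r R1)\] exp(-tau_e R2): saturation-recovery longitudinal
#' weighting times transverse decay.
#'
#' @param tau_r,tau_e recovery and echo times, seconds.
#' @param r_1,r_2 relaxation rates, s^-1.
#' @return numeric factor(s) in \[0, 1\].
#' @export
relaxation_factor <- function(tau_r, tau_e, r_1, r_2) {
  (1 - exp(-tau_r * r_1)) * exp(-tau_e * r_2)
}

#' Forward signal synthesis for a protocol
#'
#' Synthesizes per-acquisition signals for a component set, either with
#' the frequency-dependent model (`mode = "omega_dependent"`, requires a
#' protocol with waveform spectra) or the frequency-independent model
#' (`mode = "static"`, uses the integrated b-tensors). In static mode,
#' components carrying dispersion (finite gamma with d_0 set) are not
#' silently flattened: set `static_dispersion = "error"` (default) to
#' reject them, or `"low_frequency"` to use the documented convention of
#' evaluating them at their low-frequency diffusivities (d_a, d_r).
#'
#' @param prot a `dr_protocol`.
#' @param components a `component_set`.
#' @param mode "omega_dependent" or "static".
#' @param static_dispersion what to do with dispersive components in
#'   static mode: "error" or "low_frequency".
#' @return numeric vector of signals aligned with the protocol rows.
#' @export
signal <- function(prot, components, mode = c("omega_dependent", "static"),
                   static_dispersion = c("error", "low_frequency")) {
  mode <- match.arg(mode)
  static_dispersion <- match.arg(static_dispersion)
  stopifnot(inherits(prot, "dr_protocol"))
  if (!inherits(components, "component_set"))
    components <- do.call(component_set, as.list(components))
  tb <- prot$table
  n <- nrow(tb)
  if (mode == "static" && static_dispersion == "error" &&
      any(!is_dispersion_free(components)))
    stop("static mode with dispersive components; set static_dispersion = ",
         "\"low_frequency\" to evaluate them at (d_a, d_r)")
  out <- numeric(n)
  for (i in seq_len(nrow(components))) {
    comp <- components[i, ]
    relax <- relaxation_factor(tb$tau_r, tb$tau_e, comp$r_1, comp$r_2)
    if (mode == "omega_dependent" && !is_dispersion_free(components)[i]) {
      if (is.null(prot$encodings))
        stop("omega-dependent synthesis requires a protocol with waveforms")
      ids <- names(prot$encodings)
      idx <- match(tb$waveform_id, ids)
      att <- numeric(n)
      for (j in seq_len(n)) {
        if (tb$b[j] <= 0) { att[j] <- 1; next }
        enc <- prot$encodings[[idx[j]]]
        # rotating the acquisition by R is equivalent to counter-rotating
        # the component axis; scale the spectrum by b_acq / b_waveform
        r <- rotation_zyz(tb$theta[j], tb$phi[j], tb$psi[j])
        nvec <- c(sin(comp$theta) * cos(comp$phi),
                  sin(comp$theta) * sin(comp$phi),
                  cos(comp$theta))
        nloc <- as.numeric(crossprod(r, nvec))
        comp_loc <- comp
        comp_loc$theta <- acos(min(1, max(-1, nloc[3L])))
        comp_loc$phi <- atan2(nloc[2L], nloc[1L])
        att[j] <- attenuation(enc, comp_loc)^(tb$b[j] / enc$b)
      }
    } else {
      nvec <- c(sin(comp$theta) * cos(comp$phi),
                sin(comp$theta) * sin(comp$phi),
                cos(comp$theta))
      bn <- as.numeric(prot$bt6 %*% orient6(nvec))
      btr <- prot$bt6[, 1L] + prot$bt6[, 2L] + prot$bt6[, 3L]
      beta <- comp$d_r * btr + (comp$d_a - comp$d_r) * bn
      att <- exp(-beta)
    }
    out <- out + comp$w * att * relax
  }
  out
}

#' Extrapolated signal S0 of a component set
#'
#' The signal extrapolated to b = 0, tau_r = Inf and tau_e = 0 is the sum
#' of the component weights.
#'
#' @param components a `component_set`.
#' @return scalar S0.
#' @export
s0 <- function(components) sum(components$w)
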
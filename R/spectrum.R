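# Symmetric 3x3 tensors are stored as length-6 vectors in the order
# (xx, yy, zz, xy, xz, yz); sym6_* convert between the representations.

sym6_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3L, 3L)
}

mat_to_sym6 <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# Contraction weights such that sum(sym6(A) * sym6_contract_weights) = A:B
# for symmetric A, B represented as sym6.
sym6_contract <- function(a6, b6) {
  sum(a6 * b6 * c(1, 1, 1, 2, 2, 2))
}

# outer-product weights for a unit vector n: sym6(b) %*% orient6(n) = n' b n
orient6 <- function(n) {
  c(n[1]^2, n[2]^2, n[3]^2, 2 * n[1] * n[2], 2 * n[1] * n[3], 2 * n[2] * n[3])
}

trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two grid points")
  w <- numeric(n)
  dx <- diff(x)
  w[1L] <- dx[1L] / 2
  w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dx[-(n - 1L)] + dx[-1L]) / 2
  w
}

#' Spectral dephasing vector q(omega)
#'
#' Finite-interval Fourier transform of the dephasing trace,
#' q(omega) = integral over the waveform duration of q(t) exp(+i omega t) dt,
#' evaluated by zero-padded FFT (rectangle rule on the sampling grid).
#' The returned two-sided angular frequency grid is symmetric and ascending.
#'
#' @param trace a `dephasing_trace` from [dephasing()].
#' @param n_pad zero-padding factor (>= 1); the FFT length is the next power
#'   of two of `n_pad` times the number of samples. Padding controls the
#'   frequency resolution of centroids and percentiles; 8 is the default.
#' @return An object of class `q_spectrum`: list with `omega` (rad s^-1),
#'   `q_omega` (complex matrix, n_freq x 3, units rad m^-1 s) and `domega`.
#' @export
q_spectrum <- function(trace, n_pad = 8) {
  stopifnot(inherits(trace, "dephasing_trace"))
  if (!is.numeric(n_pad) || n_pad < 1) stop("n_pad must be >= 1")
  n <- nrow(trace$q)
  nfft <- 2L^ceiling(log2(n * n_pad))
  dt <- trace$dt
  qf <- matrix(0 + 0i, nfft, 3L)
  for (a in 1:3) {
    padded <- c(trace$q[, a], rep(0, nfft - n))
    # fft(..., inverse = TRUE) uses the exp(+i omega t) sign convention
    qf[, a] <- stats::fft(padded, inverse = TRUE) * dt
  }
  k <- seq_len(nfft) - 1L
  k[k >= nfft / 2] <- k[k >= nfft / 2] - nfft
  omega <- 2 * pi * k / (nfft * dt)
  ord <- order(omega)
  structure(
    list(omega = omega[ord], q_omega = qf[ord, , drop = FALSE],
         domega = 2 * pi / (nfft * dt)),
    class = "q_spectrum")
}

#' Tensor-valued encoding spectrum b(omega)
#'
#' Per-frequency outer product b(omega) = q(omega) q(-omega)^T / (2 pi).
#' For a real waveform q(-omega) equals the complex conjugate of q(omega),
#' so b(omega) is Hermitian positive semidefinite; only its real part
#' (which is symmetric and even in omega) enters scalar products with the
#' real, even diffusion spectra and is what is stored.
#'
#' @param qspec a `q_spectrum`.
#' @return An object of class `encoding_spectrum`: list with `omega`,
#'   `density` (n_freq x 6 matrix, sym6 order, s m^-2 per (rad s^-1)) and
#'   `trace` (per-frequency trace).
#' @export
b_spectrum <- function(qspec) {
  stopifnot(inherits(qspec, "q_spectrum"))
  q <- qspec$q_omega
  cq <- Conj(q)
  dens <- cbind(
    Re(q[, 1] * cq[, 1]), Re(q[, 2] * cq[, 2]), Re(q[, 3] * cq[, 3]),
    Re(q[, 1] * cq[, 2]), Re(q[, 1] * cq[, 3]), Re(q[, 2] * cq[, 3])
  ) / (2 * pi)
  structure(
    list(omega = qspec$omega, density = dens,
         trace = dens[, 1] + dens[, 2] + dens[, 3],
         domega = qspec$domega),
    class = "encoding_spectrum")
}

#' Integrated b-tensor
#'
#' Integrates the encoding spectrum over the two-sided frequency grid with
#' the trapezoid rule, yielding the conventional diffusion-encoding tensor
#' b (symmetric 3x3, s m^-2).
#'
#' @param spectrum an `encoding_spectrum`.
#' @return symmetric 3x3 matrix.
#' @export
integrate_b <- function(spectrum) {
  stopifnot(inherits(spectrum, "encoding_spectrum"))
  w <- trapz_weights(spectrum$omega)
  sym6_to_mat(as.numeric(crossprod(spectrum$density, w)))
}

#' Scalar descriptors of a diffusion encoding
#'
#' Converts an integrated b-tensor (and optionally its encoding spectrum)
#' to the conventional scalar descriptors: b-value (trace), normalized
#' anisotropy b_delta, centroid frequency omega_cent, and the polar and
#' azimuthal angles Theta, Phi of the symmetry axis.
#'
#' The eigenvalues (b_XX, b_YY, b_ZZ) are ordered by the convention
#' |b_ZZ - b/3| >= |b_XX - b/3| >= |b_YY - b/3|, with ties broken by
#' descending eigenvalue, and b_delta = (b_ZZ - (b_YY + b_XX)/2) / b.
#' Theta is restricted to [0, pi/2] by sign-flipping the b_ZZ eigenvector
#' into the upper hemisphere; Phi is in (-pi, pi].
#'
#' For b = 0 all scalars except b itself are returned as NA (undefined),
#' never fabricated.
#'
#' @param b_tensor symmetric 3x3 b-tensor (s m^-2).
#' @param spectrum optional `encoding_spectrum` used for omega_cent, the
#'   |omega|-weighted centroid of the trace spectrum.
#' @return list with `b`, `b_delta`, `omega_cent`, `theta`, `phi`,
#'   `eigenvalues` (named b_zz, b_xx, b_yy).
#' @export
encoding_scalars <- function(b_tensor, spectrum = NULL) {
  b_tensor <- (b_tensor + t(b_tensor)) / 2
  b <- sum(diag(b_tensor))
  if (b <= 0) {
    return(list(b = b, b_delta = NA_real_, omega_cent = NA_real_,
                theta = NA_real_, phi = NA_real_,
                eigenvalues = c(b_zz = NA_real_, b_xx = NA_real_,
                                b_yy = NA_real_)))
  }
  es <- eigen(b_tensor, symmetric = TRUE)
  dev <- abs(es$values - b / 3)
  # order by deviation from b/3 (descending), ties by descending eigenvalue
  ord <- order(-dev, -es$values)
  b_zz <- es$values[ord[1L]]
  b_xx <- es$values[ord[2L]]
  b_yy <- es$values[ord[3L]]
  b_delta <- (b_zz - (b_yy + b_xx) / 2) / b
  v <- es$vectors[, ord[1L]]
  if (v[3L] < 0) v <- -v
  theta <- acos(min(1, max(-1, v[3L])))
  phi <- atan2(v[2L], v[1L])
  omega_cent <- NA_real_
  if (!is.null(spectrum)) {
    w <- trapz_weights(spectrum$omega)
    omega_cent <- sum(abs(spectrum$omega) * spectrum$trace * w) / b
  }
  list(b = b, b_delta = b_delta, omega_cent = omega_cent,
       theta = theta, phi = phi,
       eigenvalues = c(b_zz = b_zz, b_xx = b_xx, b_yy = b_yy))
}

# Crop an encoding spectrum to the symmetric frequency band holding a
# fraction `keep` of the trace mass; reduces storage and downstream
# integration cost with a documented, negligible (< 1 - keep) mass loss.
crop_spectrum <- function(spectrum, keep = 1 - 1e-10) {
  w <- trapz_weights(spectrum$omega)
  mass <- spectrum$trace * w
  total <- sum(mass)
  if (total <= 0) return(spectrum)
  ord <- order(abs(spectrum$omega))
  cum <- cumsum(mass[ord])
  cut <- which(cum >= keep * total)[1L]
  radius <- abs(spectrum$omega[ord[cut]])
  sel <- abs(spectrum$omega) <= radius * (1 + 1e-12)
  structure(
    list(omega = spectrum$omega[sel],
         density = spectrum$density[sel, , drop = FALSE],
         trace = spectrum$trace[sel], domega = spectrum$domega),
    class = "encoding_spectrum")
}

#' Full encoding characterization of a gradient waveform
#'
#' Runs the chain q(t) -> q(omega) -> b(omega) -> b and scalar descriptors
#' for one gradient waveform.
#'
#' @param waveform a [gradient_waveform()].
#' @param n_pad zero-padding factor passed to [q_spectrum()].
#' @param crop if `TRUE` (default) the stored spectrum is cropped to the
#'   symmetric band holding all but 1e-10 of the trace mass, keeping the
#'   integrated tensor accurate to that fraction while bounding memory.
#' @return An object of class `acquisition_encoding`: list with
#'   `b_tensor`, `b`, `b_delta`, `omega_cent`, `theta`, `phi`,
#'   `spectrum` (the `encoding_spectrum`) and `tau` (waveform duration).
#' @export
acquisition_encoding <- function(waveform, n_pad = 8, crop = TRUE) {
  trace <- dephasing(waveform)
  spec <- b_spectrum(q_spectrum(trace, n_pad = n_pad))
  if (crop) spec <- crop_spectrum(spec)
  bt <- integrate_b(spec)
  sc <- encoding_scalars(bt, spec)
  structure(
    c(list(b_tensor = bt, spectrum = spec, tau = waveform$tau), sc),
    class = "acquisition_encoding")
}
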
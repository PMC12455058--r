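#' Roots of the spherical-compartment eigenmode condition
#'
#' Ascending positive roots mu_k of the derivative condition of the
#' first-order spherical Bessel function, j1'(mu) = 0 (mu_1 ~ 2.0816),
#' which set the eigenmode decay rates of diffusion inside an
#' impermeable sphere.
#'
#' @param n_roots number of roots.
#' @return numeric vector of length `n_roots`.
#' @export
sphere_roots <- function(n_roots = 50) {
  j1p <- function(x) {
    # j1'(x) = j0(x) - 2 j1(x) / x
    sin(x) / x - 2 * (sin(x) / x^2 - cos(x) / x) / x
  }
  roots <- numeric(0)
  lo <- 1e-3
  step <- 0.05
  x <- lo
  while (length(roots) < n_roots) {
    x2 <- x + step
    if (sign(j1p(x)) != sign(j1p(x2))) {
      r <- stats::uniroot(j1p, c(x, x2), tol = 1e-12)$root
      if (r > 1e-2) roots <- c(roots, r)
    }
    x <- x2
  }
  roots[seq_len(n_roots)]
}

#' Restricted-diffusion spectrum of a closed sphere
#'
#' Eigenmode expansion of the apparent diffusivity spectrum for water
#' with local diffusivity D_0 confined to an impermeable sphere of
#' radius r:
#' D(omega) = sum_k B_k a_k D_0 omega^2 / ((a_k D_0)^2 + omega^2),
#' with a_k = mu_k^2 / r^2 and B_k a_k = 2 / (mu_k^2 - 2). D(0) = 0
#' (closed compartment), D -> D_0 as omega -> infinity, and D is even
#' and monotone non-decreasing in |omega|.
#'
#' @param d_0 local diffusivity, m^2 s^-1.
#' @param r sphere radius, meters.
#' @param omega angular frequencies, rad s^-1.
#' @param n_roots truncation order (>= 20 recommended; default 50).
#' @return numeric vector D(omega), m^2 s^-1.
#' @export
sphere_spectrum <- function(d_0, r, omega, n_roots = 50) {
  if (r <= 0) stop("radius must be positive")
  if (d_0 <= 0) stop("d_0 must be positive")
  mu <- sphere_roots(n_roots)
  ak_d0 <- mu^2 / r^2 * d_0
  coef <- 2 / (mu^2 - 2)
  out <- numeric(length(omega))
  for (k in seq_len(n_roots))
    out <- out + coef[k] * omega^2 / (ak_d0[k]^2 + omega^2)
  out * d_0
}

# two-point Lorentzian match: find (d_low, gamma) such that
# d_0 - (d_0 - d_low) * gamma^2 / (gamma^2 + omega^2) equals the target
# spectrum values at the two frequencies
lorentzian_two_point <- function(d_0, targets, omegas) {
  stopifnot(length(targets) == 2L, length(omegas) == 2L)
  ratio <- (d_0 - targets[1L]) / (d_0 - targets[2L])
  g2 <- (omegas[2L]^2 - ratio * omegas[1L]^2) / (ratio - 1)
  if (g2 <= 0) stop("no Lorentzian matches the two points below d_0")
  gam <- sqrt(g2)
  k1 <- g2 / (g2 + omegas[1L]^2)
  d_low <- d_0 - (d_0 - targets[1L]) / k1
  list(d_low = d_low, gamma = gam)
}

#' Ground-truth component presets
#'
#' Single-component ground truths emulating the package's reference
#' systems:
#' \describe{
#'   \item{salt}{isotropic Gaussian diffusion, D = 0.4e-9 m^2 s^-1,
#'     dispersion-free (saturated salt solution); R1 = 2, R2 = 20 s^-1.}
#'   \item{lamellar}{planar anisotropic Gaussian diffusion, D_A ~ 0 and
#'     D_R = 1.5e-9 m^2 s^-1, so (D_iso, D_delta^2) = (1.0e-9, 0.25).}
#'   \item{tumor}{isotropic restricted diffusion: Lorentzian dispersion
#'     matched to the closed-sphere spectrum with local diffusivity
#'     1.2e-9 m^2 s^-1 and radius 7 um at the two anchor frequencies
#'     (defaults 35 and 320 Hz).}
#'   \item{gm}{cortex-like restricted diffusion (sphere 0.4e-9, 4 um).}
#'   \item{gmr}{cerebellar-GM-like restricted diffusion (0.7e-9, 5 um).}
#'   \item{wm}{prolate anisotropic Gaussian diffusion with
#'     D_iso = 0.2e-9 m^2 s^-1 and D_delta^2 ~ 0.89.}
#'   \item{csf}{free-water-like isotropic Gaussian, D = 3e-9 m^2 s^-1.}
#' }
#' Relaxation rates other than the salt values are plausible choices
#' within the preclinical limits, not measured values.
#'
#' @param name preset name.
#' @param anchor_hz two anchor frequencies (Hz) for the sphere-model
#'   Lorentzian match of the restricted presets.
#' @param w total weight (signal amplitude).
#' @param overrides named list of component fields to override.
#' @return a `component_set` with one row.
#' @export
make_preset <- function(name = c("salt", "lamellar", "tumor", "wm", "gm",
                                 "gmr", "csf"),
                        anchor_hz = c(35, 320), w = 1, overrides = NULL) {
  name <- match.arg(name)
  sphere_preset <- function(d_0, r, r_1, r_2) {
    om <- 2 * pi * anchor_hz
    targets <- sphere_spectrum(d_0, r, om)
    fit <- lorentzian_two_point(d_0, targets, om)
    component_set(w = w, d_a = fit$d_low, d_r = fit$d_low, d_0 = d_0,
                  gamma_a = fit$gamma, gamma_r = fit$gamma,
                  r_1 = r_1, r_2 = r_2)
  }
  comp <- switch(name,
    salt = component_set(w = w, d_a = 0.4e-9, d_r = 0.4e-9,
                         r_1 = 2, r_2 = 20),
    lamellar = component_set(w = w, d_a = 1e-13, d_r = 1.5e-9,
                             theta = pi / 3, phi = pi / 5,
                             r_1 = 1, r_2 = 15),
    tumor = sphere_preset(1.2e-9, 7e-6, r_1 = 1.5, r_2 = 25),
    gm = sphere_preset(0.4e-9, 4e-6, r_1 = 1.2, r_2 = 30),
    gmr = sphere_preset(0.7e-9, 5e-6, r_1 = 1.2, r_2 = 30),
    wm = component_set(w = w, d_a = 0.5772e-9, d_r = 0.0113e-9,
                       theta = pi / 4, phi = 0, r_1 = 1, r_2 = 40),
    csf = component_set(w = w, d_a = 3e-9, d_r = 3e-9,
                        r_1 = 0.3, r_2 = 8))
  if (!is.null(overrides)) {
    for (nm in names(overrides)) comp[[nm]] <- overrides[[nm]]
    comp <- do.call(component_set, as.list(comp))
  }
  comp
}

#' Synthetic image-shaped dataset
#'
#' Builds a small image grid of voxels, each holding a ground-truth
#' component set (a named preset or an explicit `component_set`),
#' synthesizes per-voxel signals with the forward model, and adds noise:
#' Gaussian (S + n1) or Rician (|S + n1 + i n2|) with per-voxel
#' sigma = S0(true) / SNR. `snr = Inf` gives noiseless data.
#'
#' @param prot a `dr_protocol`.
#' @param voxels either a single preset name / `component_set` applied to
#'   every voxel, or a list with one entry per voxel.
#' @param dims spatial grid dimensions, default `c(10, 10, 1)`.
#' @param snr signal-to-noise ratio (S0 / sigma); `Inf` for noiseless.
#' @param noise "gaussian" or "rician".
#' @param seed RNG seed for the noise.
#' @param mode forward model used for synthesis.
#' @return list of class `synthetic_dataset`: `data` (array
#'   dims x n_acq), `truth` (list of component sets), `clean` (noiseless
#'   signal matrix, voxels x n_acq), `snr`, `sigma` (per-voxel), `dims`.
#' @export
synth_dataset <- function(prot, voxels = "salt", dims = c(10, 10, 1),
                          snr = Inf, noise = c("gaussian", "rician"),
                          seed = 1, mode = "omega_dependent") {
  noise <- match.arg(noise)
  if (any(snr <= 0)) stop("snr must be positive")
  nvox <- prod(dims)
  n <- nrow(prot$table)
  if (!is.list(voxels) || inherits(voxels, "component_set")) {
    comp <- if (inherits(voxels, "component_set")) voxels else
      make_preset(voxels)
    truth <- rep(list(comp), nvox)
  } else {
    if (length(voxels) != nvox)
      stop("voxels list must have one entry per voxel")
    truth <- lapply(voxels, function(v)
      if (inherits(v, "component_set")) v else make_preset(v))
  }
  clean <- matrix(0, nvox, n)
  seen <- list()
  for (v in seq_len(nvox)) {
    key <- paste(format(unlist(truth[[v]]), digits = 12), collapse = ",")
    if (is.null(seen[[key]]))
      seen[[key]] <- signal(prot, truth[[v]], mode = mode,
                            static_dispersion = "low_frequency")
    clean[v, ] <- seen[[key]]
  }
  sigma <- vapply(truth, function(tt) sum(tt$w), 0) / snr
  data <- clean
  if (is.finite(snr)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    n1 <- matrix(stats::rnorm(nvox * n), nvox, n) * sigma
    if (noise == "gaussian") {
      data <- clean + n1
    } else {
      n2 <- matrix(stats::rnorm(nvox * n), nvox, n) * sigma
      data <- sqrt((clean + n1)^2 + n2^2)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  arr <- array(t(data), dim = c(n, dims))
  arr <- aperm(arr, c(2:4, 1))
  structure(list(data = arr, truth = truth, clean = clean, snr = snr,
                 sigma = sigma, dims = dims, noise = noise, seed = seed),
            class = "synthetic_dataset")
}
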
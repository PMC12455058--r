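# Precomputed per-protocol spectral arrays for fast kernel evaluation.
#
# The attenuation exponent of an axisymmetric Lorentzian-dispersion
# component factorizes as
#   beta = d0 * b - (d0 - d_r) * I_tr(gamma_r)
#          - (d0 - d_a) * I_n(gamma_a) + (d0 - d_r) * I_n(gamma_r),
# with I_tr(g) = int K(omega; g) trace b(omega) d omega and
# I_n(g) = n' [int K(omega; g) b(omega) d omega] n, K the Lorentzian
# factor. Folding the (two-sided, trapezoid) integration weights into
# one-sided spectral arrays turns every integral into a matrix product,
# which is what makes the Monte Carlo inversion affordable.

#' Precompute the spectral kernel data of a protocol
#'
#' Interpolates all acquisition encoding spectra onto a common one-sided
#' frequency grid (the real part of b(omega) is even in omega), folds in
#' the trapezoid integration weights and the two-sided factor, and
#' rescales each acquisition so its grid-integrated trace matches its
#' exact b-value. For scalar-only protocols (no waveforms) only the
#' integrated b-tensors are stored, which supports the static model.
#'
#' @param prot a `dr_protocol`.
#' @param m number of grid points of the common frequency grid.
#' @return an object of class `protocol_kernel`.
#' @export
protocol_kernel <- function(prot, m = 256) {
  stopifnot(inherits(prot, "dr_protocol"))
  tb <- prot$table
  na <- nrow(tb)
  out <- list(b = numeric(na), tau_r = tb$tau_r, tau_e = tb$tau_e)
  if (is.null(prot$encodings)) {
    out$omega <- NULL
    out$bt6k <- prot$bt6
    out$b <- rowSums(prot$bt6[, 1:3, drop = FALSE])
    class(out) <- "protocol_kernel"
    return(out)
  }
  ids <- names(prot$encodings)
  idx <- match(tb$waveform_id, ids)
  # Common grid: a dense uniform segment resolving the spectral peaks
  # plus a log-spaced tail segment out to the band holding all but 1e-7
  # of every waveform's trace mass (spectral tails decay slowly but are
  # smooth, so sparse log spacing integrates them accurately).
  radius <- 0
  knee <- 0
  for (enc in prot$encodings) {
    sp <- enc$spectrum
    w <- trapz_weights(sp$omega)
    mass <- sp$trace * w
    ord <- order(abs(sp$omega))
    cum <- cumsum(mass[ord]) / sum(mass)
    radius <- max(radius, abs(sp$omega[ord[which(cum >= 1 - 1e-7)[1L]]]))
    knee <- max(knee, abs(sp$omega[ord[which(cum >= 0.995)[1L]]]))
  }
  knee <- min(knee * 1.25, radius)
  m1 <- ceiling(0.75 * m)
  m2 <- m - m1
  omega <- seq(0, knee, length.out = m1)
  if (m2 > 0 && radius > knee)
    omega <- c(omega,
               exp(seq(log(knee), log(radius * 1.05),
                       length.out = m2 + 1L))[-1L])
  # two-sided folding: doubling the one-sided trapezoid weights turns the
  # omega = 0 edge weight into the correct interior two-sided weight
  wts <- 2 * trapz_weights(omega)
  # per-waveform one-sided interpolated density (m x 6), rescaled to b
  base <- lapply(prot$encodings, function(enc) {
    sp <- enc$spectrum
    pos <- sp$omega >= 0
    de <- vapply(1:6, function(e)
      stats::approx(sp$omega[pos], sp$density[pos, e], xout = omega,
                    yleft = 0, yright = 0, rule = 1)$y,
      numeric(m))
    btr_grid <- sum((de[, 1] + de[, 2] + de[, 3]) * wts)
    de * (enc$b / btr_grid)
  })
  BTW <- matrix(0, na, m)
  B6W <- lapply(1:6, function(e) matrix(0, na, m))
  bt6k <- matrix(0, na, 6L)
  basis <- list(
    matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3),
    matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3),
    matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 1), 3, 3),
    matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3),
    matrix(c(0, 0, 1, 0, 0, 0, 1, 0, 0), 3, 3),
    matrix(c(0, 0, 0, 0, 0, 1, 0, 1, 0), 3, 3))
  for (j in seq_len(na)) {
    if (tb$b[j] <= 0) next
    enc <- prot$encodings[[idx[j]]]
    de <- base[[idx[j]]]
    r <- rotation_zyz(tb$theta[j], tb$phi[j], tb$psi[j])
    tr6 <- vapply(basis, function(e) mat_to_sym6(r %*% e %*% t(r)),
                  numeric(6))  # 6x6, column k = image of basis tensor k
    s <- tb$b[j] / enc$b
    rot <- de %*% t(tr6) * s  # m x 6 rotated, scaled density
    roww <- rot * wts
    BTW[j, ] <- (roww[, 1] + roww[, 2] + roww[, 3])
    for (e in 1:6) B6W[[e]][j, ] <- roww[, e]
    bt6k[j, ] <- colSums(roww)
  }
  out$omega <- omega
  out$BTW <- BTW
  out$B6W <- B6W
  out$bt6k <- bt6k
  out$b <- rowSums(bt6k[, 1:3, drop = FALSE])
  class(out) <- "protocol_kernel"
  out
}

# Kernel matrix: rows = acquisitions, columns = candidate components,
# entries = attenuation * relaxation factor.
kernel_matrix <- function(kd, comp) {
  stopifnot(inherits(kd, "protocol_kernel"))
  n <- nrow(comp)
  na <- length(kd$b)
  st <- sin(comp$theta); nx <- st * cos(comp$phi); ny <- st * sin(comp$phi)
  nz <- cos(comp$theta)
  O6 <- cbind(nx^2, ny^2, nz^2, 2 * nx * ny, 2 * nx * nz, 2 * ny * nz)
  bn <- kd$bt6k %*% t(O6)  # na x n
  beta <- outer(kd$b, comp$d_r) + bn * rep(comp$d_a - comp$d_r, each = na)
  disp <- which(!is.na(comp$d_0) &
                  !(is.infinite(comp$gamma_a) & is.infinite(comp$gamma_r)))
  if (length(disp)) {
    if (is.null(kd$omega))
      stop("frequency-dependent components require a protocol with waveforms")
    om2 <- kd$omega^2
    lorK <- function(g) {
      k <- matrix(0, length(om2), length(g))
      for (i in seq_along(g))
        k[, i] <- if (is.infinite(g[i])) 1 else g[i]^2 / (g[i]^2 + om2)
      k
    }
    KA <- lorK(comp$gamma_a[disp])
    KR <- lorK(comp$gamma_r[disp])
    ITR <- kd$BTW %*% KR
    INA <- matrix(0, na, length(disp))
    INR <- matrix(0, na, length(disp))
    for (e in 1:6) {
      oe <- O6[disp, e]
      INA <- INA + (kd$B6W[[e]] %*% KA) * rep(oe, each = na)
      INR <- INR + (kd$B6W[[e]] %*% KR) * rep(oe, each = na)
    }
    d0 <- comp$d_0[disp]
    beta[, disp] <-
      outer(kd$b, d0) -
      ITR * rep(d0 - comp$d_r[disp], each = na) -
      INA * rep(d0 - comp$d_a[disp], each = na) +
      INR * rep(d0 - comp$d_r[disp], each = na)
  }
  relax <- (1 - exp(-outer(kd$tau_r, comp$r_1))) *
    exp(-outer(kd$tau_e, comp$r_2))
  exp(-pmax(beta, 0)) * relax
}
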
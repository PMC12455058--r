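#' Gyromagnetic ratio of the proton
#'
#' Angular gyromagnetic ratio of 1H in rad s^-1 T^-1.
#' @export
GAMMA_1H <- 267522187.44

#' Construct a gradient waveform
#'
#' A gradient waveform is the effective (sign-flipped after refocusing
#' pulses) magnetic field gradient vector g(t) sampled uniformly in time.
#' All quantities are strict SI: seconds and T m^-1.
#'
#' @param samples numeric matrix with one row per time point and columns
#'   gx, gy, gz in T m^-1.
#' @param dt sampling interval in seconds.
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1.
#' @return An object of class `gradient_waveform` with fields `samples`,
#'   `dt`, `gamma` and total duration `tau = nrow(samples) * dt`.
#' @export
gradient_waveform <- function(samples, dt, gamma = GAMMA_1H) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop("waveform samples must have 3 columns (gx, gy, gz)")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds)")
  if (!all(is.finite(samples)))
    stop("waveform samples must be finite")
  if (nrow(samples) < 2L)
    stop("waveform must have at least 2 samples")
  structure(
    list(samples = unname(samples), dt = dt, gamma = gamma,
         tau = nrow(samples) * dt),
    class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("gradient_waveform: %d samples, dt = %.3g us, tau = %.3g ms, |g|max = %.3g T/m\n",
              nrow(x$samples), x$dt * 1e6, x$tau * 1e3,
              max(sqrt(rowSums(x$samples^2)))))
  invisible(x)
}

#' Dephasing vector q(t) of a gradient waveform
#'
#' Cumulative time integral of gamma * g(t), evaluated with the cumulative
#' trapezoid rule on the waveform's sampling grid. The trace starts at
#' q(0) = 0; the time grid is t_j = (j - 1) * dt for sample j.
#'
#' @param waveform a [gradient_waveform()].
#' @return An object of class `dephasing_trace` with fields `times`
#'   (seconds), `q` (matrix, rad m^-1), `dt` and `gamma`.
#' @export
dephasing <- function(waveform) {
  stopifnot(inherits(waveform, "gradient_waveform"))
  g <- waveform$samples
  n <- nrow(g)
  dt <- waveform$dt
  # cumulative trapezoid: q_j = gamma * dt * (sum_{k<j} (g_k + g_{k+1})/2)
  q <- apply(g, 2L, function(col) {
    c(0, cumsum((col[-n] + col[-1L]) / 2)) * dt * waveform$gamma
  })
  structure(
    list(times = (seq_len(n) - 1L) * dt, q = q, dt = dt,
         gamma = waveform$gamma, tau = waveform$tau),
    class = "dephasing_trace")
}

#' Read a gradient waveform from a plain-text file
#'
#' The format is plain text with header lines `# dt <seconds>` and
#' `# gamma <rad/s/T>` followed by whitespace-separated `gx gy gz` rows in
#' T m^-1.
#'
#' @param path file path.
#' @return a [gradient_waveform()].
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s"), hdr, value = TRUE)
    if (length(m) != 1L) stop("waveform file must have exactly one '# ", key, "' header")
    as.numeric(sub(paste0("^#\\s*", key, "\\s+"), "", m))
  }
  dt <- get_hdr("dt")
  gamma <- get_hdr("gamma")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) %% 3L != 0L) stop("waveform body must have 3 columns")
  g <- matrix(vals, ncol = 3L, byrow = TRUE)
  if (!all(is.finite(g))) stop("non-finite entries in waveform file")
  gradient_waveform(g, dt = dt, gamma = gamma)
}

#' Write a gradient waveform to a plain-text file
#'
#' @param waveform a [gradient_waveform()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(waveform, path) {
  stopifnot(inherits(waveform, "gradient_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt %.17g", waveform$dt),
               sprintf("# gamma %.17g", waveform$gamma)), con)
  utils::write.table(format(waveform$samples, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Rotate a gradient waveform
#'
#' @param waveform a [gradient_waveform()].
#' @param rotation 3x3 rotation matrix.
#' @return the rotated waveform.
#' @export
rotate_waveform <- function(waveform, rotation) {
  stopifnot(inherits(waveform, "gradient_waveform"))
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  gradient_waveform(waveform$samples %*% t(rotation), waveform$dt,
                    waveform$gamma)
}

#' Euler-angle rotation matrix (z-y-z convention)
#'
#' R = Rz(phi) Ry(theta) Rz(psi); applying it to a waveform whose b-tensor
#' symmetry axis is z places that axis at polar angle theta, azimuth phi.
#'
#' @param theta,phi,psi Euler angles in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_zyz <- function(theta, phi, psi = 0) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
  rz(phi) %*% ry(theta) %*% rz(psi)
}
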
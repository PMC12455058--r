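#' Acquisition protocol
#'
#' A protocol is an ordered table of acquisitions, each referencing a
#' gradient waveform (by id) together with a rotation (Euler angles
#' theta, phi, psi), a target b-value (the waveform amplitude is scaled
#' accordingly), and the relaxation-encoding times tau_r (recovery) and
#' tau_e (echo). When waveforms are supplied, the per-acquisition
#' b-tensor, anisotropy b_delta and centroid frequency omega_cent are
#' computed from the waveform spectra (rotation leaves b, b_delta and
#' omega_cent invariant); without waveforms, a scalar-only protocol can
#' still be used for frequency-independent work if `b_delta`, `theta`
#' and `phi` columns are present (the axisymmetric b-tensor is then
#' reconstructed from the scalars).
#'
#' @param table data.frame with columns `n_acq`, `waveform_id`, `b`
#'   (s m^-2), `tau_r`, `tau_e` (seconds) and optionally `theta`, `phi`,
#'   `psi` (radians, default 0), `b_delta`, `omega_cent` (rad s^-1).
#' @param waveforms named list of [gradient_waveform()] objects keyed by
#'   `waveform_id`, or `NULL`.
#' @param n_pad zero-padding factor for the encoding spectra.
#' @return An object of class `dr_protocol`.
#' @export
protocol <- function(table, waveforms = NULL, n_pad = 8) {
  table <- as.data.frame(table)
  req <- c("n_acq", "waveform_id", "b", "tau_r", "tau_e")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop("protocol table missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(table) == 0L) stop("protocol table is empty")
  if (anyDuplicated(table$n_acq)) stop("n_acq values must be unique")
  for (col in c("theta", "phi", "psi"))
    if (is.null(table[[col]])) table[[col]] <- 0
  num_cols <- c("b", "tau_r", "tau_e", "theta", "phi", "psi")
  for (col in num_cols)
    if (!all(is.finite(table[[col]])))
      stop("non-finite entries in protocol column ", col)
  if (any(table$b < 0)) stop("b must be non-negative")

  encodings <- NULL
  if (!is.null(waveforms)) {
    ids <- unique(table$waveform_id)
    unresolved <- setdiff(ids, names(waveforms))
    if (length(unresolved))
      stop("waveforms not supplied for ids: ", paste(unresolved, collapse = ", "))
    encodings <- lapply(waveforms[ids], acquisition_encoding, n_pad = n_pad)
    wf_b <- vapply(encodings, function(e) e$b, 0)
    wf_bd <- vapply(encodings, function(e) e$b_delta, 0)
    wf_wc <- vapply(encodings, function(e) e$omega_cent, 0)
    idx <- match(table$waveform_id, ids)
    table$b_delta <- wf_bd[idx]
    table$omega_cent <- wf_wc[idx]
    table$omega_cent[table$b <= 0] <- NA_real_
    table$b_delta[table$b <= 0] <- NA_real_
  }

  prot <- structure(
    list(table = table, waveforms = waveforms, encodings = encodings,
         n_pad = n_pad),
    class = "dr_protocol")
  prot$bt6 <- protocol_btensors(prot)
  prot
}

#' @export
print.dr_protocol <- function(x, ...) {
  tb <- x$table
  cat(sprintf("dr_protocol: %d acquisitions, %d waveform(s)%s\n",
              nrow(tb), length(unique(tb$waveform_id)),
              if (is.null(x$waveforms)) " (scalar-only)" else ""))
  cat(sprintf("  b: %.3g - %.3g s/m^2; tau_r: %.3g - %.3g s; tau_e: %.3g - %.3g s\n",
              min(tb$b), max(tb$b), min(tb$tau_r), max(tb$tau_r),
              min(tb$tau_e), max(tb$tau_e)))
  if (!is.null(tb$omega_cent) && any(is.finite(tb$omega_cent)))
    cat(sprintf("  omega_cent/2pi: %.3g - %.3g Hz\n",
                min(tb$omega_cent / (2 * pi), na.rm = TRUE),
                max(tb$omega_cent / (2 * pi), na.rm = TRUE)))
  invisible(x)
}

# number of acquisitions
#' @export
length.dr_protocol <- function(x) nrow(x$table)

# Per-acquisition integrated b-tensors in sym6 layout (n_acq x 6).
# With waveforms: scaled + rotated waveform tensors. Without: axisymmetric
# reconstruction from (b, b_delta, theta, phi).
protocol_btensors <- function(prot) {
  tb <- prot$table
  n <- nrow(tb)
  out <- matrix(0, n, 6L)
  if (!is.null(prot$encodings)) {
    ids <- names(prot$encodings)
    idx <- match(tb$waveform_id, ids)
    for (j in seq_len(n)) {
      enc <- prot$encodings[[idx[j]]]
      if (enc$b <= 0 || tb$b[j] <= 0) next
      r <- rotation_zyz(tb$theta[j], tb$phi[j], tb$psi[j])
      bt <- (tb$b[j] / enc$b) * (r %*% enc$b_tensor %*% t(r))
      out[j, ] <- mat_to_sym6(bt)
    }
  } else {
    if (is.null(tb$b_delta) || is.null(tb$theta) || is.null(tb$phi))
      stop("scalar-only protocol needs b_delta, theta and phi columns")
    for (j in seq_len(n)) {
      if (tb$b[j] <= 0) next
      bd <- tb$b_delta[j]
      b_zz <- tb$b[j] * (1 + 2 * bd) / 3
      b_xy <- tb$b[j] * (1 - bd) / 3
      nvec <- c(sin(tb$theta[j]) * cos(tb$phi[j]),
                sin(tb$theta[j]) * sin(tb$phi[j]),
                cos(tb$theta[j]))
      bt <- diag(rep(b_xy, 3L)) + (b_zz - b_xy) * tcrossprod(nvec)
      out[j, ] <- mat_to_sym6(bt)
    }
  }
  out
}

#' Read an acquisition protocol table
#'
#' Accepts TSV (any whitespace, header row) or JSON (array of records).
#' Column `omega_cent_hz`, if present, is converted to angular frequency;
#' `b_delta` and `omega_cent_hz` are optional and recomputed when
#' waveforms are given.
#'
#' @param path file path (`.json` for JSON, anything else is read as TSV).
#' @param waveforms optional named list of waveforms passed to [protocol()].
#' @param n_pad zero-padding factor for spectra.
#' @return a `dr_protocol`.
#' @export
read_protocol <- function(path, waveforms = NULL, n_pad = 8) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tb <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    tb <- utils::read.table(path, header = TRUE)
  }
  if (!is.null(tb$omega_cent_hz)) {
    tb$omega_cent <- tb$omega_cent_hz * 2 * pi
    tb$omega_cent_hz <- NULL
  }
  protocol(tb, waveforms = waveforms, n_pad = n_pad)
}

#' Write an acquisition protocol table as TSV
#'
#' Angular frequencies are written as `omega_cent_hz` (Hz) at this I/O
#' boundary; everything else stays SI.
#'
#' @param prot a `dr_protocol` (or bare data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(prot, path) {
  tb <- if (inherits(prot, "dr_protocol")) prot$table else as.data.frame(prot)
  if (!is.null(tb$omega_cent)) {
    tb$omega_cent_hz <- tb$omega_cent / (2 * pi)
    tb$omega_cent <- NULL
  }
  utils::write.table(tb, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spectral summary of a protocol
#'
#' Computes the b-weighted percentiles of the per-acquisition centroid
#' frequencies (the weighted empirical percentile: acquisitions sorted by
#' omega_cent, percentile p is the first omega_cent whose cumulative
#' normalized b-weight reaches p; no interpolation) and, when spectra are
#' available, the total spectral content (sum of trace b(omega) over all
#' acquisitions on a common frequency grid).
#'
#' @param prot a `dr_protocol` whose table carries `b` and `omega_cent`.
#' @param probs percentile levels, default `c(0.1, 0.5, 0.9)`.
#' @param n_grid grid size for the total spectral content.
#' @return list with `omega_10`, `omega_50`, `omega_90` (rad s^-1, for the
#'   default `probs`), `percentiles` (named vector), and
#'   `total_spectral_content` (data.frame with `omega`, `density`) or NULL.
#' @export
protocol_summary <- function(prot, probs = c(0.1, 0.5, 0.9), n_grid = 512) {
  stopifnot(inherits(prot, "dr_protocol"))
  tb <- prot$table
  if (is.null(tb$omega_cent))
    stop("protocol carries no omega_cent; supply waveforms or the column")
  keep <- tb$b > 0 & is.finite(tb$omega_cent)
  if (!any(keep) || sum(tb$b[keep]) <= 0)
    stop("all acquisitions have zero b-weight")
  wc <- tb$omega_cent[keep]
  bw <- tb$b[keep]
  ord <- order(wc)
  cw <- cumsum(bw[ord]) / sum(bw)
  pct <- vapply(probs, function(p) wc[ord][which(cw >= p)[1L]], 0)
  names(pct) <- sprintf("omega_%g", probs * 100)

  tsc <- NULL
  if (!is.null(prot$encodings)) {
    wmax <- max(vapply(prot$encodings, function(e) max(abs(e$spectrum$omega)), 0))
    grid <- seq(0, wmax, length.out = n_grid)
    total <- numeric(n_grid)
    ids <- names(prot$encodings)
    idx <- match(tb$waveform_id, ids)
    for (j in which(keep)) {
      enc <- prot$encodings[[idx[j]]]
      sp <- enc$spectrum
      pos <- sp$omega >= 0
      total <- total + (tb$b[j] / enc$b) *
        stats::approx(sp$omega[pos], sp$trace[pos], xout = grid,
                      yleft = 0, yright = 0, rule = 1)$y
    }
    tsc <- data.frame(omega = grid, density = total)
  }
  out <- list(percentiles = pct, total_spectral_content = tsc)
  if (identical(probs, c(0.1, 0.5, 0.9))) {
    out$omega_10 <- pct[[1L]]
    out$omega_50 <- pct[[2L]]
    out$omega_90 <- pct[[3L]]
  }
  out
}
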
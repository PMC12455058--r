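#' Project a component onto (D_iso, D_delta^2)
#'
#' Isotropic diffusivity D_iso = (D_A + 2 D_R) / 3 and squared normalized
#' anisotropy D_delta^2 = ((D_A - D_R) / (D_A + 2 D_R))^2, evaluated from
#' the frequency-dependent eigenvalues at the requested omega (static
#' components are constant in omega).
#'
#' @param components a `component_set`.
#' @param omega evaluation angular frequency (rad s^-1), default 0.
#' @return data.frame with columns `d_iso`, `d_delta2` (NA where
#'   D_A + 2 D_R = 0).
#' @export
project_component <- function(components, omega = 0) {
  n <- nrow(components)
  d_iso <- numeric(n)
  d_delta2 <- numeric(n)
  for (i in seq_len(n)) {
    ev <- eigenvalue_spectra(components[i, ], omega)
    denom <- ev$d_a + 2 * ev$d_r
    if (denom <= 0) {
      d_iso[i] <- NA_real_
      d_delta2[i] <- NA_real_
    } else {
      d_iso[i] <- denom / 3
      d_delta2[i] <- ((ev$d_a - ev$d_r) / denom)^2
    }
  }
  data.frame(d_iso = d_iso, d_delta2 = d_delta2)
}

#' (D_iso, D_delta^2) bin definitions
#'
#' Three bins partitioning the (D_iso, D_delta^2) plane into regions with
#' diffusion properties characteristic of white matter (bin 1: low D_iso,
#' high anisotropy), gray matter (bin 2: low D_iso, low anisotropy) and
#' free water / CSF (bin 3: high D_iso). The `mouse` preset uses the
#' D_iso threshold 1e-9 m^2 s^-1, the `human` preset 2e-9; both split
#' bins 1/2 at D_delta^2 = 0.25. The printed inequalities are strict;
#' equality is assigned to the lower-D_iso / lower-D_delta^2 bin (so a
#' component exactly at D_delta^2 = 0.25 falls in bin 2, and exactly at
#' the D_iso threshold in bins 1/2).
#'
#' @param preset "mouse" or "human", or `NULL` when giving `d_iso_max`.
#' @param d_iso_max D_iso threshold separating bin 3.
#' @param d_delta2_split D_delta^2 threshold separating bins 1 and 2.
#' @return list of class `bin_definition`.
#' @export
bin_definition <- function(preset = c("mouse", "human"), d_iso_max = NULL,
                           d_delta2_split = 0.25) {
  if (is.null(d_iso_max)) {
    preset <- match.arg(preset)
    d_iso_max <- switch(preset, mouse = 1e-9, human = 2e-9)
  }
  structure(list(d_iso_max = d_iso_max, d_delta2_split = d_delta2_split),
            class = "bin_definition")
}

bin_assign <- function(proj, bins) {
  ifelse(proj$d_iso > bins$d_iso_max, 3L,
         ifelse(proj$d_delta2 > bins$d_delta2_split, 1L, 2L))
}

#' Bin-resolved signal fractions
#'
#' f_bin_n = (1/S0) * sum of weights of the components falling in bin n,
#' with S0 the total weight. In omega-dependent analyses the binning is
#' evaluated at the requested omega; frequency-independent solutions use
#' their static values regardless of omega.
#'
#' @param components a `component_set` with fitted weights.
#' @param bins a [bin_definition()].
#' @param omega evaluation frequency (rad s^-1).
#' @return named numeric vector (f_bin1, f_bin2, f_bin3); all NA when
#'   S0 = 0.
#' @export
bin_fractions <- function(components, bins, omega = 0) {
  stot <- sum(components$w)
  if (!is.finite(stot) || stot <= 0)
    return(c(f_bin1 = NA_real_, f_bin2 = NA_real_, f_bin3 = NA_real_))
  proj <- project_component(components, omega)
  bin <- bin_assign(proj, bins)
  f <- vapply(1:3, function(k) sum(components$w[bin == k]) / stot, 0)
  names(f) <- c("f_bin1", "f_bin2", "f_bin3")
  f
}

#' Bin fractions to RGB color
#'
#' \[R, G, B\] = \[f_bin1, f_bin2, f_bin3\] / max(f): the largest fraction
#' saturates its channel.
#'
#' @param f numeric vector of three non-negative fractions.
#' @return numeric vector (r, g, b) in \[0, 1\]; NA triple if all zero.
#' @export
rgb_composite <- function(f) {
  if (any(!is.finite(f)) || all(f == 0)) return(c(r = NA_real_,
                                                  g = NA_real_,
                                                  b = NA_real_))
  if (any(f < 0)) stop("fractions must be non-negative")
  out <- f / max(f)
  names(out) <- c("r", "g", "b")
  out
}

#' Weight-averaged ensemble mean E\[X\]
#'
#' E\[X\] = (1/S0) sum_i w_i X_i over the components of one solution,
#' where X is one of the projected or relaxation quantities.
#'
#' @param components a `component_set` with weights.
#' @param quantity one of "d_iso", "d_delta2", "r_1", "r_2".
#' @param omega evaluation frequency for the diffusion projections.
#' @return scalar E\[X\] (NA when S0 = 0).
#' @export
ensemble_mean <- function(components,
                          quantity = c("d_iso", "d_delta2", "r_1", "r_2"),
                          omega = 0) {
  quantity <- match.arg(quantity)
  stot <- sum(components$w)
  if (!is.finite(stot) || stot <= 0) return(NA_real_)
  x <- switch(quantity,
    d_iso = project_component(components, omega)$d_iso,
    d_delta2 = project_component(components, omega)$d_delta2,
    r_1 = components$r_1,
    r_2 = components$r_2)
  sum(components$w * x) / stot
}

#' Spectral dispersion metric
#'
#' Delta_omega/2pi E\[X\] = (E\[X(omega_90)\] - E\[X(omega_10)\]) /
#' ((omega_90 - omega_10) / 2pi): the change of an ensemble mean across
#' the investigated frequency window per Hz.
#'
#' @param e_hi,e_lo ensemble means at the upper/lower frequency.
#' @param omega_hi,omega_lo the two frequencies (rad s^-1),
#'   `omega_hi > omega_lo`.
#' @return dispersion in units of X per Hz.
#' @export
dispersion_metric <- function(e_hi, e_lo, omega_hi, omega_lo) {
  if (omega_hi <= omega_lo) stop("omega_hi must exceed omega_lo")
  (e_hi - e_lo) / ((omega_hi - omega_lo) / (2 * pi))
}

#' Normalized difference between two analyses
#'
#' 100% * (Y_dep - Y_indep) / ((Y_dep + Y_indep) / 2): the percentage
#' difference between frequency-dependent and frequency-independent
#' estimates of the same quantity, normalized by their mean.
#'
#' @param y_dep,y_indep the two estimates.
#' @return percentage (NA when the mean is zero).
#' @export
normalized_difference <- function(y_dep, y_indep) {
  denom <- (y_dep + y_indep) / 2
  ifelse(denom == 0, NA_real_, (y_dep - y_indep) / denom * 100)
}

#' Rough per-voxel SNR estimate
#'
#' Ratio between S0 and the standard deviation of the difference between
#' measured and back-calculated signals.
#'
#' @param s0_value extrapolated signal S0.
#' @param residuals measured - back-calculated signals (absolute units).
#' @return scalar SNR.
#' @export
snr_estimate <- function(s0_value, residuals) {
  s <- stats::sd(residuals)
  if (!is.finite(s) || s == 0) return(NA_real_)
  s0_value / s
}

#' 2D (D_iso, D_delta^2) projection mesh
#'
#' Maps component weights onto a 64 x 64 mesh over log10(D_iso) (x axis)
#' and D_delta^2 (y axis, linear on \[0, 1\]) by depositing each weight
#' through a 3 x 3 grid-point truncated Gaussian kernel (sigma = 0.75
#' grid spacings) centered on the component's cell. Kernel spill beyond
#' the axis ranges is clipped to the edge cells, conserving total mass.
#'
#' @param components a `component_set` (e.g. pooled over replicates or an
#'   ROI).
#' @param omega evaluation frequency.
#' @param d_iso_range log10-spanned D_iso axis range (m^2 s^-1).
#' @param d_delta2_range D_delta^2 axis range.
#' @param n_mesh mesh size per axis.
#' @param sigma kernel width in grid spacings.
#' @return object of class `projection_mesh`: list with `weights`
#'   (n_mesh x n_mesh), `d_iso_axis`, `d_delta2_axis`, `omega`.
#' @export
mesh_projection <- function(components, omega = 0,
                            d_iso_range = c(5e-12, 5e-9),
                            d_delta2_range = c(0, 1),
                            n_mesh = 64, sigma = 0.75) {
  proj <- project_component(components, omega)
  ok <- is.finite(proj$d_iso) & components$w > 0
  xaxis <- seq(log10(d_iso_range[1L]), log10(d_iso_range[2L]),
               length.out = n_mesh)
  yaxis <- seq(d_delta2_range[1L], d_delta2_range[2L], length.out = n_mesh)
  wmat <- matrix(0, n_mesh, n_mesh)
  if (any(ok)) {
    off <- -1:1
    kern <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
    kern <- kern / sum(kern)
    ix <- findInterval(log10(proj$d_iso[ok]), xaxis, all.inside = TRUE)
    # snap to nearest grid point
    xi <- ifelse(log10(proj$d_iso[ok]) - xaxis[ix] >
                   diff(xaxis[1:2]) / 2, ix + 1L, ix)
    iy <- findInterval(proj$d_delta2[ok], yaxis, all.inside = TRUE)
    yi <- ifelse(proj$d_delta2[ok] - yaxis[iy] > diff(yaxis[1:2]) / 2,
                 iy + 1L, iy)
    xi <- pmin(pmax(xi, 1L), n_mesh)
    yi <- pmin(pmax(yi, 1L), n_mesh)
    ws <- components$w[ok]
    for (j in seq_along(ws)) {
      for (a in 1:3) {
        for (b in 1:3) {
          # clip spill to the edge cells so mass is conserved
          xx <- pmin(pmax(xi[j] + off[a], 1L), n_mesh)
          yy <- pmin(pmax(yi[j] + off[b], 1L), n_mesh)
          wmat[xx, yy] <- wmat[xx, yy] + ws[j] * kern[a, b]
        }
      }
    }
  }
  structure(list(weights = wmat, d_iso_axis = xaxis, d_delta2_axis = yaxis,
                 omega = omega),
            class = "projection_mesh")
}

#' ROI-pooled projection mesh
#'
#' Concatenates the components of all solutions (e.g. all bootstrap
#' replicates of all voxels inside a region of interest) and projects the
#' pooled weights onto one mesh.
#'
#' @param solutions list of `voxel_solution` or `bootstrap_ensemble`
#'   objects.
#' @param omega evaluation frequency.
#' @param ... passed to [mesh_projection()].
#' @return a `projection_mesh`.
#' @export
roi_projection <- function(solutions, omega = 0, ...) {
  pool <- pool_components(solutions)
  if (is.null(pool)) stop("empty ROI: no components to project")
  mesh_projection(pool, omega = omega, ...)
}

pool_components <- function(solutions) {
  if (inherits(solutions, "bootstrap_ensemble"))
    solutions <- solutions$solutions
  if (inherits(solutions, "voxel_solution")) solutions <- list(solutions)
  parts <- list()
  for (s in solutions) {
    if (inherits(s, "bootstrap_ensemble")) {
      for (ss in s$solutions)
        if (!is.null(ss$components) && nrow(ss$components))
          parts[[length(parts) + 1L]] <- ss$components
    } else if (!is.null(s$components) && nrow(s$components)) {
      parts[[length(parts) + 1L]] <- s$components
    }
  }
  if (!length(parts)) return(NULL)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Scalar metric summary of one solution
#'
#' Evaluates S0, E\[D_iso\] and E\[D_delta^2\] at the given frequencies,
#' E\[R1\], E\[R2\], bin fractions, RGB and the spectral dispersion
#' metrics for one voxel solution.
#'
#' @param solution a `voxel_solution`.
#' @param bins a [bin_definition()].
#' @param omegas named vector of evaluation frequencies, typically
#'   `c(omega_10 = ..., omega_50 = ..., omega_90 = ...)` from
#'   [protocol_summary()]. Static solutions ignore the values.
#' @return named numeric vector of metrics.
#' @export
solution_metrics <- function(solution, bins, omegas) {
  nm <- c("s0",
          paste0("e_d_iso_", names(omegas)),
          paste0("e_d_delta2_", names(omegas)),
          "e_r_1", "e_r_2", "f_bin1", "f_bin2", "f_bin3",
          "rgb_r", "rgb_g", "rgb_b",
          "disp_e_d_iso", "disp_e_d_delta2", "snr")
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  comps <- solution$components
  if (is.null(comps) || nrow(comps) == 0L || sum(comps$w) <= 0) return(out)
  out["s0"] <- sum(comps$w)
  for (k in seq_along(omegas)) {
    out[paste0("e_d_iso_", names(omegas)[k])] <-
      ensemble_mean(comps, "d_iso", omegas[[k]])
    out[paste0("e_d_delta2_", names(omegas)[k])] <-
      ensemble_mean(comps, "d_delta2", omegas[[k]])
  }
  out["e_r_1"] <- ensemble_mean(comps, "r_1")
  out["e_r_2"] <- ensemble_mean(comps, "r_2")
  mid <- if ("omega_50" %in% names(omegas)) omegas[["omega_50"]] else
    omegas[[ceiling(length(omegas) / 2)]]
  f <- bin_fractions(comps, bins, mid)
  out[c("f_bin1", "f_bin2", "f_bin3")] <- f
  out[c("rgb_r", "rgb_g", "rgb_b")] <- rgb_composite(f)
  if (all(c("omega_10", "omega_90") %in% names(omegas)) &&
      omegas[["omega_90"]] > omegas[["omega_10"]]) {
    out["disp_e_d_iso"] <- dispersion_metric(
      out[["e_d_iso_omega_90"]], out[["e_d_iso_omega_10"]],
      omegas[["omega_90"]], omegas[["omega_10"]])
    out["disp_e_d_delta2"] <- dispersion_metric(
      out[["e_d_delta2_omega_90"]], out[["e_d_delta2_omega_10"]],
      omegas[["omega_90"]], omegas[["omega_10"]])
  }
  if (!is.null(solution$residuals) && any(is.finite(solution$residuals)))
    out["snr"] <- snr_estimate(out[["s0"]], solution$residuals)
  out
}

#' Assemble per-voxel parameter maps from bootstrap ensembles
#'
#' Computes the scalar metrics of every replicate of every voxel and
#' takes marginal medians over the replicates, yielding one map value
#' per metric and voxel.
#'
#' @param ensembles list (one element per voxel) of
#'   `bootstrap_ensemble` objects (or single `voxel_solution`s).
#' @param bins a [bin_definition()].
#' @param omegas named evaluation frequencies (see [solution_metrics()]).
#' @param dims optional integer vector giving the spatial grid; when
#'   supplied each metric is reshaped into an array.
#' @return list of class `parameter_maps`: per-metric numeric vectors (or
#'   arrays) plus the `omegas` used.
#' @export
map_assembly <- function(ensembles, bins, omegas, dims = NULL) {
  per_voxel <- lapply(ensembles, function(e) {
    sols <- if (inherits(e, "bootstrap_ensemble")) e$solutions else list(e)
    vals <- vapply(sols, function(s) solution_metrics(s, bins, omegas),
                   solution_metrics(sols[[1L]], bins, omegas) * NA)
    if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1L)
    apply(vals, 1L, stats::median, na.rm = TRUE)
  })
  metrics <- do.call(rbind, per_voxel)
  maps <- lapply(seq_len(ncol(metrics)), function(k) {
    v <- unname(metrics[, k])
    if (!is.null(dims)) array(v, dim = dims) else v
  })
  names(maps) <- colnames(metrics)
  structure(c(maps, list(omegas = omegas)), class = "parameter_maps")
}

#' Normalized-difference maps between two analyses
#'
#' Applies [normalized_difference()] metric-by-metric to two
#' `parameter_maps` objects (typically omega-dependent vs static).
#'
#' @param maps_dep,maps_indep `parameter_maps` from [map_assembly()].
#' @param metrics which metrics to compare.
#' @return named list of numeric vectors/arrays (percent).
#' @export
difference_maps <- function(maps_dep, maps_indep,
                            metrics = c("s0", "e_r_1", "e_r_2",
                                        "f_bin1", "f_bin2", "f_bin3")) {
  out <- lapply(metrics, function(mn)
    normalized_difference(maps_dep[[mn]], maps_indep[[mn]]))
  names(out) <- metrics
  out
}
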
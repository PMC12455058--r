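#' Monte Carlo inversion configuration
#'
#' Bundles the search-space limits and algorithm counts for the per-voxel
#' Monte Carlo inversion. The presets carry the parameter limits used for
#' microimaging ("preclinical") and whole-body ("clinical") data:
#' preclinical 5e-12 < D < 5e-9 m^2 s^-1, 0.1 < Gamma < 1e5 s^-1,
#' 0.1 < R1 < 4 s^-1, 4 < R2 < 150 s^-1; clinical 5e-11 < D < 5e-9,
#' 0.1 < Gamma < 1e4, 0.2 < R1 < 2, 1 < R2 < 30. Default algorithm
#' counts are 20 proliferation steps, 20 mutation/extinction steps, 200
#' input components per step, 10 output components and 100 bootstrap
#' replicates.
#'
#' @param mode "omega_dependent" (9-parameter component space) or
#'   "static" (6-parameter space, no d_0/gamma dimensions).
#' @param preset "preclinical" or "clinical" parameter limits.
#' @param n_proliferation,n_mutation,n_in,n_out,n_bootstrap algorithm
#'   counts.
#' @param limits optional list overriding the preset: fields `d`,
#'   `gamma`, `r_1`, `r_2`, each a length-2 numeric (lower, upper).
#' @param mutation_factor multiplicative half-range of the log-parameter
#'   perturbation (factors drawn in \[1/f, f\]).
#' @param mutation_angle orientation perturbation cap in radians.
#' @param seed master seed for all randomness.
#' @param s0_floor voxels whose maximum signal is below this value are
#'   skipped and reported as undefined.
#' @return list of class `inversion_config`.
#' @export
inversion_config <- function(mode = c("omega_dependent", "static"),
                             preset = c("preclinical", "clinical"),
                             n_proliferation = 20, n_mutation = 20,
                             n_in = 200, n_out = 10, n_bootstrap = 100,
                             limits = NULL,
                             mutation_factor = 1.2,
                             mutation_angle = 10 * pi / 180,
                             seed = 1, s0_floor = 0) {
  mode <- match.arg(mode)
  preset <- match.arg(preset)
  base <- switch(preset,
    preclinical = list(d = c(5e-12, 5e-9), gamma = c(0.1, 1e5),
                       r_1 = c(0.1, 4), r_2 = c(4, 150)),
    clinical = list(d = c(5e-11, 5e-9), gamma = c(0.1, 1e4),
                    r_1 = c(0.2, 2), r_2 = c(1, 30)))
  if (!is.null(limits)) base[names(limits)] <- limits
  for (nm in names(base)) {
    lim <- base[[nm]]
    if (length(lim) != 2L || !all(is.finite(lim)) || lim[1L] >= lim[2L])
      stop("invalid limits for ", nm)
  }
  counts <- c(n_proliferation, n_mutation, n_in, n_out, n_bootstrap)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("algorithm counts must be positive integers")
  structure(
    list(mode = mode, preset = preset, limits = base,
         n_proliferation = n_proliferation, n_mutation = n_mutation,
         n_in = n_in, n_out = n_out, n_bootstrap = n_bootstrap,
         mutation_factor = mutation_factor, mutation_angle = mutation_angle,
         seed = as.integer(seed), s0_floor = s0_floor),
    class = "inversion_config")
}

# stable integer mixing for derived seeds (voxel, replicate); keeps
# parallel and serial execution bit-identical
derive_seed <- function(seed, a = 0L, b = 0L) {
  x <- (as.double(seed) * 1103515245 + as.double(a) * 747796405 +
          as.double(b) * 2654435769 + 12345) %% 2147483647
  as.integer(x)
}

#' Draw random candidate components
#'
#' Candidates are drawn with log-uniform isotropic diffusivity D_iso
#' within the configured diffusivity limits and uniform normalized
#' anisotropy D_delta in \[-0.5, 1\] (so that log10 D_iso is uniform by
#' construction); the axial/radial pair is derived as
#' d_a = D_iso (1 + 2 D_delta), d_r = D_iso (1 - D_delta) and clipped
#' into the limits. Orientations are uniform on the hemisphere; Gamma,
#' R1 and R2 are log-uniform within their limits. In omega-dependent
#' mode d_0 is log-uniform and then raised to max(d_a, d_r) (restriction
#' can only lower the low-frequency diffusivity); static mode omits the
#' d_0 and Gamma dimensions. Weights are zero (unset) until fitted.
#'
#' @param config an `inversion_config`.
#' @param n number of candidates.
#' @return a `component_set` with `w = 0`.
#' @export
sample_candidates <- function(config, n) {
  lim <- config$limits
  runif_log <- function(n, lim) exp(stats::runif(n, log(lim[1L]), log(lim[2L])))
  d_iso <- runif_log(n, lim$d)
  d_delta <- stats::runif(n, -0.5, 1)
  # clip the shape (not the diffusivities) into the feasible set so that
  # d_a and d_r respect the limits while d_iso stays exactly log-uniform
  dd_hi <- pmin(1, (lim$d[2L] / d_iso - 1) / 2, 1 - lim$d[1L] / d_iso)
  dd_lo <- pmax(-0.5, (lim$d[1L] / d_iso - 1) / 2, 1 - lim$d[2L] / d_iso)
  d_delta <- pmin(pmax(d_delta, dd_lo), dd_hi)
  d_a <- pmin(pmax(d_iso * (1 + 2 * d_delta), lim$d[1L]), lim$d[2L])
  d_r <- pmin(pmax(d_iso * (1 - d_delta), lim$d[1L]), lim$d[2L])
  theta <- acos(stats::runif(n, 0, 1))
  phi <- stats::runif(n, -pi, pi)
  r_1 <- runif_log(n, lim$r_1)
  r_2 <- runif_log(n, lim$r_2)
  if (config$mode == "omega_dependent") {
    d_0 <- pmax(runif_log(n, lim$d), d_a, d_r)
    gamma_a <- runif_log(n, lim$gamma)
    gamma_r <- runif_log(n, lim$gamma)
  } else {
    d_0 <- NA_real_
    gamma_a <- Inf
    gamma_r <- Inf
  }
  component_set(w = rep(0, n), d_a = d_a, d_r = d_r, theta = theta,
                phi = phi, d_0 = d_0, gamma_a = gamma_a, gamma_r = gamma_r,
                r_1 = r_1, r_2 = r_2)
}

# perturb survivors: multiplicative jitter of log-parameters within
# [1/f, f], orientation within a cone of half-angle `cap`; everything
# clipped back into the limits
mutate_candidates <- function(config, survivors, n) {
  lim <- config$limits
  pick <- sample.int(nrow(survivors), n, replace = TRUE)
  out <- survivors[pick, , drop = FALSE]
  lf <- log(config$mutation_factor)
  jitter_log <- function(x, bounds) {
    pmin(pmax(x * exp(stats::runif(length(x), -lf, lf)), bounds[1L]),
         bounds[2L])
  }
  out$d_a <- jitter_log(out$d_a, lim$d)
  out$d_r <- jitter_log(out$d_r, lim$d)
  out$r_1 <- jitter_log(out$r_1, lim$r_1)
  out$r_2 <- jitter_log(out$r_2, lim$r_2)
  if (config$mode == "omega_dependent") {
    out$d_0 <- pmax(jitter_log(out$d_0, lim$d), out$d_a, out$d_r)
    out$gamma_a <- jitter_log(out$gamma_a, lim$gamma)
    out$gamma_r <- jitter_log(out$gamma_r, lim$gamma)
  }
  # rotate each axis by a random angle < cap about a random perpendicular
  st <- sin(out$theta)
  axis <- cbind(st * cos(out$phi), st * sin(out$phi), cos(out$theta))
  ang <- stats::runif(n, 0, config$mutation_angle)
  az <- stats::runif(n, 0, 2 * pi)
  for (i in seq_len(n)) {
    a <- axis[i, ]
    # orthonormal frame around a
    ref <- if (abs(a[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * a) * a
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(a[2L] * e1[3L] - a[3L] * e1[2L],
            a[3L] * e1[1L] - a[1L] * e1[3L],
            a[1L] * e1[2L] - a[2L] * e1[1L])
    newa <- cos(ang[i]) * a +
      sin(ang[i]) * (cos(az[i]) * e1 + sin(az[i]) * e2)
    if (newa[3L] < 0) newa <- -newa
    out$theta[i] <- acos(min(1, max(-1, newa[3L])))
    out$phi[i] <- atan2(newa[2L], newa[1L])
  }
  out$w <- 0
  rownames(out) <- NULL
  out
}

#' Non-negative least-squares component weights
#'
#' Solves min ||K w - s||_2 subject to w >= 0, where the kernel matrix K
#' has one row per acquisition and one column per candidate (attenuation
#' times relaxation factor). All-zero columns are dropped before the
#' solve and get zero weight. No regularization or sparsity penalty is
#' applied; sparsity emerges from the active-set solution itself.
#'
#' @param prot a `dr_protocol` or a precomputed [protocol_kernel()].
#' @param signals measured signal vector.
#' @param candidates a `component_set`.
#' @return numeric weight vector (one entry per candidate).
#' @export
fit_weights <- function(prot, signals, candidates) {
  kd <- if (inherits(prot, "protocol_kernel")) prot else protocol_kernel(prot)
  K <- kernel_matrix(kd, candidates)
  fit_weights_kernel(K, signals)
}

fit_weights_kernel <- function(K, signals) {
  stopifnot(nrow(K) == length(signals))
  w <- numeric(ncol(K))
  keep <- colSums(abs(K)) > 0
  if (!any(keep) || all(signals == 0)) return(w)
  w[keep] <- pracma::lsqnonneg(K[, keep, drop = FALSE], signals)$x
  w
}

#' Per-voxel Monte Carlo inversion
#'
#' Estimates a discrete component distribution by alternating candidate
#' proliferation and mutation/extinction: each proliferation round draws
#' `n_in` fresh candidates, appends the current survivors, fits
#' non-negative weights and keeps the components with nonzero weight;
#' each mutation round perturbs survivors within the limits, refits and
#' extinguishes zero-weight components. The final solution is truncated
#' to the `n_out` largest-weight components and refitted. Because every
#' refit includes the current survivors, the residual norm is
#' non-increasing across rounds. Deterministic for a fixed seed.
#'
#' @param prot a `dr_protocol`.
#' @param signals measured signals aligned with the protocol.
#' @param config an `inversion_config`.
#' @param kernel_data optional precomputed [protocol_kernel()] (shared
#'   across voxels for speed).
#' @param seed seed for this voxel (defaults to `config$seed`).
#' @param subset optional acquisition index vector (with repeats) used by
#'   the bootstrap: the fit uses only these rows.
#' @return An object of class `voxel_solution`: list with `components`
#'   (a `component_set` with fitted weights, at most `n_out` rows),
#'   `residuals` (measured - back-calculated, full protocol),
#'   `rss`, `s0` and `skipped`.
#' @export
invert_voxel <- function(prot, signals, config, kernel_data = NULL,
                         seed = config$seed, subset = NULL) {
  kd <- if (!is.null(kernel_data)) kernel_data else protocol_kernel(prot)
  if (length(signals) != length(kd$b))
    stop("signal vector length does not match the protocol")
  if (max(signals) <= config$s0_floor) {
    return(structure(list(components = NULL, residuals = rep(NA_real_,
      length(signals)), rss = NA_real_, s0 = NA_real_, skipped = TRUE),
      class = "voxel_solution"))
  }
  rows <- if (is.null(subset)) seq_along(signals) else subset
  y <- signals[rows]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  survivors <- NULL
  rss_trace <- numeric(0)
  for (p in seq_len(config$n_proliferation)) {
    fresh <- sample_candidates(config, config$n_in)
    cand <- if (is.null(survivors)) fresh else rbind(survivors, fresh)
    K <- kernel_matrix(kd, cand)[rows, , drop = FALSE]
    w <- fit_weights_kernel(K, y)
    cand$w <- w
    rss_trace <- c(rss_trace, sum((y - K %*% w)^2))
    survivors <- cand[w > 0, , drop = FALSE]
    if (nrow(survivors) == 0L) survivors <- NULL
  }
  if (!is.null(survivors)) {
    for (q in seq_len(config$n_mutation)) {
      mut <- mutate_candidates(config, survivors, config$n_in)
      cand <- rbind(survivors, mut)
      K <- kernel_matrix(kd, cand)[rows, , drop = FALSE]
      w <- fit_weights_kernel(K, y)
      cand$w <- w
      keep <- w > 0
      if (any(keep)) {
        survivors <- cand[keep, , drop = FALSE]
        rss_trace <- c(rss_trace, sum((y - K %*% w)^2))
      }
    }
    if (nrow(survivors) > config$n_out) {
      survivors <- survivors[order(-survivors$w)[seq_len(config$n_out)], ,
                             drop = FALSE]
      K <- kernel_matrix(kd, survivors)[rows, , drop = FALSE]
      survivors$w <- fit_weights_kernel(K, y)
      survivors <- survivors[survivors$w > 0, , drop = FALSE]
    }
    rownames(survivors) <- NULL
  }
  if (is.null(survivors) || nrow(survivors) == 0L) {
    back <- rep(0, length(signals))
    comps <- component_set(w = numeric(0), d_a = numeric(0),
                           d_r = numeric(0))
  } else {
    back <- as.numeric(kernel_matrix(kd, survivors) %*% survivors$w)
    comps <- survivors
  }
  res <- signals - back
  structure(
    list(components = comps, residuals = res,
         rss = sum(res[rows]^2), rss_trace = rss_trace,
         s0 = sum(comps$w), skipped = FALSE),
    class = "voxel_solution")
}

#' Bootstrap ensemble of per-voxel solutions
#'
#' Repeats the Monte Carlo inversion on datasets obtained by resampling
#' the acquisition indices with replacement; each replicate uses a seed
#' derived deterministically from the master seed and the replicate
#' index. Downstream statistics are medians over the replicates.
#'
#' @param prot a `dr_protocol`.
#' @param signals measured signal vector.
#' @param config an `inversion_config` (`n_bootstrap` replicates).
#' @param kernel_data optional precomputed [protocol_kernel()].
#' @param voxel_id integer mixed into the derived seeds so that each
#'   voxel gets an independent, reproducible stream.
#' @param full_resample if `TRUE` every replicate uses the identity
#'   index set (degenerate bootstrap; replicates differ only by the
#'   Monte Carlo seed).
#' @return An object of class `bootstrap_ensemble`: list with
#'   `solutions` (list of `voxel_solution`) and `index_sets`.
#' @export
bootstrap_invert <- function(prot, signals, config, kernel_data = NULL,
                             voxel_id = 0L, full_resample = FALSE) {
  kd <- if (!is.null(kernel_data)) kernel_data else protocol_kernel(prot)
  n <- length(signals)
  sols <- vector("list", config$n_bootstrap)
  idxs <- vector("list", config$n_bootstrap)
  for (r in seq_len(config$n_bootstrap)) {
    seed_r <- derive_seed(config$seed, voxel_id, r)
    if (full_resample) {
      idx <- seq_len(n)
    } else {
      old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(derive_seed(seed_r, 1L, 0L))
      idx <- sample.int(n, n, replace = TRUE)
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }
    sols[[r]] <- invert_voxel(prot, signals, config, kernel_data = kd,
                              seed = seed_r, subset = idx)
    idxs[[r]] <- idx
  }
  structure(list(solutions = sols, index_sets = idxs, config = config),
            class = "bootstrap_ensemble")
}

#' Normalized fit residuals
#'
#' (measured - back-calculated) / S0 per acquisition; S0 is the sum of
#' the fitted component weights. Undefined (all NA) when S0 = 0.
#'
#' @param prot a `dr_protocol` or `protocol_kernel`.
#' @param signals measured signal vector.
#' @param solution a `voxel_solution`.
#' @return numeric vector of normalized residuals.
#' @export
residual_map <- function(prot, signals, solution) {
  kd <- if (inherits(prot, "protocol_kernel")) prot else protocol_kernel(prot)
  if (is.null(solution$components) || nrow(solution$components) == 0L ||
      sum(solution$components$w) == 0)
    return(rep(NA_real_, length(signals)))
  back <- as.numeric(kernel_matrix(kd, solution$components) %*%
                       solution$components$w)
  (signals - back) / sum(solution$components$w)
}
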
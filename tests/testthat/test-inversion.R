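quick_config <- function(mode = "omega_dependent", seed = 7, ...) {
  inversion_config(mode, "preclinical", n_proliferation = 8,
                   n_mutation = 8, n_in = 40, n_out = 10,
                   n_bootstrap = 3, seed = seed, ...)
}

test_that("sample_candidates respects limits, constraints and seeds", {
  cfg <- inversion_config("omega_dependent", "preclinical")
  set.seed(1)
  cand <- sample_candidates(cfg, 200)
  lim <- cfg$limits
  for (col in c("d_a", "d_r", "d_0"))
    expect_true(all(cand[[col]] >= lim$d[1] & cand[[col]] <= lim$d[2]))
  expect_true(all(cand$d_0 >= pmax(cand$d_a, cand$d_r)))
  expect_true(all(cand$gamma_a >= lim$gamma[1] &
                    cand$gamma_a <= lim$gamma[2]))
  expect_true(all(cand$r_1 >= lim$r_1[1] & cand$r_1 <= lim$r_1[2]))
  expect_true(all(cand$r_2 >= lim$r_2[1] & cand$r_2 <= lim$r_2[2]))
  expect_true(all(cand$theta >= 0 & cand$theta <= pi / 2))
  expect_true(all(cand$w == 0))
  # static mode omits the dispersion dimensions
  cfg_s <- inversion_config("static", "preclinical")
  cand_s <- sample_candidates(cfg_s, 50)
  expect_true(all(is.na(cand_s$d_0)))
  expect_true(all(is.infinite(cand_s$gamma_a)))
  # determinism under a fixed seed
  set.seed(99); a <- sample_candidates(cfg, 100)
  set.seed(99); b <- sample_candidates(cfg, 100)
  expect_identical(a, b)
})

test_that("log10 isotropic diffusivity is uniform across the limits", {
  cfg <- inversion_config("omega_dependent", "preclinical")
  set.seed(123)
  cand <- sample_candidates(cfg, 1e5)
  d_iso <- (cand$d_a + 2 * cand$d_r) / 3
  ks <- suppressWarnings(  # runif's finite resolution can create a tie
    stats::ks.test(log10(d_iso), "punif",
                   log10(cfg$limits$d[1]), log10(cfg$limits$d[2])))
  expect_gt(ks$p.value, 0.01)
})

test_that("fit_weights recovers exactly representable signals and matches
           the brute-force oracle", {
  kd <- wide_kernel()
  cfg <- quick_config()
  set.seed(31)
  cand <- sample_candidates(cfg, 12)
  K <- dtdspec:::kernel_matrix(kd, cand)
  w_true <- numeric(12)
  w_true[c(2, 5, 9)] <- c(0.5, 1, 0.25)
  y <- as.numeric(K %*% w_true)
  w_fit <- fit_weights(kd, y, cand)
  expect_equal(w_fit, w_true, tolerance = 1e-6)
  # all-zero signals give all-zero weights
  expect_equal(fit_weights(kd, rep(0, length(kd$b)), cand),
               rep(0, 12))
  # noisy right-hand side: same optimum as support enumeration
  set.seed(32)
  cand8 <- sample_candidates(cfg, 8)
  K8 <- dtdspec:::kernel_matrix(kd, cand8)
  y8 <- as.numeric(K8 %*% runif(8, 0, 1)) + rnorm(length(kd$b), 0, 0.01)
  w1 <- fit_weights(kd, y8, cand8)
  oracle <- nnls_bruteforce(K8, y8)
  expect_equal(sum((y8 - K8 %*% w1)^2), oracle$obj, tolerance = 1e-10)
})

test_that("noiseless single-component voxels are recovered within 2%", {
  pw <- wide_protocol()
  kd <- wide_kernel()
  salt <- make_preset("salt")
  y <- signal(pw, salt, mode = "omega_dependent")
  sol <- invert_voxel(pw, y, quick_config(), kernel_data = kd)
  expect_false(sol$skipped)
  expect_lte(nrow(sol$components), 10)
  expect_equal(ensemble_mean(sol$components, "d_iso", 0), 0.4e-9,
               tolerance = 0.02)
  expect_equal(sol$s0, 1, tolerance = 0.02)
  # residual trace is non-increasing over proliferation rounds
  expect_true(all(diff(sol$rss_trace) <= 1e-12 * sol$rss_trace[1] + 1e-30))
})

test_that("inversion is deterministic for a fixed seed", {
  pw <- wide_protocol()
  kd <- wide_kernel()
  y <- signal(pw, make_preset("wm"), mode = "omega_dependent")
  s1 <- invert_voxel(pw, y, quick_config(seed = 5), kernel_data = kd)
  s2 <- invert_voxel(pw, y, quick_config(seed = 5), kernel_data = kd)
  expect_identical(s1$components, s2$components)
  s3 <- invert_voxel(pw, y, quick_config(seed = 6), kernel_data = kd)
  expect_false(identical(s1$components, s3$components))
})

test_that("dispersion-free voxels fit equally well in both modes", {
  pw <- wide_protocol()
  kd <- wide_kernel()
  y <- signal(pw, make_preset("lamellar"), mode = "omega_dependent")
  sol_om <- invert_voxel(pw, y, quick_config("omega_dependent"),
                         kernel_data = kd)
  sol_st <- invert_voxel(pw, y, quick_config("static"), kernel_data = kd)
  rms <- function(s) sqrt(mean((s$residuals / s$s0)^2))
  expect_lt(abs(rms(sol_om) - rms(sol_st)), 5e-3)
})

test_that("omega-dependent mode fits a dispersive voxel better than the
           static mode", {
  pw <- wide_protocol()
  kd <- wide_kernel()
  y <- signal(pw, make_preset("tumor"), mode = "omega_dependent")
  sol_om <- invert_voxel(pw, y, quick_config("omega_dependent"),
                         kernel_data = kd)
  sol_st <- invert_voxel(pw, y, quick_config("static"), kernel_data = kd)
  rms <- function(s) sqrt(mean((s$residuals / s$s0)^2))
  expect_lt(rms(sol_om), rms(sol_st))
})

test_that("residual_map normalizes by S0 and round-trips through
           serialization", {
  pw <- wide_protocol()
  kd <- wide_kernel()
  # exactly representable voxel: synthesized from candidate components
  cfg <- quick_config()
  set.seed(61)
  pool <- sample_candidates(cfg, 5)
  pool$w <- c(0.4, 0, 0.6, 0, 0.2)
  y_rep <- as.numeric(dtdspec:::kernel_matrix(kd, pool) %*% pool$w)
  sol_rep <- structure(list(components = pool[pool$w > 0, ]),
                       class = "voxel_solution")
  expect_lt(max(abs(residual_map(kd, y_rep, sol_rep))), 1e-6)
  # fitted salt voxel: residuals at the spectral-grid accuracy floor
  y <- signal(pw, make_preset("salt"), mode = "omega_dependent")
  sol <- invert_voxel(pw, y, quick_config(), kernel_data = kd)
  r <- residual_map(kd, y, sol)
  expect_lt(max(abs(r)), 2e-3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_components(sol$components, path)
  sol2 <- sol
  sol2$components <- read_components(path)
  r2 <- residual_map(kd, y, sol2)
  expect_equal(r, r2, tolerance = 1e-9)
  # pure-noise voxel: residual RMS tracks the noise level
  set.seed(44)
  sigma <- 0.02
  yn <- y + rnorm(length(y), 0, sigma)
  soln <- invert_voxel(pw, yn, quick_config(), kernel_data = kd)
  rn <- residual_map(kd, yn, soln)
  expect_equal(sd(rn) * soln$s0, sigma, tolerance = 0.25)
})

test_that("bootstrap is deterministic, nests the plain inversion and
           resamples full-length index sets", {
  pw <- wide_protocol()
  kd <- wide_kernel()
  y <- signal(pw, make_preset("salt"), mode = "omega_dependent")
  cfg <- quick_config()
  cfg$n_bootstrap <- 2
  bs1 <- bootstrap_invert(pw, y, cfg, kernel_data = kd, voxel_id = 3)
  bs2 <- bootstrap_invert(pw, y, cfg, kernel_data = kd, voxel_id = 3)
  expect_identical(bs1$solutions[[1]]$components,
                   bs2$solutions[[1]]$components)
  expect_true(all(lengths(bs1$index_sets) == length(y)))
  # degenerate bootstrap with the full index set equals invert_voxel
  cfg1 <- cfg
  cfg1$n_bootstrap <- 1
  bs <- bootstrap_invert(pw, y, cfg1, kernel_data = kd, voxel_id = 0,
                         full_resample = TRUE)
  direct <- invert_voxel(pw, y, cfg1, kernel_data = kd,
                         seed = dtdspec:::derive_seed(cfg1$seed, 0L, 1L))
  expect_identical(bs$solutions[[1]]$components, direct$components)
})

test_that("voxels below the signal floor are skipped with sentinels", {
  pw <- wide_protocol()
  kd <- wide_kernel()
  cfg <- quick_config()
  cfg$s0_floor <- 0.5
  sol <- invert_voxel(pw, rep(0.01, length(kd$b)), cfg, kernel_data = kd)
  expect_true(sol$skipped)
  expect_true(all(is.na(sol$residuals)))
  expect_true(all(is.na(solution_metrics(sol, bin_definition("mouse"),
                                         c(omega_50 = 0)))))
})
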
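test_that("component projections follow the axisymmetric formulas", {
  # planar-limit component: D_A ~ 0, D_R = 1.5e-9
  lam <- component_set(w = 1, d_a = 0, d_r = 1.5e-9)
  p <- project_component(lam)
  expect_equal(p$d_iso, 1.0e-9, tolerance = 1e-12)
  expect_equal(p$d_delta2, 0.25, tolerance = 1e-12)
  # isotropic
  iso <- component_set(w = 1, d_a = 0.7e-9, d_r = 0.7e-9)
  expect_equal(unlist(project_component(iso)),
               c(d_iso = 0.7e-9, d_delta2 = 0), tolerance = 1e-12)
  # stick limit
  stick <- component_set(w = 1, d_a = 2e-9, d_r = 0)
  expect_equal(project_component(stick)$d_delta2, 1)
  # degenerate: all-zero tensor is undefined
  zero <- component_set(w = 1, d_a = 0, d_r = 0)
  expect_true(all(is.na(project_component(zero))))
  # frequency dependence moves the projection toward d_0
  tum <- make_preset("tumor")
  p35 <- project_component(tum, 2 * pi * 35)
  p320 <- project_component(tum, 2 * pi * 320)
  expect_gt(p320$d_iso, p35$d_iso)
})

test_that("bin fractions partition unity with the documented boundary
           rule", {
  bins <- bin_definition("mouse")
  wmc <- component_set(w = 1, d_a = 0.5772e-9, d_r = 0.0113e-9)
  expect_equal(unname(bin_fractions(wmc, bins)), c(1, 0, 0))
  csf <- component_set(w = 1, d_a = 3e-9, d_r = 3e-9)
  two <- rbind(wmc, csf)
  class(two) <- class(wmc)
  expect_equal(unname(bin_fractions(two, bins)), c(0.5, 0, 0.5))
  # boundary: exactly at d_delta2 = 0.25 goes to bin 2 (closed lower set)
  border <- component_set(w = 1, d_a = 0, d_r = 1.5e-9 * 0.5)
  expect_equal(project_component(border)$d_delta2, 0.25)
  expect_equal(unname(bin_fractions(border, bins)), c(0, 1, 0))
  # human preset splits at 2e-9
  mid <- component_set(w = 1, d_a = 1.5e-9, d_r = 1.5e-9)
  expect_equal(unname(bin_fractions(mid, bin_definition("human"))),
               c(0, 1, 0))
  expect_equal(unname(bin_fractions(mid, bins)), c(0, 0, 1))
  # zero total weight: undefined
  none <- component_set(w = 0, d_a = 1e-9, d_r = 1e-9)
  expect_true(all(is.na(bin_fractions(none, bins))))
  expect_equal(sum(bin_fractions(two, bins)), 1, tolerance = 1e-9)
})

test_that("rgb max-normalizes and is permutation equivariant", {
  expect_equal(unname(rgb_composite(c(0.2, 0.3, 0.5))), c(0.4, 0.6, 1.0))
  expect_equal(unname(rgb_composite(c(1, 0, 0))), c(1, 0, 0))
  f <- c(0.1, 0.6, 0.3)
  perm <- c(3, 1, 2)
  expect_equal(unname(rgb_composite(f[perm])),
               unname(rgb_composite(f))[perm])
  # idempotent on already-normalized input
  expect_equal(unname(rgb_composite(rgb_composite(f))),
               unname(rgb_composite(f)))
  expect_true(all(is.na(rgb_composite(c(0, 0, 0)))))
})

test_that("ensemble means are weighted, bounded and scale-invariant", {
  cs <- component_set(w = c(1, 1), d_a = c(1e-9, 3e-9),
                      d_r = c(1e-9, 3e-9), r_1 = c(1, 3), r_2 = c(10, 30))
  expect_equal(ensemble_mean(cs, "d_iso"), 2e-9)
  expect_equal(ensemble_mean(cs, "r_1"), 2)
  one <- cs[1, ]
  expect_equal(ensemble_mean(one, "r_2"), 10)
  cs2 <- cs
  cs2$w <- cs$w * 7
  expect_equal(ensemble_mean(cs2, "d_iso"), ensemble_mean(cs, "d_iso"))
  expect_gte(ensemble_mean(cs, "d_iso"), 1e-9)
  expect_lte(ensemble_mean(cs, "d_iso"), 3e-9)
})

test_that("dispersion metric implements the frequency-window slope", {
  # values printed for a restricted tumor-like ensemble
  d <- dispersion_metric(1.1e-9, 0.84e-9, 2 * pi * 320, 2 * pi * 35)
  expect_equal(d, (1.1e-9 - 0.84e-9) / 285, tolerance = 1e-12)
  expect_equal(d, 9.12e-13, tolerance = 0.01)
  expect_equal(dispersion_metric(0.5, 0.5, 100, 10), 0)
  expect_lt(dispersion_metric(0.3, 0.5, 100, 10), 0)
  expect_error(dispersion_metric(1, 1, 10, 10), "exceed")
})

test_that("normalized difference and SNR estimates behave", {
  expect_equal(normalized_difference(1.1, 0.9), 20)
  expect_equal(normalized_difference(0.9, 1.1), -20)
  expect_equal(normalized_difference(3, 3), 0)
  expect_true(is.na(normalized_difference(1, -1)))
  set.seed(2)
  resid <- rnorm(5000, 0, 0.02)
  expect_equal(snr_estimate(1, resid), 50, tolerance = 0.05)
})

test_that("mesh projection conserves mass and resolves separated
           components", {
  one <- component_set(w = 0.8, d_a = 1e-9, d_r = 1e-9)
  m1 <- mesh_projection(one)
  expect_equal(sum(m1$weights), 0.8, tolerance = 1e-6)
  two <- component_set(w = c(1, 1), d_a = c(0.1e-9, 3e-9),
                       d_r = c(0.1e-9, 3e-9))
  m2 <- mesh_projection(two)
  expect_equal(sum(m2$weights), 2, tolerance = 1e-6)
  # two local maxima of equal mass in separated halves
  half <- ncol(m2$weights)
  ix <- which(m2$weights == max(m2$weights), arr.ind = TRUE)
  lo <- sum(m2$weights[m2$d_iso_axis < log10(1e-9), ])
  hi <- sum(m2$weights[m2$d_iso_axis > log10(1e-9), ])
  expect_equal(lo, hi, tolerance = 1e-6)
  # kernel spill at the d_delta2 = 0 edge is clipped, not lost
  edge <- component_set(w = 1, d_a = 1e-9, d_r = 1e-9)  # d_delta2 = 0
  me <- mesh_projection(edge)
  expect_equal(sum(me$weights), 1, tolerance = 1e-6)
  expect_gt(sum(me$weights[, 1]), 0)
  # out-of-range component is clipped to the edge cell
  out <- component_set(w = 1, d_a = 4.9e-9, d_r = 4.9e-9)
  mo <- mesh_projection(out, d_iso_range = c(1e-11, 1e-9))
  expect_equal(sum(mo$weights), 1, tolerance = 1e-6)
})

test_that("ROI pooling and map assembly aggregate solutions as
           documented", {
  mk_sol <- function(w, d) structure(
    list(components = component_set(w = w, d_a = d, d_r = d),
         residuals = rep(0.001, 10)),
    class = "voxel_solution")
  s1 <- mk_sol(1, 0.5e-9)
  s2 <- mk_sol(2, 2e-9)
  roi <- roi_projection(list(s1, s2))
  expect_equal(sum(roi$weights), 3, tolerance = 1e-6)
  # one-voxel ROI equals that voxel's own mesh
  expect_equal(roi_projection(list(s1))$weights,
               mesh_projection(s1$components)$weights)
  # replicate-constant ensemble: median equals any replicate
  ens <- structure(list(solutions = list(s1, s1, s1)),
                   class = "bootstrap_ensemble")
  maps <- map_assembly(list(ens), bin_definition("mouse"),
                       c(omega_50 = 0))
  expect_equal(maps$s0[1], 1)
  expect_equal(maps$e_d_iso_omega_50[1], 0.5e-9)
  # doubling weights doubles S0, leaves fractions and means unchanged
  s1d <- mk_sol(2, 0.5e-9)
  ensd <- structure(list(solutions = list(s1d, s1d, s1d)),
                    class = "bootstrap_ensemble")
  mapsd <- map_assembly(list(ensd), bin_definition("mouse"),
                        c(omega_50 = 0))
  expect_equal(mapsd$s0[1], 2)
  expect_equal(mapsd$e_d_iso_omega_50[1], maps$e_d_iso_omega_50[1])
  expect_equal(mapsd$f_bin2[1], maps$f_bin2[1])
})
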
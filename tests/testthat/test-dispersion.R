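test_that("Lorentzian eigenvalue spectra hit their limits and mid-point", {
  comp <- component_set(w = 1, d_a = 0.8e-9, d_r = 0.2e-9,
                        d_0 = 1.0e-9, gamma_a = 500, gamma_r = 2 * pi * 50)
  ev0 <- eigenvalue_spectra(comp[1, ], 0)
  expect_identical(c(ev0$d_a, ev0$d_r), c(comp$d_a, comp$d_r))
  evi <- eigenvalue_spectra(comp[1, ], 1e6 * comp$gamma_r)
  expect_equal(evi$d_r, 1.0e-9, tolerance = 1e-10)
  expect_equal(evi$d_a, 1.0e-9, tolerance = 1e-3)
  # mid-point of the radial transition at omega = gamma_r
  evm <- eigenvalue_spectra(comp[1, ], comp$gamma_r)
  expect_equal(evm$d_r, 0.6e-9)
  # even in omega
  expect_equal(eigenvalue_spectra(comp[1, ], -123)$d_a,
               eigenvalue_spectra(comp[1, ], 123)$d_a)
  # static components are constant
  st <- component_set(w = 1, d_a = 1e-9, d_r = 0.1e-9)
  expect_equal(eigenvalue_spectra(st[1, ], 1e5)$d_a, 1e-9)
})

test_that("tensor_spectrum builds the rotated axisymmetric tensor", {
  comp <- component_set(w = 1, d_a = 1e-9, d_r = 0.2e-9, theta = 0)
  expect_equal(tensor_spectrum(comp[1, ], 0),
               diag(c(0.2e-9, 0.2e-9, 1e-9)))
  # trace invariant under orientation
  for (th in c(0.3, 1.2)) {
    c2 <- component_set(w = 1, d_a = 1e-9, d_r = 0.2e-9, theta = th,
                        phi = 0.7)
    m <- tensor_spectrum(c2[1, ], 0)
    expect_equal(sum(diag(m)), 1.4e-9)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(ev), sort(c(0.2e-9, 0.2e-9, 1e-9)))
    # symmetry axis is the stated unit vector
    ax <- c(sin(th) * cos(0.7), sin(th) * sin(0.7), cos(th))
    expect_equal(as.numeric(m %*% ax), 1e-9 * ax)
  }
  # degenerate sphere: isotropic at all frequencies
  iso <- component_set(w = 1, d_a = 1e-9, d_r = 1e-9, d_0 = 1e-9,
                       gamma_a = 100, gamma_r = 100)
  expect_equal(tensor_spectrum(iso[1, ], 777), diag(rep(1e-9, 3)))
})

test_that("attenuation reduces to exp(-b D) without dispersion and is 1
           at b = 0", {
  enc <- acquisition_encoding(double_rotation_waveform(1, 6e-3, 0, 1.5e8))
  iso <- component_set(w = 1, d_a = 0.7e-9, d_r = 0.7e-9)
  expect_equal(attenuation(enc, iso[1, ]), exp(-enc$b * 0.7e-9),
               tolerance = 1e-9)
  # zero encoding
  enc0 <- acquisition_encoding(gradient_waveform(matrix(0, 64, 3), 1e-5))
  expect_equal(attenuation(enc0, iso[1, ]), 1)
  # anisotropic static component against the tensor contraction oracle
  an <- component_set(w = 1, d_a = 1.5e-9, d_r = 0.1e-9, theta = 0.9,
                      phi = -1.2)
  d <- tensor_spectrum(an[1, ], 0)
  expect_equal(attenuation(enc, an[1, ]),
               exp(-sum(enc$b_tensor * d)), tolerance = 1e-9)
})

test_that("attenuation of a Lorentzian component converges with padding", {
  enc8 <- acquisition_encoding(double_rotation_waveform(2, 6e-3, -0.5, 8e7),
                               n_pad = 8)
  enc16 <- acquisition_encoding(double_rotation_waveform(2, 6e-3, -0.5, 8e7),
                                n_pad = 16)
  lor <- component_set(w = 1, d_a = 0.3e-9, d_r = 0.3e-9, d_0 = 1.2e-9,
                       gamma_a = 2 * pi * 100, gamma_r = 2 * pi * 100)
  expect_equal(attenuation(enc8, lor[1, ]), attenuation(enc16, lor[1, ]),
               tolerance = 1e-4)
})

test_that("signal superposes components and recovers S0 in the
           extrapolation limit", {
  pw <- wide_protocol()
  c1 <- make_preset("salt")
  c2 <- make_preset("csf", overrides = list(w = 0.5))
  both <- rbind(c1, c2)
  class(both) <- class(c1)
  s1 <- signal(pw, c1, mode = "omega_dependent")
  s2 <- signal(pw, c2, mode = "omega_dependent")
  s12 <- signal(pw, both, mode = "omega_dependent")
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
  # S0 limit: b = 0, tau_e = 0, tau_r huge
  tb0 <- data.frame(n_acq = 1, waveform_id = "w", b = 0, tau_r = 1e6 / 0.3,
                    tau_e = 0, b_delta = NA, theta = 0, phi = 0,
                    omega_cent = NA)
  p0 <- protocol(tb0)
  expect_equal(signal(p0, both, mode = "static",
                      static_dispersion = "low_frequency"),
               s0(both), tolerance = 1e-4)
})

test_that("omega-dependent and static synthesis agree for dispersion-free
           components", {
  pw <- wide_protocol()
  comp <- component_set(w = 1, d_a = 1.2e-9, d_r = 0.3e-9, theta = 0.5,
                        phi = 0.3, d_0 = 1.2e-9, gamma_a = 300,
                        gamma_r = 300)
  comp$d_0 <- comp$d_a <- comp$d_r <- 0.8e-9  # no dispersion left
  s_om <- signal(pw, comp, mode = "omega_dependent")
  s_st <- signal(pw, comp, mode = "static",
                 static_dispersion = "low_frequency")
  expect_equal(s_om, s_st, tolerance = 1e-9)
  # static mode refuses dispersive components unless told otherwise
  tum <- make_preset("tumor")
  expect_error(signal(pw, tum, mode = "static"), "static mode")
  expect_silent(signal(pw, tum, mode = "static",
                       static_dispersion = "low_frequency"))
})

test_that("signals decrease with b and tau_e and increase with tau_r", {
  pw <- wide_protocol()
  set.seed(5)
  cfg <- inversion_config("omega_dependent", "preclinical")
  for (k in 1:5) {
    comp <- sample_candidates(cfg, 1)
    comp$w <- 1
    tb <- pw$table
    s <- signal(pw, comp, mode = "omega_dependent")
    # at fixed waveform/rotation/relaxation, larger b attenuates more
    key <- interaction(tb$waveform_id, tb$theta, tb$phi, tb$tau_r,
                       tb$tau_e, drop = TRUE)
    for (g in split(seq_len(nrow(tb)), key)) {
      if (length(g) < 2) next
      ord <- order(tb$b[g])
      expect_true(all(diff(s[g][ord]) <= 1e-12))
    }
    # relaxation monotonicity: within fixed diffusion encoding and tau_e,
    # the signal grows with tau_r; within fixed tau_r it decays with tau_e
    keyr <- interaction(tb$waveform_id, tb$b, tb$theta, tb$phi, tb$tau_e,
                        drop = TRUE)
    for (g in split(seq_len(nrow(tb)), keyr)) {
      if (length(unique(tb$tau_r[g])) < 2) next
      ord <- order(tb$tau_r[g])
      expect_true(all(diff(s[g][ord]) >= -1e-12))
    }
    keye <- interaction(tb$waveform_id, tb$b, tb$theta, tb$phi, tb$tau_r,
                        drop = TRUE)
    for (g in split(seq_len(nrow(tb)), keye)) {
      if (length(unique(tb$tau_e[g])) < 2) next
      ord <- order(tb$tau_e[g])
      expect_true(all(diff(s[g][ord]) <= 1e-12))
    }
  }
})

test_that("isotropic (spherical) encoding is invariant under component
           reorientation", {
  enc <- acquisition_encoding(double_rotation_waveform(1, 8e-3, 0, 5e8))
  set.seed(9)
  base <- component_set(w = 1, d_a = 1.6e-9, d_r = 0.1e-9, theta = 0,
                        phi = 0)
  a0 <- attenuation(enc, base[1, ])
  for (k in 1:10) {
    rot <- base
    rot$theta <- acos(runif(1, -1, 1))
    rot$phi <- runif(1, -pi, pi)
    expect_equal(attenuation(enc, rot[1, ]), a0, tolerance = 1e-4)
  }
})

test_that("powder average at linear encoding is bounded by the aligned
           cases", {
  enc <- acquisition_encoding(double_rotation_waveform(0, 8e-3, 1, 5e8))
  set.seed(21)
  cfg <- inversion_config("omega_dependent", "preclinical")
  comps <- sample_candidates(cfg, 20)
  for (i in seq_len(nrow(comps))) {
    comp <- comps[i, ]
    # powder average over 200 uniform orientations
    u <- runif(200, -1, 1)
    ph <- runif(200, -pi, pi)
    av <- mean(vapply(seq_along(u), function(j) {
      c2 <- comp
      c2$theta <- acos(u[j])
      c2$phi <- ph[j]
      attenuation(enc, c2)
    }, 0))
    perp <- comp
    perp$theta <- pi / 2  # encoding axis is z for the generator
    aperp <- attenuation(enc, perp)
    apar <- comp
    apar$theta <- 0
    apar_v <- attenuation(enc, apar)
    lo <- min(aperp, apar_v) - 1e-9
    expect_gte(av, lo)
    expect_lte(av, 1)
  }
})
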
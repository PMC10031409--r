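test_that("simulation is deterministic and validates its scenario", {
  g <- default_geometry()
  sc <- phantom_scenario(stroke_center = c(0.03, 0.02), seed = 42)
  a <- simulate_sweepset(g, sc)
  b <- simulate_sweepset(g, sc)
  expect_identical(a$s11, b$s11)

  expect_error(simulate_sweepset(g, phantom_scenario(stroke_center = c(0.2, 0))),
               "domain error")
  expect_error(paired_scenario(g, phantom_scenario()), "usage error")
})

test_that("clutter-free healthy backgrounds are exactly mirror-symmetric", {
  g <- default_geometry()
  s <- simulate_sweepset(g, phantom_scenario(clutter_level = 0, noise_level = 0))
  m <- mirror_index(seq_len(g$L), g$L)
  for (i in seq_len(g$L))
    expect_identical(s$s11[i, ], s$s11[m[i], ])
})

test_that("the stroke adds a single complex exponential of the predicted delay and amplitude", {
  g <- default_geometry()
  q <- c(0.03, 0.025)
  sc1 <- phantom_scenario(stroke_center = q, seed = 3)
  sc0 <- phantom_scenario(seed = 3)
  # same clutter seed and same noise stream: the difference is the echo alone
  withs <- simulate_sweepset(g, sc1, noise_seed = 77L)
  without <- simulate_sweepset(g, sc0, noise_seed = 77L)
  diff <- withs$s11 - without$s11

  # independent prediction from the geometry
  pts <- mwstroke:::geometry_points(g)
  d <- sqrt((pts$skin[, 1] - q[1])^2 + (pts$skin[, 2] - q[2])^2)
  amp <- sc1$stroke_reflectivity * exp(-d / sc1$attenuation_length)
  delay <- 2 * (g$standoff / 299792458 + d * sqrt(45) / 299792458)
  for (i in seq_len(g$L)) {
    expect_equal(Mod(diff[i, ]), rep(amp[i], 401), tolerance = 1e-12)
    expect_equal(diff[i, ], amp[i] * exp(-2i * pi * withs$freq_hz * delay[i]),
                 tolerance = 1e-10)
  }
})

test_that("paired scenario isolates the target echo under App-1", {
  g <- default_geometry()
  sc <- phantom_scenario(stroke_center = c(0.03, 0.025), noise_level = 0, seed = 9)
  pair <- paired_scenario(g, sc)
  resp <- remove_background_app1(to_time_domain(pair$target),
                                 to_time_domain(pair$healthy))
  # compare against the echo-only sweep, transformed on its own
  echo_only <- pair$target$s11 - pair$healthy$s11
  ref <- to_time_domain(sweep_set(g, pair$target$freq_hz, echo_only))
  expect_equal(resp$responses, ref$samples, tolerance = 1e-10)
  expect_gt(sum(resp$responses^2), 0)
})

test_that("with noise the App-1 response energy matches the echo + noise budget", {
  g <- default_geometry()
  nseeds <- 30
  ratio <- numeric(nseeds)
  for (k in seq_len(nseeds)) {
    sc <- phantom_scenario(stroke_center = c(0.03, 0.025), noise_level = 0.02,
                           seed = 5000 + k)
    pair <- paired_scenario(g, sc)
    resp <- remove_background_app1(to_time_domain(pair$target),
                                   to_time_domain(pair$healthy))
    n_fft <- ncol(resp$responses)
    # Parseval: time energy = (2/n_fft) * sum over band bins of |S|^2;
    # the echo term and two independent noise draws add in expectation
    # independent budget: echo energy from the closed-form amplitudes
    pts <- mwstroke:::geometry_points(g)
    d <- sqrt((pts$skin[, 1] - sc$stroke_center[1])^2 +
              (pts$skin[, 2] - sc$stroke_center[2])^2)
    amp <- sc$stroke_reflectivity * exp(-d / sc$attenuation_length)
    echo_energy <- 2 * 401 * sum(amp^2) / n_fft
    noise_energy <- 2 * 401 * g$L * 2 * sc$noise_level^2 / n_fft
    ratio[k] <- sum(resp$responses^2) / (echo_energy + noise_energy)
  }
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("mirroring the stroke position mirrors which half records the energy", {
  g <- default_geometry()
  for (q in list(c(0.03, 0.025), c(-0.04, 0.02))) {
    up <- paired_scenario(g, phantom_scenario(stroke_center = q,
                                              noise_level = 0, seed = 1))
    dn <- paired_scenario(g, phantom_scenario(stroke_center = q * c(1, -1),
                                              noise_level = 0, seed = 1))
    e_up <- rowSums(remove_background_app1(to_time_domain(up$target),
                                           to_time_domain(up$healthy))$responses^2)
    e_dn <- rowSums(remove_background_app1(to_time_domain(dn$target),
                                           to_time_domain(dn$healthy))$responses^2)
    upper <- 2:8   # antennas on the positive-y half
    lower <- 10:16
    expect_gt(sum(e_up[upper]), sum(e_up[lower]))
    expect_gt(sum(e_dn[lower]), sum(e_dn[upper]))
    expect_equal(e_up, e_dn[c(1L, 16:2)], tolerance = 1e-6)  # mirrored profile
  }
})

test_that("post-removal wavelet energy grows with stroke reflectivity", {
  g <- default_geometry()
  w <- make_mother_wavelet(33)
  bank <- filter_bank_config(scales = seq(1, 16, length.out = 8))
  q <- c(0.03, 0.025)
  near <- nearest_antenna(g, q)
  energies <- vapply(c(0.02, 0.05, 0.1, 0.2), function(refl) {
    sc <- phantom_scenario(stroke_center = q, stroke_reflectivity = refl,
                           noise_level = 0, seed = 21)
    pair <- paired_scenario(g, sc)
    resp <- remove_background_app1(to_time_domain(pair$target),
                                   to_time_domain(pair$healthy))
    grid <- wavelet_transform(resp$responses[near, ], w, bank)
    sum(grid$C^2)
  }, numeric(1))
  expect_true(all(diff(energies) > 0))
})
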
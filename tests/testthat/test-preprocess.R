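test_that("time-domain transform matches the direct DFT-sum oracle", {
  g <- array_geometry(L = 4)
  n <- 31L
  freq <- seq(1.1e9, 3e9, length.out = n)

  # flat unit spectrum, zero phase
  flat <- sweep_set(g, freq, matrix(1 + 0i, 4, n))
  ts <- to_time_domain(flat, n_fft = 256)
  oracle <- oracle_band_to_time(rep(1 + 0i, n), freq, 256)
  for (i in 1:4) expect_equal(ts$samples[i, ], oracle, tolerance = 1e-9)
  expect_equal(which.max(abs(oracle)), 1L)  # pulse peaks at t = 0
  expect_equal(ts$dt, 1 / (256 * diff(freq)[1]), tolerance = 1e-12)

  # single complex exponential: envelope peak lands at the sample nearest tau0
  n_fft <- 512L
  dt <- 1 / (n_fft * diff(freq)[1])
  tau0 <- 37 * dt
  s11 <- matrix(exp(-2i * pi * freq * tau0), 4, n, byrow = TRUE)
  ts2 <- to_time_domain(sweep_set(g, freq, s11), n_fft = n_fft)
  oracle2 <- oracle_band_to_time(s11[1, ], freq, n_fft)
  expect_equal(ts2$samples[1, ], oracle2, tolerance = 1e-9)
  expect_equal(which.max(abs(ts2$samples[1, ])) - 1L, 37L)

  # all-zero spectrum and the n_fft precondition
  z <- to_time_domain(sweep_set(g, freq, matrix(0 + 0i, 4, n)), n_fft = 256)
  expect_true(all(z$samples == 0))
  expect_error(to_time_domain(flat, n_fft = 16), "parameter error")
})

test_that("App-1 subtracts the healthy reference linearly", {
  g <- array_geometry(L = 4)
  healthy <- random_tset(g, n = 32, seed = 1)
  expect_true(all(remove_background_app1(healthy, healthy)$responses == 0))

  pulse <- healthy$samples
  pulse[2, 10] <- pulse[2, 10] + 5
  target <- time_signal_set(g, healthy$dt, pulse)
  r <- remove_background_app1(target, healthy)
  expect_equal(r$responses[2, 10], 5)
  expect_true(all(r$responses[-2, ] == 0))
  expect_identical(remove_background_app1(healthy, target)$responses, -r$responses)
  bad <- time_signal_set(g, healthy$dt, healthy$samples[, -1])
  expect_error(remove_background_app1(target, bad), "consistency error")
})

test_that("App-2 differences adjacent antennas with a circular wrap", {
  g <- array_geometry(L = 8)
  const <- time_signal_set(g, 1e-10, matrix(rep(rnorm(16), each = 8), 8, 16))
  expect_true(all(remove_background_app2(const)$responses == 0))

  x <- random_tset(g, n = 16, seed = 2)
  r <- remove_background_app2(x)$responses
  expect_equal(colSums(r), rep(0, 16), tolerance = 1e-12)  # telescoping
  expect_equal(r[1, ], x$samples[1, ] - x$samples[8, ])

  # a pulse at antenna k shows up positive in row k and negative in row k+1
  z <- time_signal_set(g, 1e-10, matrix(0, 8, 16))
  z$samples[3, 7] <- 1
  rp <- remove_background_app2(z)$responses
  expect_equal(rp[3, 7], 1)
  expect_equal(rp[4, 7], -1)
  expect_equal(sum(rp != 0), 2L)
})

test_that("App-3 is exactly antisymmetric and clipping disjoins mirrored supports", {
  g <- default_geometry()
  x <- random_tset(g, n = 64, seed = 3)
  r <- remove_background_app3(x)$responses
  m <- mirror_index(1:16, 16)
  for (i in 1:16) expect_identical(r[i, ], -r[m[i], ])  # bit-level negation
  expect_true(all(r[c(1, 9), ] == 0))                    # axis antennas

  # mirror-symmetric input vanishes
  sym <- x$samples[m, , drop = FALSE]
  xs <- time_signal_set(g, x$dt, (x$samples + sym) / 2)
  expect_true(all(remove_background_app3(xs)$responses == 0))

  rc <- remove_background_app3(x, clip_negative = TRUE)
  expect_true(rc$clipped)
  expect_true(all(rc$responses >= 0))
  for (i in 2:16) if (i != 9)
    expect_true(all(rc$responses[i, ] * rc$responses[m[i], ] == 0))
})

test_that("App-4 subtracts the all-antenna or neighbour average", {
  g <- array_geometry(L = 4)
  const <- time_signal_set(g, 1e-10, matrix(rep(rnorm(12), each = 4), 4, 12))
  expect_true(all(remove_background_app4(const, "all")$responses == 0))

  x <- random_tset(g, n = 12, seed = 4)
  r <- remove_background_app4(x, "all")$responses
  expect_equal(colSums(r), rep(0, 12), tolerance = 1e-12)  # mean-centred

  rn <- remove_background_app4(x, "neighbors", k = 1)$responses
  s <- x$samples
  expect_equal(rn[1, ], s[1, ] - (s[4, ] + s[2, ]) / 2)
  expect_equal(rn[3, ], s[3, ] - (s[2, ] + s[4, ]) / 2)
  expect_error(remove_background_app4(x, "neighbors", k = 2), "parameter error")
})

test_that("App-5 averages opposite antennas and breaks the App-3 antisymmetry", {
  g <- array_geometry(L = 4)
  # single-sample hand check; mirror map for L=4: 1->1, 2->4, 3->3, 4->2
  s <- c(1, 2, 4, 8)
  x <- time_signal_set(g, 1e-10, matrix(s, 4, 1))
  ra <- remove_background_app5(x, "a")$responses[, 1]
  expect_equal(ra, c(1 - (2 + 1 + 8) / 3,   # i=1: next 2, mirror 1, mirror(next) 4
                     2 - (4 + 8 + 4) / 3,   # i=2: next 3, mirror 4, mirror(3)=3
                     4 - (8 + 4 + 2) / 3,   # i=3: next 4, mirror 3, mirror(4)=2
                     8 - (1 + 2 + 1) / 3))  # i=4: next 1, mirror 2, mirror(1)=1
  rb <- remove_background_app5(x, "b")$responses[, 1]
  expect_equal(rb, c(1 - (1 + 8) / 2, 2 - (8 + 4) / 2,
                     4 - (4 + 2) / 2, 8 - (2 + 1) / 2))

  # mirror-symmetric AND circularly-constant input vanishes
  g16 <- default_geometry()
  const <- time_signal_set(g16, 1e-10, matrix(rep(rnorm(8), each = 16), 16, 8))
  expect_true(all(remove_background_app5(const, "a")$responses == 0))
  expect_true(all(remove_background_app5(const, "b")$responses == 0))

  # unlike App-3, mirrored responses are not negations on generic input
  xr <- random_tset(g16, n = 32, seed = 6)
  m <- mirror_index(1:16, 16)
  for (v in c("a", "b")) {
    r <- remove_background_app5(xr, v)$responses
    expect_gt(max(abs(r + r[m, , drop = FALSE])), 0.1)
  }
})

test_that("every removal approach is linear (except clipped App-3)", {
  g <- default_geometry()
  x1 <- random_tset(g, n = 24, seed = 7)
  x2 <- random_tset(g, n = 24, seed = 8)
  mix <- time_signal_set(g, x1$dt, 2 * x1$samples - 3 * x2$samples)
  ops <- list(
    function(t) remove_background_app2(t),
    function(t) remove_background_app3(t),
    function(t) remove_background_app4(t, "all"),
    function(t) remove_background_app4(t, "neighbors", k = 3),
    function(t) remove_background_app5(t, "a"),
    function(t) remove_background_app5(t, "b"))
  for (op in ops) {
    expect_equal(op(mix)$responses,
                 2 * op(x1)$responses - 3 * op(x2)$responses,
                 tolerance = 1e-12)
  }
  # clipping is deliberately nonlinear
  rc <- function(t) remove_background_app3(t, clip_negative = TRUE)$responses
  expect_gt(max(abs(rc(mix) - (2 * rc(x1) - 3 * rc(x2)))), 0.1)
})
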
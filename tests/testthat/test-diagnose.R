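zero_profiles <- function(L = 16L, nscale = 3L, nshift = 5L) {
  lapply(seq_len(L), function(i)
    structure(list(antenna = i, opposite = mirror_index(i, L),
                   omega_scale = numeric(nscale), omega_time = numeric(nshift),
                   epsilon = 1e-300), class = "distance_profile"))
}

test_that("uniform evidence yields an undetected, id-ordered ranking", {
  r <- rank_by_distance(zero_profiles())
  expect_identical(r$ranked$antenna, 1:16)
  expect_true(all(r$ranked$score == 0))
  rep <- detect(r)
  expect_false(rep$detected)
  expect_identical(rep$side, "undetermined")

  grids <- lapply(1:16, function(i) random_grid(3, 5, seed = 1, antenna = i))
  bundles <- lapply(grids, compute_bundle)
  re <- rank_by_energy(bundles)
  rh <- rank_by_entropy(bundles)
  expect_identical(re$ranked$antenna, 1:16)  # ties break by id
  expect_identical(rh$ranked$antenna, 1:16)
  expect_false(detect(list(re, rh))$detected)
})

test_that("rankings are score-sorted permutations and react to energy scaling", {
  grids <- lapply(1:16, function(i) random_grid(4, 7, seed = 30 + i, antenna = i))
  # doubling antenna 12's coefficients quadruples its energy -> rank 1
  grids[[12]] <- coefficient_grid(2 * grids[[12]]$C, grids[[12]]$scale_axis,
                                  grids[[12]]$shift_axis, 12L)
  bundles <- lapply(grids, compute_bundle)
  r <- rank_by_energy(bundles)
  expect_setequal(r$ranked$antenna, 1:16)
  expect_true(all(diff(r$ranked$score) <= 0))
  expect_identical(r$ranked$antenna[1], 12L)
  expect_equal(r$ranked$score[1], 4 * sum(random_grid(4, 7, seed = 42)$C^2),
               tolerance = 1e-12)

  profs <- compute_distances(grids, default_geometry())
  rd <- rank_by_distance(profs)
  expect_setequal(rd$ranked$antenna, 1:16)
  expect_true(all(diff(rd$ranked$score) <= 0))
  # determinism
  expect_identical(rd$ranked, rank_by_distance(profs)$ranked)
})

test_that("mirror ties resolve to the antenna on the stroke side", {
  L <- 16L
  profs <- zero_profiles(L)
  # antenna 6 records energy above its mirror 12: positive profile at 6
  profs[[6]]$omega_scale <- c(5, 3, 2)
  profs[[6]]$omega_time <- c(1, 2, 1, 0, 1)
  profs[[12]]$omega_scale <- -profs[[6]]$omega_scale
  profs[[12]]$omega_time <- -profs[[6]]$omega_time
  r <- rank_by_distance(profs)
  expect_identical(r$ranked$antenna[1:2], c(6L, 12L))  # signed sum breaks the tie
  expect_identical(r$side, "left")

  # the mirrored configuration points to the right half
  profs2 <- zero_profiles(L)
  profs2[[12]]$omega_scale <- c(5, 3, 2)
  profs2[[12]]$omega_time <- c(1, 2, 1, 0, 1)
  profs2[[6]]$omega_scale <- -profs2[[12]]$omega_scale
  profs2[[6]]$omega_time <- -profs2[[12]]$omega_time
  r2 <- rank_by_distance(profs2)
  expect_identical(r2$ranked$antenna[1], 12L)
  expect_identical(r2$side, "right")
  expect_true(detect(r2)$detected)  # concentrated evidence clears threshold 2
})

test_that("the detection rule honours its threshold semantics", {
  profs <- zero_profiles()
  profs[[6]]$omega_scale <- c(5, 3, 2)
  profs[[12]]$omega_scale <- -profs[[6]]$omega_scale
  r <- rank_by_distance(profs)
  expect_true(detect(r, threshold = 2)$detected)
  expect_false(detect(r, threshold = Inf)$detected)   # limit behaviour
  expect_error(detect(r, threshold = 0), "parameter error")
  expect_error(detect(list()), "usage error")

  # combined report aggregates by Borda count
  grids <- lapply(1:16, function(i) random_grid(4, 7, seed = 50 + i, antenna = i))
  grids[[3]] <- coefficient_grid(5 * grids[[3]]$C, grids[[3]]$scale_axis,
                                 grids[[3]]$shift_axis, 3L)
  bundles <- lapply(grids, compute_bundle)
  rep <- detect(list(rank_by_energy(bundles), rank_by_entropy(bundles)),
                approach = "app1")
  expect_identical(rep$method, "combined")
  expect_setequal(rep$ranked_antennas$antenna, 1:16)
  expect_identical(rep$approach, "app1")
  expect_named(rep$contrasts, c("energy", "entropy"))
})

test_that("a clutter-free stroke near antenna 6 is localized by the distance ranking", {
  g <- default_geometry()
  th <- g$angles[6] + 0.1
  q <- 0.62 * c(g$semi_axes[1] * cos(th), g$semi_axes[2] * sin(th))
  sc <- phantom_scenario(stroke_center = q, clutter_level = 0, noise_level = 0,
                         seed = 2)
  scan <- run_pipeline(run_config(scenario = sc, approach = "app1"))
  expect_true(scan$report$ranked_antennas$antenna[1] %in% 5:7)
  expect_true(scan$report$detected)
  expect_identical(scan$report$side, "left")

  # mirrored stroke -> mirrored top antenna
  sc2 <- phantom_scenario(stroke_center = q * c(1, -1), clutter_level = 0,
                          noise_level = 0, seed = 2)
  scan2 <- run_pipeline(run_config(scenario = sc2, approach = "app1"))
  expect_identical(scan2$report$ranked_antennas$antenna[1],
                   mirror_index(scan$report$ranked_antennas$antenna[1], 16L))
  expect_identical(scan2$report$side, "right")
})

test_that("max-energy and min-entropy point to the same antenna on clutter-free App-1 runs", {
  sc <- phantom_scenario(stroke_center = c(0.03, 0.025), clutter_level = 0,
                         seed = 1)
  scan <- run_pipeline(run_config(scenario = sc, approach = "app1",
                                  methods = c("energy", "entropy")))
  expect_identical(scan$rankings[[1]]$ranked$antenna[1],
                   scan$rankings[[2]]$ranked$antenna[1])
})
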
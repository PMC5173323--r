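test_that("config validation rejects bad models and parameters", {
  expect_error(sim_config("levy", list(step = 1), 5, 5), "unknown motion")
  expect_error(sim_config("random_walk", list(step = -1), 5, 5), ">= 0")
  expect_error(sim_config("random_walk", list(step = 1), 0, 5), "n_tracks")
  expect_error(sim_config("random_walk", list(step = 1), 5, 1), "n_frames")
  expect_error(sim_config("stop_and_go",
                          list(speed_stop = 0, speed_go = 5,
                               p_stop_to_go = 1.2, p_go_to_stop = 0.1),
                          5, 5), "in \\[0, 1\\]")
  expect_error(sim_config("confined", list(step = 1, tether = 0), 5, 5),
               "tether")
})

test_that("simulation is deterministic and independent of cohort size", {
  cfg <- sim_config("random_walk", list(step = 2), 6, 8, seed = 11)
  a <- simulate_trackset(cfg)
  b <- simulate_trackset(cfg)
  expect_identical(a, b)

  # sub-streams are derived by counter: the first 3 tracks of a 6-track
  # cohort equal a 3-track cohort
  small <- simulate_trackset(sim_config("random_walk", list(step = 2),
                                        3, 8, seed = 11))
  for (id in track_ids(small))
    expect_identical(small$tracks[[id]], a$tracks[[id]])

  # and the caller's RNG state is untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_trackset(cfg))
  expect_identical(.Random.seed, before)
})

test_that("constant-step random walks move at exactly step/dt", {
  ts <- simulate_trackset(sim_config("random_walk", list(step = 2.46),
                                     25, 21, frame_interval = 0.5,
                                     seed = 3))
  cm <- cohort_metrics(ts)
  expect_equal(mean_of(cm, "mean_velocity"), 4.92)
  expect_equal(cm$summary$sd[cm$summary$metric == "mean_velocity"], 0,
               tolerance = 1e-12)
})

test_that("zero-noise directed motion gives straight unit-confinement tracks", {
  ts <- simulate_trackset(sim_config("directed",
                                     list(drift = c(1, 0), step = 0),
                                     10, 15, seed = 5))
  cm <- cohort_metrics(ts)
  expect_equal(cm$metrics$confinement_ratio, rep(1, 10))
  expect_equal(cm$metrics$mean_velocity, rep(2, 10))  # 1 um/frame @ 0.5 min
})

test_that("stop_and_go arrest matches the chain's stationary occupancy", {
  # Monte-Carlo brute force over the chain: stationary stop occupancy
  # pi = p_gs / (p_sg + p_gs); expected arrest coefficient = 100 * pi
  p_sg <- 0.3; p_gs <- 0.2
  pi_stop <- p_gs / (p_sg + p_gs)
  cfg <- sim_config("stop_and_go",
                    list(speed_stop = 0.5, speed_go = 6,
                         p_stop_to_go = p_sg, p_go_to_stop = p_gs),
                    n_tracks = 1500, n_frames = 31, seed = 17)
  cm <- cohort_metrics(simulate_trackset(cfg))
  expect_equal(mean_of(cm, "arrest_coefficient"), 100 * pi_stop,
               tolerance = 0.03)
})

test_that("uniform step lengths reproduce the requested speed distribution", {
  cfg <- sim_config("random_walk",
                    list(step = list(dist = "uniform", min = 0, max = 3)),
                    400, 30, seed = 23)
  v <- unlist(lapply(simulate_trackset(cfg)$tracks,
                     instantaneous_velocities))
  expect_equal(mean(v), 3, tolerance = 0.02)   # E[speed] = 6/2 um/min
  expect_lte(max(v), 6)
  expect_gte(min(v), 0)
})

test_that("3-D simulation produces 3-D tracks with unit-length directions", {
  ts <- simulate_trackset(sim_config("random_walk",
                                     list(step = 2, dim = 3), 5, 9,
                                     seed = 2))
  expect_true(all(vapply(ts$tracks, function(tr) ncol(tr$pos),
                         integer(1)) == 3L))
  sl <- unname(unlist(lapply(ts$tracks, function(tr)
    sqrt(rowSums(diff(tr$pos)^2)))))
  expect_equal(sl, rep(2, length(sl)), tolerance = 1e-12)
})

test_that("synthetic point patterns are deterministic and respect geometry", {
  pp <- simulate_point_pattern(0.40, radius = 120, ring_width = 40,
                               intensities = c(interior = 50, ring = 500,
                                               exterior = 50), seed = 4)
  pp2 <- simulate_point_pattern(0.40, radius = 120, ring_width = 40,
                                intensities = c(interior = 50, ring = 500,
                                                exterior = 50), seed = 4)
  expect_identical(pp, pp2)
  # all points in the field
  expect_true(all(pp$points >= 0 & pp$points <= 1000 * sqrt(0.40)))
  # zero ring intensity -> no points in the annulus
  pp0 <- simulate_point_pattern(0.40, radius = 120, ring_width = 40,
                                intensities = c(interior = 50, ring = 0,
                                                exterior = 50), seed = 4)
  d <- sqrt(rowSums(sweep(pp0$points, 2, pp0$geometry$center)^2))
  expect_false(any(d >= 120 & d < 160))
  # annulus must fit inside the field
  expect_error(simulate_point_pattern(0.04, radius = 120, ring_width = 40,
                                      intensities = c(1, 1, 1)),
               "outside the imaging field")
})

test_that("compartment counts match intensity x area in expectation", {
  # Monte-Carlo mean over seeds against the Poisson expectation
  radius <- 150; w <- 50
  a_int <- pi * radius^2 / 1e6
  a_ring <- pi * ((radius + w)^2 - radius^2) / 1e6
  counts <- t(vapply(1:40, function(s) {
    pp <- simulate_point_pattern(0.40, radius, w,
                                 intensities = c(interior = 200,
                                                 ring = 1000,
                                                 exterior = 30), seed = s)
    d <- sqrt(rowSums(sweep(pp$points, 2, pp$geometry$center)^2))
    c(sum(d < radius), sum(d >= radius & d < radius + w))
  }, numeric(2)))
  expect_equal(mean(counts[, 1]), 200 * a_int, tolerance = 0.1)
  expect_equal(mean(counts[, 2]), 1000 * a_ring, tolerance = 0.1)
})
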
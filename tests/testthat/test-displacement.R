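test_that("displacement from origin follows the trajectory", {
  bal <- ballistic_track(v = 4, n = 6)           # 4 um/min, dt 0.5
  d <- displacement_from_origin(bal)
  expect_equal(d$displacement, 4 * d$t_elapsed)
  expect_equal(d$t_elapsed[1], 0)
  expect_equal(d$displacement[1], 0)

  expect_equal(displacement_from_origin(stationary_track())$displacement,
               rep(0, 5))

  # return-to-origin loop: final displacement 0, path length > 0
  loop <- track("loop", (0:4) * 0.5,
                cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)))
  dl <- displacement_from_origin(loop)
  expect_equal(dl$displacement[5], 0)
  expect_gt(track_metrics(loop)$path_length, 0)
})

test_that("the cohort curve averages cells on the common grid", {
  # identical ballistic tracks: md(t) = v t exactly
  ts <- trackset(lapply(1:6, function(i)
    ballistic_track(paste0("b", i), v = 3, n = 11)))
  curve <- mean_displacement_curve(ts)
  expect_equal(curve$md_um, 3 * curve$t_min)
  expect_equal(curve$n_cells, rep(6L, 11))

  # single track: the curve is that track's displacement series
  one <- trackset(list(ballistic_track("solo", v = 2, n = 8)))
  expect_equal(mean_displacement_curve(one)$md_um,
               displacement_from_origin(one$tracks$solo)$displacement)

  # shorter tracks drop out: n_cells non-increasing
  mix <- trackset(list(ballistic_track("long", v = 2, n = 11),
                       ballistic_track("short", v = 2, n = 5)))
  cn <- mean_displacement_curve(mix)$n_cells
  expect_true(all(diff(cn) <= 0))
  expect_equal(cn[1], 2L); expect_equal(cn[11], 1L)

  irr <- trackset(list(track("i", c(0, 0.4, 1.1), cbind(0:2, 0:2))))
  expect_error(mean_displacement_curve(irr), "resample")
})

test_that("isotropic random-walk md approaches s*sqrt(pi*k)/2", {
  # Monte-Carlo brute-force oracle, vectorized and independent of the
  # simulator: mean modulus of a sum of k unit steps, scaled by s
  s <- 2; k <- 25; n_mc <- 1e5
  set.seed(31)
  th <- matrix(runif(n_mc * k, 0, 2 * pi), n_mc)
  oracle <- mean(sqrt(rowSums(cos(th))^2 + rowSums(sin(th))^2)) * s
  expect_equal(oracle, s * sqrt(pi * k) / 2, tolerance = 0.02)

  ts <- simulate_trackset(sim_config("random_walk", list(step = s),
                                     3000, k + 1, seed = 13))
  curve <- mean_displacement_curve(ts)
  expect_equal(curve$md_um[k + 1], oracle, tolerance = 0.03)
})

test_that("md exactly proportional to sqrt(t) fits with R^2 = 1", {
  t <- (0:10) * 0.5
  curve <- structure(data.frame(t_min = t, sqrt_t = sqrt(t),
                                md_um = 3 * sqrt(t),
                                n_cells = rep(50L, 11)),
                     class = c("md_curve", "data.frame"))
  fit <- fit_md_sqrt_time(curve)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 3)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_true(fit$is_random_walk)
  expect_equal(fit$n_points, 10L)  # t = 0 excluded
})

test_that("degenerate and data-poor curves are handled explicitly", {
  t <- (0:10) * 0.5
  flat <- structure(data.frame(t_min = t, sqrt_t = sqrt(t),
                               md_um = c(0, rep(5, 10)),
                               n_cells = rep(50L, 11)),
                    class = c("md_curve", "data.frame"))
  fit <- fit_md_sqrt_time(flat)     # zero-variance guard
  expect_equal(fit$r_squared, 0)
  expect_false(fit$is_random_walk)

  starved <- flat
  starved$n_cells <- c(50L, 50L, 50L, rep(2L, 8))
  expect_error(fit_md_sqrt_time(starved), "fewer than 3")
})

test_that("min_cells_per_point drops sparse late-time points", {
  ts <- trackset(c(lapply(1:10, function(i)
    ballistic_track(paste0("a", i), v = 2, n = 9)),
    list(ballistic_track("tail", v = 2, n = 21))))
  curve <- mean_displacement_curve(ts)
  fit <- fit_md_sqrt_time(curve, min_cells_per_point = 5)
  expect_equal(fit$n_points, 8L)     # only the jointly observed grid
})

test_that("a simulated random-walk cohort passes the R^2 criterion", {
  ts <- simulate_trackset(sim_config("random_walk", list(step = 2),
                                     400, 30, seed = 19))
  fit <- fit_md_sqrt_time(mean_displacement_curve(ts))
  expect_gte(fit$r_squared, 0.95)
  expect_true(fit$is_random_walk)
})

test_that("ballistic and tethered cohorts show the opposite md shapes", {
  # ballistic: md linear in t (convex in sqrt t)
  bal <- trackset(lapply(1:20, function(i)
    ballistic_track(paste0("b", i), v = 3, n = 30)))
  cb <- mean_displacement_curve(bal)
  expect_equal(cb$md_um, 3 * cb$t_min)
  lin <- lm(md_um ~ t_min, data = cb[-1, ])
  expect_lt(max(abs(residuals(lin))), 1e-9)

  # tethered: md saturates and fails the random-walk criterion
  teth <- simulate_trackset(sim_config("confined",
                                       list(step = 2, tether = 0.8),
                                       200, 30, seed = 8))
  ct <- mean_displacement_curve(teth)
  late <- ct$md_um[ct$t_min >= 7]
  expect_lt(diff(range(late)) / mean(late), 0.2)   # plateau
  expect_false(fit_md_sqrt_time(ct)$is_random_walk)
})

test_that("curve and fit are invariant under rigid motion", {
  ts <- random_trackset(n = 15, n_frames = 12, seed = 21)
  a <- mean_displacement_curve(ts)
  b <- mean_displacement_curve(rigid_transform(ts))
  expect_equal(b$md_um, a$md_um, tolerance = 1e-10)
  fa <- fit_md_sqrt_time(a, min_cells_per_point = 3)
  fb <- fit_md_sqrt_time(b, min_cells_per_point = 3)
  expect_equal(fb$r_squared, fa$r_squared, tolerance = 1e-10)
})

test_that("the fit agrees with closed-form least squares to 1e-10", {
  ts <- simulate_trackset(sim_config("random_walk", list(step = 1.5),
                                     60, 25, seed = 29))
  curve <- mean_displacement_curve(ts)
  fit <- fit_md_sqrt_time(curve)
  pts <- curve[curve$t_min > 0, ]
  x <- pts$sqrt_t; y <- pts$md_um
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
})
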
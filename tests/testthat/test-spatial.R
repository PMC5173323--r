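test_that("cell density is exact count/area arithmetic", {
  set.seed(5)
  side <- 1000 * sqrt(0.40)
  pts <- cbind(runif(100, 0, side), runif(100, 0, side))
  labs <- rep(c("ctl", "treg"), c(80, 20))
  pp <- point_pattern(pts, labs, field_areas[["intravital_field"]])
  d <- cell_density(pp, "ctl")
  expect_equal(d$count, 80)
  expect_equal(d$density, 200)                 # 80 / 0.40
  expect_equal(cell_density(pp, "dc")$density, 0)   # absent label

  # brute-force oracle on a random pattern
  expect_equal(cell_density(pp, "treg")$density,
               sum(labs == "treg") / 0.40)

  # named field-area constants
  expect_equal(unname(field_areas), c(0.18, 0.40, 12))
  pp18 <- point_pattern(pts[1:9, ], "ctl", field_areas[["section_field"]])
  expect_equal(cell_density(pp18, "ctl")$density, 50)
})

test_that("phenotype fractions are percentages of the reference set", {
  pp <- point_pattern(cbind(1:10, 1:10),
                      rep(c("neutrophil", "other_tii"), c(6, 4)), 0.18)
  expect_equal(phenotype_fraction(pp, "neutrophil"), 60)
  expect_equal(phenotype_fraction(pp, "neutrophil", "neutrophil"), 100)
  expect_error(phenotype_fraction(pp, "neutrophil", "dc"), "undefined")
})

test_that("a majority-intensity phenotype yields a majority fraction", {
  # neutrophil intensity above half the total -> fraction > 50%
  fr <- vapply(1:10, function(s) {
    pp <- simulate_point_pattern(0.40, radius = 100, ring_width = 50,
      intensities = list(neutrophil = c(10, 600, 30),
                         other_tii = c(10, 300, 20)), seed = s)
    phenotype_fraction(pp, "neutrophil")
  }, numeric(1))
  expect_gt(mean(fr), 50)
  expect_gt(min(fr), 45)
})

test_that("ring profiles conserve counts and respect geometry", {
  pp <- simulate_point_pattern(0.40, radius = 120, ring_width = 40,
                               intensities = c(interior = 100, ring = 800,
                                               exterior = 60), seed = 6)
  prof <- radial_ring_profile(pp, bin_width = 40)
  expect_equal(sum(prof$bins$count), nrow(pp$points))
  # conservation: densities recombine to the total count
  expect_equal(sum(prof$bins$density * prof$bins$area_mm2),
               nrow(pp$points), tolerance = 1e-8)
  expect_true(all(prof$bins$density >= 0))
  expect_true(all(prof$bins$area_mm2 > 0 | prof$bins$count == 0))

  no_geom <- point_pattern(pp$points, pp$labels, 0.40)
  expect_error(radial_ring_profile(no_geom, 40), "geometry")
})

test_that("the ring index recovers simulated enrichment", {
  # uniform pattern: ring index ~ 1 (Monte-Carlo over seeds)
  ri_unif <- vapply(1:12, function(s) {
    pp <- simulate_point_pattern(0.40, radius = 150, ring_width = 50,
      intensities = c(interior = 2000, ring = 2000, exterior = 2000),
      seed = s)
    radial_ring_profile(pp, bin_width = 50)$ring_index
  }, numeric(1))
  expect_equal(mean(ri_unif), 1, tolerance = 0.1)

  # 10x ring enrichment is recovered
  ri_ring <- vapply(1:8, function(s) {
    pp <- simulate_point_pattern(0.40, radius = 150, ring_width = 50,
      intensities = c(interior = 300, ring = 3000, exterior = 100),
      seed = 100 + s)
    radial_ring_profile(pp, bin_width = 50)$ring_index
  }, numeric(1))
  expect_equal(mean(ri_ring), 10, tolerance = 0.12)
})

test_that("an empty interior yields the infinite ring-index sentinel", {
  pp <- simulate_point_pattern(0.40, radius = 120, ring_width = 40,
                               intensities = c(interior = 0, ring = 500,
                                               exterior = 0), seed = 9)
  expect_identical(radial_ring_profile(pp, bin_width = 40)$ring_index,
                   Inf)
})

test_that("densities are invariant under rigid motion of points+geometry", {
  pp <- simulate_point_pattern(0.40, radius = 120, ring_width = 40,
                               intensities = c(interior = 100, ring = 600,
                                               exterior = 50), seed = 12)
  prof <- radial_ring_profile(pp, bin_width = 40)
  shift <- c(40, -25)
  moved <- point_pattern(sweep(pp$points, 2, shift, "+"), pp$labels,
                         pp$field_area,
                         geometry = list(type = "disc",
                                         center = pp$geometry$center +
                                           shift,
                                         radius = pp$geometry$radius),
                         field = pp$field + rep(shift, each = 2))
  prof2 <- radial_ring_profile(moved, bin_width = 40)
  expect_equal(prof2$bins$count, prof$bins$count)
  expect_equal(prof2$ring_index, prof$ring_index, tolerance = 1e-6)
})

test_that("polygon geometry matches the disc on a near-circular boundary", {
  pp <- simulate_point_pattern(0.40, radius = 150, ring_width = 50,
                               intensities = c(interior = 200, ring = 1500,
                                               exterior = 80), seed = 3)
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  poly <- cbind(pp$geometry$center[1] + 150 * cos(th),
                pp$geometry$center[2] + 150 * sin(th))
  pp_poly <- point_pattern(pp$points, pp$labels, pp$field_area,
                           geometry = list(type = "polygon",
                                           vertices = poly),
                           field = pp$field)
  a <- radial_ring_profile(pp, bin_width = 50)
  b <- radial_ring_profile(pp_poly, bin_width = 50)
  expect_equal(sum(b$bins$count), sum(a$bins$count))
  expect_equal(b$ring_index, a$ring_index, tolerance = 0.1)
})
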
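# Binary mixtures: linear HSP blending, RED profiles, closed-form minima,
# synergy classification.

test_that("mole-fraction blending hits endpoints and midpoints exactly", {
  meoh <- hsp(15.1, 12.3, 22.3)
  mek <- hsp(16.0, 9.0, 5.1)
  expect_equal(unclass(mix_hsp(meoh, mek, x1 = 1)), unclass(meoh))
  expect_equal(unclass(mix_hsp(meoh, mek, x1 = 0)), unclass(mek))
  mid <- mix_hsp(meoh, mek, x1 = 0.5)
  expect_equal(unname(unclass(mid)), c(15.55, 10.65, 13.70))
  expect_error(mix_hsp(meoh, mek, x1 = 1.2), class = "hspfit_input_error")
  expect_error(mix_hsp(meoh, mek, x1 = -0.1), class = "hspfit_input_error")
})

test_that("volume-fraction blending reduces to mole fraction at equal volumes", {
  a <- hsp(15, 10, 20); b <- hsp(16, 5, 5)
  expect_equal(unclass(mix_hsp(a, b, 0.3, molar_volumes = c(75, 75))),
               unclass(mix_hsp(a, b, 0.3)))
  # a bulkier solvent 1 pulls the blend toward itself
  skewed <- mix_hsp(a, b, 0.3, molar_volumes = c(150, 75))
  plain <- mix_hsp(a, b, 0.3)
  expect_gt(skewed[2], plain[2])
  expect_error(mix_hsp(a, b, 0.3, molar_volumes = c(-1, 75)),
               class = "hspfit_input_error")
})

test_that("grid minima match the reported blend compositions", {
  lib <- builtin_lib()
  resv <- resveratrol_sphere(); hesp <- hesperetin_sphere()
  meoh <- lookup_solvent(lib, "methanol"); etoh <- lookup_solvent(lib, "ethanol")
  mek <- lookup_solvent(lib, "MEK"); mibk <- lookup_solvent(lib, "MiBK")

  expect_equal(red_profile(resv, meoh, mibk)$x_min_grid, 0.5)
  expect_equal(red_profile(resv, meoh, mek)$x_min_grid, 0.5)
  expect_equal(red_profile(hesp, meoh, mibk)$x_min_grid, 0.5)
  expect_equal(red_profile(hesp, etoh, mibk)$x_min_grid, 0.4)
})

test_that("alcohol + alcohol profiles are monotonic for both solutes", {
  lib <- builtin_lib()
  meoh <- lookup_solvent(lib, "methanol")
  etoh <- lookup_solvent(lib, "ethanol")
  for (sph in list(resveratrol_sphere(), hesperetin_sphere())) {
    prof <- red_profile(sph, meoh, etoh)
    expect_identical(prof$shape, "monotonic")
    expect_false(predict_synergy(sph, meoh, etoh)$synergy)
  }
})

test_that("profile endpoints equal the pure-solvent REDs", {
  lib <- builtin_lib()
  resv <- resveratrol_sphere()
  s1 <- lookup_solvent(lib, "methanol"); s2 <- lookup_solvent(lib, "MiBK")
  prof <- red_profile(resv, s1, s2)
  expect_equal(prof$points$red[1], red(resv, s1$hsp))
  expect_equal(prof$points$red[nrow(prof$points)], red(resv, s2$hsp))
})

test_that("closed form handles degenerate and on-segment geometries", {
  sph <- hansen_sphere(14, 9, 11, 6)
  s <- hsp(16, 8, 12)
  cf <- min_red_composition(sph, s, s)
  expect_identical(cf$a, 0)
  expect_identical(cf$x_min, 0)
  expect_equal(cf$red_min, red(sph, s))

  # solute centre sitting on the mixing segment at x2 = 0.3
  s1 <- hsp(15, 8, 10); s2 <- hsp(18, 14, 20)
  on_path <- mix_hsp(s1, s2, x1 = 0.7)   # x2 = 0.3
  sph2 <- hansen_sphere(on_path[1], on_path[2], on_path[3], 5)
  cf2 <- min_red_composition(sph2, s1, s2)
  expect_equal(cf2$x_min, 0.3)
  expect_equal(cf2$red_min, 0, tolerance = 1e-12)
})

test_that("Ra^2 is a convex quadratic and the closed form matches optimize()", {
  set.seed(77)
  for (i in 1:200) {
    sph <- hansen_sphere(runif(1, 10, 25), runif(1, 5, 25), runif(1, 5, 25),
                         runif(1, 1, 10))
    s1 <- random_hsp(); s2 <- random_hsp()
    cf <- min_red_composition(sph, s1, s2)
    expect_gte(cf$a, 0)
    ra2 <- function(x) {
      m <- mix_hsp(s1, s2, x1 = 1 - x)
      hansen_distance(sph$center, m)^2
    }
    if (cf$a > 1e-9) {
      vertex <- -cf$b / (2 * cf$a)
      if (vertex > 0.001 && vertex < 0.999) {
        x_oracle <- stats::optimize(ra2, c(0, 1), tol = 1e-10)$minimum
        expect_lt(abs(cf$x_min - x_oracle), 1e-6)
      } else {
        # clamped: the better endpoint wins
        expect_identical(cf$x_min, if (ra2(1) < ra2(0)) 1 else 0)
      }
    }
  }
})

test_that("grid argmin is the grid point nearest the closed-form minimiser", {
  set.seed(78)
  grid <- seq(0, 1, by = 0.1)
  for (i in 1:200) {
    sph <- hansen_sphere(runif(1, 10, 25), runif(1, 5, 25), runif(1, 5, 25),
                         runif(1, 1, 10))
    s1 <- random_hsp(); s2 <- random_hsp()
    prof <- red_profile(sph, s1, s2, grid = grid)
    nearest <- grid[which.min(abs(grid - prof$x_min_closed_form))]
    expect_equal(prof$x_min_grid, nearest)
    # at most one interior minimum: the profile decreases then increases
    d <- diff(prof$points$red)
    sign_changes <- sum(diff(sign(d[d != 0])) != 0)
    expect_lte(sign_changes, 1)
  }
})

test_that("swapping the solvents reflects the minimiser", {
  set.seed(79)
  for (i in 1:100) {
    sph <- hansen_sphere(runif(1, 10, 25), runif(1, 5, 25), runif(1, 5, 25),
                         runif(1, 1, 10))
    s1 <- random_hsp(); s2 <- random_hsp()
    a <- min_red_composition(sph, s1, s2)
    b <- min_red_composition(sph, s2, s1)
    if (a$a > 1e-9 && -a$b / (2 * a$a) > 0 && -a$b / (2 * a$a) < 1) {
      expect_equal(b$x_min, 1 - a$x_min, tolerance = 1e-9)
      expect_equal(b$red_min, a$red_min, tolerance = 1e-9)
    }
  }
})

test_that("grid ties resolve to the smaller mole fraction", {
  # dyadic construction: vertex at x2 = 0.375 makes red(0.25) == red(0.5)
  # exactly in floating point
  sph <- hansen_sphere(12, 12, 12, 5)
  s1 <- hsp(12, 11.625, 12); s2 <- hsp(12, 12.625, 12)
  prof <- red_profile(sph, s1, s2, grid = seq(0, 1, by = 0.25))
  expect_identical(prof$points$red[prof$points$x2 == 0.25],
                   prof$points$red[prof$points$x2 == 0.5])
  expect_equal(prof$x_min_grid, 0.25)
})

test_that("synergy classification matches the alcohol/ketone dichotomy", {
  lib <- builtin_lib()
  resv <- resveratrol_sphere()
  meoh <- lookup_solvent(lib, "methanol")
  mek <- lookup_solvent(lib, "MEK")
  expect_true(predict_synergy(resv, meoh, mek)$synergy)

  # solute centred exactly on solvent 1: RED can only grow toward solvent 2
  s1 <- hsp(15, 9, 11)
  sph <- hansen_sphere(15, 9, 11, 6)
  rep <- predict_synergy(sph, s1, hsp(18, 5, 20))
  expect_false(rep$synergy)
  expect_equal(rep$endpoint_reds[1], 0)

  # identical solvents: constant profile, no synergy
  rep2 <- predict_synergy(resv, meoh, meoh)
  expect_false(rep2$synergy)
  expect_equal(diff(range(rep2$endpoint_reds)), 0)
})

test_that("profiles serialise to the documented CSV layout", {
  lib <- builtin_lib()
  prof <- red_profile(resveratrol_sphere(), lookup_solvent(lib, "methanol"),
                      lookup_solvent(lib, "MEK"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_red_profile(prof, tmp)
  back <- read.csv(tmp)
  expect_identical(names(back), c("x2", "delta_d", "delta_p", "delta_h",
                                  "ra", "red"))
  expect_equal(back$red, prof$points$red)
})
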
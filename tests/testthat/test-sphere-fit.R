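# Constrained evolutionary sphere fitting and sphere evaluation.

test_that("fitting is deterministic given the seed", {
  d <- fittable_dataset(3)
  cfg <- fit_config(n_restarts = 2, max_gen = 60)
  f1 <- fit_sphere(d$labels, d$library, config = cfg)
  f2 <- fit_sphere(d$labels, d$library, config = cfg)
  expect_identical(unclass(f1$sphere$center), unclass(f2$sphere$center))
  expect_identical(f1$sphere$r0, f2$sphere$r0)
  expect_identical(f1$objective_value, f2$objective_value)
  expect_identical(f1$seed_used, 42L)
})

test_that("every returned sphere is feasible: all good solvents inside", {
  for (r in c(2, 5)) {
    d <- fittable_dataset(r)
    f <- fit_sphere(d$labels, d$library,
                    config = fit_config(n_restarts = 3, max_gen = 80))
    goods <- f$per_solvent[f$per_solvent$label == "good", ]
    expect_true(all(goods$red <= 1 + 1e-9))
    expect_gte(f$sphere$r0, max(goods$ra) - 1e-9)
    expect_gte(f$sphere$r0, 1)
    ctr <- unclass(f$sphere$center)
    expect_true(ctr[1] >= 10 && all(ctr >= c(10, 5, 5)) && all(ctr <= 25))
    # perfect separation is achievable on margin-protected data
    expect_identical(f$data_fit_percent, 100)
    expect_equal(f$objective_value, 1)
  }
})

test_that("fitting the polyphenol label sets contains every good solvent", {
  lib <- builtin_lib()
  labels <- classify_solvents(resv_measurements())
  # methanol's distance forces the radius above the nominal bound
  expect_warning(
    fit <- fit_sphere(labels, lib, config = fit_config(n_restarts = 3),
                      solute = "trans-resveratrol"),
    "constraint conflict")
  goods <- fit$per_solvent[fit$per_solvent$label == "good", ]
  expect_true(all(goods$red <= 1 + 1e-9))
  expect_gte(fit$data_fit_percent, 75)
})

test_that("single good solvent collapses the sphere onto it", {
  lib <- make_lib(c("g", "b1", "b2", "b3"),
                  rbind(c(15, 10, 10), c(24, 24, 24), c(11, 24, 5),
                        c(24, 5, 24)))
  labels <- data.frame(solvent = c("g", "b1", "b2", "b3"),
                       label = c("good", "bad", "bad", "bad"))
  f <- fit_sphere(labels, lib, config = fit_config(n_restarts = 3))
  expect_true(all(abs(unclass(f$sphere$center) - c(15, 10, 10)) < 0.5))
  expect_lt(f$sphere$r0, 2.5)
  expect_identical(f$data_fit_percent, 100)
})

test_that("degenerate label sets warn or fail as appropriate", {
  lib <- make_lib(c("a", "b"), rbind(c(15, 10, 10), c(16, 12, 12)))
  all_bad <- data.frame(solvent = c("a", "b"), label = "bad")
  expect_error(fit_sphere(all_bad, lib), class = "hspfit_constraint_error")
  all_good <- data.frame(solvent = c("a", "b"), label = "good")
  expect_warning(expect_warning(f <- fit_sphere(all_good, lib,
                                config = fit_config(n_restarts = 2))))
  expect_identical(f$data_fit_percent, 100)
})

test_that("evaluating the reported spheres reproduces the boundary anomalies", {
  lib <- builtin_lib()
  resv_labels <- classify_solvents(resv_measurements())
  ev <- evaluate_sphere(resveratrol_sphere(), resv_labels, lib)
  bad_inside <- ev$per_solvent[ev$per_solvent$label == "bad" &
                                 ev$per_solvent$red < 1, ]
  expect_setequal(bad_inside$solvent, c("isopropyl acetate", "n-propyl acetate"))

  hesp_labels <- classify_solvents(hesp_measurements(),
                                   overrides = c("n-propyl acetate" = "good"))
  ev2 <- evaluate_sphere(hesperetin_sphere(), hesp_labels, lib)
  bad_inside2 <- ev2$per_solvent[ev2$per_solvent$label == "bad" &
                                   ev2$per_solvent$red < 1, ]
  expect_setequal(bad_inside2$solvent,
                  c("ethanol", "1-propanol", "ethyl acetate",
                    "isopropyl acetate"))
})

test_that("an arbitrarily large sphere captures exactly the good fraction", {
  lib <- builtin_lib()
  labels <- classify_solvents(resv_measurements())
  huge <- hansen_sphere(12.2, 9.9, 12.7, 1e6)
  ev <- evaluate_sphere(huge, labels, lib)
  expect_equal(ev$data_fit_percent,
               100 * sum(labels$label == "good") / nrow(labels))
})

test_that("exhaustive grid search never beats the evolutionary optimum", {
  # 3-solvent problems with solvents on a 0.5-spaced lattice; the oracle
  # enumerates the bounded box (centre step 0.5, radius slack step 0.25)
  problems <- list(
    list(mat = rbind(c(15, 10, 10), c(18.5, 5, 5), c(14, 15.5, 20)),
         lab = c("good", "bad", "bad")),
    list(mat = rbind(c(14.5, 8, 12), c(15, 9.5, 11.5), c(20, 20, 22.5)),
         lab = c("good", "good", "bad")),
    list(mat = rbind(c(16, 6, 7.5), c(13.5, 12, 18), c(17.5, 18.5, 6)),
         lab = c("good", "bad", "good")))
  grid_centers <- as.matrix(expand.grid(delta_d = seq(10, 25, by = 0.5),
                                        delta_p = seq(5, 25, by = 0.5),
                                        delta_h = seq(5, 25, by = 0.5)))
  slacks <- seq(0, 2, by = 0.25)
  for (p in problems) {
    lib <- make_lib(c("s1", "s2", "s3"), p$mat)
    labels <- data.frame(solvent = c("s1", "s2", "s3"), label = p$lab)
    # 3-solvent problems are deliberately tiny; the size warning is expected
    fit <- suppressWarnings(fit_sphere(labels, lib,
                                       config = fit_config(n_restarts = 3)))
    good <- p$lab == "good"
    grid_best <- -Inf
    for (s in slacks) {
      theta <- cbind(grid_centers, s)
      for (chunk in split(seq_len(nrow(theta)),
                          ceiling(seq_len(nrow(theta)) / 60000))) {
        ev <- hspfit:::de_objective(theta[chunk, , drop = FALSE], p$mat, good)
        grid_best <- max(grid_best, max(ev$obj))
      }
    }
    expect_lte(grid_best, fit$objective_value + 1e-6)
  }
})

test_that("fit reports echo seed, evaluations and configuration", {
  d <- fittable_dataset(4)
  cfg <- fit_config(seed = 7L, n_restarts = 2, max_gen = 50)
  f <- fit_sphere(d$labels, d$library, config = cfg)
  expect_identical(f$seed_used, 7L)
  expect_equal(f$n_evaluations, 2 * (50 + 1) * cfg$pop_size)
  expect_identical(f$config$objective, "penalized_datafit")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fit_report(f, tmp)
  rep <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_identical(rep$seed, 7L)
  expect_true(nzchar(rep$config_hash))
  expect_identical(rep$version, as.character(packageVersion("hspfit")))
  back <- read_hansen_sphere(tmp)
  expect_equal(unclass(back$center), unclass(f$sphere$center))
  expect_equal(back$r0, f$sphere$r0)
})
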
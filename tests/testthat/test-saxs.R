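test_that("Debye intensity matches closed forms and the brute-force loop", {
  q <- c(0, 0.01, 0.1, 0.3)
  one <- debye_intensity(matrix(0, 1, 3), 1, q)
  expect_equal(one$I, rep(1, 4))

  d <- 5
  two <- debye_intensity(rbind(c(0, 0, 0), c(d, 0, 0)), 1, q)
  expect_equal(two$I, ifelse(q == 0, 4, 2 + 2 * sin(q * d) / (q * d)),
               tolerance = 1e-10)

  set.seed(10)
  coords <- matrix(rnorm(90, sd = 15), ncol = 3)
  f <- runif(30, 0.5, 2)
  qg <- default_q_grid(0.01, 0.4, 25)
  expect_equal(debye_intensity(coords, f, qg)$I, brute_debye(coords, f, qg),
               tolerance = 1e-10)
  expect_error(debye_intensity(coords, f, c(-0.1, 0.1)), "negative q")
})

test_that("Debye intensity is positive and rigid-motion invariant", {
  set.seed(11)
  coords <- matrix(rnorm(120, sd = 20), ncol = 3)
  q <- default_q_grid(0.005, 0.5, 60)
  I0 <- debye_intensity(coords, 1, q)$I
  expect_true(all(I0 > 0))
  I1 <- debye_intensity(random_rigid(coords, 6), 1, q)$I
  expect_equal(I1, I0, tolerance = 1e-9)
})

test_that("ensemble averaging is the pointwise mean of per-frame curves", {
  e <- generate_gaussian_chain_ensemble(15, 3.8, 2, seed = 12)
  q <- default_q_grid(0.01, 0.3, 20)
  avg <- ensemble_average_intensity(e, 1, q)
  f1 <- debye_intensity(get_frame(e, 1), 1, q)
  f2 <- debye_intensity(get_frame(e, 2), 1, q)
  expect_equal(avg$I, (f1$I + f2$I) / 2, tolerance = 1e-12)

  one <- e
  one$coords <- e$coords[1, , , drop = FALSE]
  expect_equal(ensemble_average_intensity(one, 1, q)$I, f1$I,
               tolerance = 1e-12)
  # q -> 0 limit: I(0) = (sum of form factors)^2
  expect_equal(ensemble_average_intensity(e, 1, c(0, 0.01))$I[1], 15^2)
})

test_that("hydration shells follow the two-scatterer closed form", {
  conf <- matrix(0, 1, 3)
  m0 <- hydration_model(shell_weight = 0)
  s0 <- add_hydration_shell(conf, 1, m0)
  q <- default_q_grid(0.01, 0.4, 30)
  expect_equal(debye_intensity(s0, q = q)$I,
               debye_intensity(conf, 1, q)$I)

  w <- 0.7
  dd <- 3.0
  m1 <- hydration_model(shell_weight = w, shell_distance = dd,
                        exposure_threshold = 0)
  # single bead at distance r from the centroid so the outward direction
  # is defined: use a 2-bead rod and check the terminal bead's shell
  rod <- rbind(c(0, 0, 0), c(10, 0, 0))
  ss <- add_hydration_shell(rod, c(1, 1), m1)
  expect_equal(nrow(ss$coords), 4L)
  expect_equal(ss$coords[3, 1], -dd)   # outward from centroid (5,0,0)
  expect_equal(ss$coords[4, 1], 10 + dd)

  # one bead + one shell point closed form: 1 + w^2 + 2w sinc(qd)
  pair <- structure(list(coords = rbind(c(0, 0, 0), c(dd, 0, 0)),
                         weights = c(1, w), is_shell = c(FALSE, TRUE)),
                    class = "scatterer_set")
  expect_equal(debye_intensity(pair, q = q)$I,
               1 + w^2 + 2 * w * sin(q * dd) / (q * dd), tolerance = 1e-10)
})

test_that("shell scatterers increase the direct weighted Rg", {
  rod <- build_initial_chain(11, 3.8)
  frac <- c(1, rep(0, 9), 1)   # shells only on the terminal beads
  ss <- add_hydration_shell(rod, frac, hydration_model(shell_weight = 0.5,
                                                       shell_distance = 3))
  expect_gt(weighted_rg(ss$coords, ss$weights),
            weighted_rg(rod, rep(1, 11)))
})

test_that("phospho-boost raises shell weights only at phosphosites", {
  rod <- build_initial_chain(5, 3.8)
  m <- hydration_model(shell_weight = 0.4, phospho_boost = 2.5,
                       exposure_threshold = 0)
  ss <- add_hydration_shell(rod, rep(1, 5), m, phospho_sites = c(2, 4))
  w <- ss$weights[ss$is_shell]
  expect_equal(sort(unique(w)), c(0.4, 1.0))
  expect_equal(sum(w == 1.0), 2L)
})

test_that("Guinier fits recover exact model curves", {
  q <- default_q_grid(0.002, 0.2, 100)
  rg <- 25
  g <- guinier_fit(scattering_curve(q, 100 * exp(-q^2 * rg^2 / 3)))
  expect_equal(g$rg, 25, tolerance = 1e-6)
  expect_equal(g$i0, 100, tolerance = 1e-6)

  R <- 30
  qs <- default_q_grid(0.002, 0.12, 120)
  gs <- guinier_fit(scattering_curve(qs, sphere_intensity(qs, R)))
  expect_equal(gs$rg, sqrt(3 / 5) * R, tolerance = 0.01)

  expect_error(guinier_fit(scattering_curve(q[1:4], rep(1, 4))), "5")
  # rising curve has no Guinier regime
  expect_error(guinier_fit(scattering_curve(q, exp(q^2 * 100))), "slope")
})

test_that("Guinier Rg of a coil ensemble matches the direct ensemble Rg", {
  e <- generate_gaussian_chain_ensemble(100, 3.8, 500, seed = 21)
  curve <- ensemble_average_intensity(e, 1, default_q_grid(0.004, 0.3, 80))
  g <- guinier_fit(curve, mode = "standard")
  direct <- mean(ensemble_rg(e, "uniform"))
  expect_equal(g$rg, direct, tolerance = 0.03)
})

test_that("chi-square absorbs scale and matches a grid-search for c", {
  q <- default_q_grid(0.01, 0.3, 40)
  I <- 50 * exp(-q^2 * 20^2 / 3)
  ref <- scattering_curve(q, I, sigma = 0.02 * I)
  same <- chi_square(scattering_curve(q, I), ref)
  expect_equal(same$chi2, 0, tolerance = 1e-20)
  expect_equal(same$fitted_scale, 1)

  doubled <- chi_square(scattering_curve(q, 2 * I), ref)
  expect_equal(doubled$chi2, 0, tolerance = 1e-20)
  expect_equal(doubled$fitted_scale, 0.5)

  set.seed(13)
  pert <- scattering_curve(q, I * exp(rnorm(40, sd = 0.05)))
  res <- chi_square(pert, ref)
  cs <- seq(0.5, 2, by = 1e-4)
  chi_of_c <- sapply(cs, function(cc)
    sum(((cc * pert$I - I) / ref$sigma)^2) / (length(q) - 1))
  expect_equal(res$fitted_scale, cs[which.min(chi_of_c)], tolerance = 1e-3)
  expect_lte(res$chi2, min(chi_of_c) + 1e-10)

  far <- scattering_curve(q + 10, I, sigma = I)
  expect_error(chi_square(far, ref), "overlap")
  expect_error(chi_square(pert, scattering_curve(q, I)), "uncertainties")
})

test_that("SAXS dat files round-trip through read/write", {
  q <- default_q_grid(0.01, 0.2, 15)
  curve <- scattering_curve(q, 10 * exp(-q^2 * 100), sigma = rep(0.3, 15))
  f <- tempfile(fileext = ".dat")
  write_saxs_dat(curve, f)
  back <- read_saxs_dat(f)
  expect_equal(back$q, curve$q, tolerance = 1e-6)
  expect_equal(back$I, curve$I, tolerance = 1e-8)
  expect_equal(back$sigma, curve$sigma, tolerance = 1e-8)
})
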
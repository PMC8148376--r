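test_that("Debye length matches the closed form and its scaling laws", {
  expect_equal(debye_length(0.1, 298), 9.6, tolerance = 0.01)
  expect_equal(debye_length(0.1, 300) / debye_length(0.4, 300), 2,
               tolerance = 1e-12)
  lam <- debye_length(c(0.05, 0.1, 0.5, 1.5), 300)
  expect_true(all(diff(lam) < 0))
  expect_error(debye_length(0), "> 0")
  expect_error(debye_length(-1), "> 0")
})

test_that("initial chains are collinear with exact spacing", {
  c81 <- build_initial_chain(81, 3.8)
  expect_equal(sqrt(sum((c81[81, ] - c81[1, ])^2)), 80 * 3.8)
  expect_equal(radius_of_gyration(build_initial_chain(1)), 0)
  expect_equal(nrow(build_initial_chain(idp_fragments()$Ash1)), 81L)
})

test_that("sampled ensembles keep rigid bonds and are seed-reproducible", {
  s <- toy_sequence()
  cv <- assign_charges(s, charge_model())
  mc <- mc_config(n_sweeps = 300, seed = 11)
  e1 <- sample_ensemble(s, cv, cg_parameters(), mc)
  e2 <- sample_ensemble(s, cv, cg_parameters(), mc)
  expect_identical(e1$coords, e2$coords)
  e3 <- sample_ensemble(s, cv, cg_parameters(), mc_config(n_sweeps = 300,
                                                          seed = 12))
  expect_false(identical(e1$coords, e3$coords))

  for (f in seq(1, n_frames(e1), length.out = 5)) {
    conf <- get_frame(e1, round(f))
    bonds <- sqrt(rowSums((conf[-1, ] - conf[-nrow(conf), ])^2))
    expect_true(all(abs(bonds - 3.8) < 1e-6))
  }
  expect_true(all(is.finite(e1$coords)))
  expect_gt(e1$provenance$acceptance$ratio, 0)
  expect_equal(e1$provenance$seed, 11L)
})

test_that("equilibration fraction and stride control the saved frames", {
  e <- sample_ensemble(10, params = cg_parameters(),
                       mc = mc_config(n_sweeps = 400,
                                      equilibration_fraction = 0.25,
                                      save_stride = 10, seed = 3))
  expect_equal(n_frames(e), 30L)  # (400 - 100) / 10
})

test_that("neutral chains follow excluded-volume coil scaling", {
  # thin-bead geometry (diameter < bond length): a bare self-avoiding
  # walk without the angular stiffness the fat default beads induce;
  # the effective exponent over N = 25-75 is averaged over seeds
  ns <- c(25, 50, 75)
  nu <- mean(sapply(c(101, 202, 303), function(seed) {
    mrg <- sapply(ns, function(n) {
      e <- sample_ensemble(n,
                           params = cg_parameters(bead_radius = 1.5,
                                                  short_range_attraction = 0),
                           mc = mc_config(n_sweeps = 1200, seed = seed))
      mean(ensemble_rg(e, "uniform"))
    })
    coef(lm(log(mrg) ~ log(ns)))[[2]]
  }))
  expect_gt(nu, 0.588 - 0.05)
  expect_lt(nu, 0.588 + 0.05)
})

test_that("Gaussian chain ensembles reproduce ideal-chain statistics", {
  n <- 100
  b <- 3.8
  e <- generate_gaussian_chain_ensemble(n, b, n_frames_out = 4000, seed = 5)
  rg2 <- ensemble_rg(e, "uniform")^2
  # freely jointed chain of n beads: <Rg^2> = b^2 (n^2 - 1) / (6 n)
  expect_equal(mean(rg2), b^2 * (n^2 - 1) / (6 * n), tolerance = 0.03)

  e1 <- generate_gaussian_chain_ensemble(1, b, n_frames_out = 10, seed = 1)
  expect_true(all(ensemble_rg(e1, "uniform") == 0))
  expect_identical(
    generate_gaussian_chain_ensemble(20, b, 50, seed = 9)$coords,
    generate_gaussian_chain_ensemble(20, b, 50, seed = 9)$coords)
})

test_that("uniform ball clouds have the sphere's second moment and CDF", {
  R <- 30
  pts <- uniform_ball_points(R, 5000, seed = 2)
  expect_equal(radius_of_gyration(pts), sqrt(3 / 5) * R, tolerance = 0.01)
  expect_true(all(sqrt(rowSums(pts^2)) <= R + 1e-12))

  one <- uniform_ball_points(R, 1, seed = 3)
  expect_lte(sqrt(sum(one^2)), R)

  big <- uniform_ball_points(R, 10000, seed = 4)
  r <- sqrt(rowSums(big^2))
  ks <- stats::ks.test(r^3 / R^3, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("single-bead and tiny chains degrade gracefully", {
  e <- sample_ensemble(1, params = cg_parameters(),
                       mc = mc_config(n_sweeps = 20, seed = 1))
  expect_true(all(ensemble_rg(e, "uniform") == 0))
})

test_that("a 3-bead chain samples the Boltzmann bond-angle distribution", {
  # With rigid bonds the only internal coordinate is the angle phi
  # between the two bond vectors; unbiased sampling makes cos(phi)
  # uniform, so with terminal charges +1/-1 the stationary density of
  # c = cos(phi) is proportional to exp(-E(r13(c))).
  b <- 3.8
  params <- cg_parameters(bead_radius = 1.5, short_range_attraction = 0,
                          salt_molarity = 0.1)
  e <- sample_ensemble(3, charges = c(1, 0, -1), params = params,
                       mc = mc_config(n_sweeps = 20000, save_stride = 2,
                                      equilibration_fraction = 0.1,
                                      seed = 17))
  cosphi <- vapply(seq_len(n_frames(e)), function(f) {
    conf <- get_frame(e, f)
    v1 <- conf[2, ] - conf[1, ]
    v2 <- conf[3, ] - conf[2, ]
    sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  }, numeric(1))
  energy <- function(c_) {
    r <- b * sqrt(2 + 2 * c_)   # distance bead1-bead3
    sig <- 2 * params$bead_radius
    wca <- ifelse(r < 2^(1 / 6) * sig,
                  4 * ((sig / r)^12 - (sig / r)^6) + 1, 0)
    wca - params$bjerrum_length * exp(-r / params$debye_len) / r
  }
  breaks <- seq(-1, 1, length.out = 9)
  obs <- tabulate(cut(cosphi, breaks), nbins = 8) / length(cosphi)
  # integrate exp(-E) over each bin (c is uniform at zero energy)
  grid <- seq(-1 + 1e-6, 1, length.out = 4001)
  wt <- exp(-energy(grid))
  bin <- cut(grid, breaks)
  expected <- tapply(wt, bin, sum)
  expected <- as.numeric(expected / sum(expected))
  expect_lt(max(abs(obs - expected)), 0.05)
})
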
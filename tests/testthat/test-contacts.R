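test_that("salt-bridge detection applies charge, distance and chain rules", {
  coords <- rbind(c(0, 0, 0), c(20, 0, 0), c(3, 0, 0))
  expect_equal(nrow(detect_salt_bridges(coords, c(1, 0, -1), 6.5)), 1L)
  expect_equal(nrow(detect_salt_bridges(coords, c(1, 0, 1), 6.5)), 0L)
  # adjacent beads (|i-j| < 2) never count
  adj <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(nrow(detect_salt_bridges(adj, c(1, -1), 6.5)), 0L)
  # counts are non-decreasing in the cutoff
  set.seed(20)
  rnd <- matrix(rnorm(300, sd = 8), ncol = 3)
  qv <- sample(c(-1, 0, 1), 100, replace = TRUE)
  cnt <- sapply(c(1e-9, 3, 6, 9, 15), function(ct)
    nrow(detect_salt_bridges(rnd, qv, ct)))
  expect_true(all(diff(cnt) >= 0))
  expect_equal(cnt[1], 0L)
})

test_that("salt-bridge scan equals the brute-force double loop", {
  set.seed(21)
  for (rep in 1:3) {
    coords <- matrix(rnorm(300, sd = 6), ncol = 3)
    qv <- sample(c(-2, -1, 0, 1), 100, replace = TRUE)
    expect_equal(nrow(detect_salt_bridges(coords, qv, 7)),
                 brute_bridges(coords, qv, 7))
  }
})

test_that("bridge classes separate D/E-R/K pairs from phospho-mediated", {
  s <- parse_annotated_sequence("KGGS_GGD")
  cv <- assign_charges(s, charge_model())   # K +1, pS -2, D -1
  coords <- build_initial_chain(7, 3.8)
  coords[4, ] <- coords[1, ] + c(3, 0, 0)   # pS near K
  coords[7, ] <- coords[1, ] + c(0, 3, 0)   # D near K
  br <- detect_salt_bridges(coords, cv, 6.5)
  expect_setequal(br$type, c("phospho", "de_rk"))
})

test_that("ensemble bridge counts reduce to per-frame detection", {
  e <- generate_gaussian_chain_ensemble(20, 3.8, 1, seed = 30)
  qv <- rep(c(1, -1), 10)
  one <- ensemble_salt_bridge_counts(e, qv, cutoff = 8)
  expect_equal(one$total,
               nrow(detect_salt_bridges(get_frame(e, 1), qv, 8)))
  zero <- ensemble_salt_bridge_counts(e, rep(0, 20), cutoff = 8)
  expect_equal(zero$total, 0)
  expect_true(is.na(zero$per_phosphosite))
})

test_that("phosphorylation raises Ash1 salt-bridge counts at 350 mM", {
  s <- idp_fragments()$Ash1
  tot <- sapply(c(FALSE, TRUE), function(phos) {
    act <- if (phos) s$phospho_sites else integer(0)
    cv <- assign_charges(s, charge_model(), act)
    e <- sample_ensemble(s, cv, cg_parameters(salt_molarity = 0.35),
                         mc_config(n_sweeps = 1200, seed = 33))
    ensemble_salt_bridge_counts(e, cv)$total
  })
  expect_gt(tot[2], tot[1])
})

test_that("SASA matches isolated-sphere and two-sphere closed forms", {
  r <- 3.8
  probe <- 1.4
  one <- shrake_rupley_sasa(matrix(0, 1, 3), r, probe)
  expect_equal(as.numeric(one), 4 * pi * (r + probe)^2, tolerance = 0.01)

  far <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(100, 0, 0)), r, probe)
  expect_equal(sum(far), 2 * 4 * pi * (r + probe)^2, tolerance = 0.01)

  Rexp <- r + probe
  for (d in c(4, 6, 8, 10)) {
    two <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), r, probe,
                              n_points = 2048)
    expect_equal(sum(two), two_sphere_area(Rexp, d),
                 tolerance = 0.01, info = paste("d =", d))
  }
})

test_that("SASA is rigid-motion invariant and monotone under occlusion", {
  set.seed(22)
  coords <- matrix(rnorm(60, sd = 5), ncol = 3)
  a0 <- shrake_rupley_sasa(coords, 3.0)
  a1 <- shrake_rupley_sasa(random_rigid(coords, 9), 3.0)
  expect_equal(as.numeric(a1), as.numeric(a0), tolerance = 0.02)

  # adding a bead never increases any existing bead's SASA
  added <- rbind(coords, colMeans(coords))
  a2 <- shrake_rupley_sasa(added, 3.0)
  expect_true(all(a2[1:20] <= a0 + 1e-9))
})

test_that("shielded area vanishes without occlusion and bounds hold", {
  # non-site residues displaced 100 A away cannot occlude the site
  chain <- build_initial_chain(20, 3.8)
  chain[11:20, 1] <- chain[11:20, 1] + 1000
  e <- new_cg_ensemble(array(chain, dim = c(1, 20, 3)))
  sh <- binding_site_shielded_area(e, 1:10, radii = 3.0)
  expect_equal(sh$shielded_area, 0, tolerance = 1e-6)
  expect_error(binding_site_shielded_area(e, integer(0)), "empty")

  # site buried at the center of a dense constructed globule
  set.seed(23)
  shellpts <- uniform_ball_points(9, 60, seed = 24)
  keep <- sqrt(rowSums(shellpts^2)) > 5
  glob <- rbind(build_initial_chain(4, 3.8) -
                  matrix(rep(c(5.7, 0, 0), each = 4), ncol = 3),
                shellpts[keep, ])
  eg <- new_cg_ensemble(array(glob, dim = c(1, nrow(glob), 3)))
  shg <- binding_site_shielded_area(eg, 1:4, radii = 3.0)
  expect_gt(shg$shielded_fraction, 0.5)

  # random coil ensembles stay within [0, 1]
  er <- generate_gaussian_chain_ensemble(30, 3.8, 5, seed = 25)
  shr <- binding_site_shielded_area(er, 10:19, radii = 3.0)
  expect_gte(shr$shielded_fraction, 0)
  expect_lte(shr$shielded_fraction, 1)
  expect_true(all(shr$series$shielded >= -1e-9))
})
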
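# Coarse-grained conformational ensemble generation.
#
# One bead per residue on rigid 3.8 A virtual bonds (Calpha spacing).
# The pair energy (in kT) is WCA excluded volume + a uniform short-range
# square-well attraction + a Debye-Hueckel screened Coulomb term
# q_i q_j lB exp(-r / lD) / r, so ionic strength enters only through the
# Debye screening length lD.

#' Debye screening length of a 1:1 salt solution
#'
#' `lambda_D = sqrt(eps_r eps_0 k_B T / (2 N_A e^2 I))` with ionic
#' strength `I` equal to the molarity for a 1:1 electrolyte.
#'
#' @param salt_molarity mol/L, > 0.
#' @param temperature Kelvin.
#' @param relative_permittivity solvent dielectric constant (water, 78.54).
#' @return Screening length in Angstrom.
#' @examples
#' debye_length(0.1, 298)  # ~9.6 A
#' @export
debye_length <- function(salt_molarity, temperature = 300,
                         relative_permittivity = 78.54) {
  if (any(salt_molarity <= 0)) stop("salt_molarity must be > 0", call. = FALSE)
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  NA_ <- 6.02214076e23       # 1/mol
  e <- 1.602176634e-19       # C
  I_si <- salt_molarity * 1000  # mol/m^3
  lam_m <- sqrt(relative_permittivity * eps0 * kB * temperature /
                  (2 * NA_ * e^2 * I_si))
  lam_m * 1e10
}

#' Coarse-grained interaction parameters
#'
#' @param bond_length rigid virtual-bond length, A (Calpha spacing 3.8).
#' @param bead_radius bead radius, A; the WCA contact distance of a pair
#'   is the sum of the two bead radii.
#' @param phosphate_radius_increment extra radius (A) of a Ser/Thr bead
#'   carrying a phosphate, modelling the compact hydrated PO4 moiety.
#'   Enters both the excluded-volume energy and the surface readout
#'   (SASA, shielding, hydration exposure) through [bead_radii()].
#' @param phosphotyrosine_radius_increment extra radius (A) of a
#'   phosphorylated Tyr bead; larger than the Ser/Thr value because the
#'   phosphate sits on the distal ring of an already bulky side chain,
#'   extending the residue's effective envelope.
#' @param excluded_volume_strength WCA epsilon, kT.
#' @param short_range_attraction depth of the uniform square-well
#'   attraction, kT (small and > 0 by default).
#' @param attraction_range square-well cutoff, A.
#' @param bjerrum_length A (7.1 in water at 300 K).
#' @param salt_molarity mol/L; sets the Debye length unless `debye_len`
#'   is given explicitly.
#' @param temperature Kelvin.
#' @param debye_len optional explicit screening length, A.
#' @return Object of class `cg_parameters`.
#' @export
cg_parameters <- function(bond_length = 3.8, bead_radius = 3.0,
                          phosphate_radius_increment = 0.3,
                          phosphotyrosine_radius_increment = 1.4,
                          excluded_volume_strength = 1.0,
                          short_range_attraction = 0.1,
                          attraction_range = 9.0,
                          bjerrum_length = 7.1,
                          salt_molarity = 0.1,
                          temperature = 300,
                          debye_len = NULL) {
  stopifnot(bond_length > 0, bead_radius > 0, bjerrum_length > 0)
  if (is.null(debye_len))
    debye_len <- debye_length(salt_molarity, temperature)
  stopifnot(debye_len > 0)
  structure(list(bond_length = bond_length, bead_radius = bead_radius,
                 phosphate_radius_increment = phosphate_radius_increment,
                 phosphotyrosine_radius_increment =
                   phosphotyrosine_radius_increment,
                 excluded_volume_strength = excluded_volume_strength,
                 short_range_attraction = short_range_attraction,
                 attraction_range = attraction_range,
                 bjerrum_length = bjerrum_length,
                 salt_molarity = salt_molarity,
                 temperature = temperature,
                 debye_len = debye_len),
            class = "cg_parameters")
}

#' Monte Carlo run configuration
#'
#' @param n_sweeps number of MC sweeps (one sweep = N trial moves).
#' @param equilibration_fraction leading fraction of sweeps discarded
#'   before any frame is saved (default 0.25).
#' @param save_stride sweeps between saved frames.
#' @param seed integer RNG seed; mandatory, recorded in the ensemble
#'   provenance.
#' @param move_weights relative proportions of pivot, crankshaft and
#'   single-bead moves.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_sweeps = 2000, equilibration_fraction = 0.25,
                      save_stride = 5, seed,
                      move_weights = c(pivot = 0.3, crankshaft = 0.5,
                                       local = 0.2)) {
  stopifnot(n_sweeps >= 1, equilibration_fraction >= 0,
            equilibration_fraction < 1, save_stride >= 1)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  structure(list(n_sweeps = as.integer(n_sweeps),
                 equilibration_fraction = equilibration_fraction,
                 save_stride = as.integer(save_stride),
                 seed = as.integer(seed),
                 move_weights = move_weights),
            class = "mc_config")
}

#' Extended linear starting conformation
#'
#' @param n_beads number of beads (or an `annotated_sequence`).
#' @param bond_length bead spacing, A.
#' @return `n_beads x 3` coordinate matrix with beads collinear along x.
#' @export
build_initial_chain <- function(n_beads, bond_length = 3.8) {
  if (inherits(n_beads, "annotated_sequence")) n_beads <- n_beads$n_residues
  stopifnot(n_beads >= 1)
  cbind(x = (seq_len(n_beads) - 1) * bond_length,
        y = numeric(n_beads), z = numeric(n_beads))
}

new_cg_ensemble <- function(coords, residues = NULL, charges = NULL,
                            radii = NULL, provenance = list()) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  structure(list(coords = coords, residues = residues, charges = charges,
                 radii = radii, provenance = provenance),
            class = "cg_ensemble")
}

#' Per-bead radii implied by coarse-grained parameters
#'
#' Uniform `bead_radius`, with the phosphate increment added at active
#' phosphosites (`phosphotyrosine_radius_increment` on Tyr,
#' `phosphate_radius_increment` on Ser/Thr).  Used both by the Monte
#' Carlo excluded-volume term and by the surface readout (SASA,
#' shielded area, hydration exposure).
#'
#' @param n bead count.
#' @param params a [cg_parameters()].
#' @param active_sites 1-based positions carrying a phosphate.
#' @param residues one-letter residue codes (to distinguish pTyr);
#'   `NULL` treats all sites as Ser/Thr.
#' @return Numeric vector of radii, A.
#' @export
bead_radii <- function(n, params, active_sites = NULL, residues = NULL) {
  r <- rep(params$bead_radius, n)
  for (i in active_sites) {
    inc <- if (!is.null(residues) && residues[i] == "Y")
      params$phosphotyrosine_radius_increment
    else params$phosphate_radius_increment
    r[i] <- r[i] + inc
  }
  r
}

#' @export
print.cg_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat("Coarse-grained ensemble: ", d[1], " frames x ", d[2], " beads\n",
      sep = "")
  invisible(x)
}

#' Number of frames / beads in an ensemble
#' @param ensemble a `cg_ensemble`.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @rdname n_frames
#' @export
n_beads <- function(ensemble) dim(ensemble$coords)[2]

#' Extract one conformation from an ensemble
#' @param ensemble a `cg_ensemble`.
#' @param frame frame index.
#' @return `n_beads x 3` matrix.
#' @export
get_frame <- function(ensemble, frame) {
  m <- ensemble$coords[frame, , , drop = TRUE]
  dim(m) <- c(dim(ensemble$coords)[2], 3L)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Sample a coarse-grained ensemble by Metropolis Monte Carlo
#'
#' Starts from the extended chain and evolves it with bond-preserving
#' pivot, crankshaft and single-bead rotation moves under the WCA +
#' square-well + Debye-Hueckel pair energy.  Frames after the
#' equilibration fraction are saved every `save_stride` sweeps.  The same
#' seed reproduces the ensemble bit-for-bit.
#'
#' @param seq an `annotated_sequence` (or a bead count for uncharged
#'   test chains).
#' @param charges a `charge_vector` aligned to the sequence; `NULL` for a
#'   neutral chain.
#' @param params a [cg_parameters()].
#' @param mc an [mc_config()].
#' @return A `cg_ensemble` with full provenance (parameters, config,
#'   seed, acceptance ratios).
#' @examples
#' e <- sample_ensemble(20, params = cg_parameters(),
#'                      mc = mc_config(n_sweeps = 50, seed = 1))
#' n_frames(e)
#' @export
sample_ensemble <- function(seq, charges = NULL, params = cg_parameters(),
                            mc) {
  if (inherits(seq, "annotated_sequence")) {
    n <- seq$n_residues
    residues <- seq$residues
  } else {
    n <- as.integer(seq)
    residues <- rep("G", n)
  }
  if (is.null(charges)) charges <- numeric(n)
  stopifnot(length(charges) == n, inherits(mc, "mc_config"))

  radii <- bead_radii(n, params, attr(charges, "active_sites"), residues)
  coords0 <- build_initial_chain(n, params$bond_length)
  n_discard <- floor(mc$n_sweeps * mc$equilibration_fraction)

  set.seed(mc$seed)
  res <- cg_sample_cpp(coords0, as.numeric(charges),
                       bead_radii = radii,
                       eps_wca = params$excluded_volume_strength,
                       eps_attr = params$short_range_attraction,
                       attr_cutoff = params$attraction_range,
                       bjerrum = params$bjerrum_length,
                       debye = params$debye_len,
                       n_sweeps = mc$n_sweeps, n_discard = n_discard,
                       save_stride = mc$save_stride,
                       move_weights = as.numeric(mc$move_weights),
                       pivot_max_angle = pi, crank_max_angle = pi)

  attempted <- sum(res$attempted)
  accepted <- sum(res$accepted)
  if (n >= 3 && attempted > 0 && accepted == 0)
    warning("sampler stall: no move accepted over the whole run",
            call. = FALSE)

  new_cg_ensemble(res$frames, residues = residues, charges = charges,
                  radii = radii,
                  provenance = list(
                    params = unclass(params), mc = unclass(mc),
                    seed = mc$seed,
                    acceptance = list(
                      attempted = setNames(res$attempted,
                                           c("pivot", "crankshaft", "local")),
                      accepted = setNames(res$accepted,
                                          c("pivot", "crankshaft", "local")),
                      ratio = accepted / max(1, attempted)),
                    final_energy = res$final_energy))
}

#' Ideal (Gaussian) chain reference ensemble
#'
#' Frames are independent fixed-step random walks: the analytic
#' mean-square radius of gyration tends to `n_beads * b^2 / 6` for long
#' chains, which makes this the reference for validating Guinier fits.
#'
#' @param n_beads beads per chain.
#' @param bond_length step length, A.
#' @param n_frames_out number of independent frames.
#' @param seed integer RNG seed.
#' @return A `cg_ensemble`.
#' @export
generate_gaussian_chain_ensemble <- function(n_beads, bond_length = 3.8,
                                             n_frames_out = 1000, seed) {
  stopifnot(n_beads >= 1, n_frames_out >= 1)
  set.seed(seed)
  coords <- array(0, dim = c(n_frames_out, n_beads, 3))
  for (f in seq_len(n_frames_out)) {
    if (n_beads > 1) {
      steps <- matrix(rnorm(3 * (n_beads - 1)), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2)) * bond_length
      coords[f, , ] <- rbind(0, apply(steps, 2, cumsum))
    }
  }
  new_cg_ensemble(coords, residues = rep("G", n_beads),
                  charges = numeric(n_beads),
                  provenance = list(model = "gaussian_chain",
                                    bond_length = bond_length, seed = seed))
}

#' Uniform point cloud in a solid ball
#'
#' Points uniform in the ball of the given radius; the direct radius of
#' gyration of a dense cloud approaches `sqrt(3/5) * radius`, the uniform
#' sphere's second moment.  Used as the rigid reference shape in SAXS and
#' Guinier tests.
#'
#' @param radius ball radius, A.
#' @param n_points number of points.
#' @param seed integer RNG seed.
#' @return `n_points x 3` coordinate matrix.
#' @export
uniform_ball_points <- function(radius, n_points, seed) {
  stopifnot(radius > 0, n_points >= 1)
  set.seed(seed)
  u <- matrix(rnorm(3 * n_points), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * runif(n_points)^(1 / 3)
  m <- u * r
  colnames(m) <- c("x", "y", "z")
  m
}
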
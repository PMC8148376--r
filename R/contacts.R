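# Salt-bridge counting and binding-site shielding from solvent
# accessible surface area.

#' Detect salt bridges in one conformation
#'
#' A salt bridge is an unordered bead pair `(i, j)` with `|i - j| >= 2`,
#' formal charges of opposite sign and center distance within the
#' cutoff.  Pairs are classified as `de_rk` when both partners are
#' unmodified D/E/K/R residues and `phospho` when at least one partner is
#' an active phosphosite.
#'
#' @param coords `n x 3` coordinates, A.
#' @param charges a `charge_vector` (carries residue identities and
#'   active sites) or plain numeric charges.
#' @param cutoff distance cutoff between charged bead centers, A.  The
#'   coarse-grained default 9.0 is 1.5 times the 6 A WCA contact
#'   diameter of two standard beads, i.e. the first coordination shell;
#'   atomistic salt-bridge cutoffs (~4 A between side-chain nitrogens
#'   and oxygens) do not transfer to one-bead residues.
#' @return Data frame with columns `i`, `j`, `distance`, `type`.
#' @export
detect_salt_bridges <- function(coords, charges, cutoff = 9.0) {
  stopifnot(cutoff > 0)
  coords <- as.matrix(coords)
  q <- as.numeric(charges)
  n <- nrow(coords)
  stopifnot(length(q) == n)
  residues <- attr(charges, "residues")
  active <- attr(charges, "active_sites")
  if (is.null(active)) active <- integer(0)

  ci <- which(q != 0)
  if (length(ci) < 2)
    return(data.frame(i = integer(0), j = integer(0),
                      distance = numeric(0), type = character(0)))
  pr <- t(combn(ci, 2))
  keep <- (pr[, 2] - pr[, 1]) >= 2 & q[pr[, 1]] * q[pr[, 2]] < 0
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) == 0)
    return(data.frame(i = integer(0), j = integer(0),
                      distance = numeric(0), type = character(0)))
  d <- sqrt(rowSums((coords[pr[, 1], , drop = FALSE] -
                       coords[pr[, 2], , drop = FALSE])^2))
  keep <- d <= cutoff
  pr <- pr[keep, , drop = FALSE]
  d <- d[keep]

  type <- rep("other", nrow(pr))
  if (!is.null(residues)) {
    de_rk <- (residues[pr[, 1]] %in% c("D", "E") &
                residues[pr[, 2]] %in% c("K", "R")) |
             (residues[pr[, 1]] %in% c("K", "R") &
                residues[pr[, 2]] %in% c("D", "E"))
    de_rk <- de_rk & !(pr[, 1] %in% active) & !(pr[, 2] %in% active)
    type[de_rk] <- "de_rk"
  }
  phos <- (pr[, 1] %in% active) | (pr[, 2] %in% active)
  type[phos] <- "phospho"
  data.frame(i = pr[, 1], j = pr[, 2], distance = d, type = type)
}

#' Frame-averaged salt-bridge counts of an ensemble
#'
#' @param ensemble a `cg_ensemble`.
#' @param charges a `charge_vector` (defaults to the ensemble's own).
#' @param cutoff distance cutoff, A.
#' @return List of class `salt_bridge_counts`: mean `total`,
#'   `de_rk_only`, `phospho` bridges per frame, `per_phosphosite`
#'   (phospho bridges over active-site count; `NA` when no site is
#'   active), `cutoff`, `n_frames`, and the per-frame `series`.
#' @export
ensemble_salt_bridge_counts <- function(ensemble, charges = NULL,
                                        cutoff = 9.0) {
  if (is.null(charges)) charges <- ensemble$charges
  nf <- n_frames(ensemble)
  totals <- de_rk <- phos <- numeric(nf)
  for (f in seq_len(nf)) {
    br <- detect_salt_bridges(get_frame(ensemble, f), charges, cutoff)
    totals[f] <- nrow(br)
    de_rk[f] <- sum(br$type == "de_rk")
    phos[f] <- sum(br$type == "phospho")
  }
  n_active <- length(attr(charges, "active_sites"))
  structure(list(total = mean(totals), de_rk_only = mean(de_rk),
                 phospho = mean(phos),
                 per_phosphosite = if (n_active > 0) mean(phos) / n_active
                                   else NA_real_,
                 cutoff = cutoff, n_frames = nf,
                 series = data.frame(frame = seq_len(nf), total = totals,
                                     de_rk = de_rk, phospho = phos)),
            class = "salt_bridge_counts")
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic golden-spiral quadrature on each bead's probe-expanded
#' sphere: the accessible fraction of quadrature points times
#' `4 pi (r + probe)^2`.
#'
#' @param coords `n x 3` coordinates, A.
#' @param radii per-bead radii, A (recycled; coarse-grained default 3.8).
#' @param probe probe radius, A (water, 1.4).
#' @param n_points quadrature points per sphere (>= 64).
#' @return Numeric vector of per-bead SASA (A^2) with attributes `probe`
#'   and `n_points`.
#' @export
shrake_rupley_sasa <- function(coords, radii = 3.8, probe = 1.4,
                               n_points = 512) {
  coords <- as.matrix(coords)
  stopifnot(all(radii > 0), probe >= 0, n_points >= 64)
  radii <- rep_len(radii, nrow(coords))
  a <- sasa_cpp(coords, radii, probe, as.integer(n_points))
  attr(a, "probe") <- probe
  attr(a, "n_points") <- n_points
  a
}

#' Binding-site shielded area
#'
#' For each frame, the site's intrinsic surface (SASA of the site-only
#' sub-conformation, same internal coordinates) minus its exposed surface
#' within the full chain: the part of the interaction site occluded by
#' the rest of the IDP.
#'
#' @param ensemble a `cg_ensemble`.
#' @param site_residues 1-based bead positions of the interaction site.
#' @param radii per-bead radius, A.
#' @param probe probe radius, A.
#' @param n_points quadrature points.
#' @return List of class `shielding_result`: `shielded_area` (ensemble
#'   mean, A^2), `shielded_fraction`, `standard_error` (block SE over
#'   frames), `site_residues`, per-frame `series`.
#' @export
binding_site_shielded_area <- function(ensemble, site_residues,
                                       radii = 3.8, probe = 1.4,
                                       n_points = 256) {
  site_residues <- as.integer(site_residues)
  if (length(site_residues) == 0) stop("empty site", call. = FALSE)
  stopifnot(all(site_residues >= 1), all(site_residues <= n_beads(ensemble)))
  nf <- n_frames(ensemble)
  shielded <- site_only <- numeric(nf)
  for (f in seq_len(nf)) {
    conf <- get_frame(ensemble, f)
    r_full <- rep_len(radii, nrow(conf))
    a_full <- shrake_rupley_sasa(conf, r_full, probe, n_points)
    sub <- conf[site_residues, , drop = FALSE]
    a_sub <- shrake_rupley_sasa(sub, r_full[site_residues], probe, n_points)
    site_only[f] <- sum(a_sub)
    shielded[f] <- sum(a_sub) - sum(a_full[site_residues])
  }
  se <- if (nf >= 4) block_standard_error(shielded)
        else if (nf >= 2) sd(shielded) / sqrt(nf) else 0
  structure(list(shielded_area = mean(shielded),
                 shielded_fraction = mean(shielded) / mean(site_only),
                 standard_error = se,
                 site_residues = site_residues,
                 n_frames = nf,
                 series = data.frame(frame = seq_len(nf),
                                     shielded = shielded,
                                     site_only = site_only)),
            class = "shielding_result")
}
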
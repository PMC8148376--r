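# Radius-of-gyration statistics, random-coil normalization and
# convergence diagnostics.

# Average residue masses (Da), used for the mass-weighted Rg.
RESIDUE_MASSES <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Mass-weighted radius of gyration of one conformation
#'
#' `sqrt(sum m_i |r_i - r_com|^2 / sum m_i)` with `r_com` the
#' mass-weighted centroid.
#'
#' @param coords `n x 3` coordinate matrix, A.
#' @param masses per-bead masses (> 0); uniform by default.
#' @return Rg in Angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n)
    stop("masses length does not match bead count", call. = FALSE)
  stopifnot(all(masses > 0))
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Per-frame Rg series of an ensemble
#'
#' @param ensemble a `cg_ensemble`.
#' @param masses `"residue"` for standard residue molecular masses (from
#'   the ensemble's residue labels), `"uniform"`, or a numeric vector.
#' @return Numeric vector of per-frame Rg values (A), ordered by frame.
#' @export
ensemble_rg <- function(ensemble, masses = c("residue", "uniform")) {
  if (is.character(masses)) {
    masses <- match.arg(masses)
    m <- if (masses == "residue" && !is.null(ensemble$residues))
      unname(RESIDUE_MASSES[ensemble$residues]) else rep(1, n_beads(ensemble))
  } else m <- masses
  vapply(seq_len(n_frames(ensemble)),
         function(f) radius_of_gyration(get_frame(ensemble, f), m),
         numeric(1))
}

#' Random-coil reference dimension
#'
#' Excluded-volume coil scaling `Rc = r0 * N^0.588` used to normalize Rg
#' across chains of different length.
#'
#' @param n_residues chain length.
#' @param r0 prefactor in A (default 2.0).
#' @return Rc in Angstrom.
#' @export
random_coil_rc <- function(n_residues, r0 = 2.0) {
  stopifnot(n_residues >= 1, r0 > 0)
  r0 * n_residues^0.588
}

#' Block-averaged standard error
#'
#' Standard error of the mean estimated from means of consecutive
#' non-overlapping blocks, robust to the autocorrelation of Monte Carlo /
#' MD series.
#'
#' @param series numeric vector (e.g. per-frame Rg).
#' @param block_size frames per block; default `round(sqrt(n))`.
#' @return Standard error (same units as the series).
#' @export
block_standard_error <- function(series, block_size = NULL) {
  n <- length(series)
  if (is.null(block_size)) block_size <- max(1L, round(sqrt(n)))
  stopifnot(block_size >= 1, block_size <= n)
  nb <- n %/% block_size
  if (nb < 2) stop("fewer than 2 blocks; reduce block_size", call. = FALSE)
  idx <- rep(seq_len(nb), each = block_size)
  bm <- tapply(series[seq_len(nb * block_size)], idx, mean)
  sd(bm) / sqrt(nb)
}

#' Cumulative-mean convergence profile
#'
#' Cumulative mean of the series at increasing fractions of the frames,
#' with the absolute change between the last two windows as a simple
#' convergence diagnostic.
#'
#' @param series numeric vector.
#' @param window_fractions increasing fractions in (0, 1].
#' @return List with a data frame `profile` (fraction, n_frames,
#'   cumulative_mean) and `final_delta`.
#' @export
convergence_profile <- function(series,
                                window_fractions = c(0.25, 0.5, 0.75, 1)) {
  stopifnot(length(series) >= 1, all(window_fractions > 0),
            all(window_fractions <= 1))
  ns <- pmax(1L, floor(length(series) * window_fractions))
  cm <- vapply(ns, function(k) mean(series[seq_len(k)]), numeric(1))
  delta <- if (length(cm) >= 2) abs(diff(utils::tail(cm, 2))) else 0
  list(profile = data.frame(fraction = window_fractions, n_frames = ns,
                            cumulative_mean = cm),
       final_delta = delta)
}

#' Ensemble Rg summary with random-coil normalization
#'
#' @param ensemble a `cg_ensemble`.
#' @param r0 random-coil prefactor, A.
#' @param block_size block size for the standard error (default
#'   `round(sqrt(n_frames))`).
#' @param masses see [ensemble_rg()].
#' @return List of class `ensemble_summary`: `mean_rg`, `standard_error`,
#'   `n_frames`, `n_residues`, `rc`, `r0`, `normalized_rg`.
#' @export
ensemble_summary <- function(ensemble, r0 = 2.0, block_size = NULL,
                             masses = "residue") {
  rg <- ensemble_rg(ensemble, masses)
  n <- length(rg)
  se <- if (n >= 4) block_standard_error(rg, block_size) else sd(rg) / sqrt(n)
  rc <- random_coil_rc(n_beads(ensemble), r0)
  structure(list(mean_rg = mean(rg), standard_error = se, n_frames = n,
                 n_residues = n_beads(ensemble), rc = rc, r0 = r0,
                 normalized_rg = mean(rg) / rc),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "Rg = %.2f +/- %.2f A over %d frames (N = %d, Rg/Rc = %.3f)\n",
    x$mean_rg, x$standard_error, x$n_frames, x$n_residues,
    x$normalized_rg))
  invisible(x)
}
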
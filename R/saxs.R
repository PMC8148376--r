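# Debye-formula SAXS forward calculation, hydration-contrast shell,
# Guinier / extended-Guinier fitting and chi-square curve comparison.

#' Construct a scattering curve
#'
#' @param q scattering vector grid, 1/A, strictly increasing, >= 0.
#' @param intensity positive intensities (arbitrary units).
#' @param sigma optional per-point uncertainties, > 0.
#' @return Object of class `scattering_curve` (a data frame q, I, sigma).
#' @export
scattering_curve <- function(q, intensity, sigma = NULL) {
  stopifnot(length(q) == length(intensity), all(is.finite(q)),
            all(is.finite(intensity)), all(q >= 0), !is.unsorted(q, strictly = TRUE))
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q), all(sigma > 0))
  }
  structure(data.frame(q = q, I = intensity,
                       sigma = if (is.null(sigma)) NA_real_ else sigma),
            class = c("scattering_curve", "data.frame"))
}

#' Default logarithmic q grid
#' @param q_min,q_max grid limits, 1/A.
#' @param n number of points.
#' @export
default_q_grid <- function(q_min = 0.005, q_max = 0.5, n = 120) {
  exp(seq(log(q_min), log(q_max), length.out = n))
}

#' Debye-formula scattering intensity of one conformation
#'
#' `I(q) = sum_i sum_j f_i(q) f_j(q) sin(q r_ij) / (q r_ij)` with the
#' `i = j` and `q -> 0` limits handled analytically.
#'
#' @param coords `n x 3` coordinates (A), or a `scatterer_set` from
#'   [add_hydration_shell()].
#' @param form_factors per-scatterer form factor: a scalar, a vector of
#'   per-scatterer weights (q-independent), or an `n x length(q)` matrix.
#' @param q scattering vector grid, 1/A, >= 0.
#' @return A `scattering_curve`.
#' @examples
#' # two unit scatterers d apart: I(q) = 2 + 2 sin(qd)/(qd)
#' debye_intensity(rbind(c(0, 0, 0), c(5, 0, 0)), q = c(0.1, 0.2))
#' @export
debye_intensity <- function(coords, form_factors = 1, q = default_q_grid()) {
  if (inherits(coords, "scatterer_set")) {
    form_factors <- coords$weights
    coords <- coords$coords
  }
  coords <- as.matrix(coords)
  if (any(q < 0)) stop("negative q", call. = FALSE)
  n <- nrow(coords)
  ff <- if (is.matrix(form_factors)) form_factors
        else matrix(rep_len(form_factors, n), nrow = n, ncol = length(q))
  stopifnot(nrow(ff) == n, ncol(ff) == length(q))
  scattering_curve(q, debye_intensity_cpp(coords, ff, as.numeric(q)))
}

#' Frame-averaged Debye intensity of an ensemble
#'
#' Unweighted arithmetic mean of the per-frame Debye intensities.
#'
#' @param ensemble a `cg_ensemble`.
#' @inheritParams debye_intensity
#' @export
ensemble_average_intensity <- function(ensemble, form_factors = 1,
                                       q = default_q_grid()) {
  if (any(q < 0)) stop("negative q", call. = FALSE)
  n <- n_beads(ensemble)
  ff <- if (is.matrix(form_factors)) form_factors
        else matrix(rep_len(form_factors, n), nrow = n, ncol = length(q))
  I <- debye_ensemble_cpp(as.numeric(ensemble$coords), n_frames(ensemble),
                          n, ff, as.numeric(q))
  scattering_curve(q, I)
}

#' Hydration-contrast model
#'
#' Parametric stand-in for the excess scattering of the solvation shell:
#' each sufficiently exposed bead receives one extra scatterer of weight
#' `shell_weight` placed `shell_distance` outward from the chain
#' centroid; at phosphosites the weight is multiplied by `phospho_boost`
#' (>= 1), lumping the dense hydration and condensed counterions of the
#' doubly charged phosphate into one excess-contrast term.
#'
#' @param shell_weight excess-scattering weight per solvated bead (>= 0),
#'   relative to a protein bead weight of 1.
#' @param shell_distance radial offset of the shell point, A.
#' @param phospho_boost multiplicative weight factor at phosphosites.
#' @param exposure_threshold SASA fraction above which a bead is
#'   considered solvated.
#' @return Object of class `hydration_model`.
#' @export
hydration_model <- function(shell_weight = 0.5, shell_distance = 5.0,
                            phospho_boost = 5.0, exposure_threshold = 0.3) {
  stopifnot(shell_weight >= 0, phospho_boost >= 1)
  structure(list(shell_weight = shell_weight,
                 shell_distance = shell_distance,
                 phospho_boost = phospho_boost,
                 exposure_threshold = exposure_threshold),
            class = "hydration_model")
}

#' Augment a conformation with hydration-shell scatterers
#'
#' @param coords `n x 3` bead coordinates, A.
#' @param sasa_fractions per-bead exposure fractions in `[0, 1]`.
#' @param model a [hydration_model()].
#' @param phospho_sites 1-based indices of beads whose shell weight is
#'   boosted.
#' @return A `scatterer_set`: list with `coords` (protein beads then
#'   shell points), `weights`, and `is_shell`.
#' @export
add_hydration_shell <- function(coords, sasa_fractions,
                                model = hydration_model(),
                                phospho_sites = integer(0)) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(sasa_fractions) == n, all(sasa_fractions >= 0),
            all(sasa_fractions <= 1))
  solvated <- which(sasa_fractions >= model$exposure_threshold)
  centroid <- colMeans(coords)
  shell <- NULL
  w_shell <- numeric(0)
  if (model$shell_weight > 0 && length(solvated) > 0) {
    out <- sweep(coords[solvated, , drop = FALSE], 2, centroid)
    nrm <- sqrt(rowSums(out^2))
    nrm[nrm < 1e-9] <- 1
    u <- out / nrm
    shell <- coords[solvated, , drop = FALSE] + model$shell_distance * u
    w_shell <- rep(model$shell_weight, length(solvated))
    w_shell[solvated %in% phospho_sites] <-
      model$shell_weight * model$phospho_boost
  }
  structure(list(coords = rbind(coords, shell),
                 weights = c(rep(1, n), w_shell),
                 is_shell = c(rep(FALSE, n), rep(TRUE, length(w_shell)))),
            class = "scatterer_set")
}

#' Guinier and extended-Guinier fit
#'
#' Weighted least squares of `ln I` against `q^2` over the largest
#' low-q window satisfying `q * Rg <= q_rg_max`, solved self-consistently
#' (fit, recompute the window from the fitted Rg, repeat to a fixed
#' point).  The standard mode uses the conservative textbook Guinier
#' region `q Rg <= 1.0`; the extended mode, intended for disordered
#' chains, widens the window to `q Rg <= 1.9`.
#'
#' @param curve a `scattering_curve`; points with `I > 0` are used,
#'   weighted by `(I / sigma)^2` when uncertainties are present.
#' @param mode `"standard"` or `"extended"`.
#' @param q_rg_max window limit override.
#' @param max_iter,tol fixed-point iteration controls.
#' @return Object of class `guinier_fit`: `rg`, `i0`, `q_window`,
#'   `mode`, `q_rg_max`, `n_points`, `r_squared`, `residuals`,
#'   `iterations`.
#' @export
guinier_fit <- function(curve, mode = c("standard", "extended"),
                        q_rg_max = NULL, max_iter = 50, tol = 1e-6) {
  mode <- match.arg(mode)
  if (is.null(q_rg_max)) q_rg_max <- if (mode == "standard") 1.0 else 1.9
  ok <- curve$I > 0 & curve$q > 0
  q <- curve$q[ok]
  I <- curve$I[ok]
  sig <- curve$sigma[ok]
  have_sigma <- all(is.finite(sig))
  if (sum(ok) < 5) stop("fewer than 5 usable points", call. = FALSE)

  fit_window <- function(idx) {
    w <- if (have_sigma) (I[idx] / sig[idx])^2 else rep(1, length(idx))
    lm(log(I[idx]) ~ I(q[idx]^2), weights = w)
  }

  # start from the lowest-q fifth of the data (at least 5 points)
  idx <- seq_len(max(5L, ceiling(length(q) / 5)))
  rg <- NA_real_
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    fit <- fit_window(idx)
    slope <- coef(fit)[[2]]
    if (slope >= 0)
      stop("Guinier fit failed: non-negative slope of ln I vs q^2",
           call. = FALSE)
    rg_new <- sqrt(-3 * slope)
    idx_new <- which(q * rg_new <= q_rg_max)
    if (length(idx_new) < 5) idx_new <- seq_len(5L)
    converged <- !is.na(rg) && abs(rg_new - rg) < tol &&
      identical(idx_new, idx)
    rg <- rg_new
    idx <- idx_new
    if (converged) break
  }
  if (iterations == max_iter && max_iter > 2)
    warning("Guinier window iteration did not fully converge", call. = FALSE)

  fit <- fit_window(idx)
  i0 <- exp(coef(fit)[[1]])
  pred <- exp(fitted(fit))
  w <- if (have_sigma) (I[idx] / sig[idx])^2 else rep(1, length(idx))
  ly <- log(I[idx])
  r2 <- 1 - sum(w * residuals(fit)^2) /
    max(sum(w * (ly - weighted.mean(ly, w))^2), .Machine$double.xmin)
  structure(list(rg = rg, i0 = i0,
                 q_window = range(q[idx]), mode = mode, q_rg_max = q_rg_max,
                 n_points = length(idx),
                 r_squared = r2,
                 residuals = pred - I[idx],
                 iterations = iterations),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "Guinier fit (%s): Rg = %.3f A, I(0) = %.4g, %d pts, q in [%.4f, %.4f]\n",
    x$mode, x$rg, x$i0, x$n_points, x$q_window[1], x$q_window[2]))
  invisible(x)
}

#' Reduced chi-square between two scattering curves
#'
#' The calculated curve is linearly interpolated onto the reference grid
#' and scaled by the closed-form least-squares constant
#' `c = sum(I_c I_r / s^2) / sum(I_c^2 / s^2)`; then
#' `chi2 = sum(((c I_c - I_r) / s)^2) / (N - 1)`.
#'
#' @param calc,reference `scattering_curve`s; the reference must carry
#'   positive uncertainties.
#' @return Object of class `chi_square_result`: `chi2`, `fitted_scale`,
#'   `residuals`, `n_points`.
#' @export
chi_square <- function(calc, reference) {
  if (!all(is.finite(reference$sigma)) || any(reference$sigma <= 0))
    stop("reference curve must carry positive uncertainties", call. = FALSE)
  qr <- reference$q
  inside <- qr >= min(calc$q) & qr <= max(calc$q)
  if (!any(inside)) stop("q ranges do not overlap", call. = FALSE)
  qr <- qr[inside]
  Ir <- reference$I[inside]
  s <- reference$sigma[inside]
  Ic <- approx(calc$q, calc$I, xout = qr)$y
  scale <- sum(Ic * Ir / s^2) / sum(Ic^2 / s^2)
  resid <- scale * Ic - Ir
  n <- length(qr)
  structure(list(chi2 = sum((resid / s)^2) / (n - 1),
                 fitted_scale = scale, residuals = resid, n_points = n),
            class = "chi_square_result")
}

#' Read / write 3-column SAXS curves
#'
#' Whitespace-separated `q I [sigma]` text with `#` comments (the common
#' `.dat` dialect).
#'
#' @param file path.
#' @export
read_saxs_dat <- function(file) {
  tab <- read.table(file, comment.char = "#", header = FALSE)
  scattering_curve(tab[[1]], tab[[2]],
                   sigma = if (ncol(tab) >= 3) tab[[3]] else NULL)
}

#' @param curve a `scattering_curve`.
#' @rdname read_saxs_dat
#' @export
write_saxs_dat <- function(curve, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# q[1/A]  I  sigma", con)
  has_sig <- all(is.finite(curve$sigma))
  for (i in seq_len(nrow(curve))) {
    writeLines(sprintf("%.8g  %.10g  %s", curve$q[i], curve$I[i],
                       if (has_sig) sprintf("%.10g", curve$sigma[i]) else "0"),
               con)
  }
  invisible(file)
}
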
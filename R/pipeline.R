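# Study orchestration: states x salt series -> per-state summaries,
# pairwise phosphorylation deltas, and the V-shape correlation of
# normalized Rg with net charge per residue.

#' Study configuration
#'
#' @param sequences named list of `annotated_sequence` objects (default:
#'   the four bundled IDP fragments).
#' @param states named list of active-site resolvers; by default each
#'   sequence gets `unphos`/`partial`(where annotated)/`full` via
#'   [default_states()].
#' @param model a [charge_model()].
#' @param salt_mM ionic strengths of the scan, mM.
#' @param seeds integer seeds; each (sequence, state, salt) is sampled
#'   once per seed, and phosphorylation deltas pair states at matched
#'   seeds.
#' @param n_sweeps,save_stride,equilibration_fraction MC controls passed
#'   to [mc_config()].
#' @param cg named list of [cg_parameters()] overrides (e.g.
#'   `short_range_attraction`).
#' @param r0 random-coil prefactor for normalization, A.
#' @param hydration a [hydration_model()] for the SAXS stage.
#' @param saxs_frames max frames used for ensemble SAXS (subsampled).
#' @param shield_frames max frames used for the shielding stage.
#' @param q q grid for SAXS.
#' @return Object of class `study_config`.
#' @export
study_config <- function(sequences = idp_fragments(), states = NULL,
                         model = charge_model(),
                         salt_mM = c(100, 350, 1500), seeds = 1:3,
                         n_sweeps = 2000, save_stride = 5,
                         equilibration_fraction = 0.25,
                         cg = list(), r0 = 2.0,
                         hydration = hydration_model(),
                         saxs_frames = 150, shield_frames = 100,
                         q = default_q_grid()) {
  stopifnot(length(sequences) >= 1, length(salt_mM) >= 1,
            length(seeds) >= 1)
  if (is.null(states)) states <- lapply(sequences, default_states)
  structure(list(sequences = sequences, states = states, model = model,
                 salt_mM = salt_mM, seeds = as.integer(seeds),
                 n_sweeps = n_sweeps, save_stride = save_stride,
                 equilibration_fraction = equilibration_fraction,
                 cg = cg, r0 = r0, hydration = hydration,
                 saxs_frames = saxs_frames, shield_frames = shield_frames,
                 q = q),
            class = "study_config")
}

resolve_params <- function(config, salt_mM) {
  args <- config$cg
  args$salt_molarity <- salt_mM / 1000
  do.call(cg_parameters, args)
}

subsample_frames <- function(nf, k) {
  if (nf <= k) seq_len(nf) else unique(round(seq(1, nf, length.out = k)))
}

#' Run one (sequence, state, salt, seed) cell of the study
#'
#' Samples the coarse-grained ensemble, summarizes Rg, forward-calculates
#' protein-only and hydration-shell SAXS curves with Guinier fits, counts
#' salt bridges, and (when the sequence defines a binding site) computes
#' the shielded area.
#'
#' @param config a [study_config()].
#' @param seq_id sequence name in `config$sequences`.
#' @param state state label in the sequence's state list.
#' @param salt_mM ionic strength, mM.
#' @param seed integer seed for this cell.
#' @param keep_ensemble return the sampled ensemble as an attribute.
#' @return One-row data frame (a StateResult).
#' @export
run_state <- function(config, seq_id, state, salt_mM, seed,
                      keep_ensemble = FALSE) {
  seq <- config$sequences[[seq_id]]
  if (is.null(seq)) stop("unknown sequence: ", seq_id, call. = FALSE)
  active <- config$states[[seq_id]][[state]]
  if (is.null(active)) stop("unknown state '", state, "' for ", seq_id,
                            call. = FALSE)
  cv <- assign_charges(seq, config$model, active)
  params <- resolve_params(config, salt_mM)
  mc <- mc_config(n_sweeps = config$n_sweeps,
                  equilibration_fraction = config$equilibration_fraction,
                  save_stride = config$save_stride, seed = seed)
  ens <- sample_ensemble(seq, cv, params, mc)
  summ <- ensemble_summary(ens, r0 = config$r0)

  # SAXS on a frame subset: protein-only and hydration-augmented curves
  sel <- subsample_frames(n_frames(ens), config$saxs_frames)
  radii <- ens$radii
  iso_area <- 4 * pi * (radii + 1.4)^2
  I_prot <- 0
  I_hyd <- 0
  for (f in sel) {
    conf <- get_frame(ens, f)
    I_prot <- I_prot + debye_intensity(conf, 1, config$q)$I
    sasa <- shrake_rupley_sasa(conf, radii, probe = 1.4, n_points = 128)
    frac <- pmin(1, sasa / iso_area)
    sset <- add_hydration_shell(conf, frac, config$hydration,
                                phospho_sites = active)
    I_hyd <- I_hyd + debye_intensity(sset, q = config$q)$I
  }
  curve_prot <- scattering_curve(config$q, I_prot / length(sel))
  curve_hyd <- scattering_curve(config$q, I_hyd / length(sel))
  g_prot <- guinier_fit(curve_prot, mode = "extended")
  g_hyd <- guinier_fit(curve_hyd, mode = "extended")

  sb <- ensemble_salt_bridge_counts(ens, cv)

  shielded <- shielded_se <- NA_real_
  site <- attr(seq, "binding_site")
  if (!is.null(site)) {
    sel_s <- subsample_frames(n_frames(ens), config$shield_frames)
    sub <- ens
    sub$coords <- ens$coords[sel_s, , , drop = FALSE]
    sh <- binding_site_shielded_area(sub, site, radii = radii)
    shielded <- sh$shielded_area
    shielded_se <- sh$standard_error
  }

  data.frame(sequence = seq_id, state = state, salt_mM = salt_mM,
             seed = seed,
             n_residues = seq$n_residues, n_active = length(active),
             net_charge = net_charge(cv), ncpr = ncpr(cv),
             mean_rg = summ$mean_rg, se_rg = summ$standard_error,
             normalized_rg = summ$normalized_rg,
             guinier_rg_protein = g_prot$rg, guinier_rg_hydrated = g_hyd$rg,
             sb_total = sb$total, sb_de_rk = sb$de_rk_only,
             sb_phospho = sb$phospho, sb_per_site = sb$per_phosphosite,
             shielded_area = shielded, shielded_se = shielded_se,
             acceptance = ens$provenance$acceptance$ratio,
             stringsAsFactors = FALSE) ->
    out
  if (keep_ensemble) attr(out, "ensemble") <- ens
  out
}

#' Run the full study grid
#'
#' Every sequence x state x salt x seed cell of the configuration.
#'
#' @param config a [study_config()].
#' @param states optional character vector restricting the states.
#' @param verbose print progress lines.
#' @return Data frame of StateResults (one row per cell).
#' @export
run_study <- function(config, states = NULL, verbose = FALSE) {
  rows <- list()
  for (seq_id in names(config$sequences)) {
    st_names <- names(config$states[[seq_id]])
    if (!is.null(states)) st_names <- intersect(st_names, states)
    for (state in st_names)
      for (salt in config$salt_mM)
        for (seed in config$seeds) {
          if (verbose)
            message(seq_id, " ", state, " ", salt, " mM seed ", seed)
          rows[[length(rows) + 1L]] <-
            run_state(config, seq_id, state, salt, seed)
        }
  }
  do.call(rbind, rows)
}

#' Pairwise phosphorylation deltas at matched seeds
#'
#' For each (sequence, salt, seed), the change of a summary column from
#' the reference state to the comparison state, then aggregated over
#' seeds (mean and standard error across seeds).
#'
#' @param results StateResult data frame from [run_study()].
#' @param column summary column to difference (default `mean_rg`).
#' @param state_from,state_to reference and comparison state labels.
#' @return Data frame: sequence, salt_mM, n_seeds, delta (mean over
#'   seeds), se (SE across seeds, or paired per-seed SE for one seed).
#' @export
state_deltas <- function(results, column = "mean_rg",
                         state_from = "unphos", state_to = "full") {
  key <- interaction(results$sequence, results$salt_mM, results$seed,
                     drop = TRUE)
  rows <- list()
  for (k in levels(key)) {
    sub <- results[key == k, ]
    a <- sub[sub$state == state_from, ]
    b <- sub[sub$state == state_to, ]
    if (nrow(a) != 1 || nrow(b) != 1) next
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = a$sequence, salt_mM = a$salt_mM, seed = a$seed,
      delta = b[[column]] - a[[column]],
      se_pair = sqrt(a$se_rg^2 + b$se_rg^2))
  }
  per_seed <- do.call(rbind, rows)
  if (is.null(per_seed)) return(NULL)
  agg <- list()
  key2 <- interaction(per_seed$sequence, per_seed$salt_mM, drop = TRUE)
  for (k in levels(key2)) {
    sub <- per_seed[key2 == k, ]
    ns <- nrow(sub)
    agg[[length(agg) + 1L]] <- data.frame(
      sequence = sub$sequence[1], salt_mM = sub$salt_mM[1], n_seeds = ns,
      delta = mean(sub$delta),
      se = if (ns >= 2) sd(sub$delta) / sqrt(ns) else sub$se_pair[1])
  }
  do.call(rbind, agg)
}

#' Salt scan of the phosphorylation effect for one sequence
#'
#' Runs `unphos` and `full` states across the salt series and reports the
#' per-salt phosphorylation delta with a monotonicity flag on
#' `|delta Rg|` versus salt.
#'
#' @param config a [study_config()].
#' @param seq_id sequence name.
#' @param results optional precomputed StateResults to reuse.
#' @return List with `table` (per-salt deltas) and
#'   `attenuation_monotone` (`NA` for a single-salt scan).
#' @export
salt_scan <- function(config, seq_id, results = NULL) {
  if (is.null(results)) {
    cfg <- config
    cfg$sequences <- config$sequences[seq_id]
    cfg$states <- config$states[seq_id]
    results <- run_study(cfg, states = c("unphos", "full"))
  } else {
    results <- results[results$sequence == seq_id, ]
  }
  d <- state_deltas(results)
  d <- d[order(d$salt_mM), ]
  mono <- if (nrow(d) >= 2) !is.unsorted(rev(abs(d$delta))) else NA
  list(table = d, attenuation_monotone = mono)
}

#' Weighted linear fit of normalized Rg against NCPR (V-shape test)
#'
#' Weighted least squares of normalized Rg on NCPR (or `|NCPR|`), with
#' weights `1 / SE^2`; the slope's two-sided p-value comes from the
#' t-statistic with `n - 2` degrees of freedom.
#'
#' @param results data frame with columns `normalized_rg`, `ncpr` and a
#'   standard-error column, e.g. aggregated StateResults.
#' @param use_abs_ncpr regress on `|NCPR|` (the V folded onto one arm).
#' @param se_column name of the standard-error column (on the normalized
#'   Rg scale).
#' @return Object of class `vshape_fit`: `slope`, `intercept`,
#'   `slope_se`, `p_value`, `n_points`, `use_abs_ncpr`.
#' @export
vshape_fit <- function(results, use_abs_ncpr = TRUE,
                       se_column = "normalized_se") {
  stopifnot(nrow(results) >= 3)
  x <- if (use_abs_ncpr) abs(results$ncpr) else results$ncpr
  if (max(x) - min(x) < 1e-12)
    stop("degenerate predictor: all NCPR values equal", call. = FALSE)
  se <- results[[se_column]]
  stopifnot(!is.null(se), all(se > 0))
  y <- results$normalized_rg
  fit <- lm(y ~ x, weights = 1 / se^2)
  sm <- summary(fit)$coefficients
  structure(list(slope = sm["x", "Estimate"],
                 intercept = sm["(Intercept)", "Estimate"],
                 slope_se = sm["x", "Std. Error"],
                 p_value = sm["x", "Pr(>|t|)"],
                 n_points = length(y),
                 use_abs_ncpr = use_abs_ncpr),
            class = "vshape_fit")
}

#' @export
print.vshape_fit <- function(x, ...) {
  cat(sprintf(
    "V-shape fit (%s): slope = %.4g +/- %.4g, p = %.4g (n = %d)\n",
    if (x$use_abs_ncpr) "|NCPR|" else "NCPR",
    x$slope, x$slope_se, x$p_value, x$n_points))
  invisible(x)
}

#' Aggregate StateResults over seeds for V-shape fitting
#'
#' One point per (sequence, state, salt): normalized Rg averaged over
#' seeds, SE across seeds (falling back to the mean block SE over Rc for
#' a single seed).
#'
#' @param results StateResult data frame.
#' @return Aggregated data frame with `normalized_rg`, `normalized_se`,
#'   `ncpr` columns.
#' @export
aggregate_states <- function(results) {
  key <- interaction(results$sequence, results$state, results$salt_mM,
                     drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- results[key == k, ]
    ns <- nrow(sub)
    rc <- sub$mean_rg[1] / sub$normalized_rg[1]
    data.frame(sequence = sub$sequence[1], state = sub$state[1],
               salt_mM = sub$salt_mM[1], n_seeds = ns,
               net_charge = sub$net_charge[1], ncpr = sub$ncpr[1],
               mean_rg = mean(sub$mean_rg),
               normalized_rg = mean(sub$normalized_rg),
               normalized_se = if (ns >= 2)
                 max(sd(sub$normalized_rg) / sqrt(ns), 1e-8)
               else mean(sub$se_rg) / rc)
  })
  do.call(rbind, rows)
}

#' Empirical type-I error of the weighted slope test
#'
#' Simulates the null (zero slope) with per-point Gaussian noise matching
#' the declared standard errors and reports the rejection rate of the
#' slope test at level `alpha`.
#'
#' @param n_points points per replicate.
#' @param n_reps replicates.
#' @param alpha test level.
#' @param seed integer RNG seed.
#' @return Rejection rate in `[0, 1]`.
#' @export
vshape_null_rejection_rate <- function(n_points = 8, n_reps = 1000,
                                       alpha = 0.05, seed = 1) {
  set.seed(seed)
  x <- seq(0, 0.3, length.out = n_points)
  se <- runif(n_points, 0.02, 0.08)
  rej <- 0L
  for (r in seq_len(n_reps)) {
    y <- 1 + rnorm(n_points, sd = se)
    f <- vshape_fit(data.frame(normalized_rg = y, ncpr = x,
                               normalized_se = se),
                    use_abs_ncpr = FALSE)
    if (f$p_value < alpha) rej <- rej + 1L
  }
  rej / n_reps
}

#' Write study reports
#'
#' Writes `results.csv` (StateResults), `fits.json` (V-shape fits) and a
#' plain-text `report.txt` summarizing net charges, phosphorylation
#' deltas, the salt trend and shielding directions.
#'
#' @param results StateResult data frame.
#' @param fits named list of `vshape_fit` objects (may be empty).
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, fits = list(), dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(results = file.path(dir, "results.csv"),
             fits = file.path(dir, "fits.json"),
             report = file.path(dir, "report.txt"))
  write.csv(results, paths["results"], row.names = FALSE)
  jsonlite::write_json(lapply(fits, unclass), paths["fits"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  con <- file(paths["report"], "w")
  on.exit(close(con))
  writeLines("Phosphorylation response study report", con)
  writeLines(strrep("=", 38), con)
  if (nrow(results) > 0) {
    writeLines("\nNet charges by state:", con)
    u <- unique(results[, c("sequence", "state", "n_active", "net_charge",
                            "ncpr")])
    for (i in seq_len(nrow(u)))
      writeLines(sprintf("  %-10s %-8s sites=%2d net=%+3d NCPR=%+.4f",
                         u$sequence[i], u$state[i], u$n_active[i],
                         u$net_charge[i], u$ncpr[i]), con)
    d <- state_deltas(results)
    if (!is.null(d)) {
      writeLines("\nPhosphorylation deltas (full - unphos), mean Rg [A]:",
                 con)
      for (i in seq_len(nrow(d)))
        writeLines(sprintf(
          "  %-10s %5g mM  dRg = %+7.2f +/- %.2f (%s)",
          d$sequence[i], d$salt_mM[i], d$delta[i], d$se[i],
          if (d$delta[i] < 0) "shrinks" else "expands"), con)
    }
  } else {
    writeLines("\n(no results)", con)
  }
  for (nm in names(fits)) {
    f <- fits[[nm]]
    writeLines(sprintf(
      "\nV-shape fit [%s] (%s): slope = %.4g +/- %.4g, p = %.4g",
      nm, if (f$use_abs_ncpr) "|NCPR|" else "NCPR", f$slope, f$slope_se,
      f$p_value), con)
  }
  writeLines("\nNote: per-fit p-values are reported without multiple-testing correction.",
             con)
  invisible(paths)
}
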
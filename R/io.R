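# Ensemble I/O: multi-model PDB (beads as CA atoms), compact XYZ text,
# and JSON provenance sidecars.

AA_3LETTER <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
                L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
AA_1LETTER <- setNames(names(AA_3LETTER), AA_3LETTER)

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL per frame, one CA atom per bead, residue identities
#' preserved.  A JSON provenance sidecar (`<file>.json`) records the
#' generating parameters and seed when the ensemble carries them.
#'
#' @param ensemble a `cg_ensemble`.
#' @param file output path.
#' @param sidecar write the provenance sidecar (default `TRUE`).
#' @export
write_ensemble_pdb <- function(ensemble, file, sidecar = TRUE) {
  res3 <- AA_3LETTER[ensemble$residues]
  res3[is.na(res3)] <- "GLY"
  con <- file(file, "w")
  on.exit(close(con))
  nb <- n_beads(ensemble)
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    conf <- get_frame(ensemble, f)
    lines <- sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nb), res3, seq_len(nb), conf[, 1], conf[, 2], conf[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (sidecar && length(ensemble$provenance) > 0)
    write_provenance(ensemble, paste0(file, ".json"))
  invisible(file)
}

#' Read a multi-model PDB ensemble
#'
#' @param file path to a multi-model PDB (CA atoms are used as beads).
#' @return A `cg_ensemble`.
#' @export
read_ensemble_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  ca <- bio3d::atom.select(pdb, "calpha")
  xyz <- pdb$xyz[, ca$xyz, drop = FALSE]
  nb <- length(ca$atom)
  nf <- nrow(xyz)
  coords <- array(0, dim = c(nf, nb, 3))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[f, , ] <- m
  }
  res1 <- unname(AA_1LETTER[pdb$atom$resid[ca$atom]])
  res1[is.na(res1)] <- "G"
  prov_file <- paste0(file, ".json")
  prov <- if (file.exists(prov_file))
    jsonlite::read_json(prov_file, simplifyVector = TRUE) else list()
  new_cg_ensemble(coords, residues = res1, provenance = prov)
}

#' Write / read an ensemble in whitespace XYZ-per-frame text format
#'
#' Standard XYZ blocks: bead count, a comment line, then one
#' `<residue> x y z` line per bead, repeated per frame.
#'
#' @param ensemble a `cg_ensemble`.
#' @param file path.
#' @export
write_ensemble_xyz <- function(ensemble, file) {
  con <- file(file, "w")
  on.exit(close(con))
  nb <- n_beads(ensemble)
  res <- if (is.null(ensemble$residues)) rep("G", nb) else ensemble$residues
  for (f in seq_len(n_frames(ensemble))) {
    conf <- get_frame(ensemble, f)
    writeLines(as.character(nb), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", res, conf[, 1], conf[, 2],
                       conf[, 3]), con)
  }
  invisible(file)
}

#' @rdname write_ensemble_xyz
#' @export
read_ensemble_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  res <- NULL
  i <- 1L
  while (i <= length(lines)) {
    nb <- as.integer(lines[i])
    block <- lines[(i + 2L):(i + 1L + nb)]
    parts <- strsplit(trimws(block), "\\s+")
    res <- vapply(parts, `[[`, character(1), 1L)
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + nb
  }
  nf <- length(frames)
  nb <- nrow(frames[[1]])
  coords <- array(0, dim = c(nf, nb, 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  new_cg_ensemble(coords, residues = res)
}

#' Write ensemble provenance (parameters + seed) as JSON
#'
#' @param ensemble a `cg_ensemble`.
#' @param file path.
#' @export
write_provenance <- function(ensemble, file) {
  jsonlite::write_json(ensemble$provenance, file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}
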
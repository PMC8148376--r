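# Phosphosite-annotated sequences and formal charge assignment.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a phosphosite-annotated amino-acid sequence
#'
#' Parses the annotated-string dialect in which a phosphosite is a
#' Ser/Thr/Tyr residue immediately followed by a marker character
#' (underscore by default), and leading/trailing `^NNN^` numbering tokens
#' give the residue numbering offset of the fragment.  Whitespace is
#' ignored.  Alternatively, an unannotated sequence can be combined with
#' an explicit vector of 1-based site positions (local to the fragment).
#'
#' @param text character scalar: the annotated (or plain) sequence.
#' @param sites optional integer vector of 1-based phosphosite positions,
#'   used when `text` carries no markers (FASTA-style input).
#' @param marker the annotation marker character.
#' @param offset first-residue number in the parent protein (overridden by
#'   a leading `^NNN^` token if present).
#' @param capped_termini logical; `TRUE` (default) models acetyl/amide
#'   capped chain ends, which carry no formal charge.
#' @param name optional identifier.
#' @return An object of class `annotated_sequence`: a list with elements
#'   `residues` (character vector of one-letter codes), `phospho_sites`
#'   (1-based local positions), `n_residues`, `offset`, `capped_termini`,
#'   and `name`.
#' @examples
#' s <- parse_annotated_sequence("GGS_KDG", name = "toy")
#' s$phospho_sites  # 3
#' @export
parse_annotated_sequence <- function(text, sites = NULL, marker = "_",
                                     offset = 1L, capped_termini = TRUE,
                                     name = NULL) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  text <- gsub("\\s", "", text)
  num_tok <- regmatches(text, regexpr("^\\^([0-9]+)\\^", text))
  if (length(num_tok) == 1L && nzchar(num_tok)) {
    offset <- as.integer(gsub("\\^", "", num_tok))
  }
  text <- gsub("\\^[0-9]+\\^", "", text)

  chars <- strsplit(text, "")[[1]]
  residues <- character(0)
  marked <- integer(0)
  for (ch in chars) {
    if (ch == marker) {
      if (length(residues) == 0L)
        stop("annotation marker with no preceding residue", call. = FALSE)
      marked <- c(marked, length(residues))
    } else {
      if (!ch %in% AA_ALPHABET)
        stop("unknown residue letter: ", ch, call. = FALSE)
      residues <- c(residues, ch)
    }
  }
  n <- length(residues)
  if (n == 0L) stop("empty sequence", call. = FALSE)

  if (!is.null(sites)) {
    if (length(marked) > 0L)
      stop("give phosphosites either as markers or as a position list, not both",
           call. = FALSE)
    marked <- as.integer(sites)
  }
  if (any(marked < 1L | marked > n))
    stop("phosphosite position out of range [1, ", n, "]", call. = FALSE)
  bad <- marked[!residues[marked] %in% c("S", "T", "Y")]
  if (length(bad) > 0L)
    stop("phosphosite at non-S/T/Y residue (position ", bad[1L], ": ",
         residues[bad[1L]], ")", call. = FALSE)

  structure(list(residues = residues,
                 phospho_sites = sort(unique(marked)),
                 n_residues = n,
                 offset = as.integer(offset),
                 capped_termini = isTRUE(capped_termini),
                 name = name),
            class = "annotated_sequence")
}

#' Read a sequence from FASTA plus a phosphosite list file
#'
#' @param fasta path to a single-record FASTA file.
#' @param sites_file optional path to a text file with one 1-based local
#'   phosphosite position per line.
#' @inheritParams parse_annotated_sequence
#' @return An `annotated_sequence`.
#' @export
read_annotated_fasta <- function(fasta, sites_file = NULL, offset = 1L,
                                 capped_termini = TRUE) {
  fa <- bio3d::read.fasta(fasta)
  seq_chars <- as.character(fa$ali[1L, ])
  seq_chars <- seq_chars[seq_chars != "-"]
  sites <- NULL
  if (!is.null(sites_file)) {
    sites <- as.integer(scan(sites_file, what = integer(), quiet = TRUE,
                             comment.char = "#"))
  }
  parse_annotated_sequence(paste(seq_chars, collapse = ""), sites = sites,
                           offset = offset, capped_termini = capped_termini,
                           name = rownames(fa$ali)[1L])
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat("Annotated sequence", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "\n  ", x$n_residues, " residues (", x$offset, "-",
      x$offset + x$n_residues - 1L, "), ",
      length(x$phospho_sites), " phosphosites\n", sep = "")
  invisible(x)
}

#' Formal charge model for IDP sequences
#'
#' Fixed formal charges at pH ~7.5: Asp/Glu -1, Lys/Arg +1, His neutral by
#' default.  Phosphosites carry `phosphate_charge` (-2 bis-deprotonated,
#' -1 mono-protonated).  In phosphomimetic mode active sites are rewritten
#' to Glu with charge -1 instead.  Capped termini contribute no charge;
#' the free-termini mode adds +1/-1 at the chain ends.
#'
#' @param phosphate_charge -2 (default) or -1.
#' @param phosphomimetic logical; mutually exclusive with a -2/-1
#'   phosphate (sites become E, charge -1).
#' @param histidine_charge formal charge for His (default 0).
#' @param free_termini logical; add +1 (N-term) and -1 (C-term) when the
#'   sequence is not capped.
#' @return An object of class `charge_model`.
#' @export
charge_model <- function(phosphate_charge = -2, phosphomimetic = FALSE,
                         histidine_charge = 0, free_termini = FALSE) {
  if (!phosphate_charge %in% c(-1, -2))
    stop("phosphate_charge must be -1 or -2", call. = FALSE)
  structure(list(phosphate_charge = phosphate_charge,
                 phosphomimetic = isTRUE(phosphomimetic),
                 histidine_charge = histidine_charge,
                 free_termini = isTRUE(free_termini)),
            class = "charge_model")
}

#' Assign per-residue formal charges
#'
#' @param seq an `annotated_sequence`.
#' @param model a [charge_model()].
#' @param active_sites subset of `seq$phospho_sites` (1-based local
#'   positions) carrying a phosphate; defaults to all annotated sites.
#'   Use `integer(0)` for the unphosphorylated state.
#' @return A `charge_vector`: numeric vector of per-residue charges with
#'   attributes `residues` (post-modification identities) and
#'   `active_sites`.
#' @examples
#' ash1 <- idp_fragments()$Ash1
#' net_charge(assign_charges(ash1, charge_model(), integer(0)))  # +15
#' @export
assign_charges <- function(seq, model = charge_model(),
                           active_sites = seq$phospho_sites) {
  stopifnot(inherits(seq, "annotated_sequence"),
            inherits(model, "charge_model"))
  active_sites <- as.integer(active_sites)
  if (!all(active_sites %in% seq$phospho_sites))
    stop("active site not among annotated phosphosites", call. = FALSE)

  res <- seq$residues
  q <- numeric(seq$n_residues)
  q[res %in% c("D", "E")] <- -1
  q[res %in% c("K", "R")] <- 1
  q[res == "H"] <- model$histidine_charge
  if (model$phosphomimetic) {
    res[active_sites] <- "E"
    q[active_sites] <- -1
  } else {
    q[active_sites] <- q[active_sites] + model$phosphate_charge
  }
  if (model$free_termini && !seq$capped_termini) {
    q[1L] <- q[1L] + 1
    q[seq$n_residues] <- q[seq$n_residues] - 1
  }
  structure(q, residues = res, active_sites = active_sites,
            class = "charge_vector")
}

#' Net formal charge of a charge vector
#' @param cv a `charge_vector` (any numeric vector works).
#' @return Signed total charge in elementary-charge units.
#' @export
net_charge <- function(cv) sum(unclass(cv))

#' Net charge per residue (NCPR)
#' @inheritParams net_charge
#' @export
ncpr <- function(cv) {
  stopifnot(length(cv) >= 1L)
  sum(unclass(cv)) / length(cv)
}

#' Fraction of charged residues
#'
#' Counts residues carrying any nonzero formal charge (a -2 phosphosite
#' counts once) over the chain length.
#' @inheritParams net_charge
#' @export
charged_fraction <- function(cv) mean(unclass(cv) != 0)

#' Sequence Coulomb potential and force descriptors
#'
#' Dimensionless pairwise descriptors over sequence separation:
#' potential `sum_{i<j} Q_i Q_j / |j - i|` and force
#' `sum_{i<j} Q_i Q_j / |j - i|^2`.
#'
#' @inheritParams net_charge
#' @return Named numeric vector `c(potential = , force = )`.
#' @export
coulomb_descriptors <- function(cv) {
  q <- unclass(cv)
  n <- length(q)
  stopifnot(n >= 2L)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  qq <- outer(q, q)
  upper <- upper.tri(sep)
  c(potential = sum(qq[upper] / sep[upper]),
    force = sum(qq[upper] / sep[upper]^2))
}

#' Descriptor table for a set of sequence states
#'
#' @param seq an `annotated_sequence`.
#' @param states named list mapping a state label to the integer vector of
#'   active phosphosites for that state.
#' @param model a [charge_model()].
#' @return A data frame with one row per state: net charge, NCPR, charged
#'   fraction, and the sequence Coulomb potential/force descriptors.
#' @export
sequence_descriptors <- function(seq, states = default_states(seq),
                                 model = charge_model()) {
  rows <- lapply(names(states), function(st) {
    cv <- assign_charges(seq, model, states[[st]])
    cd <- coulomb_descriptors(cv)
    data.frame(name = if (is.null(seq$name)) NA_character_ else seq$name,
               state = st,
               n_residues = seq$n_residues,
               n_active_sites = length(states[[st]]),
               net_charge = net_charge(cv),
               ncpr = ncpr(cv),
               charged_fraction = charged_fraction(cv),
               coulomb_potential = unname(cd["potential"]),
               coulomb_force = unname(cd["force"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default phosphorylation states of a sequence
#'
#' `unphos` (no active sites) and `full` (all annotated sites); a
#' `partial` state with the two most biologically relevant sites is added
#' when the sequence carries a `relevant_sites` attribute (as the bundled
#' fragments do).
#'
#' @param seq an `annotated_sequence`.
#' @return Named list of active-site vectors.
#' @export
default_states <- function(seq) {
  states <- list(unphos = integer(0))
  rel <- attr(seq, "relevant_sites")
  if (!is.null(rel)) states$partial <- as.integer(rel)
  states$full <- seq$phospho_sites
  states
}
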
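# The four IDP fragments of the study, as phosphosite-annotated strings.
#
# Ash1 (P34233, 420-500): 10 Ser/Thr phosphosites, net charge +15 -> -5.
# CTD2' (AAA28868.1, 1659-1741): RNA polymerase II C-terminal domain
#   repeats, 10 Ser phosphosites, net charge 0 -> -20.
# E-Cadherin cytosolic domain (P12830, 735-800): 8 phosphosites including
#   the adjacent tyrosines Y753/Y754/Y755 of the p120-binding
#   juxtamembrane region, net charge -9 -> -25.
# p130Cas substrate/Src-binding fragment (P56945, 631-696): 6 phosphosites
#   including Y664/Y666 of the Src SH2-binding EDYDYVHL motif, net charge
#   -4 -> -16.  Note the Src SH3-binding RPLPSPP motif near the N-terminus.

.IDP_STRINGS <- list(
  Ash1 = paste0(
    "^420^SASSS_PS_PST_PTKSGKMRSRSSS_PVRPKAYT_PS_PRS_PNYHRFALDS_PPQS_",
    "PRRSSNSSITKKGSRRSSGSS_PTRHTTRVCV^500^"),
  CTD2p = paste0(
    "^1659^FAGSGSNIYSPGNAYS_PSSSNYS_PNSPSYS_PTSPSYS_PSSPS_YSPTS_PCYSPTS_",
    "PSYSPTS_PNYTPVTPS_YSPTS_PNYSASPQ^1741^"),
  ECadherin = paste0(
    "^735^AVVKEPLLPPEDDT_RDNVY_Y_Y_DEEGGGEEDQDFDLS_QLHRGLDARPEVTRNDVAPT_",
    "LMS_VPRY_LPR^800^"),
  p130Cas = paste0(
    "^631^SIQSRPLPS_PPKFTSQDS_PDGQY_ENSEGGWMEDY_DY_VHLQGKEEFEKTQKELLEKGS",
    "ITRQGKS_QL^696^")
)

# Local (1-based) positions of the two most biologically relevant
# phosphosites and the 10-residue binding-site window containing them.
.RELEVANT_SITES <- list(
  ECadherin = c(19L, 20L),   # Y753, Y754 (p120-binding region)
  p130Cas = c(34L, 36L)      # Y664, Y666 (Src SH2 site)
)
.BINDING_WINDOWS <- list(
  ECadherin = 15:24,
  p130Cas = 30:39
)

#' The four IDP fragments of the study
#'
#' Phosphosite-annotated ~66-83 residue fragments of Ash1 (420-500),
#' the RNA polymerase II CTD2' repeat region (1659-1741), the E-Cadherin
#' cytosolic domain (735-800) and p130Cas (631-696), with acetyl/amide
#' capped termini.  E-Cadherin and p130Cas additionally carry
#' `relevant_sites` (the two most biologically relevant phosphosites) and
#' `binding_site` (a 10-residue interaction-site window containing them)
#' attributes.
#'
#' @return Named list of `annotated_sequence` objects:
#'   `Ash1`, `CTD2p`, `ECadherin`, `p130Cas`.
#' @examples
#' sapply(idp_fragments(), function(s) length(s$phospho_sites))
#' @export
idp_fragments <- function() {
  out <- lapply(names(.IDP_STRINGS), function(nm) {
    s <- parse_annotated_sequence(.IDP_STRINGS[[nm]], name = nm)
    if (!is.null(.RELEVANT_SITES[[nm]])) {
      attr(s, "relevant_sites") <- .RELEVANT_SITES[[nm]]
      attr(s, "binding_site") <- .BINDING_WINDOWS[[nm]]
    }
    s
  })
  names(out) <- names(.IDP_STRINGS)
  out
}
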
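#!/usr/bin/env Rscript

# Sequence charge descriptors of the four IDP fragments.
#
# For each fragment and each phosphorylation state (unphosphorylated,
# the two biologically relevant sites where annotated, fully
# phosphorylated) this computes net charge, net charge per residue
# (NCPR), charged fraction, and the sequence Coulomb potential/force
# descriptors.  The net charges of the unphosphorylated and fully
# phosphorylated states are the table the rest of the study builds on:
# Ash1 +15/-5, CTD2' 0/-20, E-Cadherin -9/-25, p130Cas -4/-16.

library(phosflex)

dir.create("results", showWarnings = FALSE)

tab <- do.call(rbind, lapply(idp_fragments(), sequence_descriptors))
rownames(tab) <- NULL
write.csv(tab, "results/descriptors.csv", row.names = FALSE)

cat("Charge descriptors (phosphate charge -2, capped termini):\n\n")
print(tab, digits = 3)

cat("\nMono-protonated phosphate (-1) net charges, fully phosphorylated:\n")
for (s in idp_fragments())
  cat(sprintf("  %-10s %+d\n", s$name,
              net_charge(assign_charges(s, charge_model(-1)))))
cat("\nWrote results/descriptors.csv\n")
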
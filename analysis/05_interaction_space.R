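#!/usr/bin/env Rscript
# Stage 5 -- accessible-interaction-space scan under cumulative restraints.
#
# On the two-lobe toy geometry (a receptor wall with an off-wall
# degron anchor), counts clash-free rigid ligand placements as crosslink
# restraints and finally the degron-tail restraint are applied. Finding:
# the accessible-complex curve is non-linear in the number of restraints
# and shows its sharpest relative drop when the degron-tail restraint is
# added last -- the tail restraint, not the crosslinks alone, pins the
# ligand to one lobe. The scan is verified against the brute-force census.

suppressPackageStartupMessages(library(coreceptor))
dir.create("results", showWarnings = FALSE)

t <- gen_toy_structures(500, "two_lobe")
sc <- scan_interaction_space(t$receptor, t$ligand, t$restraints,
                             t$params$grid_spacing, t$params$n_rotations,
                             t$params$clash_dist)
cat("scan counts vs brute-force census identical:",
    all(as.numeric(sc$counts) == as.numeric(unlist(t$truth$census))), "\n")

dc <- restraint_drop_curve(t$receptor, t$ligand, t$restraints,
                           t$params$grid_spacing, t$params$n_rotations,
                           t$params$clash_dist)
dc$relative_drop <- c(NA, round(1 - dc$accessible[-1] /
                                dc$accessible[-nrow(dc)], 4))
utils::write.table(dc, "results/05_drop_curve.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
print(dc, row.names = FALSE)
cat(sprintf("sharpest relative drop at the %s restraint step\n",
            dc$source[which.max(dc$relative_drop)]))

# interface residues from placements consistent with all restraints
pr <- interaction_propensity(t$receptor, t$ligand, t$restraints,
                             contact_dist = 5,
                             grid_spacing = t$params$grid_spacing,
                             n_rotations = t$params$n_rotations,
                             clash_dist = t$params$clash_dist)
utils::write.table(pr$propensity, "results/05_propensity.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat(sprintf("%d placements satisfy all restraints; %d active residues (propensity > 1): %s\n",
            pr$n_consistent, nrow(pr$active),
            paste(pr$active$residue, collapse = ", ")))
cat("wrote results/05_drop_curve.tsv, 05_propensity.tsv\n")
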
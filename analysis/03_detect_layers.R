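#!/usr/bin/env Rscript
# Planted beta-layer fixtures through the two-step detector, with
# register assignment and ground-truth comparison; fixture coordinates
# and annotations are written for inspection.
#
# Finding: all planted layers (nonad, hexad, tandem-hexad) are recovered
# with exact central residues; registers read a-b-c-b1-b2-b3-e-f-g for
# nonads and e-f-g/c-b1-b2-b3-e-f-g for hexads; the tandem layers carry
# the C-capping (K in beta1) and N-capping (V in beta1) networks.

library(betalayer)

dir.create("results", showWarnings = FALSE)

axis <- bundle_axis_line(c(0, 0, 0), c(0, 0, 1))
reports <- list()
for (sp in c("nonad", "hexad", "tandem-hexad")) {
  model <- generate_beta_layer_fixture(sp)
  ann <- attr(model, "annotation")
  write_fixture(model, file.path("results", sprintf("fixture_%s.pdb", sp)))
  layers <- detect_beta_layers(model)
  rep_tab <- layer_report(layers)
  rep_tab$spacing <- sp
  found <- sort(unlist(lapply(layers, function(l) l$strands$beta2_resno)))
  planted <- sort(rep(unique(ann$layers$beta2_resno), 3))
  rep_tab$exact_match <- length(found) == length(planted) &&
    all(found == planted)
  reports[[sp]] <- rep_tab

  trace <- periodicity_trace(model$chains[[1]], axis)
  reg <- assign_register(trace, layers)
  s <- min(ann$layers$beta1_resno)
  e <- max(ann$layers$beta3_resno)
  cat(sprintf("%-13s %d layer(s); register: %s\n", sp, length(layers),
              paste(reg[(s - 3):(e + 3)], collapse = "-")))
}
tab <- do.call(rbind, reports)
rownames(tab) <- NULL
write.table(tab, "results/detected_layers.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab)

# negative control: a pure-alpha heptad trimer
coil <- generate_crick_coil(crick_params(n_chains = 3), 28)
cat(sprintf("\nnegative control (heptad trimer): %d layers\n",
            length(detect_beta_layers(coil))))
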
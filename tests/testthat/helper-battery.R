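# Shared fixtures: built once per test run and cached. The battery spans
# the three spacings, several flanking-helix lengths, radius offsets and
# sequence motifs -- 20 deterministic planted-layer geometries in all.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- builder()
  .test_cache[[key]]
}

base_fixture <- function(spacing) {
  cached(paste0("fix_", spacing),
         function() generate_beta_layer_fixture(spacing))
}

battery_configs <- function() {
  cfg <- list()
  for (sp in c("nonad", "hexad", "tandem-hexad")) {
    for (nh in c(10, 12, 14, 16)) {
      cfg[[length(cfg) + 1]] <- list(spacing = sp, helix_len = nh,
                                     radius = "auto", motif = NULL)
    }
  }
  for (sp in c("nonad", "hexad")) {
    for (off in c(-0.15, 0.15)) {
      cfg[[length(cfg) + 1]] <- list(spacing = sp, helix_len = 14,
                                     radius_offset = off, motif = NULL)
    }
  }
  cfg[[length(cfg) + 1]] <- list(spacing = "nonad", helix_len = 13,
                                 radius = "auto", motif = "IENKADKAD")
  cfg[[length(cfg) + 1]] <- list(spacing = "hexad", helix_len = 13,
                                 radius = "auto", motif = NULL)
  cfg[[length(cfg) + 1]] <- list(spacing = "nonad", helix_len = 11,
                                 radius = "auto", motif = NULL)
  cfg[[length(cfg) + 1]] <- list(spacing = "hexad", helix_len = 11,
                                 radius = "auto", motif = NULL)
  cfg
}

build_battery <- function() {
  cached("battery", function() {
    lapply(battery_configs(), function(cf) {
      radius <- if (!is.null(cf$radius_offset)) {
        ann <- attr(base_fixture(cf$spacing), "annotation")
        ann$bundle_radius + cf$radius_offset
      } else "auto"
      generate_beta_layer_fixture(cf$spacing, sequence_motif = cf$motif,
                                  bundle_radius = radius,
                                  helix_len = cf$helix_len)
    })
  })
}

# TRUE when detection recovers exactly the planted central residues
battery_exact <- function(model) {
  ann <- attr(model, "annotation")
  layers <- detect_beta_layers(model)
  planted <- sort(rep(unique(ann$layers$beta2_resno), 3))
  found <- sort(unlist(lapply(layers, function(ly) ly$strands$beta2_resno)))
  length(found) == length(planted) && all(found == planted)
}

# synthetic torsion_series from a run of classes, for window-scan tests
class_run_series <- function(classes, chain_id = "A") {
  n <- length(classes)
  out <- data.frame(resno = seq_len(n), icode = "", aa = "A",
                    phi = -90, psi = -30, ss = classes,
                    segment = 1L, stringsAsFactors = FALSE)
  attr(out, "chain_id") <- chain_id
  class(out) <- c("torsion_series", class(out))
  out
}
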
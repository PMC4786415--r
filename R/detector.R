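# The two-step beta-layer search: seven-residue sliding-window torsion
# patterns (bbbaaaa / aaaabbb) propose three-residue strand candidates,
# then cross-strand backbone hydrogen bonds between the central residues
# within the (assembly-expanded) model group candidates into layers.

WINDOW_PATTERNS <- list(bbbaaaa = c("beta", "beta", "beta",
                                    "alpha", "alpha", "alpha", "alpha"),
                        aaaabbb = c("alpha", "alpha", "alpha", "alpha",
                                    "beta", "beta", "beta"))

#' Scan torsion classes for beta-layer strand candidates
#'
#' Slides the two seven-residue patterns bbbaaaa and aaaabbb over the
#' per-residue alpha/beta classes of each chain (within continuous
#' segments; windows are not matched across chain breaks or termini).
#' Every match yields the candidate strand formed by its beta triplet;
#' a triplet matched by both patterns is reported once, with both
#' pattern names recorded.
#'
#' @param torsions A `torsion_series` (from [compute_torsions]) or a list
#'   of them (one per chain).
#' @return Data frame with one row per candidate strand: `chain`,
#'   `beta1_resno`, `beta2_resno`, `beta3_resno`, `beta1_idx` (row index
#'   of beta1 in its chain), `sequence`, `patterns` (comma-joined).
#' @export
scan_windows <- function(torsions) {
  if (inherits(torsions, "torsion_series")) torsions <- list(torsions)
  rows <- list()
  for (tt in torsions) {
    cid <- attr(tt, "chain_id")
    n <- nrow(tt)
    if (n < 7) next
    hits <- list() # keyed by beta1 row index
    for (start in seq_len(n - 6)) {
      idx <- start:(start + 6)
      if (length(unique(tt$segment[idx])) != 1 || anyNA(tt$segment[idx])) next
      cls <- tt$ss[idx]
      for (pname in names(WINDOW_PATTERNS)) {
        if (!all(cls == WINDOW_PATTERNS[[pname]])) next
        b1 <- if (pname == "bbbaaaa") start else start + 4
        key <- as.character(b1)
        hits[[key]] <- union(hits[[key]], pname)
      }
    }
    for (key in names(hits)) {
      b1 <- as.integer(key)
      rows[[length(rows) + 1]] <- data.frame(
        chain = cid, beta1_resno = tt$resno[b1],
        beta2_resno = tt$resno[b1 + 1], beta3_resno = tt$resno[b1 + 2],
        beta1_idx = b1,
        sequence = paste(tt$aa[b1:(b1 + 2)], collapse = ""),
        patterns = paste(sort(hits[[key]]), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chain = character(0), beta1_resno = integer(0),
                      beta2_resno = integer(0), beta3_resno = integer(0),
                      beta1_idx = integer(0), sequence = character(0),
                      patterns = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$chain, out$beta1_resno), , drop = FALSE]
}

#' Group strand candidates into beta-layers by central-residue H-bonds
#'
#' Builds a graph over candidate strands with an edge wherever the
#' central (beta2) residues of two strands share a backbone N-O contact
#' at or below `cutoff`; connected components with at least two strands
#' become layers. Strands of the same chain may pair (the pseudo-threefold
#' monomer case).
#'
#' @param candidates Output of [scan_windows] on the same model.
#' @param model The [structure_model] the candidates were derived from.
#' @param cutoff N-O distance cutoff in Angstrom (default 3.5).
#' @param strict_trimer If `TRUE`, only canonical three-strand layers are
#'   returned.
#' @return List of `beta_layer` objects: each a list with `strands` (rows
#'   of `candidates`), `n_strands`, `canonical` (exactly 3 strands),
#'   `hbonds` (contact table), `capping` and `transition` (filled by
#'   [classify_capping] / [annotate_transition] via
#'   [detect_beta_layers]).
#' @export
pair_strands <- function(candidates, model, cutoff = HBOND_CUTOFF,
                         strict_trimer = FALSE) {
  m <- nrow(candidates)
  if (m == 0) return(list())
  # adjacency via central-residue backbone H-bonds
  adj <- matrix(FALSE, m, m)
  hb_all <- vector("list", m * (m - 1) / 2)
  hi <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ci <- model$chains[[candidates$chain[i]]]
      cj <- model$chains[[candidates$chain[j]]]
      ri <- candidates$beta1_idx[i] + 1L
      rj <- candidates$beta1_idx[j] + 1L
      hb <- backbone_hbonds(ci, ri, cj, rj, cutoff = cutoff)
      if (nrow(hb)) {
        adj[i, j] <- adj[j, i] <- TRUE
        hi <- hi + 1
        hb_all[[hi]] <- hb
      }
    }
  }
  # connected components (union-find)
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (adj[i, j]) parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(m), find, integer(1))
  layers <- list()
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) < 2) next
    if (strict_trimer && length(members) != 3) next
    strands <- candidates[members, , drop = FALSE]
    strands <- strands[order(strands$chain, strands$beta1_resno), ,
                       drop = FALSE]
    hb <- do.call(rbind, Filter(Negate(is.null), hb_all[seq_len(hi)]))
    layers[[length(layers) + 1]] <- structure(
      list(strands = strands, n_strands = length(members),
           canonical = length(members) == 3, hbonds = hb,
           capping = NA_character_, transition = NA_character_),
      class = "beta_layer")
  }
  # deterministic report order: by first chain, then first residue
  if (length(layers) > 1) {
    key <- vapply(layers, function(ly) sprintf(
      "%s_%06d", ly$strands$chain[1], ly$strands$beta1_resno[1]),
      character(1))
    layers <- layers[order(key)]
  }
  layers
}

#' Classify the capping network of a beta-layer
#'
#' The interaction network of a layer inside or at the end of a coiled
#' coil is determined by the beta1 residue: lysine reaches across the
#' trimer core and C-caps the preceding helices, while a hydrophobic
#' beta1 leaves the network that N-caps the following helices.
#'
#' @param layer A `beta_layer`.
#' @return The layer with `capping` set to `"C-cap"` (beta1 = K),
#'   `"N-cap"` (beta1 in A, V, L, I, M, F) or `"unclassified"`.
#' @export
classify_capping <- function(layer) {
  b1 <- substr(layer$strands$sequence, 1, 1)
  lab <- ifelse(b1 == "K", "C-cap",
                ifelse(b1 %in% c("A", "V", "L", "I", "M", "F"),
                       "N-cap", "unclassified"))
  u <- unique(lab)
  layer$capping <- if (length(u) == 1) u else "mixed"
  layer
}

#' Annotate the secondary-structure transition type of a layer
#'
#' Labels a layer by the classes flanking its strand: at least four
#' alpha residues on both sides is a coiled-coil-internal layer
#' (`cc-to-cc`); alpha upstream with beta downstream is `cc-to-beta` and
#' the reverse `beta-to-cc`; fewer than four residues upstream of beta1
#' in the chain is `Nterm-to-cc`; anything else `other`.
#'
#' @param layer A `beta_layer`.
#' @param torsions The `torsion_series` (or list) used for detection.
#' @return The layer with `transition` set.
#' @export
annotate_transition <- function(layer, torsions) {
  if (inherits(torsions, "torsion_series")) torsions <- list(torsions)
  names(torsions) <- vapply(torsions, attr, character(1), "chain_id")
  s <- layer$strands[1, ]
  tt <- torsions[[s$chain]]
  b1 <- s$beta1_idx
  b3 <- b1 + 2L
  up <- if (b1 > 1) tt$ss[max(1, b1 - 4):(b1 - 1)] else character(0)
  dn <- if (b3 < nrow(tt)) tt$ss[(b3 + 1):min(nrow(tt), b3 + 4)] else character(0)
  up_a <- length(up) == 4 && all(up == "alpha")
  dn_a <- length(dn) == 4 && all(dn == "alpha")
  up_b <- length(up) > 0 && up[length(up)] == "beta"
  dn_b <- length(dn) > 0 && dn[1] == "beta"
  layer$transition <-
    if (up_a && dn_a) "cc-to-cc"
    else if (up_a && dn_b) "cc-to-beta"
    else if (up_b && dn_a) "beta-to-cc"
    else if (b1 <= 4 && dn_a) "Nterm-to-cc"
    else if (up_a && length(dn) < 4) "cc-to-coil"
    else "other"
  layer
}

#' Detect beta-layers in a structure model
#'
#' The full two-step search: per-chain torsion classification, sliding
#' seven-residue window scan, central-residue hydrogen-bond pairing, then
#' capping and transition annotation. Deterministic for a fixed input;
#' layers are reported in order of (chain, first residue).
#'
#' @param model A [structure_model] with backbone-complete chains
#'   (assembly-expanded if the deposit stores one chain of a trimer).
#' @param cutoff N-O distance cutoff in Angstrom (default 3.5).
#' @param strict_trimer Restrict to canonical three-strand layers.
#' @return List of annotated `beta_layer` objects.
#' @export
detect_beta_layers <- function(model, cutoff = HBOND_CUTOFF,
                               strict_trimer = FALSE) {
  torsions <- lapply(model$chains, compute_torsions)
  candidates <- scan_windows(torsions)
  layers <- pair_strands(candidates, model, cutoff = cutoff,
                         strict_trimer = strict_trimer)
  lapply(layers, function(ly) {
    annotate_transition(classify_capping(ly), torsions)
  })
}

#' @export
print.beta_layer <- function(x, ...) {
  cat(sprintf(
    "<beta_layer: %d strand(s)%s, capping %s, transition %s>\n",
    x$n_strands, if (x$canonical) " (canonical)" else "",
    x$capping, x$transition))
  for (i in seq_len(nrow(x$strands))) {
    s <- x$strands[i, ]
    cat(sprintf("  %s %d-%d %s\n", s$chain, s$beta1_resno, s$beta3_resno,
                s$sequence))
  }
  invisible(x)
}

#' Tabular report of detected beta-layers
#'
#' @param layers List of `beta_layer` objects.
#' @return Data frame with one row per layer: id, chains, residue ranges
#'   (author numbering), strand sequence, size, flags and annotations.
#' @export
layer_report <- function(layers) {
  if (!length(layers)) {
    return(data.frame(layer = integer(0), chains = character(0),
                      beta_residues = character(0), sequence = character(0),
                      n_strands = integer(0), canonical = logical(0),
                      capping = character(0), transition = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(layers), function(i) {
    ly <- layers[[i]]
    data.frame(
      layer = i,
      chains = paste(ly$strands$chain, collapse = ","),
      beta_residues = paste(sprintf("%d-%d", ly$strands$beta1_resno,
                                    ly$strands$beta3_resno), collapse = ","),
      sequence = ly$strands$sequence[1],
      n_strands = ly$n_strands, canonical = ly$canonical,
      capping = ly$capping, transition = ly$transition,
      stringsAsFactors = FALSE)
  }))
}
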
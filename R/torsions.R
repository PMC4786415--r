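# Backbone dihedrals, Ramachandran-box classification and backbone
# hydrogen-bond geometry.
#
# The two torsion boxes used throughout the beta-layer search are:
#   alpha:  -70 <= psi <= -10  and  -180 <= phi <= -40
#   beta:    20 <= psi <= 180  and  -180 <= phi <= -40
# with inclusive boundaries. The boxes are disjoint in psi, so no residue
# is both alpha and beta.

ALPHA_BOX <- list(phi = c(-180, -40), psi = c(-70, -10))
BETA_BOX  <- list(phi = c(-180, -40), psi = c(20, 180))

# default backbone N-O hydrogen-bond distance cutoff (Angstrom)
HBOND_CUTOFF <- 3.5

#' Classify (phi, psi) pairs into alpha/beta Ramachandran boxes
#'
#' @param phi,psi Numeric vectors of torsions in degrees; `NA` allowed.
#' @return Character vector with entries `"alpha"`, `"beta"`, `"other"` or
#'   `"undefined"` (for `NA` input). Boundaries are inclusive.
#' @export
classify_ss <- function(phi, psi) {
  out <- rep("other", length(phi))
  out[is.na(phi) | is.na(psi)] <- "undefined"
  ok <- out != "undefined"
  in_phi <- ok & phi >= ALPHA_BOX$phi[1] & phi <= ALPHA_BOX$phi[2]
  out[in_phi & psi >= ALPHA_BOX$psi[1] & psi <= ALPHA_BOX$psi[2]] <- "alpha"
  out[in_phi & psi >= BETA_BOX$psi[1] & psi <= BETA_BOX$psi[2]] <- "beta"
  out
}

#' Backbone torsions and secondary-structure class of a chain
#'
#' Computes phi(i) from C(i-1)-N(i)-CA(i)-C(i) and psi(i) from
#' N(i)-CA(i)-C(i)-N(i+1) within each continuous segment of complete
#' residues; torsions are never computed across chain breaks or through
#' incomplete residues. Each residue is then classified into the alpha or
#' beta Ramachandran box (see [classify_ss]).
#'
#' @param chain A [backbone_chain].
#' @return A data frame of class `torsion_series` with columns `resno`,
#'   `icode`, `aa`, `phi`, `psi`, `ss` and `segment` (index of the
#'   continuous segment, `NA` for incomplete residues); attribute
#'   `chain_id` carries the chain identifier.
#' @export
compute_torsions <- function(chain) {
  n <- nrow(chain$res)
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  segment <- rep(NA_integer_, n)
  segs <- chain_segments(chain)
  for (k in seq_along(segs)) {
    idx <- segs[[k]]
    segment[idx] <- k
    for (i in idx) {
      if (i > idx[1]) {
        phi[i] <- dihedral(chain$C[i - 1, ], chain$N[i, ],
                           chain$CA[i, ], chain$C[i, ])
      }
      if (i < idx[length(idx)]) {
        psi[i] <- dihedral(chain$N[i, ], chain$CA[i, ],
                           chain$C[i, ], chain$N[i + 1, ])
      }
    }
  }
  out <- data.frame(resno = chain$res$resno, icode = chain$res$icode,
                    aa = chain$res$aa, phi = phi, psi = psi,
                    ss = classify_ss(phi, psi), segment = segment,
                    stringsAsFactors = FALSE)
  attr(out, "chain_id") <- chain$chain_id
  class(out) <- c("torsion_series", class(out))
  out
}

#' Backbone hydrogen-bond contacts between two residues
#'
#' Tests both directions, N(i)-O(j) and N(j)-O(i), against a plain
#' heavy-atom distance criterion (no angular term): a contact is recorded
#' when the amide N to carbonyl O distance is at or below `cutoff`.
#'
#' @param chain_i,chain_j [backbone_chain] objects (may be identical).
#' @param i,j Residue indices (row positions) within the two chains.
#' @param cutoff N-O distance cutoff in Angstrom (default 3.5, inclusive).
#' @return Data frame with one row per contact: `donor_chain`,
#'   `donor_resno`, `acceptor_chain`, `acceptor_resno`, `n_o_distance`.
#'   Zero rows (with a warning) when either residue lacks the atoms.
#' @export
backbone_hbonds <- function(chain_i, i, chain_j, j, cutoff = HBOND_CUTOFF) {
  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      n_o_distance = numeric(0), stringsAsFactors = FALSE)
  Ni <- chain_i$N[i, ]; Oi <- chain_i$O[i, ]
  Nj <- chain_j$N[j, ]; Oj <- chain_j$O[j, ]
  if (anyNA(c(Ni, Oi, Nj, Oj))) {
    warning("missing backbone atoms; no hydrogen bonds evaluated")
    return(empty)
  }
  rows <- list()
  d1 <- sqrt(sum((Ni - Oj)^2))
  if (d1 <= cutoff) {
    rows[[1]] <- data.frame(donor_chain = chain_i$chain_id,
                            donor_resno = chain_i$res$resno[i],
                            acceptor_chain = chain_j$chain_id,
                            acceptor_resno = chain_j$res$resno[j],
                            n_o_distance = d1, stringsAsFactors = FALSE)
  }
  d2 <- sqrt(sum((Nj - Oi)^2))
  if (d2 <= cutoff) {
    rows[[length(rows) + 1]] <-
      data.frame(donor_chain = chain_j$chain_id,
                 donor_resno = chain_j$res$resno[j],
                 acceptor_chain = chain_i$chain_id,
                 acceptor_resno = chain_i$res$resno[i],
                 n_o_distance = d2, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Per-residue torsion table for a whole model
#'
#' Convenience wrapper running [compute_torsions] on every chain and
#' binding the results into one table suitable for TSV export.
#'
#' @param model A [structure_model].
#' @return Data frame with columns `chain`, `resno`, `icode`, `aa`, `phi`,
#'   `psi`, `ss`.
#' @export
torsion_table <- function(model) {
  out <- lapply(model$chains, function(ch) {
    tt <- compute_torsions(ch)
    cbind(data.frame(chain = ch$chain_id, stringsAsFactors = FALSE),
          tt[, c("resno", "icode", "aa", "phi", "psi", "ss")])
  })
  rownames(res <- do.call(rbind, out)) <- NULL
  res
}
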
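# Core containers: backbone_chain (ordered N/CA/C/O coordinates with
# residue identity) and structure_model (a named set of chains).

#' Construct a backbone chain
#'
#' The substrate of all geometry in the package: an ordered protein main
#' chain holding, per residue, the author numbering, one-letter amino-acid
#' code and the four backbone heavy atoms N, CA, C, O. Residues missing
#' any backbone atom are kept but flagged incomplete; torsions are never
#' computed for or across them. Chain continuity breaks (peptide C-N
#' distance above a threshold) are recorded as gaps.
#'
#' @param chain_id Single character chain identifier.
#' @param resno Integer vector of author residue numbers (ascending).
#' @param aa Character vector of one-letter amino-acid codes.
#' @param N,CA,C,O Numeric n x 3 coordinate matrices (Angstrom); rows with
#'   any `NA` mark missing atoms.
#' @param icode Insertion codes (default empty strings).
#' @param break_cutoff Peptide-bond C(i)-N(i+1) distance (Angstrom) above
#'   which chain continuity is broken. Default 2.5.
#' @return An object of class `backbone_chain`.
#' @export
backbone_chain <- function(chain_id, resno, aa, N, CA, C, O,
                           icode = NULL, break_cutoff = 2.5) {
  n <- length(resno)
  stopifnot(length(aa) == n, nrow(N) == n, nrow(CA) == n,
            nrow(C) == n, nrow(O) == n)
  if (is.null(icode)) icode <- rep("", n)
  if (n > 1 && any(diff(resno) < 0 & icode[-1] == "" & icode[-n] == "")) {
    stop("residues must be in ascending sequence order")
  }
  complete <- !(rowSums(is.na(N)) > 0 | rowSums(is.na(CA)) > 0 |
                  rowSums(is.na(C)) > 0 | rowSums(is.na(O)) > 0)
  gaps <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (!complete[i] || !complete[i + 1]) {
        gaps <- c(gaps, i)
      } else {
        d <- sqrt(sum((C[i, ] - N[i + 1, ])^2))
        if (d > break_cutoff) gaps <- c(gaps, i)
      }
    }
  }
  structure(list(chain_id = as.character(chain_id),
                 res = data.frame(resno = as.integer(resno),
                                  icode = icode, aa = aa,
                                  complete = complete,
                                  stringsAsFactors = FALSE),
                 N = N, CA = CA, C = C, O = O, gaps = gaps),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain %s: %d residues (%d complete), %d gap(s)>\n",
              x$chain_id, nrow(x$res), sum(x$res$complete), length(x$gaps)))
  invisible(x)
}

#' @export
length.backbone_chain <- function(x) nrow(x$res)

# indices of maximal continuous runs of complete residues
chain_segments <- function(chain) {
  n <- nrow(chain$res)
  if (n == 0) return(list())
  brk <- rep(FALSE, n)
  if (length(chain$gaps)) brk[chain$gaps] <- TRUE
  segs <- list()
  start <- NULL
  for (i in seq_len(n)) {
    if (chain$res$complete[i]) {
      if (is.null(start)) start <- i
      if (i == n || brk[i] || !chain$res$complete[min(i + 1, n)]) {
        segs[[length(segs) + 1]] <- start:i
        start <- NULL
      }
    } else {
      start <- NULL
    }
  }
  segs
}

# apply a rigid transform to every atom of a chain
transform_chain <- function(chain, R = diag(3), shift = c(0, 0, 0)) {
  for (at in c("N", "CA", "C", "O")) {
    ok <- !is.na(chain[[at]][, 1])
    chain[[at]][ok, ] <- transform_coords(chain[[at]][ok, , drop = FALSE],
                                          R, shift)
  }
  chain
}

#' Construct a structure model
#'
#' A set of uniquely named backbone chains, typically one biological
#' assembly of a deposited structure or a generated synthetic bundle.
#'
#' @param id Identifier text.
#' @param chains List of [backbone_chain] objects with unique chain ids.
#' @param assembly_id Assembly label (`"asu"` for deposited chains), or
#'   `NA` when not applicable.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(id, chains, assembly_id = NA_character_) {
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids)) stop("chain identifiers must be unique")
  names(chains) <- ids
  structure(list(id = as.character(id), chains = chains,
                 assembly_id = assembly_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model %s: %d chain(s) [%s], assembly %s>\n",
              x$id, length(x$chains),
              paste(names(x$chains), collapse = ","),
              ifelse(is.na(x$assembly_id), "-", x$assembly_id)))
  invisible(x)
}

# apply a rigid transform to every chain of a model
transform_model <- function(model, R = diag(3), shift = c(0, 0, 0)) {
  model$chains <- lapply(model$chains, transform_chain, R = R, shift = shift)
  model
}
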
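# Periodicity algebra of residue insertions into the heptad repeat:
# exact rational periodicities, supercoil handedness, the accessible
# band, and the accommodation of 1-6 residue insertions by progressive
# delocalization over neighboring heptads.

# band of periodicities accessible to alpha-helical coiled coils:
# 10/3 = 3.33 residues/turn marks the lower limit (beyond it the helices
# overwind); the upper limit mirrors it about the unperturbed-helix
# reference at about 3.9
ACCESSIBLE_BAND <- c(10 / 3, 3.90)

#' Periodicity of a repeat pattern
#'
#' A repeat of `residues` residues over `turns` helical turns has
#' periodicity residues/turns (an exact rational). Values below the
#' unperturbed-helix reference (about 3.63 residues per turn) supercoil
#' left-handed, above it right-handed; periodicities outside roughly
#' [3.33, 3.90] are inaccessible to alpha-helical coiled coils.
#'
#' @param residues,turns Positive integers.
#' @param reference Reference periodicity of the unperturbed helix
#'   (default 3.63).
#' @param band Accessible band, default `c(10/3, 3.90)`.
#' @return Data frame (one row) of class `repeat_spec`: `residues`,
#'   `turns`, `periodicity`, `handedness` (`"left"`, `"right"`,
#'   `"none"`), `accessible`.
#' @export
#' @examples
#' periodicity(7, 2)   # heptad: 3.5, left-handed
#' periodicity(11, 3)  # hendecad: 3.67, right-handed
periodicity <- function(residues, turns,
                        reference = HELIX_REFERENCE_PERIODICITY,
                        band = ACCESSIBLE_BAND) {
  if (any(residues < 1) || any(turns < 1) ||
      any(residues != round(residues)) || any(turns != round(turns))) {
    stop("residues and turns must be positive integers")
  }
  p <- residues / turns
  out <- data.frame(
    residues = as.integer(residues), turns = as.integer(turns),
    periodicity = p,
    handedness = ifelse(p < reference, "left",
                        ifelse(p > reference, "right", "none")),
    accessible = p >= band[1] & p <= band[2],
    stringsAsFactors = FALSE)
  class(out) <- c("repeat_spec", class(out))
  out
}

#' Periodicity resulting from an insertion into the heptad repeat
#'
#' An insertion of `insert_length` residues delocalized over `heptads`
#' neighboring heptads yields a repeat of `7 * heptads + insert_length`
#' residues over `2 * heptads + added_turns` turns. With
#' `added_turns = "optimal"` the integer turn count minimizing the
#' distance to the unperturbed-helix reference is chosen (ties broken
#' toward the lower periodicity, the left-handed bias of the heptad
#' background). E.g. an insertion of 4 delocalized over one heptad is
#' accommodated as 11/3, over two heptads as 18/5.
#'
#' @param insert_length Integer 1-6.
#' @param heptads Number of heptads the insertion is delocalized over.
#' @param added_turns Integer number of turns added by the insertion, or
#'   `"optimal"`.
#' @param reference,band Passed to [periodicity].
#' @return A `repeat_spec` row.
#' @export
insertion_periodicity <- function(insert_length, heptads,
                                  added_turns = "optimal",
                                  reference = HELIX_REFERENCE_PERIODICITY,
                                  band = ACCESSIBLE_BAND) {
  stopifnot(insert_length %in% 1:6, heptads >= 1)
  residues <- 7 * heptads + insert_length
  if (identical(added_turns, "optimal")) {
    cand <- 0:6
    p <- residues / (2 * heptads + cand)
    dist <- abs(p - reference)
    best <- which(dist == min(dist))
    if (length(best) > 1) best <- best[which.min(p[best])]
    added_turns <- cand[best]
  }
  turns <- 2 * heptads + added_turns
  if (turns < 1) stop("added_turns leaves no full turn")
  periodicity(residues, turns, reference = reference, band = band)
}

#' Accommodation table for an insertion
#'
#' For each delocalization breadth 1..`max_heptads`, the optimal repeat
#' spec; insertions for which no delocalization up to `max_heptads`
#' reaches the accessible band (2 and 6 residues at the default breadth)
#' cannot be absorbed by supercoiling and are flagged as requiring a
#' beta-layer.
#'
#' @param insert_length Integer 1-6.
#' @param max_heptads Maximum delocalization breadth (default 2).
#' @param reference,band Passed to [periodicity].
#' @return Data frame: one `repeat_spec` row per delocalization plus
#'   columns `insert_length`, `heptads`; attribute `requires_beta_layer`.
#' @export
accommodation_report <- function(insert_length, max_heptads = 2,
                                 reference = HELIX_REFERENCE_PERIODICITY,
                                 band = ACCESSIBLE_BAND) {
  stopifnot(max_heptads >= 1)
  rows <- lapply(seq_len(max_heptads), function(h) {
    spec <- insertion_periodicity(insert_length, h, "optimal",
                                  reference = reference, band = band)
    cbind(data.frame(insert_length = insert_length, heptads = h), spec)
  })
  out <- do.call(rbind, rows)
  attr(out, "requires_beta_layer") <- !any(out$accessible)
  out
}
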
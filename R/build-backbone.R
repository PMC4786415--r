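# Internal-coordinate chain growth: build full N/CA/C/O backbones from
# (phi, psi, omega) torsion lists with ideal bond lengths and angles.

# ideal backbone geometry (Engh & Huber style averages)
IDEAL_GEOM <- list(
  b_n_ca  = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

# canonical alpha-helical torsions used for all helical segments
ALPHA_PHI <- -57.8
ALPHA_PSI <- -47.0

#' Build a backbone chain from torsion angles
#'
#' Grows an all-atom (N, CA, C, O) backbone residue by residue from a list
#' of (phi, psi, omega) torsions using ideal bond lengths and angles.
#' `phi[1]` is unused (undefined at the chain start) and `psi` of the last
#' residue only orients its carbonyl oxygen. Round trip holds: running
#' [compute_torsions] on the built chain recovers the inputs to well below
#' 1e-3 degrees.
#'
#' @param phi,psi Numeric vectors of torsions in degrees, equal length.
#' @param omega Peptide-bond torsions (degrees); scalar or vector;
#'   default 180 (trans).
#' @param aa One-letter amino-acid codes (default all `"A"`).
#' @param chain_id Chain identifier (default `"A"`).
#' @param resno Residue numbers (default `1:n`).
#' @return A [backbone_chain].
#' @export
#' @examples
#' ch <- build_backbone_from_torsions(rep(-57.8, 10), rep(-47, 10))
#' compute_torsions(ch)
build_backbone_from_torsions <- function(phi, psi, omega = 180,
                                         aa = NULL, chain_id = "A",
                                         resno = NULL) {
  n <- length(phi)
  stopifnot(n >= 1, length(psi) == n)
  if (length(omega) == 1) omega <- rep(omega, n)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(resno)) resno <- seq_len(n)
  g <- IDEAL_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  # seed residue in the xy-plane
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- (180 - g$a_n_ca_c) * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, omega[i - 1])
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    psi_o <- if (is.na(psi[i])) ALPHA_PSI else psi[i]
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi_o + 180)
  }
  backbone_chain(chain_id, resno, aa, N, CA, C, O)
}
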
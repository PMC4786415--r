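# Parametric coiled-coil backbone generation: Ca traces from the
# two-level (Crick) helix parameterization, full backbones rebuilt from
# the Ca path, and exact n-fold symmetric bundle assembly.

#' Crick parameters for a synthetic coiled coil
#'
#' @param n_chains Number of chains (>= 1; 1 gives a single helix).
#' @param superhelix_radius Distance of each helix axis from the bundle
#'   axis (Angstrom); 0 reduces to straight helices.
#' @param supercoil_periodicity Target residues per turn relative to the
#'   bundle axis (e.g. 3.5 for heptads). The supercoil frequency follows
#'   from the constraint that the helix itself keeps the twist of an
#'   unperturbed alpha-helix (360/3.63 degrees per residue): values below
#'   3.63 give left-handed, above 3.63 right-handed supercoiling.
#' @param twist_per_residue Explicit local twist (degrees/residue); only
#'   meaningful with `superhelix_radius = 0`, where the periodicity equals
#'   `360 / twist_per_residue`. Overrides `supercoil_periodicity`.
#' @param rise_per_residue Rise along the bundle axis (Angstrom/residue).
#' @param helix_radius Minor-helix radius (Angstrom), default 2.28.
#' @param phase Crick phase of the first residue (degrees; 0 points at the
#'   bundle axis).
#' @return List of class `crick_params`.
#' @export
crick_params <- function(n_chains = 3, superhelix_radius = 6.7,
                         supercoil_periodicity = 3.5,
                         twist_per_residue = NULL,
                         rise_per_residue = 1.5, helix_radius = 2.28,
                         phase = 25.714) {
  stopifnot(n_chains >= 1, superhelix_radius >= 0, rise_per_residue > 0)
  if (is.null(twist_per_residue)) {
    stopifnot(supercoil_periodicity > 0)
  } else {
    stopifnot(twist_per_residue > 0, twist_per_residue < 180)
    supercoil_periodicity <- 360 / twist_per_residue
  }
  structure(list(n_chains = n_chains, superhelix_radius = superhelix_radius,
                 supercoil_periodicity = supercoil_periodicity,
                 rise_per_residue = rise_per_residue,
                 helix_radius = helix_radius, phase = phase),
            class = "crick_params")
}

# Ca trace of one chain of a Crick coil, bundle axis = z.
# omega1: rotation per residue in the frame co-rotating with the
# superhelix (so periodicity relative to the bundle axis is 360/omega1);
# omega0: superhelix rotation per residue about the bundle axis, set so
# that the local helix twist stays at the unperturbed-helix reference.
crick_ca_trace <- function(params, n_res) {
  P <- params$supercoil_periodicity
  omega1 <- 360 / P
  omega0 <- if (params$superhelix_radius == 0) 0 else
    360 / HELIX_REFERENCE_PERIODICITY - omega1
  R0 <- params$superhelix_radius
  R1 <- params$helix_radius
  d <- params$rise_per_residue
  ca <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    t <- i - 1
    Phi <- .rad(omega0 * t)
    A <- c(R0 * cos(Phi), R0 * sin(Phi), d * t)
    Tg <- .unit(c(-R0 * .rad(omega0) * sin(Phi),
                  R0 * .rad(omega0) * cos(Phi), d))
    U <- c(cos(Phi), sin(Phi), 0)         # radial, outward
    V <- .cross(Tg, U)
    th <- .rad(params$phase + omega1 * t)
    ca[i, ] <- A + R1 * (-cos(th) * U - sin(th) * V)
  }
  ca
}

# Local-frame coefficients for rebuilding N/C/O from a Ca path, calibrated
# once on an ideal NeRF-built alpha-helix. Frames:
#  interior residue i: e1 = unit(CA[i+1]-CA[i]), plane with CA[i-1]
#  first residue:      forward frame from CA[1..3]
#  last residue:       backward frame from CA[n-2..n]
.ca_frame <- function(p_prev, p, p_next) {
  e1 <- .unit(p_next - p)
  v2 <- p_prev - p
  e3 <- .unit(.cross(e1, v2))
  e2 <- .cross(e3, e1)
  rbind(e1, e2, e3)
}

.calibrate_backbone_coeffs <- function() {
  nref <- 12
  h <- build_backbone_from_torsions(rep(ALPHA_PHI, nref), rep(ALPHA_PSI, nref))
  mid <- 6
  Fm <- .ca_frame(h$CA[mid - 1, ], h$CA[mid, ], h$CA[mid + 1, ])
  interior <- lapply(c(N = "N", C = "C", O = "O"),
                     function(at) as.numeric(Fm %*% (h[[at]][mid, ] - h$CA[mid, ])))
  # terminal frames: express atoms of residue i in frames built without a
  # neighbor on one side (using i, i+1, i+2 or i-2, i-1, i)
  Ff <- .ca_frame(h$CA[mid + 2, ], h$CA[mid, ], h$CA[mid + 1, ])
  first <- lapply(c(N = "N", C = "C", O = "O"),
                  function(at) as.numeric(Ff %*% (h[[at]][mid, ] - h$CA[mid, ])))
  Fb <- .ca_frame(h$CA[mid - 1, ], h$CA[mid, ], h$CA[mid - 2, ])
  last <- lapply(c(N = "N", C = "C", O = "O"),
                 function(at) as.numeric(Fb %*% (h[[at]][mid, ] - h$CA[mid, ])))
  list(interior = interior, first = first, last = last)
}

.pkg_cache <- new.env(parent = emptyenv())

backbone_coeffs <- function() {
  if (is.null(.pkg_cache$coeffs)) {
    .pkg_cache$coeffs <- .calibrate_backbone_coeffs()
  }
  .pkg_cache$coeffs
}

#' Rebuild a full backbone from a Ca trace
#'
#' Places N, C and O in the local frame of each consecutive Ca triple,
#' with offsets calibrated on an ideal alpha-helix; Ca positions are kept
#' exactly. Intended for near-helical paths (the Crick generator), where
#' the resulting torsions fall in the alpha box.
#'
#' @param ca Numeric n x 3 Ca matrix, n >= 3.
#' @param chain_id,aa,resno Passed through to [backbone_chain].
#' @return A [backbone_chain].
#' @export
backbone_from_ca <- function(ca, chain_id = "A", aa = NULL, resno = NULL) {
  n <- nrow(ca)
  stopifnot(n >= 3)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(resno)) resno <- seq_len(n)
  cf <- backbone_coeffs()
  N <- C <- O <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i == 1) {
      Fr <- .ca_frame(ca[3, ], ca[1, ], ca[2, ]); co <- cf$first
    } else if (i == n) {
      Fr <- .ca_frame(ca[n - 1, ], ca[n, ], ca[n - 2, ]); co <- cf$last
    } else {
      Fr <- .ca_frame(ca[i - 1, ], ca[i, ], ca[i + 1, ]); co <- cf$interior
    }
    N[i, ] <- ca[i, ] + as.numeric(t(Fr) %*% co$N)
    C[i, ] <- ca[i, ] + as.numeric(t(Fr) %*% co$C)
    O[i, ] <- ca[i, ] + as.numeric(t(Fr) %*% co$O)
  }
  backbone_chain(chain_id, resno, aa, N, ca, C, O)
}

#' Generate a Crick-parameterized coiled coil
#'
#' Builds the Ca trace of one chain from the two-level helix
#' parameterization, rebuilds the full backbone, and places `n_chains`
#' copies with exact n-fold rotational symmetry about the bundle (z)
#' axis. The nominal periodicity is recorded in the annotation.
#'
#' @param params A [crick_params] object.
#' @param n_res Residues per chain (>= 8).
#' @param sequence Optional amino-acid sequence (one-letter string),
#'   recycled to `n_res`; default poly-A.
#' @return A [structure_model] with attribute `annotation` (list with
#'   `nominal_periodicity` and `params`).
#' @export
generate_crick_coil <- function(params, n_res, sequence = NULL) {
  stopifnot(inherits(params, "crick_params"), n_res >= 8)
  aa <- if (is.null(sequence)) rep("A", n_res) else
    rep(strsplit(sequence, "")[[1]], length.out = n_res)
  ca <- crick_ca_trace(params, n_res)
  base <- backbone_from_ca(ca, chain_id = "A", aa = aa)
  chains <- list(base)
  if (params$n_chains > 1) {
    for (k in seq_len(params$n_chains - 1)) {
      R <- rotation_matrix(c(0, 0, 1), 360 * k / params$n_chains)
      ch <- transform_chain(base, R)
      ch$chain_id <- LETTERS[k + 1]
      chains[[k + 1]] <- ch
    }
  }
  model <- structure_model(sprintf("crick_%s", params$supercoil_periodicity),
                           chains)
  attr(model, "annotation") <- list(
    nominal_periodicity = params$supercoil_periodicity, params = params)
  model
}

#' Perturb a model with Gaussian coordinate noise
#'
#' Adds isotropic Gaussian noise of standard deviation `sigma` to every
#' backbone atom; reproducible for a fixed seed.
#'
#' @param model A [structure_model].
#' @param sigma Noise standard deviation (Angstrom, >= 0).
#' @param seed Integer RNG seed (default 0).
#' @return The perturbed model.
#' @export
perturb <- function(model, sigma, seed = 0) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(model)
  set.seed(seed)
  model$chains <- lapply(model$chains, function(ch) {
    for (at in c("N", "CA", "C", "O")) {
      ok <- !is.na(ch[[at]][, 1])
      ch[[at]][ok, ] <- ch[[at]][ok, ] +
        matrix(stats::rnorm(3 * sum(ok), sd = sigma), ncol = 3)
    }
    ch
  })
  model
}
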
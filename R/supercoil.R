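# TWISTER-style local coiled-coil analysis: per-residue local helix axis
# (bisector construction on consecutive Ca), local periodicity relative to
# the bundle axis, Crick angles, three-residue smoothing and heptad
# register assignment including the hybrid g/c position.

# reference periodicity of the unperturbed alpha-helix (residues/turn)
HELIX_REFERENCE_PERIODICITY <- 3.63

# ideal Crick angles of the seven heptad positions, phased so that the
# core positions a and d straddle the direction toward the bundle axis
ideal_crick_angles <- function() {
  step <- 360 / 3.5
  ang <- wrap_angle(step / 4 + step * (0:6))
  names(ang) <- letters[1:7]
  ang
}

#' Per-residue local helix axis and twist from a Ca trace
#'
#' Classic bisector construction: at each interior residue the bisector of
#' the two Ca-Ca bonds points toward the local helix axis; consecutive
#' bisectors give the local axis direction (their cross product), the
#' local twist (the angle between them, in (0, 180)), the rise and the
#' helix radius, from which per-residue axis points follow.
#'
#' @param ca Numeric n x 3 matrix of consecutive Ca positions (one
#'   continuous segment, n >= 4).
#' @return List with n-row elements `axis_point` (n x 3), `axis_dir`
#'   (n x 3, oriented along the chain), `twist` (degrees/residue),
#'   `radius`, `rise` and logical `valid`. Terminal residues (and all
#'   residues of degenerate, straight-line traces) are invalid.
#' @export
local_helix_axis <- function(ca) {
  stopifnot(is.matrix(ca), ncol(ca) == 3)
  n <- nrow(ca)
  out <- list(axis_point = matrix(NA_real_, n, 3),
              axis_dir = matrix(NA_real_, n, 3),
              twist = rep(NA_real_, n), radius = rep(NA_real_, n),
              rise = rep(NA_real_, n), valid = rep(FALSE, n))
  if (n < 4) return(out)
  bis <- matrix(NA_real_, n, 3)
  for (i in 2:(n - 1)) {
    b <- .unit(.unit(ca[i - 1, ] - ca[i, ]) + .unit(ca[i + 1, ] - ca[i, ]))
    bis[i, ] <- b
  }
  for (i in 2:(n - 2)) {
    b1 <- bis[i, ]; b2 <- bis[i + 1, ]
    if (anyNA(b1) || anyNA(b2)) next
    cr <- .cross(b1, b2)
    if (.vnorm(cr) < 1e-8) next # straight-line degenerate trace
    h <- .unit(cr)
    step <- ca[i + 1, ] - ca[i, ]
    if (sum(h * step) < 0) h <- -h
    tw <- .deg(atan2(sum(.cross(b1, b2) * h), sum(b1 * b2)))
    if (is.na(tw) || tw <= 0) next
    d <- sum(step * h)
    chord2 <- sum(step * step) - d^2
    if (chord2 < 0) next
    r <- sqrt(chord2) / (2 * sin(.rad(tw) / 2))
    out$twist[i] <- tw
    out$rise[i] <- d
    out$radius[i] <- r
    out$axis_dir[i, ] <- h
    out$axis_point[i, ] <- ca[i, ] + r * b1
    out$valid[i] <- TRUE
  }
  # last interior residue: reuse the preceding frame for its axis point
  i <- n - 1
  if (out$valid[n - 2] && !anyNA(bis[i, ])) {
    out$axis_dir[i, ] <- out$axis_dir[n - 2, ]
    out$twist[i] <- out$twist[n - 2]
    out$radius[i] <- out$radius[n - 2]
    out$axis_point[i, ] <- ca[i, ] + out$radius[n - 2] * bis[i, ]
    out$valid[i] <- TRUE
  }
  out
}

#' Central bundle axis of a multi-chain bundle
#'
#' The axis curve is the pointwise centroid, across chains, of the
#' per-chain local helix axis points, lightly smoothed; for an exactly
#' C3-symmetric bundle it coincides with the symmetry axis. A straight
#' line is also fitted through the centroids for use where the curve is
#' undefined (near termini).
#'
#' @param chains List (length >= 2) of Ca matrices, or [backbone_chain]
#'   objects, with compatible residue indexing.
#' @return Object of class `bundle_axis`: list with `points` (n x 3 curve,
#'   `NA` where undefined), `origin` and `dir` (unit vector) of the line
#'   fit.
#' @export
bundle_axis <- function(chains) {
  if (length(chains) < 2) stop("bundle_axis needs at least 2 chains")
  cas <- lapply(chains, function(ch) if (inherits(ch, "backbone_chain")) ch$CA else ch)
  n <- min(vapply(cas, nrow, integer(1)))
  pts <- array(NA_real_, c(n, 3, length(cas)))
  for (k in seq_along(cas)) {
    ax <- local_helix_axis(cas[[k]][seq_len(n), , drop = FALSE])
    pts[, , k] <- ax$axis_point[seq_len(n), ]
  }
  centroid <- apply(pts, c(1, 2), mean)
  ok <- !is.na(centroid[, 1])
  if (sum(ok) < 2) stop("too few valid axis points to define a bundle axis")
  sm <- centroid
  sm[ok, ] <- apply(centroid[ok, , drop = FALSE], 2,
                    function(v) smooth_series(v, 3))
  fit <- prcomp(sm[ok, , drop = FALSE])
  dirv <- fit$rotation[, 1]
  idx <- which(ok)
  if (sum((sm[idx[length(idx)], ] - sm[idx[1], ]) * dirv) < 0) dirv <- -dirv
  structure(list(points = sm, origin = colMeans(sm[ok, , drop = FALSE]),
                 dir = as.numeric(dirv)),
            class = "bundle_axis")
}

#' A straight reference bundle axis
#'
#' For single straight helices (where no partner chain defines a bundle)
#' analysis can be run against an explicit reference line, e.g. the known
#' helix axis.
#'
#' @param origin Point on the line.
#' @param dir Direction vector (normalized internally).
#' @return A `bundle_axis` object without a curve component.
#' @export
bundle_axis_line <- function(origin, dir) {
  structure(list(points = NULL, origin = as.numeric(origin),
                 dir = .unit(as.numeric(dir))),
            class = "bundle_axis")
}

# reference point of the bundle axis for residue i given its local axis point
.bundle_point <- function(axis, i, local_point) {
  if (!is.null(axis$points) && i <= nrow(axis$points) &&
      !is.na(axis$points[i, 1])) {
    return(axis$points[i, ])
  }
  # projection onto the line fit
  axis$origin + sum((local_point - axis$origin) * axis$dir) * axis$dir
}

#' Local periodicity and Crick-angle trace of a chain
#'
#' Per residue, the local periodicity (residues per turn relative to the
#' bundle axis) is 360 / (rotation of the Ca about the local helix axis,
#' corrected by the rotation of the local axis itself about the bundle
#' axis), and the Crick angle is the signed angle, in the plane normal to
#' the local axis, between the direction from the local axis toward the
#' bundle axis and the direction toward the Ca. A heptad coiled coil
#' measures 3.5 residues/turn; an unsupercoiled helix about 3.63.
#'
#' @param chain A [backbone_chain] or a Ca coordinate matrix.
#' @param axis A `bundle_axis` (from [bundle_axis] or [bundle_axis_line]).
#' @return Data frame of class `periodicity_trace` with columns `resno`,
#'   `periodicity`, `crick`, `twist`, `radius`, `valid`.
#' @export
periodicity_trace <- function(chain, axis) {
  ca <- if (inherits(chain, "backbone_chain")) chain$CA else chain
  resno <- if (inherits(chain, "backbone_chain")) chain$res$resno else seq_len(nrow(ca))
  n <- nrow(ca)
  loc <- local_helix_axis(ca)
  crick <- rep(NA_real_, n)
  # fixed fallback reference for helices lying on the bundle axis, where
  # "toward the bundle axis" is undefined but the axis does not rotate
  # about the bundle either, so any fixed perpendicular serves
  ref0 <- .unit(.cross(axis$dir, c(0, 0, 1)))
  if (anyNA(ref0)) ref0 <- .unit(.cross(axis$dir, c(0, 1, 0)))
  for (i in seq_len(n)) {
    if (!loc$valid[i]) next
    A <- loc$axis_point[i, ]
    h <- loc$axis_dir[i, ]
    b <- .bundle_point(axis, i, A)
    w <- (b - A) - sum((b - A) * h) * h
    if (.vnorm(w) < 0.2) w <- ref0 - sum(ref0 * h) * h
    v <- (ca[i, ] - A) - sum((ca[i, ] - A) * h) * h
    if (.vnorm(w) > 1e-6 && .vnorm(v) > 1e-6) {
      crick[i] <- .deg(atan2(sum(.cross(w, v) * h), sum(w * v)))
    }
  }
  # the Crick angle is measured against the direction toward the bundle
  # axis, so its per-residue increment is the rotation of the Ca about the
  # local helix axis already corrected for the rotation of the local axis
  # about the bundle axis
  periodicity <- rep(NA_real_, n)
  for (i in seq_len(n - 1)) {
    if (!is.na(crick[i]) && !is.na(crick[i + 1])) {
      step <- wrap_angle(crick[i + 1] - crick[i])
      if (!is.na(step) && step > 0) periodicity[i] <- 360 / step
    }
  }
  out <- data.frame(resno = resno, periodicity = periodicity, crick = crick,
                    twist = loc$twist, radius = loc$radius,
                    valid = !is.na(periodicity))
  attr(out, "chain_id") <- if (inherits(chain, "backbone_chain")) chain$chain_id else NA
  class(out) <- c("periodicity_trace", class(out))
  out
}

# centered moving average over valid (non-NA) neighbors; length-preserving,
# shrinking window at ends
smooth_series <- function(x, window = 3) {
  if (window %% 2 == 0) stop("smoothing window must be odd")
  if (window == 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    lo <- max(1, i - half); hi <- min(n, i + half)
    v <- x[lo:hi]
    out[i] <- mean(v[!is.na(v)])
  }
  out
}

#' Smooth a periodicity trace
#'
#' Centered moving average of width `window` (default 3, the width used
#' for all periodicity plots) over valid neighbors; invalid residues stay
#' invalid and the trace length is preserved.
#'
#' @param trace A `periodicity_trace` (or any numeric vector).
#' @param window Odd integer window width (default 3; 1 is the identity).
#' @return Same shape as the input with `periodicity` (and `crick`)
#'   smoothed.
#' @export
smooth_trace <- function(trace, window = 3) {
  if (is.numeric(trace)) return(smooth_series(trace, window))
  trace$periodicity <- smooth_series(trace$periodicity, window)
  trace
}

#' Assign heptad register from Crick angles
#'
#' Helical residues are labeled by the nearest ideal Crick angle among the
#' seven heptad positions; beta-layer triplets are labeled beta1, beta2,
#' beta3; the residue after beta3 is forced to e (beta-layers dictate the
#' downstream register); and a residue immediately preceding a beta1 whose
#' Crick angle is displaced from ideal g toward c by more than `gc_threshold`
#' degrees is labeled "g/c" (the hybrid position seen before beta-layers in
#' hexad spacing).
#'
#' @param trace A `periodicity_trace` for one chain.
#' @param layers Optional list of beta-layers (from [detect_beta_layers])
#'   or a data frame of strand annotations with columns `chain` and
#'   `beta2_resno`; only strands on this trace's chain are used.
#' @param gc_threshold Displacement toward c (degrees) beyond which a
#'   pre-beta1 g residue is relabeled g/c. Default 10.
#' @return Character vector of position labels, one per residue
#'   (`NA` where unassignable).
#' @export
assign_register <- function(trace, layers = NULL, gc_threshold = 10) {
  ideal <- ideal_crick_angles()
  n <- nrow(trace)
  lab <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(trace$crick[i])) next
    d <- abs(wrap_angle(trace$crick[i] - ideal))
    lab[i] <- names(ideal)[which.min(d)]
  }
  strands <- .layer_strands(layers)
  if (!is.null(strands) && nrow(strands)) {
    cid <- attr(trace, "chain_id")
    strands <- strands[is.na(cid) | strands$chain == cid, , drop = FALSE]
    for (s in seq_len(nrow(strands))) {
      mid <- match(strands$beta2_resno[s], trace$resno)
      if (is.na(mid)) next
      if (mid > 1) lab[mid - 1] <- "beta1"
      lab[mid] <- "beta2"
      if (mid < n) lab[mid + 1] <- "beta3"
      if (mid + 2 <= n) lab[mid + 2] <- "e"
      pre <- mid - 2
      if (pre >= 1 && !is.na(trace$crick[pre])) {
        # displacement from ideal g along the (shorter) arc toward c
        toward_c <- sign(wrap_angle(ideal["c"] - ideal["g"]))
        disp <- toward_c * wrap_angle(trace$crick[pre] - ideal["g"])
        span <- abs(wrap_angle(ideal["c"] - ideal["g"]))
        # displaced toward c but still nearer g than c: a full displacement
        # is simply a c position (the nonad junction), not the hybrid
        if (disp >= gc_threshold && disp <= span / 2) lab[pre] <- "g/c"
      }
    }
  }
  lab
}

# normalize the `layers` argument of assign_register into a strand table
.layer_strands <- function(layers) {
  if (is.null(layers)) return(NULL)
  if (is.data.frame(layers)) return(layers)
  do.call(rbind, lapply(layers, function(ly) ly$strands))
}
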
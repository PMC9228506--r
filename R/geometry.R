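# Periodic-boundary geometry and centre-of-mass utilities.

#' Minimum-image displacement
#'
#' @param d displacement vector/matrix (columns x, y, z), Angstrom
#' @param box orthorhombic box edges, Angstrom
#' @return displacement folded into \[-box/2, box/2) per component
#' @export
minimum_image <- function(d, box) {
  if (is.matrix(d)) {
    sweep_box <- matrix(box, nrow(d), 3, byrow = TRUE)
    d - sweep_box * round(d / sweep_box)
  } else {
    d - box * round(d / box)
  }
}

#' Reassemble a molecule split by the periodic boundary
#'
#' Makes a set of coordinates "whole" by anchoring at the first atom and
#' applying minimum-image shifts to every other atom relative to it.
#' Deterministic: the anchor is always the first supplied index.
#'
#' @param xyz n x 3 coordinate matrix
#' @param box orthorhombic box edges
#' @return n x 3 matrix of reassembled coordinates (may lie outside the box)
#' @export
make_whole <- function(xyz, box) {
  xyz <- as.matrix(xyz)
  anchor <- xyz[1, ]
  disp <- sweep(xyz, 2, anchor)
  sweep(minimum_image(disp, box), 2, anchor, FUN = "+")
}

#' Centre of mass of a set of atoms in a frame
#'
#' If the atoms span the periodic boundary they are first made whole around
#' the first index (see [make_whole()]).  With `mass_weighted = FALSE` the
#' geometric centre is returned instead.
#'
#' @param fr a [frame()]
#' @param top a [topology()] (supplies masses)
#' @param indices atom indices
#' @param mass_weighted logical, default TRUE
#' @return length-3 numeric vector, Angstrom
#' @export
center_of_mass <- function(fr, top, indices, mass_weighted = TRUE) {
  if (!length(indices)) stop("indices must be non-empty")
  xyz <- make_whole(fr$xyz[indices, , drop = FALSE], fr$box)
  w <- if (mass_weighted) top$atoms$mass[indices] else rep(1, length(indices))
  tot <- sum(w)
  if (tot <= 0) stop("zero total mass in centre-of-mass computation")
  colSums(xyz * w) / tot
}

#' Assign lipids to leaflets by phosphorus z-coordinate
#'
#' The bilayer normal is taken to be z.  A lipid is "upper" iff its
#' phosphorus z exceeds the (mass-weighted) z of the phosphorus centre of
#' mass.  A degenerate assignment (all on one side) yields a warning, not
#' an error, so vesiculated or broken inputs can still be inspected.
#'
#' @param fr a [frame()]
#' @param top a [topology()]
#' @param p_indices indices of the lipid phosphorus atoms, one per lipid
#' @return character vector `"upper"`/`"lower"`, one per phosphorus
#' @export
assign_leaflets <- function(fr, top, p_indices) {
  if (!length(p_indices)) stop("no phosphorus atoms supplied")
  zc <- center_of_mass(fr, top, p_indices)[3]
  z <- fr$xyz[p_indices, 3]
  lab <- ifelse(z > zc, "upper", "lower")
  if (length(unique(lab)) < 2L) {
    warning("degenerate leaflet assignment: all lipids on one side")
  }
  lab
}

#' Angle between two vectors in degrees
#'
#' @param u,v numeric length-3 vectors
#' @return angle in \[0, 180\] degrees
#' @export
vector_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length vector in angle computation")
  ca <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}
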
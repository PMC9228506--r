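# Structural observables of the bilayer: area per lipid, thickness,
# deuterium order parameters, tilt-angle distributions, density profiles.

#' Per-frame observable time series
#' @param name observable name
#' @param times ns
#' @param values per-frame values
#' @param units unit string (non-empty)
#' @return data.frame of class `"observable_series"` with columns `time`,
#'   `value` and attributes `name`, `units`
#' @export
observable_series <- function(name, times, values, units) {
  stopifnot(length(times) == length(values), nzchar(units))
  structure(data.frame(time = times, value = values),
            name = name, units = units,
            class = c("observable_series", "data.frame"))
}

#' @export
print.observable_series <- function(x, ...) {
  cat(sprintf("<observable_series> %s [%s]: %d frames, mean %.4g, sd %.3g\n",
              attr(x, "name"), attr(x, "units"), nrow(x),
              mean(x$value), stats::sd(x$value)))
  invisible(x)
}

#' Area per lipid
#'
#' The lateral box cross-section divided by the number of lipids in one
#' leaflet, per frame.
#'
#' @param traj a [trajectory()]
#' @param lipids_per_leaflet lipids in each leaflet (> 0)
#' @return [observable_series()] in Angstrom^2
#' @export
area_per_lipid <- function(traj, lipids_per_leaflet) {
  if (lipids_per_leaflet <= 0) stop("lipids_per_leaflet must be > 0")
  observable_series("area_per_lipid", traj$times,
                    traj$boxes[, 1] * traj$boxes[, 2] / lipids_per_leaflet,
                    "A^2")
}

#' Bilayer thickness from phosphorus-plane separation
#'
#' Per frame, the absolute z-distance between the centres of mass of the
#' upper- and lower-leaflet phosphorus atoms (leaflets assigned per frame;
#' see [assign_leaflets()]).  A frame whose phosphorus atoms all fall on
#' one side of their centre of mass is degenerate: it yields 0 with a
#' warning rather than an error.
#'
#' @param traj a [trajectory()]
#' @param p_indices phosphorus atom indices (default: atoms tagged
#'   `lipid_P`)
#' @return [observable_series()] in Angstrom
#' @export
bilayer_thickness <- function(traj, p_indices = NULL) {
  if (is.null(p_indices)) {
    p_indices <- select_atoms(traj$topology, selection_spec(role = "lipid_P"))
  }
  m <- traj$topology$atoms$mass[p_indices]
  vals <- numeric(n_frames(traj))
  degenerate <- FALSE
  for (i in seq_len(n_frames(traj))) {
    z <- traj$coords[p_indices, 3, i]
    zc <- sum(z * m) / sum(m)
    up <- z > zc
    if (!any(up) || all(up)) {
      degenerate <- TRUE
      vals[i] <- 0
    } else {
      vals[i] <- abs(sum(z[up] * m[up]) / sum(m[up]) -
                     sum(z[!up] * m[!up]) / sum(m[!up]))
    }
  }
  if (degenerate) warning("degenerate leaflet assignment in >= 1 frame; thickness 0 reported there")
  observable_series("bilayer_thickness", traj$times, vals, "A")
}

#' Per-lipid chain atom index lists, ordered along the chain
#'
#' @param top a [topology()]
#' @param role chain role tag (`"sn1_chain"` or `"sn2_chain"`)
#' @return list of integer vectors, one per molecule containing the role
#' @export
chain_indices <- function(top, role = c("sn1_chain", "sn2_chain")) {
  role <- match.arg(role)
  tagged <- which(has_role(top, role))
  if (!length(tagged)) stop("no atoms tagged ", role)
  mol_of <- rep(seq_len(nrow(top$molecules)),
                top$molecules$end - top$molecules$start + 1L)
  unname(split(tagged, mol_of[tagged]))
}

#' Deuterium order parameter profile along an acyl chain
#'
#' For carbon i the orientation vector is the heavy-atom central difference
#' from atom i-1 to atom i+1 (the standard surrogate when no hydrogens are
#' present); terminal carbons fall back to their single adjacent bond
#' vector and are flagged.  `Scd = 0.5 * <3 cos^2 theta - 1>` with theta
#' measured against the z axis, averaged over lipids and frames.
#'
#' @param traj a [trajectory()]
#' @param chains list of per-lipid atom index vectors (ordered along the
#'   chain, length >= 3), e.g. from [chain_indices()]
#' @param chain label stored in the result (`"sn1"` or `"sn2"`)
#' @return data.frame of class `"scd_profile"`: `carbon_index`, `scd`,
#'   `terminal`; attributes `chain`, `n_frames_averaged`
#' @export
scd_profile <- function(traj, chains, chain = "sn1") {
  len <- unique(lengths(chains))
  if (length(len) != 1L) stop("all chains must have equal length")
  if (len < 3L) stop("chains must have >= 3 atoms for central differences")
  nf <- n_frames(traj)
  acc <- numeric(len)
  for (fi in seq_len(nf)) {
    xyz <- traj$coords[, , fi]
    for (ch in chains) {
      p <- xyz[ch, , drop = FALSE]
      iprev <- c(1L, seq_len(len - 2L), len - 1L)
      inext <- c(2L, seq_len(len - 2L) + 2L, len)
      v <- p[inext, , drop = FALSE] - p[iprev, , drop = FALSE]
      c2 <- v[, 3]^2 / rowSums(v^2)
      acc <- acc + 0.5 * (3 * c2 - 1)
    }
  }
  scd <- acc / (nf * length(chains))
  structure(data.frame(carbon_index = seq_len(len), scd = scd,
                       terminal = c(TRUE, rep(FALSE, len - 2L), TRUE)),
            chain = chain, n_frames_averaged = nf,
            class = c("scd_profile", "data.frame"))
}

#' Order parameter of explicit orientation vectors
#'
#' `0.5 * (3 cos^2 theta - 1)` for each row vector against z; the building
#' block of [scd_profile()], exported for analytic checks.
#'
#' @param v n x 3 matrix of vectors
#' @return numeric vector of per-vector order parameters
#' @export
order_parameter <- function(v) {
  v <- matrix(v, ncol = 3)
  0.5 * (3 * v[, 3]^2 / rowSums(v^2) - 1)
}

#' Tilt-angle distribution of lipid vectors
#'
#' Angles between per-lipid vectors (e.g. P to N, or first to last chain
#' carbon) and the +z axis, pooled over frames into a normalised histogram
#' on [0, 180] degrees.  Zero-length vectors are skipped with a warning.
#'
#' @param traj a [trajectory()]
#' @param endpoints 2-column integer matrix, one row per lipid:
#'   (from atom, to atom)
#' @param breaks histogram bin edges in degrees (default 1-degree bins)
#' @return data.frame of class `"angle_distribution"`: `angle` (bin
#'   middle), `probability` (sums to 1)
#' @export
tilt_angle_distribution <- function(traj, endpoints,
                                    breaks = seq(0, 180, by = 1)) {
  endpoints <- matrix(as.integer(endpoints), ncol = 2)
  nf <- n_frames(traj)
  angles <- numeric(0)
  skipped <- 0L
  for (fi in seq_len(nf)) {
    xyz <- traj$coords[, , fi]
    v <- xyz[endpoints[, 2], , drop = FALSE] - xyz[endpoints[, 1], , drop = FALSE]
    nrm <- sqrt(rowSums(v^2))
    zero <- nrm == 0
    skipped <- skipped + sum(zero)
    ca <- pmin(1, pmax(-1, v[!zero, 3] / nrm[!zero]))
    angles <- c(angles, acos(ca) * 180 / pi)
  }
  if (skipped > 0L) warning(skipped, " zero-length vectors skipped")
  nb <- length(breaks) - 1L
  b <- pmin(pmax(findInterval(angles, breaks, rightmost.closed = TRUE), 1L), nb)
  counts <- tabulate(b, nbins = nb)
  structure(data.frame(angle = (breaks[-1] + breaks[-length(breaks)]) / 2,
                       probability = counts / sum(counts)),
            n_angles = length(angles),
            class = c("angle_distribution", "data.frame"))
}

#' Endpoint matrix for lipid P-N vectors
#' @param top a [topology()]
#' @return 2-column matrix (P index, N index) per lipid
#' @export
pn_endpoints <- function(top) {
  p <- select_atoms(top, selection_spec(role = "lipid_P"))
  n <- select_atoms(top, selection_spec(role = "lipid_N"))
  if (length(p) != length(n)) stop("P and N counts differ")
  cbind(p, n)
}

#' Endpoint matrix (first carbon, last carbon) for an acyl chain
#' @inheritParams chain_indices
#' @export
chain_endpoints <- function(top, role = c("sn1_chain", "sn2_chain")) {
  ch <- chain_indices(top, match.arg(role))
  t(vapply(ch, function(x) c(x[1], x[length(x)]), integer(2)))
}

#' Mass density profile along the membrane normal
#'
#' Mass of the selected atoms per slab volume, averaged over frames.  With
#' edges covering the full z extent, the integral of density times the
#' lateral box area recovers the total selected mass exactly.
#'
#' @param traj a [trajectory()]
#' @param indices atom indices of the component
#' @param edges z bin edges, Angstrom (uniform)
#' @param label component label stored on the result
#' @return data.frame of class `"density_profile"`: `z` (bin middle),
#'   `density` (amu A^-3)
#' @export
density_profile <- function(traj, indices, edges, label = "component") {
  dz <- diff(edges)
  if (any(dz <= 0) || diff(range(dz)) > 1e-9) stop("edges must be uniform and increasing")
  dz <- dz[1]
  m <- traj$topology$atoms$mass[indices]
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  for (fi in seq_len(n_frames(traj))) {
    z <- traj$coords[indices, 3, fi]
    b <- findInterval(z, edges, rightmost.closed = TRUE)
    ok <- b >= 1L & b <= nb
    sums <- as.numeric(tapply(m[ok], factor(b[ok], levels = seq_len(nb)),
                              sum, default = 0))
    area <- traj$boxes[fi, 1] * traj$boxes[fi, 2]
    acc <- acc + sums / (area * dz)
  }
  structure(data.frame(z = (edges[-1] + edges[-length(edges)]) / 2,
                       density = acc / n_frames(traj)),
            label = label, units = "amu/A^3",
            class = c("density_profile", "data.frame"))
}
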
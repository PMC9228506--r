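# Solute configuration statistics: dz position, ring orientation theta,
# side-chain angle alpha, 2D free-energy surfaces, insertion/translocation
# event detection, and aggregation (cluster) analysis.

#' Signed solute position along the membrane normal
#'
#' Per frame, the z component of (solute reference-group COM minus bilayer
#' COM), both PBC-reassembled.  This is the permeation reaction coordinate.
#'
#' @param traj a [trajectory()]
#' @param ring_indices atom indices of the solute reference group (benzene
#'   ring)
#' @param lipid_indices atom indices defining the bilayer COM
#' @param mass_weighted use mass weighting for both COMs (default TRUE)
#' @return numeric vector of dz per frame, Angstrom
#' @export
solute_dz <- function(traj, ring_indices, lipid_indices,
                      mass_weighted = TRUE) {
  vapply(seq_len(n_frames(traj)), function(i) {
    fr <- get_frame(traj, i)
    center_of_mass(fr, traj$topology, ring_indices, mass_weighted)[3] -
      center_of_mass(fr, traj$topology, lipid_indices, mass_weighted)[3]
  }, numeric(1))
}

#' Ring orientation angle theta
#'
#' Two conventions for "the orientation of the benzene ring against z":
#' `in_plane_axis` (default) measures the para axis, the in-plane vector
#' from ring atom 1 to ring atom 4 — a ring lying flat in the membrane
#' plane then gives theta = 90 degrees; `plane_normal` measures the
#' SVD-fitted ring-plane normal — a flat-lying ring then gives 0.  Both
#' are folded to [0, 90] degrees (the ring axis is unsigned).
#'
#' @param fr a [frame()]
#' @param ring_indices ring atom indices in ring order (>= 3 non-collinear;
#'   >= 4 for the para-axis convention)
#' @param convention `"in_plane_axis"` or `"plane_normal"`
#' @return angle in degrees, [0, 90]
#' @export
ring_angle_theta <- function(fr, ring_indices,
                             convention = c("in_plane_axis", "plane_normal")) {
  convention <- match.arg(convention)
  xyz <- make_whole(fr$xyz[ring_indices, , drop = FALSE], fr$box)
  if (convention == "in_plane_axis") {
    if (length(ring_indices) < 4L) stop("para-axis convention needs >= 4 ring atoms")
    v <- xyz[4, ] - xyz[1, ]
    a <- vector_angle(v, c(0, 0, 1))
  } else {
    if (length(ring_indices) < 3L) stop("plane fit needs >= 3 ring atoms")
    cen <- sweep(xyz, 2, colMeans(xyz))
    sv <- svd(cen)
    if (sv$d[2] < 1e-8 * sv$d[1]) stop("ring atoms are collinear; no plane defined")
    a <- vector_angle(sv$v[, 3], c(0, 0, 1))
  }
  min(a, 180 - a)
}

#' Angle alpha between the two solute side chains
#'
#' Arc-cosine of the normalised dot product of the two chain vectors,
#' each given by a (from, to) atom index pair; minimum-image displacements.
#'
#' @param fr a [frame()]
#' @param chain1,chain2 length-2 integer vectors (from, to)
#' @return angle in degrees, [0, 180]
#' @export
chain_angle_alpha <- function(fr, chain1, chain2) {
  v1 <- minimum_image(fr$xyz[chain1[2], ] - fr$xyz[chain1[1], ], fr$box)
  v2 <- minimum_image(fr$xyz[chain2[2], ] - fr$xyz[chain2[1], ], fr$box)
  vector_angle(v1, v2)
}

#' Two-dimensional free-energy surface from (dz, theta) occupancy
#'
#' `F(bin) = -kB T ln(count / max count)`: the modal bin sits at zero and
#' every other defined bin is positive.  Empty bins are undefined (NA),
#' never zero-filled.  Invariant under rescaling all counts by a constant.
#'
#' @param dz per-frame dz values, Angstrom
#' @param theta per-frame theta values, degrees (aligned with `dz`)
#' @param dz_edges,theta_edges bin edges
#' @param temperature K
#' @return object of class `"fes"`: `dz_edges`, `theta_edges`, `counts`
#'   matrix, `F` matrix (kcal mol-1), `temperature`
#' @export
free_energy_surface <- function(dz, theta, dz_edges, theta_edges,
                                temperature = 303.15) {
  stopifnot(length(dz) == length(theta), temperature > 0)
  nd <- length(dz_edges) - 1L; nt <- length(theta_edges) - 1L
  bi <- findInterval(dz, dz_edges, rightmost.closed = TRUE)
  bj <- findInterval(theta, theta_edges, rightmost.closed = TRUE)
  ok <- bi >= 1L & bi <= nd & bj >= 1L & bj <= nt
  counts <- matrix(0L, nd, nt)
  if (any(ok)) {
    tb <- table(factor(bi[ok], levels = seq_len(nd)),
                factor(bj[ok], levels = seq_len(nt)))
    counts <- matrix(as.integer(tb), nd, nt)
  }
  if (all(counts == 0L)) stop("all histogram bins are empty")
  F <- -kB_kcal * temperature * log(counts / max(counts))
  F[counts == 0L] <- NA_real_
  structure(list(dz_edges = dz_edges, theta_edges = theta_edges,
                 counts = counts, F = F, temperature = temperature),
            class = "fes")
}

#' Detect membrane insertion of a solute
#'
#' First frame index from which `|dz| < threshold` holds for at least
#' `persistence` consecutive frames; `NA` if the solute never inserts.
#' With `persistence = 1` this reduces to the first threshold crossing.
#'
#' @param dz per-frame dz series, Angstrom
#' @param threshold insertion threshold, Angstrom (> 0); the default sits
#'   near the phosphate plane of a fluid-phase bilayer
#' @param persistence minimum run length in frames
#' @return integer frame index or `NA_integer_`
#' @export
detect_insertion <- function(dz, threshold = 20, persistence = 10) {
  if (threshold <= 0) stop("threshold must be > 0")
  inside <- abs(dz) < threshold
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (!length(hit)) return(NA_integer_)
  as.integer(starts[hit[1]])
}

#' Count midplane translocation events with hysteresis
#'
#' An event is a transition from the state "dz > +band" to "dz < -band" or
#' vice versa; excursions that do not reach the opposite band never count,
#' so midplane chatter is suppressed.
#'
#' @param dz per-frame dz series, Angstrom
#' @param band half-width of the hysteresis band, Angstrom (> 0)
#' @return integer event count
#' @export
count_translocations <- function(dz, band = 5) {
  if (band <= 0) stop("band must be > 0")
  s <- sign(dz) * (abs(dz) > band)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Leaflet residence sequence of a solute
#'
#' Collapsed sequence of sides ("upper"/"lower") the solute occupies,
#' using the same hysteresis band as [count_translocations()].
#'
#' @inheritParams count_translocations
#' @return character vector of residence episodes
#' @export
residence_sequence <- function(dz, band = 5) {
  s <- sign(dz) * (abs(dz) > band)
  s <- s[s != 0]
  if (!length(s)) return(character(0))
  s <- s[c(TRUE, diff(s) != 0)]
  ifelse(s > 0, "upper", "lower")
}

#' Cluster solutes by minimum inter-atomic contact distance
#'
#' Single-linkage components of the graph joining two solutes whenever
#' their minimum-image minimum atom-atom distance is at most `cutoff`.
#'
#' @param fr a [frame()]
#' @param solute_indices list of atom index vectors, one per solute
#' @param cutoff contact distance, Angstrom (> 0); the default is a
#'   typical first-solvation-shell contact distance
#' @return list: `labels` (integer cluster id per solute), `sizes`
#'   (cluster size per solute)
#' @export
cluster_solutes <- function(fr, solute_indices, cutoff = 6) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  n <- length(solute_indices)
  if (n == 0L) return(list(labels = integer(0), sizes = integer(0)))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- fr$xyz[solute_indices[[i]], , drop = FALSE]
      b <- fr$xyz[solute_indices[[j]], , drop = FALSE]
      dmin <- Inf
      for (r in seq_len(nrow(a))) {
        d <- minimum_image(sweep(b, 2, a[r, ], FUN = "-"), fr$box)
        dmin <- min(dmin, sqrt(min(rowSums(d^2))))
      }
      adj[i, j] <- adj[j, i] <- dmin <= cutoff
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  labels <- as.integer(comp$membership)
  list(labels = labels, sizes = as.integer(comp$csize[labels]))
}

#' Per-solute insertion and translocation event report
#'
#' Combines [detect_insertion()], [count_translocations()] and
#' [residence_sequence()] per solute, and classifies the insertion mode as
#' `"single"` or `"clustered"` from the cluster size at the insertion
#' frame (when a trajectory and solute atom lists are supplied).
#'
#' @param dz_list list of per-solute dz series
#' @param threshold,persistence see [detect_insertion()]
#' @param band see [count_translocations()]
#' @param traj optional [trajectory()] for insertion-mode classification
#' @param solute_indices optional list of per-solute atom index vectors
#' @param cutoff cluster contact cutoff, Angstrom
#' @return data.frame of class `"event_report"`: one row per solute with
#'   `insertion_frame`, `translocation_count`, `insertion_mode`, plus the
#'   residence sequences as an attribute
#' @export
solute_event_report <- function(dz_list, threshold = 20, persistence = 10,
                                band = 5, traj = NULL,
                                solute_indices = NULL, cutoff = 6) {
  ins <- vapply(dz_list, detect_insertion, integer(1),
                threshold = threshold, persistence = persistence)
  trans <- vapply(dz_list, count_translocations, integer(1), band = band)
  mode <- rep(NA_character_, length(dz_list))
  if (!is.null(traj) && !is.null(solute_indices)) {
    for (i in seq_along(dz_list)) {
      if (is.na(ins[i])) next
      cl <- cluster_solutes(get_frame(traj, ins[i]), solute_indices, cutoff)
      mode[i] <- if (cl$sizes[i] == 1L) "single" else "clustered"
    }
  }
  structure(data.frame(solute = seq_along(dz_list), insertion_frame = ins,
                       translocation_count = trans, insertion_mode = mode),
            residence = lapply(dz_list, residence_sequence, band = band),
            class = c("event_report", "data.frame"))
}
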
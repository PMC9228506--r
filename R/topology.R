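# Topology, frames, trajectories and atom selection.
#
# Units everywhere: coordinates Angstrom, box edges Angstrom (orthorhombic
# only), time ns, mass amu.

#' Controlled vocabulary of atom role tags
#'
#' Roles tag atoms by their function in the analyses rather than by chemistry:
#' `lipid_P`/`lipid_N` are the phosphate and choline reference beads used for
#' thickness, leaflet assignment and P-N tilt; `sn1_chain`/`sn2_chain` mark
#' the acyl-chain atoms (order parameters, chain tilt); `ring` marks the
#' solute benzene ring (the permeation reaction-coordinate reference group);
#' `chain1`/`chain2` the two solute side chains; `carbonyl_O`/`alkyl_O` the
#' solute ester oxygens (hydrogen-bond acceptors); `water_O`/`water_H` the
#' solvent sites.
#' @export
role_vocabulary <- c(
  "lipid_P", "lipid_N", "glycerol", "sn1_chain", "sn2_chain",
  "ring", "chain1", "chain2", "carbonyl_O", "alkyl_O",
  "water_O", "water_H", "ion"
)

#' Molecule type labels recognised by the selection machinery
#' @export
molecule_vocabulary <- c("POPC", "DMP", "DBP", "DEHP", "water", "ion", "other")

#' Build a topology
#'
#' @param atoms data.frame with columns `atom_name`, `residue_name`,
#'   `residue_index` (>= 1), `mass` (amu, > 0) and `roles` (character,
#'   comma-separated role tags from [role_vocabulary], may be empty strings).
#' @param molecules data.frame with columns `start`, `end` (1-based atom
#'   index ranges, contiguous, partitioning the atom list) and `type`
#'   (see [molecule_vocabulary]).
#' @return object of class `"topology"`
#' @export
topology <- function(atoms, molecules) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  molecules <- as.data.frame(molecules, stringsAsFactors = FALSE)
  need <- c("atom_name", "residue_name", "residue_index", "mass", "roles")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(atoms$mass <= 0)) stop("all atom masses must be > 0")
  if (any(atoms$residue_index < 1)) stop("residue_index must be >= 1")
  tags <- unlist(strsplit(atoms$roles[nzchar(atoms$roles)], ",", fixed = TRUE))
  bad <- setdiff(unique(trimws(tags)), role_vocabulary)
  if (length(bad)) {
    stop("unknown role tag(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(role_vocabulary, collapse = ", "))
  }
  mol <- molecules[order(molecules$start), , drop = FALSE]
  if (nrow(mol) == 0L || mol$start[1] != 1L ||
      mol$end[nrow(mol)] != nrow(atoms) ||
      (nrow(mol) > 1L && any(mol$start[-1] != mol$end[-nrow(mol)] + 1L))) {
    stop("molecule ranges must partition the atom list contiguously")
  }
  structure(list(atoms = atoms, molecules = mol), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d molecules (%s)\n",
              nrow(x$atoms), nrow(x$molecules),
              paste(sprintf("%s: %d", names(table(x$molecules$type)),
                            as.integer(table(x$molecules$type))),
                    collapse = ", ")))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Molecule type label per atom
#' @param top a [topology()]
#' @return character vector, one entry per atom
#' @export
atom_molecule_type <- function(top) {
  rep(top$molecules$type, top$molecules$end - top$molecules$start + 1L)
}

has_role <- function(top, role) {
  vapply(strsplit(top$atoms$roles, ",", fixed = TRUE),
         function(r) role %in% trimws(r), logical(1))
}

#' Selection specification
#'
#' All supplied filters are AND-combined.  An entirely empty spec is an
#' error (use explicit filters; "select everything" is never implicit).
#'
#' @param molecule_type optional molecule type filter (see
#'   [molecule_vocabulary])
#' @param atom_name optional character vector of atom names
#' @param role optional character vector of role tags
#' @param residues optional integer vector of residue indices
#' @return object of class `"selection_spec"`
#' @export
selection_spec <- function(molecule_type = NULL, atom_name = NULL,
                           role = NULL, residues = NULL) {
  if (is.null(molecule_type) && is.null(atom_name) && is.null(role) &&
      is.null(residues)) {
    stop("empty selection spec: supply at least one filter")
  }
  structure(list(molecule_type = molecule_type, atom_name = atom_name,
                 role = role, residues = residues),
            class = "selection_spec")
}

#' Resolve a selection to atom indices
#'
#' Deterministic and order-preserving: indices come back in topology order.
#' Zero matches is an error naming the spec, so silently empty analyses
#' cannot happen.
#'
#' @param top a [topology()]
#' @param spec a [selection_spec()]
#' @return integer vector of 1-based atom indices
#' @export
select_atoms <- function(top, spec) {
  stopifnot(inherits(top, "topology"), inherits(spec, "selection_spec"))
  keep <- rep(TRUE, n_atoms(top))
  if (!is.null(spec$molecule_type)) {
    keep <- keep & atom_molecule_type(top) %in% spec$molecule_type
  }
  if (!is.null(spec$atom_name)) {
    keep <- keep & top$atoms$atom_name %in% spec$atom_name
  }
  if (!is.null(spec$role)) {
    rk <- rep(FALSE, n_atoms(top))
    for (r in spec$role) rk <- rk | has_role(top, r)
    keep <- keep & rk
  }
  if (!is.null(spec$residues)) {
    keep <- keep & top$atoms$residue_index %in% spec$residues
  }
  idx <- which(keep)
  if (!length(idx)) {
    stop("selection matched zero atoms: ",
         paste(vapply(
           Filter(Negate(is.null), unclass(spec)[!vapply(unclass(spec), is.null, TRUE)]),
           function(v) paste(v, collapse = "/"), character(1)),
           collapse = ", "))
  }
  idx
}

#' Construct a single frame
#'
#' @param xyz numeric matrix, n_atoms x 3, Angstrom
#' @param box numeric length-3 orthorhombic box edges, Angstrom
#' @param time time stamp, ns
#' @return object of class `"frame"`
#' @export
frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  if (!all(is.finite(xyz))) stop("positions must be finite")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) {
    stop("box must be three positive orthorhombic edge lengths")
  }
  structure(list(xyz = unname(xyz), box = box, time = as.numeric(time)),
            class = "frame")
}

#' Bundle a topology with time-ordered frames
#'
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array.  The
#' `unwrapped` flag records whether coordinates are continuous across the
#' periodic boundary (required for mean-squared-displacement analysis).
#'
#' @param top a [topology()]
#' @param frames list of [frame()] objects with strictly increasing times
#' @param unwrapped logical; TRUE if coordinates are unwrapped
#' @return object of class `"trajectory"`
#' @export
trajectory <- function(top, frames, unwrapped = FALSE) {
  stopifnot(inherits(top, "topology"), length(frames) >= 1L)
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  na <- n_atoms(top)
  for (f in frames) {
    if (nrow(f$xyz) != na) stop("frame atom count does not match topology")
  }
  coords <- array(NA_real_, c(na, 3L, length(frames)))
  boxes <- matrix(NA_real_, length(frames), 3L)
  for (i in seq_along(frames)) {
    coords[, , i] <- frames[[i]]$xyz
    boxes[i, ] <- frames[[i]]$box
  }
  structure(list(topology = top, coords = coords, boxes = boxes,
                 times = times, unwrapped = unwrapped),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d atoms x %d frames, t = %.4g..%.4g ns, %s coordinates\n",
    dim(x$coords)[1], dim(x$coords)[3], x$times[1],
    x$times[length(x$times)], if (isTRUE(x$unwrapped)) "unwrapped" else "wrapped"))
  print(x$topology)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()]
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame from a trajectory
#' @param traj a [trajectory()]
#' @param i frame index (1-based)
#' @export
get_frame <- function(traj, i) {
  frame(traj$coords[, , i, drop = TRUE], traj$boxes[i, ], traj$times[i])
}

#' Apply a role-tag configuration to a topology
#'
#' Maps atom names (optionally per molecule type) to role tags, the way an
#' analysis config names "the phosphorus atoms" or "the ring carbons".  The
#' config is a named list `role -> character vector of atom names`, or a
#' YAML file with that structure.  Existing roles are replaced.
#'
#' @param top a [topology()]
#' @param config named list or path to a YAML file
#' @return topology with `roles` rebuilt from the config
#' @export
apply_role_config <- function(top, config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  bad <- setdiff(names(config), role_vocabulary)
  if (length(bad)) stop("unknown role(s) in config: ", paste(bad, collapse = ", "))
  roles <- rep("", n_atoms(top))
  for (role in names(config)) {
    hit <- top$atoms$atom_name %in% config[[role]]
    roles[hit] <- ifelse(nzchar(roles[hit]), paste0(roles[hit], ",", role), role)
  }
  top$atoms$roles <- roles
  topology(top$atoms, top$molecules)
}
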
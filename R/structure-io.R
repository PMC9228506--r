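# Structure file I/O (GRO, PDB) and the plain-text trajectory container.
#
# GRO files store nm; everything in memory is Angstrom, converted on
# read/write.  Only orthorhombic boxes are supported: a GRO box line with
# off-diagonal components, or CRYST1 angles differing from 90 degrees, is
# rejected explicitly.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, NA. = 22.990, CL = 35.45)

guess_mass <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", atom_name))
  first <- substr(nm, 1, 1)
  out <- unname(.element_masses[first])
  out[nm %in% c("NA", "SOD")] <- .element_masses[["NA."]]
  out[nm %in% c("CL", "CLA")] <- .element_masses[["CL"]]
  out[is.na(out)] <- 12.011
  out
}

.molecule_type_of <- function(resname) {
  up <- toupper(resname)
  ifelse(up == "POPC", "POPC",
  ifelse(up %in% c("DMP", "DBP", "DEHP"), up,
  ifelse(up %in% c("SOL", "TIP3", "WAT", "HOH", "SPC"), "water",
  ifelse(up %in% c("NA", "CL", "SOD", "CLA", "K", "POT", "ION"), "ion",
         "other"))))
}

# Build the molecules table from contiguous runs of (residue_index, resname).
.molecules_from_residues <- function(resid, resname) {
  brk <- c(TRUE, resid[-1] != resid[-length(resid)] |
                 resname[-1] != resname[-length(resname)])
  start <- which(brk)
  end <- c(start[-1] - 1L, length(resid))
  data.frame(start = start, end = end,
             type = .molecule_type_of(resname[start]),
             stringsAsFactors = FALSE)
}

#' Read a structure file
#'
#' @param path file path
#' @param format `"gro"` or `"pdb"`; default guessed from the extension
#' @return list with elements `topology` and `frame`
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, gro = read_gro(path), pdb = read_pdb_structure(path))
}

#' Write a structure file
#'
#' @param top a [topology()]
#' @param fr a [frame()]
#' @param path output path
#' @param format `"gro"` or `"pdb"`
#' @export
write_structure <- function(top, fr, path, format = c("gro", "pdb")) {
  format <- match.arg(format)
  switch(format, gro = write_gro(top, fr, path), pdb = write_pdb_structure(top, fr, path))
}

#' @rdname read_structure
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("GRO file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("GRO parse error at line 2: atom count expected")
  if (length(lines) < n + 3L) stop("GRO file truncated: expected ", n, " atoms")
  at <- lines[3:(n + 2L)]
  resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
  resname <- trimws(substr(at, 6, 10))
  aname <- trimws(substr(at, 11, 15))
  x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) stop("GRO parse error at line ", bad[1] + 2L, ": ",
                        sQuote(at[bad[1]]))
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3L]), "\\s+")[[1]]))
  if (length(boxv) < 3L || anyNA(boxv[1:3])) {
    stop("GRO parse error at line ", n + 3L, ": box line expected")
  }
  if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-9)) {
    stop("triclinic GRO box not supported (off-diagonal components present)")
  }
  atoms <- data.frame(atom_name = aname, residue_name = resname,
                      residue_index = resid, mass = guess_mass(aname),
                      roles = "", stringsAsFactors = FALSE)
  top <- topology(atoms, .molecules_from_residues(resid, resname))
  fr <- frame(cbind(x, y, z) * 10, boxv[1:3] * 10, 0)
  list(topology = top, frame = fr)
}

#' @rdname write_structure
#' @export
write_gro <- function(top, fr, path) {
  n <- n_atoms(top)
  xyz_nm <- fr$xyz / 10
  lines <- c(
    "generated by memperm",
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            top$atoms$residue_index %% 100000L,
            substr(top$atoms$residue_name, 1, 5),
            substr(top$atoms$atom_name, 1, 5),
            seq_len(n) %% 100000L,
            xyz_nm[, 1], xyz_nm[, 2], xyz_nm[, 3]),
    sprintf("%10.5f%10.5f%10.5f", fr$box[1] / 10, fr$box[2] / 10, fr$box[3] / 10)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_structure
#' @export
read_pdb_structure <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) stop("PDB file has no CRYST1 record; box is required: ", path)
  f <- suppressWarnings(as.numeric(c(
    substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33),
    substr(cr[1], 34, 40), substr(cr[1], 41, 47), substr(cr[1], 48, 54))))
  if (anyNA(f[1:3])) stop("malformed CRYST1 record in ", path)
  if (any(abs(f[4:6] - 90) > 1e-6)) {
    stop("triclinic PDB box not supported (CRYST1 angles must be 90)")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(atom_name = a$elety, residue_name = a$resid,
                      residue_index = a$resno, mass = guess_mass(a$elety),
                      roles = "", stringsAsFactors = FALSE)
  top <- topology(atoms, .molecules_from_residues(a$resno, a$resid))
  fr <- frame(cbind(a$x, a$y, a$z), f[1:3], 0)
  list(topology = top, frame = fr)
}

#' @rdname write_structure
#' @export
write_pdb_structure <- function(top, fr, path) {
  n <- n_atoms(top)
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            fr$box[1], fr$box[2], fr$box[3], 90, 90, 90),
    sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
            seq_len(n) %% 100000L,
            substr(top$atoms$atom_name, 1, 4),
            substr(top$atoms$residue_name, 1, 4),
            top$atoms$residue_index %% 10000L,
            fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]),
    "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory to a plain-text directory container
#'
#' Layout (all whitespace-delimited text, documented here and in the
#' package vignette): `meta.json` (atom/frame counts, unwrapped flag),
#' `topology.csv` (atom table + molecule table), `times.dat` (one time per
#' line, ns), `boxes.dat` (n_frames rows x 3, Angstrom), `positions.dat`
#' (n_frames * n_atoms rows x 3, frame-major, Angstrom).
#'
#' @param traj a [trajectory()]
#' @param dir output directory (created if needed)
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  na <- dim(traj$coords)[1]; nf <- dim(traj$coords)[3]
  jsonlite::write_json(
    list(n_atoms = na, n_frames = nf, unwrapped = isTRUE(traj$unwrapped),
         units = list(length = "Angstrom", time = "ns")),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  data.table::fwrite(traj$topology$atoms, file.path(dir, "atoms.csv"))
  data.table::fwrite(traj$topology$molecules, file.path(dir, "molecules.csv"))
  data.table::fwrite(data.table::as.data.table(traj$boxes),
                     file.path(dir, "boxes.dat"), sep = " ", col.names = FALSE)
  writeLines(format(traj$times, digits = 12), file.path(dir, "times.dat"))
  # rows ordered frame-major: frame 1 atoms 1..n, frame 2 atoms 1..n, ...
  pos <- do.call(rbind, lapply(seq_len(nf), function(i) traj$coords[, , i]))
  data.table::fwrite(data.table::as.data.table(pos),
                     file.path(dir, "positions.dat"), sep = " ", col.names = FALSE)
  invisible(dir)
}

#' Read a trajectory from the plain-text directory container
#'
#' @param dir directory written by [write_trajectory()]
#' @return a [trajectory()]
#' @export
read_trajectory <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  atoms <- as.data.frame(data.table::fread(file.path(dir, "atoms.csv")))
  atoms$roles[is.na(atoms$roles)] <- ""
  mols <- as.data.frame(data.table::fread(file.path(dir, "molecules.csv")))
  top <- topology(atoms, mols)
  times <- as.numeric(readLines(file.path(dir, "times.dat")))
  boxes <- as.matrix(data.table::fread(file.path(dir, "boxes.dat")))
  pos <- as.matrix(data.table::fread(file.path(dir, "positions.dat")))
  na <- meta$n_atoms; nf <- meta$n_frames
  coords <- array(NA_real_, c(na, 3L, nf))
  for (i in seq_len(nf)) coords[, , i] <- pos[((i - 1L) * na + 1L):(i * na), ]
  structure(list(topology = top, coords = coords,
                 boxes = matrix(boxes, nf, 3L), times = times,
                 unwrapped = isTRUE(meta$unwrapped)),
            class = "trajectory")
}
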
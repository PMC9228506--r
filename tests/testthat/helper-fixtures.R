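# Fixture builders and independent brute-force oracles shared by the suite.

# 3-atom GRO text with the 66 x 66 x 90 A box (GRO stores nm).
tiny_gro_lines <- function() {
  c("tiny fixture",
    "    3",
    "    1POPC    P    1   1.000   2.000   3.000",
    "    1POPC    N    2   1.100   2.100   3.100",
    "    2SOL    OW    3   4.000   4.000   4.000",
    "   6.60000   6.60000   9.00000")
}

# minimal topology of n single-atom particles (for walks / RDF fixtures)
particle_topology <- function(n, type = "ion", name = "NA", mass = 22.99) {
  topology(
    data.frame(atom_name = rep(name, n), residue_name = rep(name, n),
               residue_index = seq_len(n), mass = rep(mass, n),
               roles = rep("ion", n), stringsAsFactors = FALSE),
    data.frame(start = seq_len(n), end = seq_len(n), type = rep(type, n),
               stringsAsFactors = FALSE))
}

# trajectory of independent 2D random walks with known diffusion constant
random_walk_trajectory <- function(n_particles, n_steps, d_A2_ns, dt = 0.1,
                                   box = 1000) {
  top <- particle_topology(n_particles)
  sdev <- sqrt(2 * d_A2_ns * dt)
  frames <- vector("list", n_steps)
  xyz <- cbind(runif(n_particles, 0, box), runif(n_particles, 0, box),
               rep(box / 2, n_particles))
  for (i in seq_len(n_steps)) {
    if (i > 1L) {
      xyz[, 1] <- xyz[, 1] + rnorm(n_particles, 0, sdev)
      xyz[, 2] <- xyz[, 2] + rnorm(n_particles, 0, sdev)
    }
    frames[[i]] <- frame(xyz, rep(box, 3), time = (i - 1) * dt)
  }
  trajectory(top, frames, unwrapped = TRUE)
}

# Brute-force COM over explicit periodic images: for every non-anchor atom
# try shifts of -1, 0, +1 boxes per axis and take the image closest to the
# anchor, then average.  Independent of make_whole().
bf_com_images <- function(xyz, box, masses) {
  anchor <- xyz[1, ]
  out <- xyz
  for (i in seq_len(nrow(xyz))[-1]) {
    best <- NULL; bestd <- Inf
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      cand <- xyz[i, ] + c(sx, sy, sz) * box
      d <- sum((cand - anchor)^2)
      if (d < bestd) { bestd <- d; best <- cand }
    }
    out[i, ] <- best
  }
  colSums(out * masses) / sum(masses)
}

# Brute-force single-linkage clustering by union-find over all pairs.
bf_clusters <- function(fr, solute_indices, cutoff) {
  n <- length(solute_indices)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mindist <- function(a, b) {
    dmin <- Inf
    for (p in a) for (q in b) {
      d <- minimum_image(fr$xyz[q, ] - fr$xyz[p, ], fr$box)
      dmin <- min(dmin, sqrt(sum(d^2)))
    }
    dmin
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && mindist(solute_indices[[i]], solute_indices[[j]]) <= cutoff) {
      parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Brute-force hydrogen-bond triple enumeration.
bf_hbond <- function(fr, hydrogens, donor_of, acceptors, d_cut, angle_cut) {
  count <- 0L
  for (i in seq_along(hydrogens)) {
    for (a in acceptors) {
      if (a == donor_of[i]) next
      ha <- minimum_image(fr$xyz[a, ] - fr$xyz[hydrogens[i], ], fr$box)
      if (sqrt(sum(ha^2)) > d_cut || sum(ha^2) == 0) next
      hd <- minimum_image(fr$xyz[donor_of[i], ] - fr$xyz[hydrogens[i], ], fr$box)
      ang <- acos(min(1, max(-1, sum(ha * hd) /
                               sqrt(sum(ha^2) * sum(hd^2))))) * 180 / pi
      if (ang >= angle_cut) count <- count + 1L
    }
  }
  count
}

# Brute-force translocation state machine.
bf_translocations <- function(dz, band) {
  state <- 0L; events <- 0L
  for (v in dz) {
    s <- if (v > band) 1L else if (v < -band) -1L else 0L
    if (s != 0L) {
      if (state != 0L && s != state) events <- events + 1L
      state <- s
    }
  }
  events
}

# i.i.d. samples from exp(-U/kT) on [lo, hi] by rejection sampling --
# the independent route to the Boltzmann distribution (no dynamics).
boltzmann_rejection_sample <- function(pot, n, temperature, lo, hi) {
  kT <- kB_kcal * temperature
  grid <- seq(lo, hi, length.out = 4001)
  umin <- min(potential_energy(pot, grid))
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 100L
    z <- runif(m, lo, hi)
    keep <- log(runif(m)) < -(potential_energy(pot, z) - umin) / kT
    out <- c(out, z[keep])
  }
  out[seq_len(n)]
}

# shared landscape mirroring an interfacial entry barrier, an interfacial
# well and a midplane barrier (heights 2.14 / -5.0 / -4.0 kcal/mol); the
# terms are narrow enough that each extremum equals its height to < 0.005
permeation_landscape <- function() {
  potential_spec(heights = c(2.14, -5.0, -4.0), centers = c(20, 12, 0),
                 widths = c(2, 2, 3))
}

# anchored exact PMF of a potential evaluated at given bin centres
anchored_exact_pmf <- function(pot, z, temperature, region = c(30, 35)) {
  ex <- exact_pmf(pot, z, temperature)
  ex$F - mean(ex$F[z >= region[1] & z <= region[2]])
}

# n_a + n_b ideal-gas atoms resampled uniformly every frame
make_gas_trajectory <- function(n_a, n_b, box, n_frames, seed) {
  set.seed(seed)
  top <- particle_topology(n_a + n_b)
  frames <- lapply(seq_len(n_frames), function(i)
    frame(matrix(runif((n_a + n_b) * 3, 0, box), ncol = 3), rep(box, 3),
          time = i - 1))
  trajectory(top, frames)
}

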
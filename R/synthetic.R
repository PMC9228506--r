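# Synthetic bilayer + solute trajectories with known ground truth.
#
# The lipid model is deliberately minimal geometry, not chemistry: one
# phosphate bead, one choline bead, one glycerol bead and two straight
# 8-bead tails per lipid — the least structure that supports P-N tilt,
# per-chain order parameters, thickness and lateral diffusion.  Chain
# orientations are drawn from a Maier-Saupe-type distribution whose order
# parameter is exactly the requested Scd; within a frame each chain is
# straight, so the measured central-difference order parameter recovers
# the target without geometric bias.

#' Ground-truth parameters of a synthetic bilayer
#'
#' @param lipids_per_leaflet lipids per leaflet (>= 4)
#' @param target_apl area per lipid, A^2
#' @param target_thickness phosphate-plane separation, A
#' @param target_scd chain order parameter in [-0.5, 1]
#' @param d_lateral lipid lateral diffusion constant, nm^2 ns^-1 (>= 0)
#' @param pn_tilt_mean,pn_tilt_width P-N vector tilt vs z, degrees
#' @param positional_jitter per-frame positional noise, A
#' @param n_frames,dt frames and frame spacing (ns)
#' @param seed RNG seed
#' @return object of class `"bilayer_params"`
#' @export
bilayer_params <- function(lipids_per_leaflet = 64, target_apl = 68.0625,
                           target_thickness = 38, target_scd = 0.2,
                           d_lateral = 0.01, pn_tilt_mean = 72,
                           pn_tilt_width = 10, positional_jitter = 0.5,
                           n_frames = 200, dt = 0.1, seed = 1L) {
  if (lipids_per_leaflet < 4) stop("lipids_per_leaflet must be >= 4")
  if (target_scd < -0.5 || target_scd > 1) stop("target_scd must be in [-0.5, 1]")
  if (d_lateral < 0) stop("d_lateral must be >= 0")
  spacing <- sqrt(target_apl)
  if (4 * positional_jitter > spacing) {
    stop("positional_jitter too large for the requested area per lipid: lipids would overlap")
  }
  structure(as.list(environment()), class = "bilayer_params")
}

#' Ground-truth parameters of synthetic solutes
#'
#' Species templates fix the side-chain lengths: 1 bead for DMP, 4 for
#' DBP, 8 for DEHP; the ring is always 6 beads.
#'
#' @param n_solutes number of solutes (>= 0)
#' @param species `"DMP"`, `"DBP"` or `"DEHP"`
#' @param dz_mean,dz_width solute dz distribution, A
#' @param theta_mean,theta_width ring para-axis tilt distribution, degrees
#' @param alpha_mean,alpha_width side-chain opening angle, degrees
#' @param cluster_mode `"single"` (uniform lateral placement) or
#'   `"clustered"` (all solutes within `cluster_radius` of a seed solute)
#' @param cluster_radius lateral clustering radius, A
#' @param seed RNG seed
#' @return object of class `"solute_params"`
#' @export
solute_params <- function(n_solutes = 8, species = c("DMP", "DBP", "DEHP"),
                          dz_mean = 12, dz_width = 2, theta_mean = 90,
                          theta_width = 10, alpha_mean = 90,
                          alpha_width = 15,
                          cluster_mode = c("single", "clustered"),
                          cluster_radius = 6, seed = 1L) {
  species <- match.arg(species)
  cluster_mode <- match.arg(cluster_mode)
  if (n_solutes < 0) stop("n_solutes must be >= 0")
  chain_len <- c(DMP = 1L, DBP = 4L, DEHP = 8L)[[species]]
  structure(c(as.list(environment())), class = "solute_params")
}

# Solve the Maier-Saupe concentration parameter lambda such that
# <P2(cos theta)> under p(c) ~ exp(lambda P2(c)) equals the target.
.p2 <- function(c) 0.5 * (3 * c^2 - 1)

.mean_p2 <- function(lambda) {
  num <- stats::integrate(function(c) .p2(c) * exp(lambda * (.p2(c) - 1)),
                          -1, 1, rel.tol = 1e-10)$value
  den <- stats::integrate(function(c) exp(lambda * (.p2(c) - 1)),
                          -1, 1, rel.tol = 1e-10)$value
  num / den
}

.lambda_for_scd <- function(target) {
  if (abs(target) < 1e-12) return(0)
  stats::uniroot(function(l) .mean_p2(l) - target,
                 lower = -400, upper = 400, tol = 1e-10)$root
}

#' Sample unit vectors with a prescribed orientational order parameter
#'
#' Draws orientations from the Maier-Saupe distribution
#' `p(cos theta) ~ exp(lambda P2(cos theta))` with lambda solved so that
#' `<P2> = target_scd` exactly; azimuth uniform.  `target_scd = 1` returns
#' the z axis deterministically, `target_scd = 0` is isotropic, and
#' `target_scd = -0.5` confines vectors to the xy plane.
#'
#' @param target_scd target order parameter in [-0.5, 1]
#' @param n number of vectors
#' @return n x 3 matrix of unit vectors
#' @export
sample_chain_orientation <- function(target_scd, n = 1) {
  if (target_scd < -0.5 || target_scd > 1) {
    stop("target_scd must be in [-0.5, 1]")
  }
  if (target_scd > 0.9995) {
    c <- rep(1, n)
  } else if (target_scd < -0.4995) {
    c <- rep(0, n)
  } else {
    lambda <- .lambda_for_scd(target_scd)
    # rejection sampling with a uniform envelope on cos theta
    logM <- max(lambda * .p2(c(-1, 0, 1)))
    c <- numeric(0)
    while (length(c) < n) {
      m <- max(2L * (n - length(c)), 100L)
      cand <- stats::runif(m, -1, 1)
      acc <- log(stats::runif(m)) < lambda * .p2(cand) - logM
      c <- c(c, cand[acc])
    }
    c <- c[seq_len(n)]
  }
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - c^2))
  cbind(s * cos(phi), s * sin(phi), c)
}

# Bead masses (amu): coarse but positive and stable across analyses.
.bead_masses <- c(P = 94.97, N = 87.16, GL = 41.07, CH2 = 14.03,
                  CR = 13.02, OW = 15.999, HW = 1.008)

.hexagon <- function(radius = 1.39) {
  phi <- (0:5) * pi / 3
  cbind(cos(phi), sin(phi), 0) * radius
}

#' Generate a synthetic bilayer (+ solutes) trajectory with ground truth
#'
#' Lipids sit on a lattice whose cell area is exactly `target_apl`, so the
#' measured area per lipid is exact by construction; phosphate planes sit
#' at +/- `target_thickness / 2` with zero-mean jitter; tails are straight
#' chains re-oriented each frame from the order-parameter distribution;
#' lipid centres random-walk laterally with the requested diffusion
#' constant (coordinates are kept unwrapped).  Solutes are placed by their
#' per-frame (dz, theta, alpha) draws.
#'
#' @param bp a [bilayer_params()]
#' @param sp optional [solute_params()]
#' @return list: `trajectory` (a [trajectory()]) and `truth` (generator
#'   ground-truth record: targets, leaflet labels, per-frame solute
#'   dz/theta/alpha draws, key index sets)
#' @export
generate_bilayer_trajectory <- function(bp, sp = NULL) {
  stopifnot(inherits(bp, "bilayer_params"))
  set.seed(bp$seed)
  L <- bp$lipids_per_leaflet
  box_xy <- sqrt(L * bp$target_apl)
  box_z <- bp$target_thickness + 52
  box <- c(box_xy, box_xy, box_z)

  tail_len <- 8L; bond <- 1.53
  beads_per_lipid <- 3L + 2L * tail_len
  n_lip <- 2L * L

  # lattice sites (first L cells of the smallest square grid)
  m <- ceiling(sqrt(L))
  cell <- box_xy / m
  sites <- expand.grid(x = (seq_len(m) - 0.5) * cell,
                       y = (seq_len(m) - 0.5) * cell)[seq_len(L), ]

  atom_name <- character(0); res_name <- character(0)
  res_idx <- integer(0); mass <- numeric(0); roles <- character(0)
  mol <- list()
  for (i in seq_len(n_lip)) {
    atom_name <- c(atom_name, "P", "N", "GL",
                   paste0("C1", seq_len(tail_len)),
                   paste0("C2", seq_len(tail_len)))
    res_name <- c(res_name, rep("POPC", beads_per_lipid))
    res_idx <- c(res_idx, rep(i, beads_per_lipid))
    mass <- c(mass, .bead_masses[["P"]], .bead_masses[["N"]],
              .bead_masses[["GL"]], rep(.bead_masses[["CH2"]], 2L * tail_len))
    roles <- c(roles, "lipid_P", "lipid_N", "glycerol",
               rep("sn1_chain", tail_len), rep("sn2_chain", tail_len))
    mol[[length(mol) + 1L]] <- "POPC"
  }
  n_sol <- if (is.null(sp)) 0L else sp$n_solutes
  ring_n <- 6L
  if (n_sol > 0L) {
    cl <- sp$chain_len
    for (s in seq_len(n_sol)) {
      atom_name <- c(atom_name, paste0("R", seq_len(ring_n)),
                     paste0("A", seq_len(cl)), paste0("B", seq_len(cl)))
      res_name <- c(res_name, rep(sp$species, ring_n + 2L * cl))
      res_idx <- c(res_idx, rep(n_lip + s, ring_n + 2L * cl))
      mass <- c(mass, rep(.bead_masses[["CR"]], ring_n),
                rep(.bead_masses[["CH2"]], 2L * cl))
      roles <- c(roles, rep("ring", ring_n), rep("chain1", cl),
                 rep("chain2", cl))
      mol[[length(mol) + 1L]] <- sp$species
    }
  }
  sizes <- c(rep(beads_per_lipid, n_lip),
             rep(ring_n + 2L * (if (n_sol) sp$chain_len else 0L), n_sol))
  ends <- cumsum(sizes)
  top <- topology(
    data.frame(atom_name = atom_name, residue_name = res_name,
               residue_index = res_idx, mass = mass, roles = roles,
               stringsAsFactors = FALSE),
    data.frame(start = ends - sizes + 1L, end = ends,
               type = unlist(mol), stringsAsFactors = FALSE))

  leaflet <- rep(c("upper", "lower"), each = L)
  sign_z <- ifelse(leaflet == "upper", 1, -1)
  half <- bp$target_thickness / 2
  d_A2 <- bp$d_lateral * 100          # nm^2/ns -> A^2/ns
  step_sd <- sqrt(2 * d_A2 * bp$dt)

  # lateral random walk of each lipid's anchor (unwrapped)
  walks <- array(0, c(n_lip, 2L, bp$n_frames))
  base_xy <- rbind(as.matrix(sites), as.matrix(sites))
  if (step_sd > 0 && bp$n_frames > 1L) {
    steps <- array(stats::rnorm(n_lip * 2L * (bp$n_frames - 1L), 0, step_sd),
                   c(n_lip, 2L, bp$n_frames - 1L))
    for (f in 2:bp$n_frames) walks[, , f] <- walks[, , f - 1L] + steps[, , f - 1L]
  }

  # solute lateral placement
  if (n_sol > 0L) {
    if (sp$cluster_mode == "clustered") {
      seed_xy <- stats::runif(2, 0, box_xy)
      ang <- stats::runif(n_sol, 0, 2 * pi)
      rad <- stats::runif(n_sol, 0, sp$cluster_radius)
      sol_xy <- cbind(seed_xy[1] + rad * cos(ang), seed_xy[2] + rad * sin(ang))
      sol_xy[1, ] <- seed_xy
    } else {
      sol_xy <- cbind(stats::runif(n_sol, 0, box_xy),
                      stats::runif(n_sol, 0, box_xy))
    }
    dz_draw <- matrix(stats::rnorm(n_sol * bp$n_frames, sp$dz_mean, sp$dz_width),
                      n_sol, bp$n_frames)
    th_draw <- matrix(stats::rnorm(n_sol * bp$n_frames, sp$theta_mean, sp$theta_width),
                      n_sol, bp$n_frames)
    th_draw <- abs(th_draw); th_draw <- ifelse(th_draw > 90, 180 - th_draw, th_draw)
    al_draw <- matrix(pmin(180, pmax(0, stats::rnorm(n_sol * bp$n_frames,
                                                     sp$alpha_mean, sp$alpha_width))),
                      n_sol, bp$n_frames)
  } else {
    dz_draw <- th_draw <- al_draw <- NULL
  }

  frames <- vector("list", bp$n_frames)
  na <- ends[length(ends)]
  for (f in seq_len(bp$n_frames)) {
    xyz <- matrix(NA_real_, na, 3L)
    # chain directions for this frame, one per chain per lipid
    dirs <- sample_chain_orientation(bp$target_scd, 2L * n_lip)
    tilts <- stats::rnorm(n_lip, bp$pn_tilt_mean, bp$pn_tilt_width) * pi / 180
    phis <- stats::runif(n_lip, 0, 2 * pi)
    for (i in seq_len(n_lip)) {
      o <- ends[i] - sizes[i]
      xy <- base_xy[i, ] + walks[i, , f]
      pz <- sign_z[i] * half + stats::rnorm(1, 0, bp$positional_jitter)
      p <- c(xy, pz)
      nvec <- c(sin(tilts[i]) * cos(phis[i]), sin(tilts[i]) * sin(phis[i]),
                cos(tilts[i]) * sign_z[i])
      gl <- p - c(0, 0, sign_z[i] * 2)
      xyz[o + 1L, ] <- p
      xyz[o + 2L, ] <- p + 4.5 * nvec
      xyz[o + 3L, ] <- gl
      for (t in 1:2) {
        d <- dirs[2L * (i - 1L) + t, ]
        if (sign(d[3]) == sign_z[i] && d[3] != 0) d <- -d  # tails point inward
        idx <- o + 3L + (t - 1L) * tail_len + seq_len(tail_len)
        xyz[idx, ] <- matrix(gl, tail_len, 3L, byrow = TRUE) +
          outer(bond * seq_len(tail_len), d)
      }
    }
    if (n_sol > 0L) {
      hex <- .hexagon()
      for (s in seq_len(n_sol)) {
        o <- ends[n_lip + s] - sizes[n_lip + s]
        th <- th_draw[s, f] * pi / 180
        u <- c(sin(th), 0, cos(th))       # para axis at angle theta to z
        w <- c(cos(th), 0, -sin(th))      # in-plane, perpendicular to u
        v2 <- c(0, 1, 0)
        ring <- t(vapply(seq_len(ring_n), function(k) {
          phi <- (k - 1) * pi / 3
          1.39 * (cos(phi) * u + sin(phi) * v2)
        }, numeric(3)))
        # para axis: atom 1 (+u) to atom 4 (-u)
        com <- c(sol_xy[s, ], dz_draw[s, f])
        ring <- sweep(ring, 2, com, FUN = "+")
        xyz[o + seq_len(ring_n), ] <- ring
        al <- al_draw[s, f] * pi / 180
        d1 <- cos(al / 2) * w + sin(al / 2) * v2
        d2 <- cos(al / 2) * w - sin(al / 2) * v2
        cl <- sp$chain_len
        xyz[o + ring_n + seq_len(cl), ] <-
          matrix(ring[2, ], cl, 3L, byrow = TRUE) + outer(bond * seq_len(cl), d1)
        xyz[o + ring_n + cl + seq_len(cl), ] <-
          matrix(ring[3, ], cl, 3L, byrow = TRUE) + outer(bond * seq_len(cl), d2)
      }
    }
    frames[[f]] <- frame(xyz, box, time = (f - 1L) * bp$dt)
  }
  traj <- trajectory(top, frames, unwrapped = TRUE)
  truth <- list(
    apl = bp$target_apl, thickness = bp$target_thickness,
    scd = bp$target_scd, d_lateral = bp$d_lateral, box = box,
    leaflet = leaflet,
    p_indices = which(has_role(top, "lipid_P")),
    solute_dz = dz_draw, solute_theta = th_draw, solute_alpha = al_draw,
    bilayer_params = bp, solute_params = sp)
  list(trajectory = traj, truth = truth)
}

#' Build a hydrogen-bond geometry fixture
#'
#' One carbonyl-oxygen acceptor and one rigid water, with the H...O
#' distance and the O-H...O angle (at the hydrogen) exactly as requested.
#' Used to pin RDF first peaks and hydrogen-bond criteria to a known
#' geometry.
#'
#' @param distance H...acceptor distance, Angstrom (> 0)
#' @param angle donor-H...acceptor angle, degrees
#' @param box cubic box edge, Angstrom
#' @return list: `topology`, `frame`, plus `hydrogens`, `donor_of`,
#'   `acceptors` index shortcuts
#' @export
make_hbond_fixture <- function(distance = 1.8, angle = 180, box = 50) {
  if (distance <= 0) stop("distance must be > 0")
  oh <- 0.9572; hoh <- 104.52 * pi / 180
  d_o <- c(0, 0, 0)
  h1 <- c(0, 0, oh)
  th <- (180 - angle) * pi / 180
  acc <- h1 + distance * c(sin(th), 0, cos(th))
  h2 <- oh * c(sin(hoh), 0, cos(hoh))
  center <- rep(box / 2, 3)
  xyz <- rbind(acc, d_o, h1, h2)
  xyz <- sweep(xyz, 2, center - d_o, FUN = "+")
  top <- topology(
    data.frame(atom_name = c("O1", "OW", "HW1", "HW2"),
               residue_name = c("DMP", "SOL", "SOL", "SOL"),
               residue_index = c(1L, 2L, 2L, 2L),
               mass = c(.bead_masses[["OW"]], .bead_masses[["OW"]],
                        .bead_masses[["HW"]], .bead_masses[["HW"]]),
               roles = c("carbonyl_O", "water_O", "water_H", "water_H"),
               stringsAsFactors = FALSE),
    data.frame(start = c(1L, 2L), end = c(1L, 4L),
               type = c("DMP", "water"), stringsAsFactors = FALSE))
  list(topology = top, frame = frame(xyz, rep(box, 3)),
       hydrogens = c(3L, 4L), donor_of = c(2L, 2L), acceptors = 1L)
}
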
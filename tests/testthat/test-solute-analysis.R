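# Solute position/orientation statistics, free-energy surfaces, event
# detection and aggregation analysis.

test_that("solute dz is the signed ring-bilayer COM separation", {
  top <- particle_topology(2)
  fr <- frame(rbind(c(5, 5, 30), c(5, 5, 0)), c(66, 66, 90))
  tr <- trajectory(top, list(fr))
  expect_equal(solute_dz(tr, 1L, 2L), 30)
  # reflecting all z flips the sign
  fr2 <- frame(cbind(fr$xyz[, 1:2], -fr$xyz[, 3]), fr$box)
  expect_equal(solute_dz(trajectory(top, list(fr2)), 1L, 2L), -30)
})

test_that("generator dz distribution is recovered", {
  g <- generate_bilayer_trajectory(
    bilayer_params(lipids_per_leaflet = 16, n_frames = 150, seed = 41),
    solute_params(n_solutes = 1, dz_mean = 12, dz_width = 1, seed = 41))
  tr <- g$trajectory
  ring <- select_atoms(tr$topology, selection_spec(role = "ring"))
  lip <- select_atoms(tr$topology, selection_spec(molecule_type = "POPC"))
  dz <- solute_dz(tr, ring, lip)
  expect_lt(abs(mean(dz) - 12), 0.2)
  # dz/theta/alpha means within 3 standard errors of generator truth
  th <- vapply(seq_len(n_frames(tr)), function(i)
    ring_angle_theta(get_frame(tr, i), ring), numeric(1))
  tdraw <- g$truth$solute_theta[1, ]
  expect_lt(abs(mean(th) - mean(tdraw)), 3 * sd(tdraw) / sqrt(length(tdraw)) + 1e-6)
  ch1 <- select_atoms(tr$topology, selection_spec(role = "chain1"))
  ch2 <- select_atoms(tr$topology, selection_spec(role = "chain2"))
  # chain vectors run from the ring attachment atom to the chain end
  al <- vapply(seq_len(n_frames(tr)), function(i)
    chain_angle_alpha(get_frame(tr, i), c(ring[2], max(ch1)),
                      c(ring[3], max(ch2))), numeric(1))
  expect_lt(abs(mean(al) - mean(g$truth$solute_alpha[1, ])),
            3 * sd(al) / sqrt(length(al)) + 1e-6)
})

test_that("ring angle conventions behave as defined", {
  hexagon <- function() {
    phi <- (0:5) * pi / 3
    cbind(cos(phi), sin(phi), 0) * 1.39
  }
  box <- c(50, 50, 50)
  # ring flat in the xy plane: para axis in-plane -> 90; plane normal -> 0
  flat <- sweep(hexagon(), 2, c(25, 25, 25), FUN = "+")
  expect_equal(ring_angle_theta(frame(flat, box), 1:6), 90)
  expect_equal(ring_angle_theta(frame(flat, box), 1:6, "plane_normal"), 0)
  # ring plane containing z, para axis along z -> 0 (default convention)
  upright <- hexagon()[, c(3, 2, 1)]  # para axis now along z
  upright <- sweep(upright, 2, c(25, 25, 25), FUN = "+")
  expect_equal(ring_angle_theta(frame(upright, box), 1:6), 0)
  # para axis at 45 degrees
  rot <- hexagon() %*% t(matrix(c(cos(pi / 4), 0, sin(pi / 4),
                                  0, 1, 0,
                                  -sin(pi / 4), 0, cos(pi / 4)), 3, byrow = TRUE))
  rot <- sweep(rot, 2, c(25, 25, 25), FUN = "+")
  expect_equal(ring_angle_theta(frame(rot, box), 1:6), 45, tolerance = 1e-9)
  # collinear atoms have no plane
  line <- cbind(1:6, 1, 1)
  expect_error(ring_angle_theta(frame(line, box), 1:6, "plane_normal"),
               "collinear")
})

test_that("side-chain angle alpha spans [0, 180] as constructed", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0),
               c(0, 1, 0), c(1, 1, 0),
               c(5, 5, 5), c(4, 5, 5),
               c(2, 2, 2), c(2, 3, 2))
  fr <- frame(xyz, c(50, 50, 50))
  expect_equal(chain_angle_alpha(fr, c(1, 2), c(3, 4)), 0)
  expect_equal(chain_angle_alpha(fr, c(1, 2), c(5, 6)), 180)
  expect_equal(chain_angle_alpha(fr, c(1, 2), c(7, 8)), 90)
  expect_error(chain_angle_alpha(fr, c(1, 1), c(3, 4)), "zero-length")
})

test_that("free-energy surfaces follow Boltzmann inversion of occupancy", {
  # 75/25 split at 303.15 K: delta F = kBT ln 3
  dz <- c(rep(1, 75), rep(3, 25))
  th <- rep(45, 100)
  fes <- free_energy_surface(dz, th, c(0, 2, 4), c(0, 90), 303.15)
  expect_equal(fes$F[1, 1], 0)
  expect_equal(fes$F[2, 1], kB_kcal * 303.15 * log(3), tolerance = 1e-9)
  expect_equal(fes$F[2, 1], 0.6619, tolerance = 2e-4)
  # invariant under count rescaling
  fes2 <- free_energy_surface(rep(dz, 4), rep(th, 4), c(0, 2, 4), c(0, 90),
                              303.15)
  expect_equal(fes2$F, fes$F, tolerance = 1e-12)
  # empty bins undefined, not zero
  fes3 <- free_energy_surface(dz, th, c(0, 2, 4, 6), c(0, 90), 303.15)
  expect_true(is.na(fes3$F[3, 1]))
  # bimodal generator occupancy puts both minima where it should
  set.seed(51)
  dzb <- c(rnorm(5000, 10, 1), rnorm(5000, -10, 1))
  edges <- seq(-15.5, 15.5, 1)
  fesb <- free_energy_surface(dzb, rep(45, 10000), edges, c(0, 90))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  mins <- order(fesb$F[, 1])[1:2]
  expect_setequal(mids[mins], c(-10, 10))
})

test_that("insertion detection requires persistent residence", {
  expect_true(is.na(detect_insertion(rep(30, 50), threshold = 20)))
  expect_equal(detect_insertion(c(30, 25, 15, 14, 13), 20, persistence = 3), 3L)
  expect_equal(detect_insertion(c(30, 25, 15, 14, 13), 20, persistence = 1), 3L)
  # persistence 1 is first crossing
  expect_equal(detect_insertion(c(30, 15, 30, 30), 20, persistence = 1), 2L)
  expect_true(is.na(detect_insertion(c(30, 15, 30, 30), 20, persistence = 2)))
})

test_that("translocation counting uses hysteresis", {
  expect_equal(count_translocations(c(20, 10, 5, -5, -10), band = 5), 1L)
  expect_equal(count_translocations(c(3, -3, 2, -2), band = 5), 0L)
  expect_equal(count_translocations(c(10, -10, 10, -10), band = 5), 3L)
  # never leaves one band -> zero
  expect_equal(count_translocations(c(10, 9, 8, 30, 8), band = 5), 0L)
  # matches the brute-force state machine, and is even under negation
  set.seed(61)
  for (i in 1:20) {
    dz <- cumsum(rnorm(200, 0, 4))
    expect_equal(count_translocations(dz, 5), bf_translocations(dz, 5))
    expect_equal(count_translocations(-dz, 5), count_translocations(dz, 5))
  }
})

test_that("solute clustering equals brute-force connected components", {
  box <- c(60, 60, 60)
  # chain A-B 5, B-C 5, A-C ~9: one cluster by single linkage
  xyz <- rbind(c(10, 10, 10), c(15, 10, 10), c(12.5, 14.33, 10))
  cl <- cluster_solutes(frame(xyz, box), list(1L, 2L, 3L), cutoff = 6)
  expect_equal(cl$labels, c(1L, 1L, 1L))
  expect_equal(cl$sizes, c(3L, 3L, 3L))
  far <- rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0))
  cl2 <- cluster_solutes(frame(far, box), list(1L, 2L, 3L), cutoff = 6)
  expect_equal(cl2$sizes, c(1L, 1L, 1L))
  set.seed(71)
  for (i in 1:10) {
    n <- sample(3:16, 1)
    sol <- lapply(seq_len(n), function(s)
      (s - 1L) * 2L + 1:2)
    xyz <- matrix(runif(n * 2 * 3, 0, 40), ncol = 3)
    fr <- frame(xyz, c(40, 40, 40))
    got <- cluster_solutes(fr, sol, cutoff = 8)$labels
    want <- bf_clusters(fr, sol, 8)
    # same partition up to label permutation
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("event reports classify insertion modes from cluster size", {
  g <- generate_bilayer_trajectory(
    bilayer_params(lipids_per_leaflet = 16, n_frames = 30, seed = 81),
    solute_params(n_solutes = 4, dz_mean = 10, dz_width = 1,
                  cluster_mode = "clustered", seed = 81))
  tr <- g$trajectory
  lip <- select_atoms(tr$topology, selection_spec(molecule_type = "POPC"))
  sol_mols <- which(tr$topology$molecules$type == "DMP")
  sol_idx <- lapply(sol_mols, function(m)
    tr$topology$molecules$start[m]:tr$topology$molecules$end[m])
  dz_list <- lapply(sol_idx, function(ix) solute_dz(tr, ix[1:6], lip))
  evr <- solute_event_report(dz_list, threshold = 20, persistence = 5,
                             traj = tr, solute_indices = sol_idx)
  expect_equal(evr$insertion_frame, rep(1L, 4))
  expect_true(all(evr$insertion_mode == "clustered"))
  expect_true(all(evr$translocation_count == 0L))
})
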
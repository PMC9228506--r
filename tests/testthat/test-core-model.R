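# Data model, file I/O, selection, PBC geometry and centres of mass.

test_that("GRO reading recovers atoms, residues and the box", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(tiny_gro_lines(), f)
  st <- read_structure(f, "gro")
  expect_equal(nrow(st$topology$atoms), 3L)
  expect_equal(st$topology$atoms$atom_name, c("P", "N", "OW"))
  expect_equal(st$frame$box, c(66, 66, 90))
  expect_equal(st$frame$xyz[1, ], c(10, 20, 30))
  expect_equal(st$topology$molecules$type, c("POPC", "water"))
})

test_that("malformed GRO lines and triclinic boxes are rejected with context", {
  f <- withr::local_tempfile(fileext = ".gro")
  bad <- tiny_gro_lines(); bad[4] <- "    1POPC    P    1   x.xxx   2.000   3.000"
  writeLines(bad, f)
  expect_error(read_gro(f), "line 4")
  tri <- tiny_gro_lines(); tri[6] <- "   6.6   6.6   9.0   0.0   0.0   1.2   0.0   0.0   0.0"
  writeLines(tri, f)
  expect_error(read_gro(f), "triclinic")
})

test_that("GRO round-trips generated coordinates at the printed precision", {
  g <- generate_bilayer_trajectory(bilayer_params(n_frames = 2, seed = 7))
  fr <- get_frame(g$trajectory, 1)
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro(g$trajectory$topology, fr, f)
  st <- read_gro(f)
  expect_equal(st$topology$atoms$atom_name, g$trajectory$topology$atoms$atom_name)
  expect_equal(st$topology$atoms$residue_index, g$trajectory$topology$atoms$residue_index)
  expect_lt(max(abs(st$frame$xyz - fr$xyz)), 0.0051)  # 0.001 nm print precision
  expect_equal(st$frame$box, fr$box, tolerance = 1e-6)
  # second round trip is exact: values already at printed precision
  f2 <- withr::local_tempfile(fileext = ".gro")
  write_gro(st$topology, st$frame, f2)
  expect_identical(readLines(f)[-1], readLines(f2)[-1])
})

test_that("PDB requires CRYST1 and round-trips box and coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  P   POPC    1      10.000  20.000  30.000  1.00  0.00",
               "END"), f)
  expect_error(read_structure(f, "pdb"), "CRYST1")
  top <- particle_topology(3, name = "P", mass = 30.97)
  fr <- frame(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, byrow = TRUE),
              c(66, 66, 90))
  write_pdb_structure(top, fr, f)
  st <- read_structure(f, "pdb")
  expect_equal(st$frame$box, c(66, 66, 90))
  expect_equal(st$frame$xyz, fr$xyz, tolerance = 1e-6)
})

test_that("trajectory container round-trips through the on-disk layout", {
  g <- generate_bilayer_trajectory(bilayer_params(lipids_per_leaflet = 8,
                                                  n_frames = 5, seed = 3),
                                   solute_params(n_solutes = 2, seed = 3))
  d <- withr::local_tempdir()
  write_trajectory(g$trajectory, d)
  tr <- read_trajectory(d)
  expect_equal(tr$coords, g$trajectory$coords, tolerance = 1e-9)
  expect_equal(tr$times, g$trajectory$times)
  expect_equal(tr$topology$atoms$roles, g$trajectory$topology$atoms$roles)
  expect_true(tr$unwrapped)
})

test_that("selection is exact, idempotent and monotone under conjunction", {
  g <- generate_bilayer_trajectory(bilayer_params(n_frames = 1, seed = 2))
  top <- g$trajectory$topology
  p1 <- select_atoms(top, selection_spec(molecule_type = "POPC", role = "lipid_P"))
  expect_length(p1, 128L)
  p2 <- select_atoms(top, selection_spec(atom_name = "P"))
  expect_identical(p1, p2)
  # adding a filter never grows the set
  wide <- select_atoms(top, selection_spec(molecule_type = "POPC"))
  expect_true(all(p1 %in% wide))
  expect_lte(length(p1), length(wide))
  expect_error(select_atoms(top, selection_spec(molecule_type = "DMP")),
               "zero atoms")
  expect_error(selection_spec(), "empty")
})

test_that("role configs retag atoms by name", {
  g <- generate_bilayer_trajectory(bilayer_params(lipids_per_leaflet = 4,
                                                  n_frames = 1, seed = 2))
  top <- g$trajectory$topology
  top2 <- apply_role_config(top, list(lipid_P = "P", lipid_N = "N"))
  expect_identical(select_atoms(top2, selection_spec(role = "lipid_P")),
                   select_atoms(top, selection_spec(atom_name = "P")))
  expect_error(apply_role_config(top, list(bogus_role = "P")), "unknown role")
})

test_that("centre of mass honours weights and reassembles split molecules", {
  top <- particle_topology(2, mass = 1)
  fr <- frame(rbind(c(0, 0, 1), c(0, 0, -1)), c(10, 10, 10))
  expect_equal(center_of_mass(fr, top, 1:2)[3], 0)
  top$atoms$mass <- c(1, 3)
  fr <- frame(rbind(c(0, 0, 0), c(0, 0, 4)), c(20, 20, 20))
  expect_equal(center_of_mass(fr, top, 1:2)[3], 3)
  # split across the boundary: 9.8 and 0.2 in a box of 10 -> COM at 10 = 0
  top$atoms$mass <- c(1, 1)
  fr <- frame(rbind(c(9.8, 5, 5), c(0.2, 5, 5)), c(10, 10, 10))
  com <- center_of_mass(fr, top, 1:2)
  expect_equal(com[1] %% 10, 0, tolerance = 1e-12)
  expect_equal(com, bf_com_images(fr$xyz, fr$box, c(1, 1)), tolerance = 1e-12)
})

test_that("centre of mass is translation-equivariant modulo the box", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    box <- runif(3, 8, 30)
    xyz <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
    # keep the molecule compact so the whole-molecule reassembly is unique
    xyz <- sweep(xyz * 0.2, 2, box * runif(3), FUN = "+") %% rep(box, each = n)
    masses <- runif(n, 1, 16)
    top <- particle_topology(n); top$atoms$mass <- masses
    shift <- runif(3, -50, 50)
    c0 <- center_of_mass(frame(xyz, box), top, seq_len(n))
    c1 <- center_of_mass(frame(sweep(xyz, 2, shift, FUN = "+") %% rep(box, each = n),
                               box), top, seq_len(n))
    expect_equal(minimum_image(c1 - c0 - shift, box), rep(0, 3),
                 tolerance = 1e-8)
    expect_equal(c0, bf_com_images(xyz, box, masses), tolerance = 1e-8)
  }
})

test_that("leaflet assignment matches construction and generator truth", {
  top <- particle_topology(128, name = "P", mass = 94.97)
  z <- rep(c(19, -19), each = 64)
  fr <- frame(cbind(runif(128, 0, 66), runif(128, 0, 66), z), c(66, 66, 90))
  lab <- assign_leaflets(fr, top, 1:128)
  expect_equal(sum(lab == "upper"), 64L)
  expect_equal(sum(lab == "lower"), 64L)
  g <- generate_bilayer_trajectory(bilayer_params(n_frames = 3, seed = 5))
  fr <- get_frame(g$trajectory, 2)
  lab <- assign_leaflets(fr, g$trajectory$topology, g$truth$p_indices)
  expect_identical(lab, g$truth$leaflet)
  # degenerate: all on one side warns
  fr1 <- frame(cbind(0, 0, c(1, 1, 1)), c(10, 10, 10))
  expect_warning(assign_leaflets(fr1, particle_topology(3), 1:3), "degenerate")
})
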
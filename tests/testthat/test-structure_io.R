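test_that("read_pdb keeps heavy atoms, drops hydrogens, resolves altlocs", {
  txt <- paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA AGLY A   2       4.500   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CA BGLY A   2       4.700   0.000   0.000  0.60  0.00           C",
    "ATOM      5  CA  SER A   3       8.000   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  at <- read_pdb(txt)
  expect_equal(nrow(at), 4)
  expect_true(4.7 %in% at$x)   # higher-occupancy altloc wins
  expect_false(4.5 %in% at$x)

  with_h <- sub("END", paste(
    "ATOM      6  H   SER A   3       8.000   1.000   0.000  1.00  0.00           H",
    "END", sep = "\n"), txt)
  expect_identical(read_pdb(with_h), at)

  # equal occupancies: first listed wins
  tie <- gsub("0.40", "0.60", txt)
  expect_true(4.5 %in% read_pdb(tie)$x)
})

test_that("read_pdb errors name the offending residue", {
  txt <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   2       4.500   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  expect_error(read_pdb(txt), "GLY2")
  expect_error(read_pdb("ATOM      1  H   ALA A   1       0.0     0.0     0.0  1.00  0.00           H\nEND"),
               "empty")
})

test_that("contact map applies the 4.5 A cutoff strictly and uses CA distances", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0.2), c(11.4, 0, 0),
              c(0, 4.49, 0))
  atoms <- entfold:::fixture_atoms(ca)
  ct <- build_contact_map(atoms)
  expect_true(any(ct$i == 1 & ct$j == 5))
  expect_equal(ct$r0[ct$i == 1 & ct$j == 5], 4.49)

  ca[5, 2] <- 4.51
  expect_false(any(build_contact_map(entfold:::fixture_atoms(ca))$j == 5))

  # j - i >= 4: residues 1 and 4 at 4.4 A are not a contact
  ca2 <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0.2), c(0, 4.4, 0),
               c(20, 0, 0))
  expect_equal(nrow(build_contact_map(entfold:::fixture_atoms(ca2))), 0)
})

test_that("contact map is invariant under atom reordering and rigid motion", {
  tn <- make_toy_native(12, "hairpin")
  ct <- build_contact_map(tn$atoms)
  perm <- tn$atoms[sample(nrow(tn$atoms)), ]
  expect_identical(build_contact_map(perm), ct)

  rm <- random_rigid_motion(77)
  moved <- tn$atoms
  xyz <- apply_rigid(as.matrix(tn$atoms[, c("x", "y", "z")]), rm)
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  ct2 <- build_contact_map(moved)
  expect_equal(ct2$i, ct$i)
  expect_equal(ct2$j, ct$j)
  expect_lt(max(abs(ct2$r0 - ct$r0)), 1e-9)
})

test_that("native geometry: degenerate and symmetric cases are handled", {
  # collinear chain: angles pi, dihedrals flagged degenerate
  ca <- cbind(3.8 * (0:3), 0, 0)
  topo <- native_topology(ca, data.frame(i = integer(0), j = integer(0)))
  expect_equal(as.numeric(topo$bond_lengths), rep(3.8, 3))
  expect_equal(as.numeric(topo$angles), rep(pi, 2))
  expect_true(all(topo$degenerate_dihedrals))

  # planar zigzag: dihedrals exactly pi (trans) by symmetry
  zz <- cbind(3.5 * (0:5), rep(c(0, 1.5), 3), 0)
  tz <- native_topology(zz, data.frame(i = integer(0), j = integer(0)))
  expect_equal(abs(as.numeric(tz$dihedrals)), rep(pi, 3), tolerance = 1e-12)

  expect_error(extract_native_geometry(
    entfold:::fixture_atoms(cbind(3.8 * (0:2), 0, 0))), "4 residues")
})

test_that("internal geometry round-trips through forward kinematics", {
  for (seed in c(3, 14, 15)) {
    x <- random_coil(10, seed = seed)
    topo <- native_topology(x, data.frame(i = integer(0), j = integer(0)))
    y <- chain_from_internal(topo$bond_lengths, topo$angles, topo$dihedrals)
    expect_lt(max(abs(dist(x) - dist(y))), 1e-9)
  }
})

test_that("topology JSON, XYZ and observable TSV round-trip", {
  tn <- make_toy_native(12, "hairpin")
  p <- withr::local_tempfile(fileext = ".json")
  write_topology_json(tn$topology, p)
  back <- read_topology_json(p)
  expect_equal(back$ca, tn$topology$ca, ignore_attr = TRUE)
  expect_equal(back$contacts$r0, tn$topology$contacts$r0)
  expect_equal(back$residue_labels, tn$topology$residue_labels)

  frames <- list(tn$native, tn$native + 1)
  px <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(frames, px)
  back_frames <- read_xyz(px)
  expect_equal(length(back_frames), 2)
  expect_equal(back_frames[[2]], unname(tn$native + 1), tolerance = 1e-6)

  ser <- data.frame(step = 1:3, Q = c(0.1, 0.5, 1), Gprime = c(0, -0.3, -0.7),
                    E = c(-1, -5, -12), RMSD = c(9, 4, 0))
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_observables(ser, pt)
  expect_equal(readLines(pt)[1], "step\tQ\tGprime\tE\tRMSD")
  expect_equal(as.data.frame(read_observables(pt)), ser)
})
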
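test_that("a minimal hand-written PDB loads with roles, elements and the water counting atom", {
  path <- withr::local_tempfile(fileext = ".pdb")
  tiny_pdb(path)
  sys <- load_structure(path)
  expect_equal(n_atoms(sys$topology), 5)
  expect_equal(length(water_oxygens(sys$topology)), 1)
  expect_equal(sys$topology$atoms$role,
               c(rep("protein", 4), "water"))
  # is_heavy is false exactly for hydrogen
  expect_equal(sys$topology$atoms$is_heavy, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(sys$frame$box, c(20, 20, 20))
  expect_equal(sys$frame$xyz[2, ], c(2, 2, 3))
})

test_that("unknown residue names are rejected by name", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  XYZ A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), path)
  expect_error(load_structure(path), "XYZ")
})

test_that("the synthetic pentamer round-trips through PDB with residue indexing intact", {
  sys <- toy_system()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys$topology, sys$frame, path)
  back <- load_structure(path)
  expect_equal(back$topology$subunits, LETTERS[1:5])
  expect_equal(n_atoms(back$topology), n_atoms(sys$topology))
  # every (subunit, residue) key of the original resolves to the same count
  a <- sys$topology$atoms
  keys <- unique(a[a$role == "protein", c("subunit_id", "residue_seq")])
  for (i in sample(nrow(keys), 25)) {
    expect_equal(
      length(residue_atoms(back$topology, keys$subunit_id[i],
                           keys$residue_seq[i])),
      length(residue_atoms(sys$topology, keys$subunit_id[i],
                           keys$residue_seq[i])))
  }
  expect_equal(back$frame$xyz, sys$frame$xyz, tolerance = 1e-3)
})

test_that("trajectory write/read round-trips coordinates, times and boxes in both dialects", {
  sys <- toy_system(n_ligands = 2, n_waters_in_gate = 3, n_bulk_waters = 2)
  sc <- script_trajectory(sys$topology, sys$frame, n_frames = 5, dt = 500,
                          tilt_program = c(0, 2, 4, 6, 8))
  for (dialect in c("multi-pdb", "xyz")) {
    path <- withr::local_tempfile()
    write_trajectory(sc$trajectory, path, dialect = dialect)
    back <- load_trajectory(sys$topology, path, dialect = dialect)
    expect_equal(n_frames(back), 5)
    expect_equal(back$times, sc$trajectory$times)
    expect_equal(back$frame_interval, 500)
    expect_equal(back$box, sc$trajectory$box)
    tol <- if (dialect == "multi-pdb") 1e-3 else 1e-6
    expect_equal(back$coords, sc$trajectory$coords, tolerance = tol)
  }
})

test_that("trajectory loading validates atom counts, frame times and emptiness", {
  sys <- toy_system(n_ligands = 1, n_waters_in_gate = 2, n_bulk_waters = 0)
  path <- withr::local_tempfile()
  sc <- script_trajectory(sys$topology, sys$frame, n_frames = 3)
  write_trajectory(sc$trajectory, path)
  # a frame-interval of 1 ns is inferred from the first two frames
  expect_equal(load_trajectory(sys$topology, path)$frame_interval, 1000)
  # atom-count mismatch names the offending frame
  other <- toy_system(n_ligands = 2, n_waters_in_gate = 2, n_bulk_waters = 0)
  expect_error(load_trajectory(other$topology, path), "frame 1")
  # empty file
  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(load_trajectory(sys$topology, empty), "no frames")
  # non-monotone times
  lines <- readLines(path)
  lines <- sub("TIME= 2000", "TIME= 0", lines, fixed = TRUE)
  writeLines(lines, path)
  expect_error(load_trajectory(sys$topology, path), "increasing")
})

test_that("site resolution returns the named residues of one subunit and partitions subunits", {
  sys <- toy_system()
  sites <- default_sites()
  tm2 <- resolve_selection(sys$topology, sites$TM2, "A")
  a <- sys$topology$atoms
  expect_true(all(a$subunit_id[tm2] == "A"))
  expect_setequal(unique(a$residue_seq[tm2]), c(254, 307))
  # TM1 resolves to exactly the 13 member residues in every subunit
  for (s in sys$topology$subunits) {
    tm1 <- resolve_selection(sys$topology, sites$TM1, s)
    expect_setequal(unique(a$residue_seq[tm1]), sites$TM1$members$residue_seq)
    expect_true(all(a$subunit_id[tm1] == s))
  }
  # no overlap across subunits
  all_idx <- unlist(resolve_selection_all(sys$topology, sites$TM1))
  expect_equal(anyDuplicated(all_idx), 0L)
  # missing residue names the (subunit, residue) pair
  expect_error(resolve_selection(sys$topology,
                                 site_definition("bogus", 9999L), "A"),
               "9999")
})

test_that("prime-notation aliases map to author numbering", {
  expect_equal(prime_to_residue(c("-2'", "9'", "16'")), c(222L, 233L, 240L))
})

test_that("minimum-image distances wrap the orthorhombic box", {
  box <- c(10, 10, 10)
  a <- matrix(c(0.5, 0, 0), 1)
  b <- matrix(c(9.5, 0, 0), 1)
  expect_equal(min_distance(a, b, box), 1)
  expect_equal(min_distance(a, b, NULL), 9)
  # brute-force oracle over shifted replicas on random sets
  set.seed(11)
  for (rep in 1:5) {
    A <- matrix(runif(9, 0, 10), 3)
    B <- matrix(runif(9, 0, 10), 3)
    shifts <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * 10
    brute <- min(vapply(seq_len(nrow(shifts)), function(s)
      min_distance(A, B + matrix(shifts[s, ], 3, 3, byrow = TRUE), NULL),
      numeric(1)))
    expect_equal(min_distance(A, B, box), brute)
  }
})

test_that("cutoff validation enforces dissociation >= enter", {
  expect_error(site_definition("s", 1L, contact_enter_cutoff = 4,
                               dissociation_cutoff = 3), ">=")
  expect_error(site_definition("s", 1L, contact_enter_cutoff = -1), "positive")
})
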
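# Shared fixtures: toy channel systems, hand-built minimal topologies, and
# a tiny hand-written PDB. Everything is generated in code at test time.

toy_system <- function(...) {
  build_toy_channel(toy_channel_spec(...))
}

# minimal one-residue "protein" plus a single-atom ligand, for hand-traced
# distance series
point_system <- function() {
  atoms <- data.frame(
    atom_name = c("CA", "C1"), element = c("C", "C"),
    residue_seq = c(1L, 1L), residue_name = c("ALA", "DES"),
    subunit_id = c("A", "X"), role = c("protein", "ligand"),
    stringsAsFactors = FALSE)
  channel_topology(atoms)
}

# trajectory in which the ligand sits at the given distances (angstrom,
# along +x) from the protein atom at the origin, one frame per ns
distance_trajectory <- function(distances, dt = 1000, box = c(100, 100, 100)) {
  topo <- point_system()
  frames <- lapply(seq_along(distances), function(i)
    channel_frame(rbind(c(0, 0, 0), c(distances[i], 0, 0)), box,
                  (i - 1) * dt))
  channel_trajectory(topo, frames)
}

point_site <- function(...) site_definition("pocket", 1L, ...)

tiny_pdb <- function(path) {
  writeLines(c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  HA  ALA A   1       2.500   2.500   3.000  1.00  0.00           H",
    "ATOM      4  C   ALA A   1       3.000   2.000   3.000  1.00  0.00           C",
    "ATOM      5  O   HOH W   2      10.000  10.000  10.000  1.00  0.00           O",
    "END"), path)
  path
}

expect_events_equal <- function(detected, scripted, tol_ps = 0) {
  expect_equal(nrow(detected), nrow(scripted))
  ord <- order(detected$t_start)
  sord <- order(scripted$t_start)
  expect_true(all(abs(detected$t_start[ord] - scripted$t_start[sord]) <=
                    tol_ps + 1e-9))
  expect_true(all(abs(detected$t_end[ord] - scripted$t_end[sord]) <=
                    tol_ps + 1e-9))
  expect_equal(detected$subunit_id[ord], scripted$subunit_id[sord])
}
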
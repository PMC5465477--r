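test_that("the hysteresis state machine reproduces a hand-traced distance series", {
  # ligand-protein distances 2,2,6,2,2,6 A at 1 ns/frame: two events of 2 ns
  traj <- distance_trajectory(c(2, 2, 6, 2, 2, 6))
  ev <- detect_binding_events(traj, "X:1", point_site(),
                              min_duration_frames = 1)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$t_start, c(0, 3000))
  expect_equal(ev$t_end, c(2000, 5000))
  expect_equal(ev$residence_ns, c(2, 2))
  expect_false(any(ev$censored))
})

test_that("hysteresis keeps the bound state between 3.5 and 5 angstrom", {
  # excursion to 4.5 A (outside contact, inside dissociation) does not split
  traj <- distance_trajectory(c(2, 4.5, 4.5, 2, 6, 6))
  ev <- detect_binding_events(traj, "X:1", point_site(),
                              min_duration_frames = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$t_start, ev$t_end), c(0, 4000))
})

test_that("short events are discarded and absent contact yields no events", {
  traj <- distance_trajectory(c(6, 2, 6, 6, 6, 6))
  expect_equal(nrow(detect_binding_events(traj, "X:1", point_site(),
                                          min_duration_frames = 2)), 0)
  expect_equal(nrow(detect_binding_events(distance_trajectory(rep(8, 6)),
                                          "X:1", point_site())), 0)
})

test_that("scripted binding events are recovered exactly without noise", {
  sys <- toy_system(n_ligands = 2)
  script <- data.frame(
    ligand_id = c("X:1", "X:1", "X:2"),
    site_name = "TM1",
    subunit_id = c("A", "C", "B"),
    t_start = c(50000, 200000, 30000),
    t_end = c(150000, 260000, 120000))
  sc <- script_trajectory(sys$topology, sys$frame, event_script(script),
                          n_frames = 300)
  det <- detect_all_binding_events(sc$trajectory, default_sites()$TM1)
  for (lg in c("X:1", "X:2")) {
    expect_events_equal(det[det$ligand_id == lg, ],
                        script[script$ligand_id == lg, ], tol_ps = 0)
  }
  # one 100 ns residence for the first event, as scripted
  expect_equal(det$residence_ns[det$t_start == 50000], 100)
})

test_that("noisy scripted events are recovered within one frame interval", {
  sys <- toy_system(n_ligands = 1)
  script <- data.frame(ligand_id = "X:1", site_name = "TM2",
                       subunit_id = "D", t_start = 20000, t_end = 80000)
  sc <- script_trajectory(sys$topology, sys$frame, event_script(script),
                          noise_amplitude = 0.2, seed = 31, n_frames = 120)
  det <- detect_binding_events(sc$trajectory, "X:1", default_sites()$TM2)
  expect_events_equal(det, script, tol_ps = 1000)
})

test_that("total event residence never exceeds the trajectory duration", {
  set.seed(17)
  sys <- toy_system(n_ligands = 1)
  for (rep in 1:3) {
    starts <- sort(sample(seq(0, 80000, by = 1000), 3))
    ends <- starts + sample(5:12, 3) * 1000
    ends <- pmin(ends, c(starts[-1], 100000))
    keep <- ends > starts
    script <- data.frame(ligand_id = "X:1", site_name = "TM1",
                         subunit_id = sample(LETTERS[1:5], sum(keep), TRUE),
                         t_start = starts[keep], t_end = ends[keep])
    sc <- script_trajectory(sys$topology, sys$frame, event_script(script),
                            n_frames = 101)
    det <- detect_binding_events(sc$trajectory, "X:1", default_sites()$TM1,
                                 min_duration_frames = 1)
    span_ns <- diff(range(sc$trajectory$times)) / 1000
    expect_lte(sum(det$residence_ns), span_ns)
  }
})

test_that("the event report aggregates per-replicate counts into a grand total", {
  rep_counts <- c(5, 6, 5, 8, 8)
  tab <- event_report(rep_counts)
  expect_equal(tab$n_events[tab$replicate == "All"], 32)
  # with full event tables, both averaging conventions are reported
  evs <- lapply(c(2, 3), function(n)
    data.frame(residence_ns = seq_len(n) * 10))
  tab2 <- event_report(evs)
  all_row <- tab2[tab2$replicate == "All", ]
  expect_equal(all_row$n_events, 5)
  expect_equal(all_row$residence_mean, mean(c(10, 20, 10, 20, 30)))
  expect_equal(all_row$replicate_weighted_mean, mean(c(15, 20)))
})

test_that("bound-ligand RMSF matches closed forms in the lab frame", {
  # static ligand: exactly zero
  traj <- distance_trajectory(rep(2, 10))
  ev <- data.frame(ligand_id = "X:1", t_start = 0, t_end = 10000)
  expect_equal(bound_ligand_rmsf(traj, ev, sample_interval = 1000), 0)
  # point ligand alternating between two positions d apart: d / 2
  traj2 <- distance_trajectory(rep(c(2, 3.2), 10))
  ev2 <- data.frame(ligand_id = "X:1", t_start = 0, t_end = 20000)
  expect_equal(bound_ligand_rmsf(traj2, ev2, sample_interval = 1000), 0.6)
  # isotropic Gaussian wobble of sigma = 1 per coordinate: sqrt(3)
  sys <- toy_system(n_ligands = 1)
  script <- data.frame(ligand_id = "X:1", site_name = "TM1",
                       subunit_id = "A", t_start = 0, t_end = 100000)
  sc <- script_trajectory(sys$topology, sys$frame, event_script(script),
                          noise_amplitude = 1, seed = 12, dt = 200,
                          n_frames = 500)
  ev3 <- data.frame(ligand_id = "X:1", t_start = 0, t_end = 100000)
  expect_equal(bound_ligand_rmsf(sc$trajectory, ev3, sample_interval = 200),
               sqrt(3), tolerance = 0.05)
  # too few samples is an error
  expect_error(bound_ligand_rmsf(traj, data.frame(ligand_id = "X:1",
                                                  t_start = 0, t_end = 500),
                                 sample_interval = 1000), "2 samples")
})

test_that("event statistics attach the named pair distance", {
  sys <- toy_system(n_ligands = 1)
  script <- data.frame(ligand_id = "X:1", site_name = "TM2",
                       subunit_id = "B", t_start = 0, t_end = 50000)
  sc <- script_trajectory(sys$topology, sys$frame, event_script(script),
                          n_frames = 60)
  det <- detect_binding_events(sc$trajectory, "X:1", default_sites()$TM2)
  st <- event_statistics(sc$trajectory, det,
                         pair = list(residue_seq = 254, atom_name = "OH"))
  # the TM2 anchor is built 2.5 A radially inward of the Tyr-254 hydroxyl
  expect_equal(st$mean_pair_distance, 2.5, tolerance = 1e-6)
  expect_equal(st$rmsf, 0)
})

test_that("distance series match fixed and brute-force min-pair geometry", {
  traj <- distance_trajectory(rep(4.5, 6))
  ds <- distance_series(traj, 1L, 2L)
  expect_equal(ds$distance, rep(4.5, 6))
  # linearly separating atoms: interior running mean equals the ramp
  traj2 <- distance_trajectory(seq(2, 12, by = 2))
  ds2 <- distance_series(traj2, 1L, 2L, running_window = 2)
  expect_equal(ds2$running[2:5], ds2$distance[2:5])
  expect_equal(ds2$running[1], mean(ds2$distance[1:2]))
  # multi-atom group vs point equals the brute-force pair minimum
  sys <- toy_system(n_ligands = 1)
  sc <- script_trajectory(sys$topology, sys$frame, n_frames = 3)
  grp <- resolve_selection(sys$topology, default_sites()$TM1, "C")
  ds3 <- distance_series(sc$trajectory, grp, list(subunit = "X",
                                                  residue_seq = 1))
  lig <- ligand_atoms(sys$topology, "X:1")
  brute <- min(pair_distances(sc$trajectory$coords[grp, , 1],
                              sc$trajectory$coords[lig, , 1, drop = FALSE],
                              sc$trajectory$box[1, ]))
  expect_equal(ds3$distance[1], brute)
})

test_that("occupancy series count simultaneously bound ligands with the chosen SD convention", {
  sys <- toy_system(n_ligands = 3)
  # two ligands bound at all times, the third always aqueous
  script <- data.frame(ligand_id = c("X:1", "X:2"), site_name = "TM1",
                       subunit_id = c("A", "C"), t_start = 0, t_end = 10000)
  sc <- script_trajectory(sys$topology, sys$frame, event_script(script),
                          n_frames = 10)
  oc <- occupancy_series(sc$trajectory, default_sites()$TM1)
  expect_equal(attr(oc, "mean"), 2)
  expect_equal(attr(oc, "sd"), 0)
  # alternating 1 and 3 bound: mean 2, population SD 1
  ev <- rbind(
    data.frame(ligand_id = "X:1", site_name = "TM1", subunit_id = "A",
               t_start = 0, t_end = 10000),
    do.call(rbind, lapply(seq(0, 8, by = 2), function(k)
      data.frame(ligand_id = c("X:2", "X:3"), site_name = "TM1",
                 subunit_id = c("B", "D"), t_start = k * 1000,
                 t_end = (k + 1) * 1000))))
  sc2 <- script_trajectory(sys$topology, sys$frame, event_script(ev),
                           n_frames = 10)
  oc2 <- occupancy_series(sc2$trajectory, default_sites()$TM1)
  expect_equal(oc2$n_bound, rep(c(3L, 1L), 5))
  expect_equal(attr(oc2, "mean"), 2)
  expect_equal(attr(oc2, "sd"), 1)
  oc3 <- occupancy_series(sc2$trajectory, default_sites()$TM1,
                          sd_type = "sample")
  expect_equal(attr(oc3, "sd"), sd(rep(c(3, 1), 5)))
})
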
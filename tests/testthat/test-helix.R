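test_that("helix tilt reads 0 for a vertical helix, the applied angle after rotation, and 180 when inverted", {
  sys <- toy_system()
  t0 <- helix_tilt(sys$topology, sys$frame, "A")
  expect_equal(unname(t0), c(0, 0), tolerance = 1e-8)
  # rigid 10-degree rotation about x: both turn vectors follow
  fr <- sys$frame
  fr$xyz <- rotate_about(fr$xyz, c(1, 0, 0), 10)
  t10 <- helix_tilt(sys$topology, fr, "A")
  expect_equal(unname(t10), c(10, 10), tolerance = 0.01)
  # inverted helix
  fr2 <- sys$frame
  fr2$xyz <- rotate_about(fr2$xyz, c(1, 0, 0), 180)
  t180 <- helix_tilt(sys$topology, fr2, "A")
  expect_equal(unname(t180), c(180, 180), tolerance = 1e-6)
})

test_that("tilt is invariant to translation and to rotation about the membrane normal", {
  sys <- toy_system()
  sc <- script_trajectory(sys$topology, sys$frame, tilt_program = 7,
                          n_frames = 2)
  fr <- get_frame(sc$trajectory, 2)
  base <- helix_tilt(sys$topology, fr, "B")
  fr$xyz <- sweep(fr$xyz, 2, c(5, -3, 11), "+")
  expect_equal(helix_tilt(sys$topology, fr, "B"), base, tolerance = 1e-9)
  fr$xyz <- rotate_about(fr$xyz, c(0, 0, 1), 37)
  expect_equal(helix_tilt(sys$topology, fr, "B"), base, tolerance = 1e-9)
})

test_that("scripted per-subunit tilt programs are recovered by the tilt series", {
  sys <- toy_system()
  prog <- matrix(c(0, 0, 0, 0, 0,
                   2, 4, 6, 8, 10), 2, 5, byrow = TRUE)
  sc <- script_trajectory(sys$topology, sys$frame, tilt_program = prog,
                          n_frames = 2)
  ts <- tilt_series(sc$trajectory)
  got <- ts$top_angle[ts$time == 1000]
  expect_equal(got, c(2, 4, 6, 8, 10), tolerance = 1e-6)
  expect_equal(ts$bottom_angle[ts$time == 1000], c(2, 4, 6, 8, 10),
               tolerance = 1e-6)
  expect_true(all(abs(ts$top_angle[ts$time == 0]) < 1e-8))
})

test_that("running averages handle constants, ramps and hand-computed windows", {
  expect_equal(running_average(rep(3, 10), window = 4), rep(3, 10))
  ramp <- seq(0, 18, by = 2)
  ra <- running_average(ramp, window = 4)
  expect_equal(ra[3:8], ramp[3:8])     # interior of a line is unchanged
  expect_equal(ra[1], mean(ramp[1:3])) # truncated leading edge
  step <- c(0, 0, 0, 6, 6, 6)
  expect_equal(running_average(step, window = 2),
               c(0, 0, 2, 4, 6, 6))
  expect_error(running_average(1:5, window = 0.5), "interval")
  # commutes with affine rescaling
  x <- rnorm(20)
  expect_equal(running_average(2 * x + 1, window = 3),
               2 * running_average(x, window = 3) + 1)
})

test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(41)
  P <- matrix(rnorm(30), 10, 3)
  R <- rotation_matrix(c(1, -2, 0.5), 33)
  tr <- c(4, -1, 7)
  Q <- P %*% t(R) + matrix(tr, 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, tr, tolerance = 1e-9)
  # symmetric: fitting Q onto P is the inverse transform, same rmsd
  fit2 <- kabsch_superpose(Q, P)
  expect_lt(fit2$rmsd, 1e-10)
  expect_equal(fit2$rotation, t(R), tolerance = 1e-9)
  # identical structures
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-12)
})

test_that("Kabsch RMSD matches a rotation-grid oracle on 4-point toys", {
  # independent oracle: coarse axis-angle grid plus Nelder-Mead refinement
  grid_oracle <- function(P, Q) {
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    rmsd_of <- function(axis, ang) {
      Rm <- rotation_matrix(axis, ang)
      sqrt(mean(rowSums((Pc %*% t(Rm) - Qc)^2)))
    }
    best <- Inf; best_p <- c(0, 0, 1, 0)
    for (th in seq(0, 180, by = 20)) for (ph in seq(0, 340, by = 20)) {
      ax <- c(sin(th * pi / 180) * cos(ph * pi / 180),
              sin(th * pi / 180) * sin(ph * pi / 180), cos(th * pi / 180))
      for (ang in seq(0, 350, by = 10)) {
        r <- rmsd_of(ax, ang)
        if (r < best) { best <- r; best_p <- c(ax, ang) }
      }
    }
    obj <- function(p) {
      ax <- p[1:3]; n <- sqrt(sum(ax^2))
      if (n < 1e-8) return(1e6)
      rmsd_of(ax / n, p[4])
    }
    stats::optim(best_p, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))$value
  }
  set.seed(7)
  for (rep in 1:3) {
    P <- matrix(rnorm(12), 4, 3)
    Q <- rotate_about(P, rnorm(3), runif(1, 0, 180))
    Q[2, ] <- Q[2, ] + rnorm(3, 0, 0.5)  # one displaced point
    expect_equal(kabsch_superpose(P, Q)$rmsd, grid_oracle(P, Q),
                 tolerance = 1e-3)
  }
})

test_that("degenerate and mismatched superposition inputs are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
  expect_error(kabsch_superpose(matrix(rnorm(9), 3),
                                matrix(rnorm(12), 4)), "selection|differ")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2),
                                matrix(rnorm(6), 2)), "3 atoms")
})

test_that("RMSD reports are zero against the reference and track scripted deformations", {
  sys <- toy_system(n_ligands = 0, n_waters_in_gate = 0, n_bulk_waters = 0)
  sc <- script_trajectory(sys$topology, sys$frame, n_frames = 5)
  rr <- rmsd_report(sc$trajectory, sys$frame,
                    ranges = list(Pore = 221:244), stride = 1000)
  expect_equal(rr$mean_rmsd, 0, tolerance = 1e-10)
  expect_equal(rr$sd_rmsd, 0, tolerance = 1e-10)
  # tilted pore helices: nonzero pore RMSD, restricted tail, errors on misuse
  sc2 <- script_trajectory(sys$topology, sys$frame,
                           tilt_program = c(0, 0, 0, 5, 5), n_frames = 5)
  rr2 <- rmsd_report(sc2$trajectory, sys$frame,
                     ranges = list(Pore = 221:244), stride = 1000,
                     tail_ns = 2)
  expect_gt(rr2$mean_rmsd, 0.1)
  expect_equal(rr2$n_frames, 3)
  expect_error(rmsd_report(sc2$trajectory, sys$frame, tail_ns = 10,
                           ranges = list(Pore = 221:244)), "exceeds")
})
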
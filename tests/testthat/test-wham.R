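# WHAM tests use small window batches; the full 50-window layout of the
# umbrella protocol is exercised by the acceptance suite.

make_windows <- function(potential, centers, k = 7.17, n = 4000, seed = 1,
                         temperature = 298) {
  lapply(seq_along(centers), function(i)
    umbrella_window(centers[i], k,
                    sample_biased_window(potential, centers[i], k, n,
                                         temperature = temperature,
                                         seed = seed + i),
                    retained_fraction = 1))
}

pmf_rmsd <- function(pmf, truth_fun, central = 0.8) {
  ok <- !is.na(pmf$pmf)
  z <- pmf$z[ok]; g <- pmf$pmf[ok]
  lo <- quantile(z, (1 - central) / 2); hi <- quantile(z, 1 - (1 - central) / 2)
  keep <- z >= lo & z <= hi
  truth <- truth_fun(z[keep])
  resid <- g[keep] - truth
  resid <- resid - mean(resid)  # PMFs are defined up to a constant
  sqrt(mean(resid^2))
}

test_that("umbrella bookkeeping matches the recording protocol", {
  expect_equal(expected_frames(10, 0.2), 50000L)
  expect_equal(expected_frames(1, 1), 1000L)
  expect_equal(expected_frames(9.5, 0.2), 47500L)
  expect_error(expected_frames(0, 1), "> 0")
  expect_error(expected_frames(1, -0.1), "> 0")
})

test_that("window planning steps from the start toward the end inclusively", {
  w <- plan_windows(-5, -54, 1)
  expect_length(w, 50)
  expect_equal(w[[1]]$center, -5)
  expect_equal(w[[50]]$center, -54)
  expect_equal(w[[1]]$spring_k, 7.17)
  expect_length(plan_windows(0, 10, 2), 6)
  expect_error(plan_windows(0, 0, 1), "zero length")
  expect_error(plan_windows(0, 5, -1), "spacing")
})

test_that("window validation and burn-in retention behave as documented", {
  expect_error(umbrella_window(0, -1), "spring_k")
  w <- umbrella_window(0, 7.17, 1:100, retained_fraction = 0.95)
  expect_equal(retained_samples(w), 6:100)
  expect_error(retained_samples(umbrella_window(0, 7.17)), "no samples")
  expect_error(umbrella_window(0, 1, 1:5, retained_fraction = 0), "retained")
})

test_that("window files round-trip through the plain-text dialect", {
  w <- umbrella_window(-12.5, 7.17, c(-12.4, -12.6, -12.55))
  path <- withr::local_tempfile()
  write_window_file(w, path)
  back <- read_window_file(path, retained_fraction = 1)
  expect_equal(back$center, -12.5)
  expect_equal(back$spring_k, 7.17)
  expect_equal(back$samples, w$samples)
})

test_that("WHAM recovers a flat landscape from biased windows", {
  flat <- analytic_potential("flat")
  wins <- make_windows(flat, seq(-4, 4, by = 1), seed = 10)
  pmf <- wham_solve(wins, bin_width = 0.1)
  expect_lt(pmf_rmsd(pmf, function(z) 0), 0.1)
  expect_true(pmf$converged)
  # zero is pinned exactly at the reference bin
  pmf2 <- wham_solve(wins, bin_width = 0.1, reference_z = 2)
  j <- which.min(abs(pmf2$z - pmf2$reference_z))
  expect_identical(pmf2$pmf[j], 0)
})

test_that("WHAM recovers a harmonic landscape within tolerance", {
  harm <- analytic_potential("harmonic", stiffness = 1.0, center = 0)
  wins <- make_windows(harm, seq(-5, 5, by = 1), seed = 20)
  pmf <- wham_solve(wins, bin_width = 0.1)
  expect_lt(pmf_rmsd(pmf, function(z) 0.5 * z^2), 0.1)
})

test_that("WHAM output is invariant under window permutation", {
  flat <- analytic_potential("flat")
  wins <- make_windows(flat, seq(-3, 3, by = 1), n = 2000, seed = 30)
  p1 <- wham_solve(wins, bin_width = 0.1, reference_z = 0)
  p2 <- wham_solve(rev(wins), bin_width = 0.1, reference_z = 0)
  expect_equal(p1$pmf, p2$pmf, tolerance = 1e-5)
})

test_that("gapped windows and non-convergence are reported as errors", {
  flat <- analytic_potential("flat")
  wins <- make_windows(flat, c(-8, 8), n = 2000, seed = 40)
  expect_error(wham_solve(wins, bin_width = 0.1), "overlap")
  wins2 <- make_windows(flat, c(0, 1), n = 2000, seed = 41)
  expect_error(wham_solve(wins2, bin_width = 0.1, max_iterations = 1,
                          tolerance = 1e-12), "converge")
  expect_error(wham_solve(wins2[1], bin_width = 0.1), "2 windows")
})

test_that("near-zero bias reduces WHAM to Boltzmann inversion of the histogram", {
  # two almost-unbiased windows sampling a harmonic well directly
  harm <- analytic_potential("harmonic", stiffness = 1.0, center = 0)
  wins <- make_windows(harm, c(-0.1, 0.1), k = 1e-6, n = 20000, seed = 50)
  pmf <- wham_solve(wins, bin_width = 0.2)
  kT <- 0.0019872 * 298
  h <- hist(c(retained_samples(wins[[1]]), retained_samples(wins[[2]])),
            breaks = seq(min(pmf$z) - 0.1, max(pmf$z) + 0.1, by = 0.2),
            plot = FALSE)
  direct <- -kT * log(h$counts / sum(h$counts))
  ok <- is.finite(direct) & !is.na(pmf$pmf)
  resid <- (pmf$pmf - direct)[ok]
  expect_lt(max(abs(resid - mean(resid))), 0.02)
})

test_that("PMF accuracy improves with the per-window sample count", {
  flat <- analytic_potential("flat")
  small <- make_windows(flat, seq(-3, 3, by = 1), n = 500, seed = 60)
  big <- make_windows(flat, seq(-3, 3, by = 1), n = 8000, seed = 60)
  r_small <- pmf_rmsd(wham_solve(small, bin_width = 0.1), function(z) 0)
  r_big <- pmf_rmsd(wham_solve(big, bin_width = 0.1), function(z) 0)
  expect_lte(r_big, r_small)
})

test_that("barrier heights are read off profiles correctly", {
  # a constructed profile: exact arithmetic, no sampling
  prof <- structure(list(z = seq(-5, 5, by = 0.1),
                         pmf = pmax(0, 3 - abs(seq(-5, 5, by = 0.1)) * 1.5),
                         reference_z = -5, temperature = 298),
                    class = "pmf_profile")
  expect_equal(barrier_height(prof, region = c(-1, 1),
                              baseline = c(-5, -4)), 3)
  expect_equal(barrier_height(prof, region = c(-5, -4)), 0)
  expect_error(barrier_height(prof, region = c(30, 40)), "support")
  # difference of two profiles equals the element-wise difference's maximum
  prof2 <- prof; prof2$pmf <- prof$pmf + 1.25
  expect_equal(barrier_height(prof2, c(-1, 1), c(-5, -4)) -
                 barrier_height(prof, c(-1, 1), c(-5, -4)), 0,
               tolerance = 1e-12)
})

test_that("a sampled double-well barrier is recovered from umbrella windows", {
  dw <- analytic_potential("double_well", center = 0, barrier_height = 3,
                           well_separation = 6)
  wins <- make_windows(dw, seq(-5, 5, by = 1), n = 6000, seed = 70)
  pmf <- wham_solve(wins, bin_width = 0.1)
  expect_lt(pmf_rmsd(pmf, dw$fun), 0.12)
  got <- barrier_height(pmf, region = c(-1, 1), baseline = c(-4, -2))
  expect_equal(got, 3, tolerance = 0.15 / 3)
})
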
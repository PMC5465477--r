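# Umbrella-sampling bookkeeping and WHAM reconstruction of a 1-D potential
# of mean force. The bias is harmonic, w_i(z) = k/2 (z - z_i)^2 by default
# (a full-k convention, w_i = k (z - z_i)^2, is available because restraint
# conventions differ between MD engines). The self-consistent WHAM equations
# are iterated on a fixed-width histogram grid:
#
#   P(z_j) = sum_i n_ij / sum_i N_i exp(beta (f_i - w_i(z_j)))
#   f_i    = -kB T log sum_j P(z_j) exp(-beta w_i(z_j))
#
# until the largest per-window free-energy change drops below tolerance.

#' Construct an umbrella window
#'
#' @param center bias center z0 (angstrom).
#' @param spring_k harmonic bias stiffness (kcal/mol/A^2, > 0).
#' @param samples reaction-coordinate time series (angstrom).
#' @param retained_fraction trailing fraction of samples kept; the default
#'   0.95 discards the first 5 percent as equilibration (mirroring a 10 ns
#'   window analysed over its last 9.5 ns).
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, spring_k, samples = numeric(0),
                            retained_fraction = 0.95) {
  if (spring_k <= 0) stop("spring_k must be > 0")
  if (retained_fraction <= 0 || retained_fraction > 1)
    stop("retained_fraction must be in (0, 1]")
  structure(list(center = center, spring_k = spring_k,
                 samples = as.numeric(samples),
                 retained_fraction = retained_fraction),
            class = "umbrella_window")
}

#' Samples of a window after burn-in removal
#' @param window an `umbrella_window`.
#' @return numeric vector (error when empty after burn-in).
#' @export
retained_samples <- function(window) {
  n <- length(window$samples)
  keep <- floor(n * window$retained_fraction)
  if (keep < 1) stop("window at z = ", window$center,
                     " has no samples after burn-in")
  window$samples[(n - keep + 1):n]
}

#' Lay out umbrella windows along the axis
#'
#' Centers run from `z_start` toward `z_end` (inclusive of the start) in
#' steps of `spacing`; e.g. from -5 to -54 at 1 angstrom spacing gives 50
#' windows.
#'
#' @param z_start,z_end first center and range end (angstrom); must differ.
#' @param spacing center spacing (> 0, angstrom).
#' @param spring_k bias stiffness assigned to every window (kcal/mol/A^2);
#'   default 7.17.
#' @return list of empty `umbrella_window` objects.
#' @export
plan_windows <- function(z_start, z_end, spacing, spring_k = 7.17) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (z_start == z_end) stop("window range has zero length")
  centers <- seq(z_start, z_end, by = sign(z_end - z_start) * spacing)
  lapply(centers, umbrella_window, spring_k = spring_k)
}

#' Expected frame count of an umbrella window
#'
#' @param window_length_ns simulated window length (ns, > 0).
#' @param record_interval_ps recording interval (ps, > 0).
#' @return integer: floor(window_length / record_interval); 10 ns at 0.2 ps
#'   gives 50,000 frames.
#' @export
expected_frames <- function(window_length_ns, record_interval_ps) {
  if (window_length_ns <= 0 || record_interval_ps <= 0)
    stop("window length and record interval must be > 0")
  ## guard against binary representation of intervals like 0.2 ps
  as.integer(floor(window_length_ns * 1000 / record_interval_ps + 1e-9))
}

.bias_energy <- function(k, center, z, convention) {
  if (convention == "half_k") 0.5 * k * (z - center)^2 else k * (z - center)^2
}

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' @param windows list of `umbrella_window` objects with samples (>= 2
#'   windows; adjacent windows must share at least one occupied histogram
#'   bin).
#' @param temperature kelvin.
#' @param bin_width histogram bin width (angstrom).
#' @param tolerance convergence threshold on the per-window free-energy
#'   constants (kcal/mol per iteration).
#' @param max_iterations iteration cap; non-convergence is an error.
#' @param reference_z z at which the PMF is pinned to zero (nearest occupied
#'   bin); `NULL` zeroes the profile minimum.
#' @param bias_convention `"half_k"` for k/2 (z - z0)^2 (default) or
#'   `"full_k"` for k (z - z0)^2.
#' @return object of class `pmf_profile`: data frame fields `z` (bin
#'   centers) and `pmf` (kcal/mol) plus convergence metadata.
#' @export
wham_solve <- function(windows, temperature = 298, bin_width = 0.1,
                       tolerance = 1e-6, max_iterations = 1e5,
                       reference_z = NULL,
                       bias_convention = c("half_k", "full_k")) {
  bias_convention <- match.arg(bias_convention)
  if (length(windows) < 2) stop("WHAM needs at least 2 windows")
  if (temperature <= 0) stop("temperature must be > 0")
  if (bin_width <= 0) stop("bin_width must be > 0")
  kT <- KB_KCAL * temperature
  beta <- 1 / kT

  samples <- lapply(windows, retained_samples)
  lo <- min(vapply(samples, min, numeric(1)))
  hi <- max(vapply(samples, max, numeric(1)))
  breaks <- seq(floor(lo / bin_width) * bin_width,
                ceiling(hi / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  nb <- length(centers)
  nw <- length(windows)

  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    b <- findInterval(samples[[i]], breaks, rightmost.closed = TRUE)
    b[b < 1] <- 1; b[b > nb] <- nb
    counts[i, ] <- tabulate(b, nbins = nb)
  }
  Ni <- rowSums(counts)

  ## adjacent-window overlap check
  ord <- order(vapply(windows, function(w) w$center, numeric(1)))
  for (k in seq_len(nw - 1)) {
    i1 <- ord[k]; i2 <- ord[k + 1]
    if (!any(counts[i1, ] > 0 & counts[i2, ] > 0))
      stop("no histogram overlap between windows at z = ",
           windows[[i1]]$center, " and z = ", windows[[i2]]$center)
  }

  wmat <- t(vapply(windows, function(w)
    .bias_energy(w$spring_k, w$center, centers, bias_convention),
    numeric(nb)))
  hj <- colSums(counts)
  ## shift each window's bias by its minimum over occupied bins: a pure
  ## gauge change absorbed by f_i that keeps exp(-beta w) away from
  ## underflow when samples sit far from the window center
  wshift <- vapply(seq_len(nw), function(i) min(wmat[i, hj > 0]), numeric(1))
  wmat <- wmat - wshift
  expw <- exp(-beta * wmat)             # nw x nb

  f <- numeric(nw)
  iter <- 0L
  residual <- Inf
  repeat {
    iter <- iter + 1L
    denom <- as.numeric(t(expw) %*% (Ni * exp(beta * f)))
    P <- ifelse(denom > 0, hj / denom, 0)
    fz <- as.numeric(expw %*% P)
    fnew <- -kT * log(fz)
    fnew <- fnew - fnew[1]
    residual <- max(abs(fnew - f))
    f <- fnew
    if (residual < tolerance) break
    if (iter >= max_iterations)
      stop("WHAM did not converge in ", max_iterations,
           " iterations (residual ", signif(residual, 3), " kcal/mol)")
  }

  denom <- as.numeric(t(expw) %*% (Ni * exp(beta * f)))
  P <- ifelse(denom > 0 & hj > 0, hj / denom, NA_real_)
  P <- P / sum(P, na.rm = TRUE)
  pmf <- -kT * log(P)

  occupied <- which(!is.na(pmf))
  if (is.null(reference_z)) {
    shift <- min(pmf, na.rm = TRUE)
    ref_used <- centers[occupied[which.min(pmf[occupied])]]
  } else {
    j <- occupied[which.min(abs(centers[occupied] - reference_z))]
    shift <- pmf[j]
    ref_used <- centers[j]
  }
  pmf <- pmf - shift

  structure(list(z = centers, pmf = pmf, reference_z = ref_used,
                 temperature = temperature, bin_width = bin_width,
                 iterations = iter, residual = residual, converged = TRUE,
                 window_free_energies = f + wshift - wshift[1],
                 bias_convention = bias_convention),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("pmf_profile:", length(x$z), "bins over [", min(x$z), ",", max(x$z),
      "] A;", x$iterations, "WHAM iterations, residual",
      signif(x$residual, 3), "kcal/mol; zero at z =", x$reference_z, "A\n")
  invisible(x)
}

#' PMF value interpolated at given z
#' @param pmf a `pmf_profile`.
#' @param z query positions (angstrom).
#' @return PMF values (kcal/mol).
#' @export
pmf_at <- function(pmf, z) {
  ok <- !is.na(pmf$pmf)
  stats::approx(pmf$z[ok], pmf$pmf[ok], xout = z, rule = 2)$y
}

#' Barrier height over a region relative to a baseline
#'
#' @param pmf a `pmf_profile`.
#' @param region z interval `c(lo, hi)` scanned for the maximum.
#' @param baseline z interval whose minimum is the reference; `NULL` uses the
#'   profile's zero reference.
#' @return barrier height in kcal/mol.
#' @export
barrier_height <- function(pmf, region, baseline = NULL) {
  sel <- function(interval) {
    idx <- which(pmf$z >= min(interval) & pmf$z <= max(interval) &
                   !is.na(pmf$pmf))
    if (length(idx) == 0)
      stop("interval [", min(interval), ", ", max(interval),
           "] is outside the profile's support")
    idx
  }
  top <- max(pmf$pmf[sel(region)])
  base <- if (is.null(baseline)) 0 else min(pmf$pmf[sel(baseline)])
  top - base
}

#' Write umbrella-window samples to a plain-text file
#'
#' Dialect: comment header `# center= <z>` and `# spring_k= <k>`, then one z
#' value per line.
#'
#' @param window an `umbrella_window`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_file <- function(window, path) {
  writeLines(c(sprintf("# center= %.6f", window$center),
               sprintf("# spring_k= %.6f", window$spring_k),
               sprintf("%.6f", window$samples)), path)
  invisible(path)
}

#' Read an umbrella-window sample file
#' @param path file written in the [write_window_file()] dialect.
#' @param retained_fraction trailing fraction of samples kept.
#' @return an `umbrella_window`.
#' @export
read_window_file <- function(path, retained_fraction = 0.95) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  center <- .kv_num(hdr[grep("center=", hdr)][1], "center")
  k <- .kv_num(hdr[grep("spring_k=", hdr)][1], "spring_k")
  if (is.null(center) || is.null(k))
    stop("window file lacks center=/spring_k= header: ", path)
  z <- as.numeric(grep("^#", lines, value = TRUE, invert = TRUE))
  z <- z[!is.na(z)]
  umbrella_window(center, k, z, retained_fraction)
}
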
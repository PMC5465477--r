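# Helix geometry and structure comparison: M2 tilt angles measured from
# four-residue turns, centered running averages, Kabsch least-squares
# superposition and backbone RMSD reports over named residue ranges.

#' Default four-residue turn windows of the M2 helix
#'
#' The intracellular, middle and extracellular turns span the -2'..16'
#' stretch of the pore-lining helix: residues 222-225, 230-233, 237-240.
#' @return named list of integer residue quadruples.
#' @export
default_turn_windows <- function() {
  list(intracellular = 222:225, middle = 230:233, extracellular = 237:240)
}

.backbone_names <- c("N", "CA", "C", "O")

.turn_com <- function(topology, frame, subunit, residues) {
  a <- topology$atoms
  idx <- which(a$subunit_id == subunit & a$residue_seq %in% residues &
                 a$atom_name %in% .backbone_names & a$is_heavy)
  if (length(idx) == 0)
    stop("no backbone atoms for residues ",
         paste(range(residues), collapse = "-"), " in subunit ", subunit)
  .com(frame$xyz[idx, , drop = FALSE], a$mass[idx])
}

#' M2 helix tilt angles for one subunit
#'
#' Mass-weighted backbone centers of mass are taken for each four-residue
#' turn; the bottom vector runs from the intracellular to the middle turn,
#' the top vector from the middle to the extracellular turn, and each angle
#' is measured against the membrane normal. A helix parallel to the normal
#' reads (0, 0) degrees; an inverted one reads 180.
#'
#' @param topology a `channel_topology`.
#' @param frame a `channel_frame`.
#' @param subunit chain identifier.
#' @param turns named list of three residue quadruples
#'   (intracellular/middle/extracellular); see [default_turn_windows()].
#' @param membrane_normal unit vector, default the z axis.
#' @return named vector `c(top_angle, bottom_angle)` in degrees.
#' @export
helix_tilt <- function(topology, frame, subunit,
                       turns = default_turn_windows(),
                       membrane_normal = c(0, 0, 1)) {
  com_ic <- .turn_com(topology, frame, subunit, turns$intracellular)
  com_mid <- .turn_com(topology, frame, subunit, turns$middle)
  com_ec <- .turn_com(topology, frame, subunit, turns$extracellular)
  c(top_angle = vector_angle(com_ec - com_mid, membrane_normal),
    bottom_angle = vector_angle(com_mid - com_ic, membrane_normal))
}

#' Tilt-angle time series for all subunits
#' @inheritParams helix_tilt
#' @param traj a `channel_trajectory`.
#' @param stride sampling interval in ps.
#' @return data frame: `time`, `subunit`, `top_angle`, `bottom_angle`.
#' @export
tilt_series <- function(traj, turns = default_turn_windows(),
                        membrane_normal = c(0, 0, 1), stride = NULL) {
  fidx <- sample_frames(traj, stride)
  rows <- list()
  for (f in fidx) {
    fr <- get_frame(traj, f)
    for (s in traj$topology$subunits) {
      ang <- helix_tilt(traj$topology, fr, s, turns, membrane_normal)
      rows[[length(rows) + 1]] <- data.frame(
        time = traj$times[f], subunit = s,
        top_angle = ang[["top_angle"]], bottom_angle = ang[["bottom_angle"]])
    }
  }
  do.call(rbind, rows)
}

#' Centered running average with truncated edges
#'
#' @param values numeric series.
#' @param times sample times (same length); defaults to an index grid.
#' @param window full window width in the units of `times`; must be at least
#'   the sampling interval.
#' @return numeric vector of the same length.
#' @export
running_average <- function(values, times = seq_along(values) - 1, window) {
  if (length(values) != length(times)) stop("values/times length mismatch")
  if (length(values) > 1) {
    interval <- min(diff(times))
    if (window < interval)
      stop("window (", window, ") is below the sampling interval (",
           interval, ")")
  }
  half <- window / 2
  vapply(seq_along(values), function(i)
    mean(values[times >= times[i] - half - 1e-9 &
                  times <= times[i] + half + 1e-9]), numeric(1))
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected mobile atoms onto the reference, via SVD with the determinant
#' sign correction (no reflections).
#'
#' @param mobile,reference N x 3 coordinate matrices with matching rows.
#' @param selection optional row indices used for the fit and the RMSD.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   mobile is `mobile %*% t(rotation) + translation`), `rmsd` (angstrom over
#'   the selection) and `fitted` (all mobile coordinates transformed).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(selection)) {
    if (nrow(mobile) != nrow(reference)) stop("atom counts differ")
    selection <- seq_len(nrow(mobile))
  }
  if (max(selection) > nrow(mobile) || max(selection) > nrow(reference))
    stop("selection exceeds coordinate rows")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selected atom counts differ")
  if (nrow(P) < 3) stop("superposition needs at least 3 atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) selection: rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- as.numeric(cq - R %*% cp)
  fitted <- mobile %*% t(R) + matrix(translation, nrow(mobile), 3,
                                     byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted[selection, , drop = FALSE] - Q)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd, fitted = fitted)
}

#' Default residue ranges for structure comparison
#'
#' `Protein` is every protein residue; `ECD` the extracellular domain
#' (14-192), `TMD` the transmembrane domain (195-315) and `Pore` the
#' pore-lining stretch (221-244).
#' @return named list of residue ranges (`NULL` = all).
#' @export
default_rmsd_ranges <- function() {
  list(Protein = NULL, ECD = 14:192, TMD = 195:315, Pore = 221:244)
}

.range_backbone <- function(topology, residues) {
  a <- topology$atoms
  keep <- a$role == "protein" & a$atom_name %in% .backbone_names & a$is_heavy
  if (!is.null(residues)) keep <- keep & a$residue_seq %in% residues
  idx <- which(keep)
  key <- paste(a$subunit_id[idx], a$residue_seq[idx], a$atom_name[idx])
  list(idx = idx, key = key)
}

#' Backbone RMSD versus a reference structure over named residue ranges
#'
#' For each range, the trajectory backbone is superposed onto the matching
#' reference backbone (atoms matched by subunit, residue and atom name) at
#' every sampled frame of the trajectory tail, and the post-fit RMSD is
#' summarized as mean +/- sample SD.
#'
#' @param traj a `channel_trajectory`.
#' @param reference list with `topology` and `frame` (or a `channel_frame`
#'   sharing the trajectory's topology).
#' @param ranges named list of residue ranges; see [default_rmsd_ranges()].
#' @param stride sampling interval in ps (default 100).
#' @param tail_ns analyse only the last `tail_ns` nanoseconds; `NULL` for the
#'   whole trajectory; longer than the trajectory is an error.
#' @return data frame: `range`, `n_frames`, `mean_rmsd`, `sd_rmsd`
#'   (angstrom).
#' @export
rmsd_report <- function(traj, reference, ranges = default_rmsd_ranges(),
                        stride = 100, tail_ns = NULL) {
  if (inherits(reference, "channel_frame"))
    reference <- list(topology = traj$topology, frame = reference)
  span <- traj$times[length(traj$times)] - traj$times[1]
  t_min <- traj$times[1]
  if (!is.null(tail_ns)) {
    if (tail_ns * 1000 > span + 1e-9)
      stop("tail (", tail_ns, " ns) exceeds the trajectory span")
    t_min <- traj$times[length(traj$times)] - tail_ns * 1000
  }
  fidx <- sample_frames(traj, stride)
  fidx <- fidx[traj$times[fidx] >= t_min - 1e-9]
  rows <- list()
  for (rn in names(ranges)) {
    mob <- .range_backbone(traj$topology, ranges[[rn]])
    ref <- .range_backbone(reference$topology, ranges[[rn]])
    common <- intersect(mob$key, ref$key)
    if (length(common) < 3)
      stop("range '", rn, "' resolves to fewer than 3 matched backbone atoms")
    mi <- mob$idx[match(common, mob$key)]
    ri <- ref$idx[match(common, ref$key)]
    refx <- reference$frame$xyz[ri, , drop = FALSE]
    r <- vapply(fidx, function(f)
      kabsch_superpose(matrix(traj$coords[mi, , f], ncol = 3), refx)$rmsd,
      numeric(1))
    rows[[rn]] <- data.frame(range = rn, n_frames = length(fidx),
                             mean_rmsd = mean(r), sd_rmsd = stats::sd(r))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
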
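# Pore geometry: channel axis estimation, a pore-radius profiler (sphere
# that fits at each axial position without overlapping any protein atom's
# van der Waals sphere), gate water counting inside the 9'-16' cylinder,
# and the dehydration classification (fewer than 5 gate waters).

#' Estimate the channel pore axis
#'
#' Fits a line through the per-residue ring centroids of the pore-lining M2
#' helices (the centroid over subunits of each M2 residue's atoms), by
#' principal component; with `method = "z_axis"` the laboratory z axis
#' through the transmembrane centroid is used instead.
#'
#' @param topology a `channel_topology` (>= 3 protein subunits).
#' @param frame a `channel_frame`.
#' @param method `"m2_fit"` or `"z_axis"`.
#' @param m2_residues residue numbers of the pore-lining helix.
#' @return list with `origin` (point on the axis) and `direction` (unit
#'   vector, oriented toward +z).
#' @export
pore_axis <- function(topology, frame, method = c("m2_fit", "z_axis"),
                      m2_residues = 221:244) {
  method <- match.arg(method)
  if (length(topology$subunits) < 3)
    stop("pore axis needs at least 3 protein subunits")
  a <- topology$atoms
  m2 <- which(a$role == "protein" & a$residue_seq %in% m2_residues)
  if (length(m2) == 0) stop("no pore-lining helix atoms found")
  if (method == "z_axis") {
    return(list(origin = colMeans(frame$xyz[m2, , drop = FALSE]),
                direction = c(0, 0, 1)))
  }
  centroids <- t(vapply(unique(a$residue_seq[m2]), function(r) {
    idx <- m2[a$residue_seq[m2] == r]
    colMeans(frame$xyz[idx, , drop = FALSE])
  }, numeric(3)))
  ctr <- colMeans(centroids)
  pc <- stats::prcomp(centroids, center = TRUE)
  dir <- pc$rotation[, 1]
  if (dir[3] < 0) dir <- -dir
  list(origin = ctr, direction = dir / sqrt(sum(dir^2)))
}

.axial_coord <- function(xyz, axis) {
  as.numeric(rbind(xyz) %*% axis$direction)
}

.radial_dist <- function(xyz, axis) {
  xyz <- rbind(xyz)
  s <- .axial_coord(xyz, axis) - sum(axis$origin * axis$direction)
  foot <- matrix(axis$origin, nrow(xyz), 3, byrow = TRUE) + s %o% axis$direction
  sqrt(rowSums((xyz - foot)^2))
}

## point on the axis whose axial coordinate (projection onto the direction)
## equals z
.axis_point <- function(axis, z) {
  axis$origin + (z - sum(axis$origin * axis$direction)) * axis$direction
}

#' Pore radius profile along the channel axis
#'
#' At each axial position the radius is that of the largest probe sphere
#' centered in the perpendicular plane that touches no protein atom's van
#' der Waals sphere: `min_i (|c - x_i| - r_vdw,i)`, clamped at zero. With
#' `probe = "on-axis"` the center is fixed on the axis; with
#' `"in-plane-search"` it is optimized within `search_radius` of the axis by
#' a deterministic coarse grid (0.5 angstrom) plus Nelder-Mead refinement, so
#' the searched radius is never below the on-axis one.
#'
#' @param topology a `channel_topology` (supplies per-atom vdW radii).
#' @param frame a `channel_frame`.
#' @param z_range axial interval `c(lo, hi)` (angstrom).
#' @param z_step grid spacing (angstrom).
#' @param axis from [pore_axis()]; computed from the frame when `NULL`.
#' @param probe `"on-axis"` or `"in-plane-search"`.
#' @param search_radius maximal in-plane displacement of the probe center.
#' @return data frame of class `pore_profile` (`z`, `radius`) with the axis
#'   recorded in attributes.
#' @export
pore_radius_profile <- function(topology, frame, z_range, z_step = 0.5,
                                axis = NULL,
                                probe = c("on-axis", "in-plane-search"),
                                search_radius = 5) {
  probe <- match.arg(probe)
  if (length(z_range) != 2 || z_range[1] >= z_range[2])
    stop("z_range must be an ordered, non-empty interval")
  if (is.null(axis)) axis <- pore_axis(topology, frame)
  prot <- role_atoms(topology, "protein", heavy_only = TRUE)
  if (length(prot) == 0) stop("no protein atoms")
  px <- frame$xyz[prot, , drop = FALSE]
  pr <- topology$atoms$vdw[prot]
  radius_at <- function(c0) {
    d <- sqrt(colSums((t(px) - c0)^2)) - pr
    max(0, min(d))
  }
  ## orthonormal in-plane basis
  dir <- axis$direction
  u <- if (abs(dir[3]) < 0.9) c(-dir[2], dir[1], 0) else c(1, 0, 0) - dir[1] * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2], dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  zs <- seq(z_range[1], z_range[2], by = z_step)
  radii <- vapply(zs, function(z) {
    c0 <- .axis_point(axis, z)
    r0 <- radius_at(c0)
    if (probe == "on-axis") return(r0)
    ## coarse grid then local refinement, center constrained near the axis
    offs <- expand.grid(a = seq(-search_radius, search_radius, by = 0.5),
                        b = seq(-search_radius, search_radius, by = 0.5))
    offs <- offs[offs$a^2 + offs$b^2 <= search_radius^2, ]
    grid_r <- mapply(function(a, b) radius_at(c0 + a * u + b * v),
                     offs$a, offs$b)
    best <- which.max(grid_r)
    obj <- function(p) {
      if (sum(p^2) > search_radius^2) return(1e6)
      -radius_at(c0 + p[1] * u + p[2] * v)
    }
    opt <- stats::optim(c(offs$a[best], offs$b[best]), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 200))
    max(r0, grid_r[best], -opt$value)
  }, numeric(1))
  structure(data.frame(z = zs, radius = radii),
            axis = axis, probe = probe,
            class = c("pore_profile", "data.frame"))
}

#' Count waters inside the hydrophobic-gate cylinder for one frame
#'
#' The gate cylinder has the given radius about the pore axis and spans, in
#' axial coordinate, the band between the mean z of the 9' C-beta ring and
#' the mean z of the 16' C-beta ring (band boundaries re-read from the frame,
#' inclusive). Water molecules are counted by their oxygen atoms.
#'
#' @param topology a `channel_topology`.
#' @param frame a `channel_frame`.
#' @param gate gate `site_definition`; defaults to the built-in 9'/16'
#'   C-beta markers.
#' @param cylinder_radius cylinder radius (angstrom, default 4).
#' @param axis pore axis; recomputed from the frame when `NULL`.
#' @return integer water count.
#' @export
hydration_count <- function(topology, frame, gate = default_sites()$gate,
                            cylinder_radius = 4, axis = NULL) {
  if (is.null(axis)) axis <- pore_axis(topology, frame)
  wox <- water_oxygens(topology)
  if (length(wox) == 0) stop("topology contains no waters")
  ring_z <- vapply(unique(gate$members$residue_seq), function(r) {
    idx <- unlist(lapply(topology$subunits, function(s) {
      an <- gate$members$atom_name[gate$members$residue_seq == r][1]
      hit <- residue_atoms(topology, s, r, if (is.na(an)) NULL else an)
      if (length(hit) == 0)
        stop("gate marker missing: residue ", r, " (",
             ifelse(is.na(an), "any atom", an), ") in subunit ", s)
      hit
    }))
    mean(.axial_coord(frame$xyz[idx, , drop = FALSE], axis))
  }, numeric(1))
  band <- range(ring_z)
  wz <- .axial_coord(frame$xyz[wox, , drop = FALSE], axis)
  wr <- .radial_dist(frame$xyz[wox, , drop = FALSE], axis)
  sum(wz >= band[1] & wz <= band[2] & wr <= cylinder_radius)
}

#' Gate hydration over time with the dehydration flag
#'
#' Applies [hydration_count()] per frame (the axis and the C-beta band are
#' re-evaluated each frame) and flags frames with strictly fewer than
#' `threshold` gate waters as dehydrated; a frame with exactly `threshold`
#' waters is hydrated.
#'
#' @param traj a `channel_trajectory`.
#' @param gate gate `site_definition`.
#' @param cylinder_radius cylinder radius (angstrom).
#' @param threshold dehydration cutoff (default 5, i.e. dehydrated when
#'   n < 5).
#' @param stride sampling interval in ps.
#' @param recenter_axis re-fit the pore axis each frame; `FALSE` uses the
#'   first frame's axis throughout.
#' @return data frame of class `hydration_series`: `time`, `n_waters`,
#'   `dehydrated`; the threshold is stored as an attribute.
#' @export
hydration_series <- function(traj, gate = default_sites()$gate,
                             cylinder_radius = 4, threshold = 5,
                             stride = NULL, recenter_axis = TRUE) {
  fidx <- sample_frames(traj, stride)
  fixed_axis <- if (recenter_axis) NULL else
    pore_axis(traj$topology, get_frame(traj, fidx[1]))
  n <- vapply(fidx, function(f)
    hydration_count(traj$topology, get_frame(traj, f), gate,
                    cylinder_radius, axis = fixed_axis), numeric(1))
  structure(data.frame(time = traj$times[fidx], n_waters = as.integer(n),
                       dehydrated = n < threshold),
            threshold = threshold,
            class = c("hydration_series", "data.frame"))
}
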
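# Ligand phase partitioning. Each ligand is classified per frame as
# protein-associated (within the contact cutoff of any protein atom),
# membrane (center of mass between the phosphate planes) or aqueous, in that
# precedence order; membrane bounds are the per-leaflet mean phosphate z,
# re-read each frame.

#' Phosphate-plane membrane bounds of one frame
#'
#' Leaflets are assigned by the sign of each phosphorus marker's z relative
#' to the mean phosphate z (the membrane center).
#'
#' @param topology a `channel_topology`.
#' @param frame a `channel_frame`.
#' @return numeric `c(z_low, z_high)`: mean phosphate z per leaflet.
#' @export
membrane_bounds <- function(topology, frame) {
  a <- topology$atoms
  p <- which(a$role == "lipid" & a$element == "P")
  if (length(p) == 0) stop("no phosphate marker atoms in topology")
  z <- frame$xyz[p, 3]
  mid <- mean(z)
  lower <- z[z < mid]; upper <- z[z >= mid]
  if (length(lower) == 0 || length(upper) == 0)
    stop("phosphate markers found in only one leaflet")
  c(mean(lower), mean(upper))
}

#' Membrane width of one frame
#'
#' Mean z of the upper-leaflet phosphorus markers minus the lower leaflet's.
#'
#' @inheritParams membrane_bounds
#' @return width in angstrom.
#' @export
membrane_width <- function(topology, frame) {
  b <- membrane_bounds(topology, frame)
  b[2] - b[1]
}

#' Classify a ligand's phase in one frame
#'
#' Precedence: `protein` when any ligand heavy atom is within
#' `protein_cutoff` of any protein heavy atom (even inside the membrane
#' band), else `membrane` when the ligand center of mass lies strictly
#' between the phosphate planes, else `aqueous`.
#'
#' @param topology a `channel_topology`.
#' @param frame a `channel_frame`.
#' @param ligand_id ligand identifier (see [ligand_ids()]).
#' @param bounds membrane bounds `c(z_low, z_high)`; computed from the frame
#'   when `NULL`.
#' @param protein_cutoff angstrom; defaults to the 3.5 angstrom contact
#'   criterion.
#' @param periodic minimum-image distances for the protein criterion.
#' @return one of `"protein"`, `"membrane"`, `"aqueous"`.
#' @export
classify_phase <- function(topology, frame, ligand_id, bounds = NULL,
                           protein_cutoff = 3.5, periodic = TRUE) {
  if (is.null(bounds)) bounds <- membrane_bounds(topology, frame)
  lig <- ligand_atoms(topology, ligand_id, heavy_only = TRUE)
  prot <- role_atoms(topology, "protein", heavy_only = TRUE)
  d <- min_distance(frame$xyz[lig, , drop = FALSE],
                    frame$xyz[prot, , drop = FALSE],
                    if (periodic) frame$box else NULL)
  if (d <= protein_cutoff) return("protein")
  comz <- .com(frame$xyz[lig, , drop = FALSE],
               topology$atoms$mass[lig])[3]
  if (comz > bounds[1] && comz < bounds[2]) "membrane" else "aqueous"
}

#' Phase fractions of all ligands over a trajectory
#'
#' @param traj a `channel_trajectory`.
#' @param stride sampling interval in ps.
#' @param protein_cutoff angstrom.
#' @param periodic minimum-image distances.
#' @return data frame of class `phase_series`: `time`, counts `n_aqueous`,
#'   `n_membrane`, `n_protein` and the corresponding fractions (summing to 1
#'   each frame).
#' @export
phase_fractions <- function(traj, stride = NULL, protein_cutoff = 3.5,
                            periodic = TRUE) {
  topo <- traj$topology
  lids <- ligand_ids(topo)
  if (length(lids) == 0) stop("topology contains no ligands")
  fidx <- sample_frames(traj, stride)
  rows <- lapply(fidx, function(f) {
    fr <- get_frame(traj, f)
    bounds <- membrane_bounds(topo, fr)
    ph <- vapply(lids, function(id)
      classify_phase(topo, fr, id, bounds, protein_cutoff, periodic),
      character(1))
    n <- c(aqueous = sum(ph == "aqueous"), membrane = sum(ph == "membrane"),
           protein = sum(ph == "protein"))
    data.frame(time = traj$times[f], n_aqueous = n[["aqueous"]],
               n_membrane = n[["membrane"]], n_protein = n[["protein"]],
               frac_aqueous = n[["aqueous"]] / length(lids),
               frac_membrane = n[["membrane"]] / length(lids),
               frac_protein = n[["protein"]] / length(lids))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phase_series", "data.frame")
  out
}

#' Aqueous ligand concentration
#'
#' Converts a molecule count in a given aqueous volume to millimolar:
#' c = n / (N_A V), with N_A = 6.02214e23 and V in cubic angstrom.
#'
#' @param n_ligands_aqueous molecule count.
#' @param aqueous_volume volume in cubic angstrom (> 0).
#' @return concentration in mM.
#' @export
aqueous_concentration <- function(n_ligands_aqueous, aqueous_volume) {
  if (any(aqueous_volume <= 0)) stop("aqueous volume must be > 0")
  n_ligands_aqueous * 1e30 / (6.02214e23 * aqueous_volume)
}

#' Rough aqueous-volume estimate of one frame
#'
#' Box volume minus the membrane slab (box cross-section times the
#' phosphate-to-phosphate width) minus an approximate protein volume outside
#' the slab (atoms above/below the slab at an effective 20 A^3 per heavy
#' atom). This is an explicit approximation intended for order-of-magnitude
#' molarity estimates, clamped to [0, box volume].
#'
#' @inheritParams membrane_bounds
#' @return estimated aqueous volume in cubic angstrom.
#' @export
estimate_aqueous_volume <- function(topology, frame) {
  b <- membrane_bounds(topology, frame)
  vbox <- prod(frame$box)
  slab <- frame$box[1] * frame$box[2] * (b[2] - b[1])
  prot <- role_atoms(topology, "protein", heavy_only = TRUE)
  pz <- frame$xyz[prot, 3]
  outside <- sum(pz > b[2] | pz < b[1]) * 20
  min(vbox, max(0, vbox - slab - outside))
}
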
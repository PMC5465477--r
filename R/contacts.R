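# Ligand-residue contact statistics. A residue is "in contact" in a frame
# when any ligand heavy atom lies within the cutoff (default 3.5 angstrom)
# of any heavy atom of the residue; probabilities are the percentage of
# sampled frames in contact, tabulated per subunit and aggregated across
# subunits as mean and sample (n - 1) standard deviation.

#' Is a ligand in contact with a residue in one frame?
#'
#' @param frame a `channel_frame`.
#' @param ligand_atoms,residue_atoms non-empty atom index vectors.
#' @param cutoff contact distance (angstrom); the boundary is inclusive, a
#'   pair at exactly the cutoff counts as contact.
#' @param periodic use minimum-image distances under the frame's box.
#' @return logical.
#' @export
residue_contact <- function(frame, ligand_atoms, residue_atoms, cutoff = 3.5,
                            periodic = TRUE) {
  if (length(ligand_atoms) == 0 || length(residue_atoms) == 0)
    stop("atom sets must be non-empty")
  d <- min_distance(frame$xyz[ligand_atoms, , drop = FALSE],
                    frame$xyz[residue_atoms, , drop = FALSE],
                    if (periodic) frame$box else NULL)
  d <= cutoff
}

#' Cross-subunit mean and standard deviation of contact percentages
#'
#' @param values per-subunit contact percentages.
#' @param n_expected required number of values (default 5, a pentamer).
#' @return named vector `c(mean, sd)`; sd uses the n - 1 denominator.
#' @export
aggregate_subunits <- function(values, n_expected = 5) {
  if (length(values) != n_expected)
    stop("expected ", n_expected, " per-subunit values, got ", length(values))
  c(mean = mean(values), sd = stats::sd(values))
}

#' Assemble a contact table from per-subunit percentages
#'
#' @param residue_seq residue numbers (rows).
#' @param values matrix of contact percentages, residues x subunits.
#' @param subunits column labels.
#' @param residue_name optional residue names.
#' @return data frame of class `contact_table` with per-subunit columns and
#'   aggregated `mean` and `sd` columns.
#' @export
contact_table <- function(residue_seq, values,
                          subunits = LETTERS[seq_len(ncol(values))],
                          residue_name = NULL) {
  values <- as.matrix(values)
  agg <- t(apply(values, 1, aggregate_subunits, n_expected = ncol(values)))
  out <- data.frame(residue_seq = residue_seq,
                    residue_name = if (is.null(residue_name)) NA_character_
                                   else residue_name)
  out[subunits] <- as.data.frame(values)
  out$mean <- agg[, "mean"]
  out$sd <- agg[, "sd"]
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Contact probability table over a trajectory
#'
#' For every member residue of `site` and every subunit, the percentage of
#' sampled frames in which the subunit's ligand contacts the residue. With
#' `stop_rule = "until_dissociated"` sampling of a subunit stops at the first
#' frame where its ligand is more than the dissociation cutoff from the whole
#' protein (the ligand is judged to have unbound).
#'
#' @param traj a `channel_trajectory`.
#' @param site a `site_definition` whose members are tabulated.
#' @param stride sampling interval in ps (default 1000, i.e. every 1 ns).
#' @param stop_rule `"until_dissociated"` or `"full"`.
#' @param ligand_map named character vector subunit -> ligand id; by default
#'   the i-th ligand is paired with the i-th subunit.
#' @param include_hydrogens count hydrogens in the contact criterion; by
#'   default only heavy atoms are used.
#' @param periodic minimum-image distances.
#' @return a `contact_table`.
#' @export
contact_probability <- function(traj, site, stride = 1000,
                                stop_rule = c("until_dissociated", "full"),
                                ligand_map = NULL, include_hydrogens = FALSE,
                                periodic = TRUE) {
  stop_rule <- match.arg(stop_rule)
  topo <- traj$topology
  subunits <- topo$subunits
  fidx <- sample_frames(traj, stride)
  if (length(fidx) < 2) stop("trajectory spans fewer than 2 sampled frames")
  if (is.null(ligand_map)) {
    lids <- ligand_ids(topo)
    if (length(lids) < length(subunits))
      stop("fewer ligands than subunits; supply ligand_map")
    ligand_map <- stats::setNames(lids[seq_along(subunits)], subunits)
  }
  heavy <- !include_hydrogens
  prot <- role_atoms(topo, "protein", heavy_only = heavy)
  res <- site$members$residue_seq
  box <- if (periodic) traj$box else NULL

  vals <- matrix(NA_real_, length(res), length(subunits),
                 dimnames = list(res, subunits))
  for (s in seq_along(subunits)) {
    lig <- ligand_atoms(topo, ligand_map[[subunits[s]]], heavy_only = heavy)
    res_atoms <- lapply(res, function(r) {
      idx <- residue_atoms(topo, subunits[s], r)
      if (heavy) idx <- idx[topo$atoms$is_heavy[idx]]
      if (length(idx) == 0)
        stop("no atoms for (subunit ", subunits[s], ", residue ", r, ")")
      idx
    })
    hits <- matrix(FALSE, length(fidx), length(res))
    used <- 0L
    for (fi in seq_along(fidx)) {
      f <- fidx[fi]
      bx <- if (periodic) traj$box[f, ] else NULL
      xyz <- traj$coords[, , f]
      if (stop_rule == "until_dissociated") {
        dprot <- min_distance(xyz[lig, , drop = FALSE],
                              xyz[prot, , drop = FALSE], bx)
        if (dprot > site$dissociation_cutoff) break
      }
      used <- used + 1L
      for (ri in seq_along(res)) {
        d <- min_distance(xyz[lig, , drop = FALSE],
                          xyz[res_atoms[[ri]], , drop = FALSE], bx)
        hits[fi, ri] <- d <= site$contact_enter_cutoff
      }
    }
    if (used == 0) used <- 1L  # dissociated before the first sample: all 0
    vals[, s] <- 100 * colSums(hits) / used
  }
  rn <- vapply(res, function(r) {
    i <- which(topo$atoms$residue_seq == r & topo$atoms$role == "protein")[1]
    if (is.na(i)) NA_character_ else topo$atoms$residue_name[i]
  }, character(1))
  contact_table(res, vals, subunits, residue_name = rn)
}
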
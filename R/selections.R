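# Named residue selections (binding sites, gate markers) with the contact
# and dissociation cutoffs that the event detector uses.

#' Define a named site
#'
#' A site is a named set of residues, applied per subunit, together with the
#' two cutoffs of the binding criterion: a ligand is judged bound when any of
#' its heavy atoms comes within `contact_enter_cutoff` of a site atom, and
#' judged to unbind when it moves more than `dissociation_cutoff` from the
#' whole protein.
#'
#' @param name site name (e.g. `"TM1"`, `"TM2"`, `"gate"`).
#' @param members data frame with column `residue_seq` and optional
#'   `atom_name` (`NA` = all atoms of the residue), or a plain integer vector
#'   of residue numbers.
#' @param contact_enter_cutoff angstrom; default 3.5.
#' @param dissociation_cutoff angstrom; default 5.0; must be >= the enter
#'   cutoff.
#' @return object of class `site_definition`.
#' @export
site_definition <- function(name, members, contact_enter_cutoff = 3.5,
                            dissociation_cutoff = 5.0) {
  if (is.numeric(members))
    members <- data.frame(residue_seq = as.integer(members),
                          atom_name = NA_character_)
  if (is.null(members$atom_name)) members$atom_name <- NA_character_
  if (contact_enter_cutoff <= 0 || dissociation_cutoff <= 0)
    stop("cutoffs must be positive")
  if (dissociation_cutoff < contact_enter_cutoff)
    stop("dissociation_cutoff must be >= contact_enter_cutoff")
  structure(list(name = name,
                 members = members[, c("residue_seq", "atom_name")],
                 contact_enter_cutoff = contact_enter_cutoff,
                 dissociation_cutoff = dissociation_cutoff),
            class = "site_definition")
}

#' Built-in site definitions
#'
#' `TM1` is the intrasubunit anesthetic site seen crystallographically,
#' defined by its 13 lumen-lining residues (Tyr-119, Pro-120, Phe-121,
#' Tyr-197, Ile-201, Ile-202, Met-205, Lys-206, Val-242, Tyr-254, Thr-255,
#' Ile-258, Asn-307). `TM2` is the membrane-facing site held by Tyr-254 and
#' Asn-307. `gate` marks the hydrophobic gate boundaries 9' (Ile-233) and
#' 16' (Ile-240) via their C-beta atoms, and `filter` the -2' glutamate ring
#' (Glu-222).
#'
#' @return named list of `site_definition` objects.
#' @export
default_sites <- function() {
  tm1 <- c(119L, 120L, 121L, 197L, 201L, 202L, 205L, 206L, 242L,
           254L, 255L, 258L, 307L)
  list(
    TM1 = site_definition("TM1", tm1),
    TM2 = site_definition("TM2", c(254L, 307L)),
    gate = site_definition("gate",
      data.frame(residue_seq = prime_to_residue(c("9'", "16'")),
                 atom_name = "CB")),
    filter = site_definition("filter", prime_to_residue("-2'"))
  )
}

#' Resolve a site to atom indices within one subunit
#'
#' @param topology a `channel_topology`.
#' @param site a `site_definition`.
#' @param subunit chain identifier; all member residues must exist there.
#' @param heavy_only keep only non-hydrogen atoms.
#' @return integer vector of atom indices.
#' @export
resolve_selection <- function(topology, site, subunit, heavy_only = FALSE) {
  idx <- integer(0)
  for (i in seq_len(nrow(site$members))) {
    rs <- site$members$residue_seq[i]
    an <- site$members$atom_name[i]
    hit <- residue_atoms(topology, subunit, rs,
                         if (is.na(an)) NULL else an)
    if (length(hit) == 0)
      stop("site '", site$name, "': no atoms for (subunit ", subunit,
           ", residue ", rs, if (!is.na(an)) paste0(", atom ", an) else "",
           ")")
    idx <- c(idx, hit)
  }
  idx <- sort(unique(idx))
  if (heavy_only) idx <- idx[topology$atoms$is_heavy[idx]]
  idx
}

#' Resolve a site across all subunits
#' @inheritParams resolve_selection
#' @return named list of atom index vectors, one per subunit.
#' @export
resolve_selection_all <- function(topology, site, heavy_only = FALSE) {
  stats::setNames(lapply(topology$subunits, function(s)
    resolve_selection(topology, site, s, heavy_only)), topology$subunits)
}

#' Resolve an atom selector
#'
#' Selectors name atoms for distance series: either an integer vector of atom
#' indices or a list with fields `subunit`, `residue_seq` and optional
#' `atom_name`.
#'
#' @param topology a `channel_topology`.
#' @param selector integer indices or a list selector.
#' @return integer vector of atom indices (error if empty).
#' @export
resolve_atoms <- function(topology, selector) {
  idx <- if (is.numeric(selector)) {
    as.integer(selector)
  } else if (is.list(selector)) {
    residue_atoms(topology, selector$subunit, selector$residue_seq,
                  selector$atom_name)
  } else stop("unsupported selector")
  if (length(idx) == 0) stop("selector resolves to no atoms")
  idx
}
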
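#' @section Coordinate conventions:
#' All coordinates are in angstrom, times in picoseconds, energies in
#' kcal/mol. The channel pore axis is z with the extracellular side at high z
#' by default; boxes are orthorhombic and distances use the minimum-image
#' convention in all three dimensions unless periodicity is disabled.
#'
#' @keywords internal
"_PACKAGE"

## Boltzmann constant in kcal/(mol K)
KB_KCAL <- 0.0019872

## van der Waals radii (angstrom) used by the pore profiler; overridable.
.default_vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
                  F = 1.47, NA. = 2.27, CL = 1.75)

## atomic masses (amu) for mass-weighted centres of mass
.default_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008,
                   P = 30.974, F = 18.998, NA. = 22.990, CL = 35.45)

#' Map M2 prime-notation positions to author residue numbers
#'
#' Pore-lining M2 helix positions are conventionally indexed with prime
#' notation; in this channel -2' is Glu-222, 9' is Ile-233 (lower gate
#' boundary) and 16' is Ile-240 (upper gate boundary).
#'
#' @param prime character vector such as `"-2'"`, `"9'"`, `"16'"`.
#' @return integer residue numbers (author numbering).
#' @export
#' @examples
#' prime_to_residue(c("9'", "16'"))
prime_to_residue <- function(prime) {
  table <- c("-2'" = 222L, "9'" = 233L, "16'" = 240L)
  ## general rule: n' corresponds to residue 224 + n
  out <- table[prime]
  missing <- is.na(out)
  if (any(missing)) {
    n <- suppressWarnings(as.integer(sub("'$", "", prime[missing])))
    if (anyNA(n)) stop("unparseable prime position: ",
                       paste(prime[missing][is.na(n)], collapse = ", "))
    out[missing] <- 224L + n
  }
  unname(out)
}

.element_from_name <- function(atom_name) {
  ## strip digits/primes, take leading alphabetic part; two-letter elements
  ## only for known cases (NA, CL) to avoid eating CA (alpha carbon)
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  el <- substr(nm, 1L, 1L)
  el[nm %in% c("NA", "SOD")] <- "NA."
  el[nm %in% c("CL", "CLA")] <- "CL"
  el
}

#' Default residue-name to role rules
#'
#' Maps residue names to one of `protein`, `lipid`, `water`, `ligand`, `ion`.
#' Standard amino-acid codes map to protein; common water, lipid and ion
#' codes are included, and `DES` (desflurane) maps to ligand.
#'
#' @return named character vector: residue name -> role.
#' @export
default_role_rules <- function() {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
          "THR", "TRP", "TYR", "VAL")
  rules <- c(stats::setNames(rep("protein", length(aa)), aa),
             HOH = "water", TIP = "water", TIP3 = "water", WAT = "water",
             SOL = "water", SPC = "water",
             POP = "lipid", POPC = "lipid", PC = "lipid", LIP = "lipid",
             DES = "ligand", LIG = "ligand",
             SOD = "ion", CLA = "ion", "NA" = "ion", CL = "ion",
             POT = "ion", K = "ion")
  rules
}

#' Construct a system topology
#'
#' A topology is the static identity of the system: one row per atom with
#' its name, element, residue, chain (subunit) and role. Protein chains are
#' the subunits; for a pentamer there are exactly five.
#'
#' @param atoms data frame with columns `atom_name`, `element`, `residue_seq`
#'   (author numbering), `residue_name`, `subunit_id` (chain), `role`
#'   (protein/lipid/water/ligand/ion). Optional `vdw` and `mass` columns
#'   override the built-in element tables.
#' @return object of class `channel_topology`.
#' @export
channel_topology <- function(atoms) {
  required <- c("atom_name", "element", "residue_seq", "residue_name",
                "subunit_id", "role")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("topology atoms missing columns: ", paste(missing, collapse = ", "))
  roles <- c("protein", "lipid", "water", "ligand", "ion")
  bad <- setdiff(unique(atoms$role), roles)
  if (length(bad) > 0)
    stop("unknown atom roles: ", paste(bad, collapse = ", "))
  atoms$residue_seq <- as.integer(atoms$residue_seq)
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  if (is.null(atoms$vdw)) {
    atoms$vdw <- unname(.default_vdw[atoms$element])
    atoms$vdw[is.na(atoms$vdw)] <- 1.70
  }
  if (is.null(atoms$mass)) {
    atoms$mass <- unname(.default_mass[atoms$element])
    atoms$mass[is.na(atoms$mass)] <- 12.011
  }
  rownames(atoms) <- NULL
  subunits <- sort(unique(atoms$subunit_id[atoms$role == "protein"]))
  structure(list(atoms = atoms, subunits = subunits),
            class = "channel_topology")
}

#' @export
print.channel_topology <- function(x, ...) {
  cat("channel_topology:", nrow(x$atoms), "atoms,",
      length(x$subunits), "protein subunits (",
      paste(x$subunits, collapse = ", "), ")\n")
  print(table(x$atoms$role))
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology a `channel_topology`.
#' @return integer atom count.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Atom indices for a (subunit, residue) pair
#'
#' @param topology a `channel_topology`.
#' @param subunit chain identifier.
#' @param residue_seq author residue number.
#' @param atom_name optional atom name filter.
#' @return integer vector of atom indices (1-based rows of the atom table).
#' @export
residue_atoms <- function(topology, subunit, residue_seq, atom_name = NULL) {
  a <- topology$atoms
  idx <- which(a$subunit_id == subunit & a$residue_seq == residue_seq)
  if (!is.null(atom_name)) idx <- idx[a$atom_name[idx] %in% atom_name]
  idx
}

#' Atom indices by role
#' @param topology a `channel_topology`.
#' @param role one of protein, lipid, water, ligand, ion.
#' @param heavy_only drop hydrogens.
#' @return integer vector of atom indices.
#' @export
role_atoms <- function(topology, role, heavy_only = FALSE) {
  a <- topology$atoms
  idx <- which(a$role == role)
  if (heavy_only) idx <- idx[a$is_heavy[idx]]
  idx
}

#' Water counting atoms (one oxygen per water molecule)
#' @param topology a `channel_topology`.
#' @return integer vector of oxygen atom indices among waters.
#' @export
water_oxygens <- function(topology) {
  a <- topology$atoms
  which(a$role == "water" & a$element == "O")
}

#' Ligand identifiers present in a topology
#'
#' Each ligand molecule is one residue of role `ligand`; its identifier is
#' `subunit:residue_seq`.
#'
#' @param topology a `channel_topology`.
#' @return character vector of ligand ids.
#' @export
ligand_ids <- function(topology) {
  a <- topology$atoms
  lig <- a[a$role == "ligand", , drop = FALSE]
  if (nrow(lig) == 0) return(character(0))
  unique(paste0(lig$subunit_id, ":", lig$residue_seq))
}

#' Atom indices of one ligand
#' @param topology a `channel_topology`.
#' @param ligand_id id as returned by [ligand_ids()].
#' @param heavy_only drop hydrogens.
#' @return integer vector of atom indices.
#' @export
ligand_atoms <- function(topology, ligand_id, heavy_only = TRUE) {
  parts <- strsplit(ligand_id, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("ligand_id must be 'chain:resid': ", ligand_id)
  a <- topology$atoms
  idx <- which(a$role == "ligand" & a$subunit_id == parts[1] &
                 a$residue_seq == as.integer(parts[2]))
  if (length(idx) == 0) stop("no such ligand: ", ligand_id)
  if (heavy_only) idx <- idx[a$is_heavy[idx]]
  idx
}
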
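# Synthetic toy-channel systems with known ground truth. The generator
# builds a C_n-symmetric arrangement of pseudo-helical subunits around the z
# axis carrying the same residue labels as the real channel (TM1/TM2 site
# residues, 9'/16' gate C-beta markers, an M2 pseudo-helix), a slab of
# phosphate markers standing in for the membrane, waters in the gate
# cylinder, and free ligand particles. Scripted trajectories then realize
# binding events, helix tilts, hydration programs and phase labels exactly,
# so each analysis operation can be checked against construction.

#' Specification of a synthetic toy channel
#'
#' @param n_subunits number of subunits (>= 3; default 5, a pentamer).
#' @param pore_radius ring radius (angstrom) of the pore-lining pseudo-helix
#'   atoms; the open-pore profile is `pore_radius - r_vdw` with the uniform
#'   carbon-like pseudo-atom radius 1.7 angstrom.
#' @param gate_z_range z positions (angstrom) of the 9' and 16' gate
#'   C-beta rings, ordered low to high.
#' @param membrane_half_width half the phosphate-to-phosphate membrane
#'   width (angstrom); markers are placed at +/- this z.
#' @param n_waters_in_gate waters placed inside the gate cylinder.
#' @param n_bulk_waters reserve waters parked in the aqueous phase.
#' @param n_ligands ligand particles, initially aqueous.
#' @param box orthorhombic box lengths (angstrom).
#' @param seed integer seed recorded in the spec.
#' @return object of class `toy_channel_spec`.
#' @export
toy_channel_spec <- function(n_subunits = 5, pore_radius = 5,
                             gate_z_range = c(-5, 5),
                             membrane_half_width = 18.655,
                             n_waters_in_gate = 7, n_bulk_waters = 20,
                             n_ligands = 5, box = c(116, 115, 130),
                             seed = 1) {
  if (n_subunits < 3) stop("n_subunits must be >= 3")
  if (pore_radius <= 0) stop("pore_radius must be > 0")
  if (length(gate_z_range) != 2 || gate_z_range[1] >= gate_z_range[2])
    stop("gate_z_range must be ordered (z_low, z_high)")
  if (membrane_half_width <= 0) stop("membrane_half_width must be > 0")
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  structure(list(n_subunits = as.integer(n_subunits),
                 pore_radius = pore_radius, gate_z_range = gate_z_range,
                 membrane_half_width = membrane_half_width,
                 n_waters_in_gate = as.integer(n_waters_in_gate),
                 n_bulk_waters = as.integer(n_bulk_waters),
                 n_ligands = as.integer(n_ligands),
                 box = as.numeric(box), seed = as.integer(seed)),
            class = "toy_channel_spec")
}

.cyl <- function(r, ang_deg, z) {
  a <- ang_deg * pi / 180
  c(r * cos(a), r * sin(a), z)
}

## residue labels of the intrasubunit (TM1) lumen; V242 lives on the M2 ring
.lumen_residues <- data.frame(
  residue_seq = c(119L, 120L, 121L, 197L, 201L, 202L, 205L, 206L,
                  254L, 255L, 258L, 307L),
  residue_name = c("TYR", "PRO", "PHE", "TYR", "ILE", "ILE", "MET", "LYS",
                   "TYR", "THR", "ILE", "ASN"))

.m2_resname <- function(res) {
  ifelse(res == 222L, "GLU",
         ifelse(res %in% c(233L, 240L), "ILE",
                ifelse(res == 242L, "VAL", "ALA")))
}

## gate water lattice: rings of 4 at r = 2 angstrom, levels 2.8 apart
.gate_lattice <- function(gate_z_range) {
  zs <- seq(gate_z_range[1] + 1.4, gate_z_range[2] - 1.4, by = 2.8)
  if (length(zs) == 0) return(matrix(numeric(0), 0, 3))
  pos <- list()
  for (l in seq_along(zs)) {
    off <- if (l %% 2 == 0) 45 else 0
    for (k in 0:3) pos[[length(pos) + 1]] <- .cyl(2.0, off + 90 * k, zs[l])
  }
  do.call(rbind, pos)
}

#' Build a synthetic toy channel
#'
#' Constructs the topology and a single frame. Subunit A is built as a
#' template and replicated by exact rotation about z, so the system is
#' C_n-symmetric to machine precision. The topology carries a `meta` element
#' (spec, site anchors, water lattice) consumed by [script_trajectory()].
#'
#' @param spec a [toy_channel_spec()].
#' @return list with `topology` and `frame`.
#' @export
build_toy_channel <- function(spec) {
  stopifnot(inherits(spec, "toy_channel_spec"))
  R <- spec$pore_radius
  z9 <- spec$gate_z_range[1]; z16 <- spec$gate_z_range[2]
  dz <- (z16 - z9) / 7  # residue 233 sits at z9, 240 at z16

  ## --- subunit template (atom name, element, resid, resname, x, y, z)
  rows <- list()
  add <- function(name, element, resid, resname, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      atom_name = name, element = element, residue_seq = resid,
      residue_name = resname, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }
  for (res in 221:244) {
    z0 <- z9 + (res - 233) * dz
    ## straight pseudo-helix columns: keeps the four-residue turn centers of
    ## mass on one vertical line (tilt oracle reads 0 for the untilted toy)
    ## and the pore wall an analytic cylinder of radius `pore_radius`
    tw <- 0
    rn <- .m2_resname(res)
    add("N", "N", res, rn, .cyl(R, tw - 4, z0 - 0.48))
    add("CA", "C", res, rn, .cyl(R, tw, z0))
    add("C", "C", res, rn, .cyl(R, tw + 4, z0 + 0.48))
    add("O", "O", res, rn, .cyl(R + 0.6, tw + 6, z0 + 0.60))
    if (res %in% c(233L, 240L))
      add("CB", "C", res, rn, .cyl(R + 1.0, tw, z0))
  }
  for (j in seq_len(nrow(.lumen_residues))) {
    res <- .lumen_residues$residue_seq[j]
    rn <- .lumen_residues$residue_name[j]
    ang <- -25 + 50 * (j - 1) / (nrow(.lumen_residues) - 1)
    zl <- -8 + 16 * (j - 1) / (nrow(.lumen_residues) - 1)
    add("CA", "C", res, rn, .cyl(12, ang, zl))
    if (res == 254L) add("OH", "O", res, rn, .cyl(12.8, ang, zl + 1.2))
    if (res == 307L) add("ND2", "N", res, rn, .cyl(12.8, ang, zl - 1.2))
  }
  template <- do.call(rbind, rows)

  ## --- replicate subunits by rotation about z
  chains <- LETTERS[seq_len(spec$n_subunits)]
  angles <- (seq_len(spec$n_subunits) - 1) * 360 / spec$n_subunits
  prot <- list()
  for (k in seq_len(spec$n_subunits)) {
    rot <- rotate_about(as.matrix(template[, c("x", "y", "z")]),
                        c(0, 0, 1), angles[k])
    tk <- template
    tk$x <- rot[, 1]; tk$y <- rot[, 2]; tk$z <- rot[, 3]
    tk$subunit_id <- chains[k]
    tk$role <- "protein"
    prot[[k]] <- tk
  }

  ## --- membrane phosphate markers, two leaflets
  lip <- list(); rid <- 0L
  for (zl in c(-spec$membrane_half_width, spec$membrane_half_width)) {
    for (r in c(30, 42)) {
      for (k in 0:11) {
        rid <- rid + 1L
        p <- .cyl(r, 30 * k + (r == 42) * 15, zl)
        lip[[rid]] <- data.frame(atom_name = "P", element = "P",
                                 residue_seq = rid, residue_name = "POP",
                                 x = p[1], y = p[2], z = p[3],
                                 subunit_id = "M", role = "lipid",
                                 stringsAsFactors = FALSE)
      }
    }
  }

  ## --- waters: gate lattice first, then parked bulk reserve
  lattice <- .gate_lattice(spec$gate_z_range)
  if (spec$n_waters_in_gate > nrow(lattice))
    stop("requested ", spec$n_waters_in_gate, " gate waters but only ",
         nrow(lattice), " fit at 2.8 angstrom exclusion")
  nw <- spec$n_waters_in_gate + spec$n_bulk_waters
  park <- t(vapply(seq_len(max(nw, 1)), function(i)
    .cyl(38, 25 * (i - 1), 34 + 3 * ((i - 1) %% 10) + 0.3 * (i - 1)),
    numeric(3)))
  wat <- NULL
  if (nw > 0) {
    wpos <- matrix(NA_real_, nw, 3)
    if (spec$n_waters_in_gate > 0)
      wpos[seq_len(spec$n_waters_in_gate), ] <-
        lattice[seq_len(spec$n_waters_in_gate), , drop = FALSE]
    if (spec$n_bulk_waters > 0)
      wpos[(spec$n_waters_in_gate + 1):nw, ] <-
        park[(spec$n_waters_in_gate + 1):nw, , drop = FALSE]
    wat <- data.frame(atom_name = "O", element = "O",
                      residue_seq = seq_len(nw), residue_name = "HOH",
                      x = wpos[, 1], y = wpos[, 2], z = wpos[, 3],
                      subunit_id = "W", role = "water",
                      stringsAsFactors = FALSE)
  }

  ## --- ligands, initially in the aqueous phase
  lig <- NULL
  if (spec$n_ligands > 0) {
    lpos <- t(vapply(seq_len(spec$n_ligands), function(i)
      .lig_anchor(spec, i, "aqueous"), numeric(3)))
    lig <- data.frame(atom_name = "C1", element = "C",
                      residue_seq = seq_len(spec$n_ligands),
                      residue_name = "DES",
                      x = lpos[, 1], y = lpos[, 2], z = lpos[, 3],
                      subunit_id = "X", role = "ligand",
                      stringsAsFactors = FALSE)
  }

  atoms <- do.call(rbind, c(prot, list(do.call(rbind, lip)), list(wat),
                            list(lig)))
  topo <- channel_topology(atoms[, c("atom_name", "element", "residue_seq",
                                     "residue_name", "subunit_id", "role")])
  frame <- channel_frame(as.matrix(atoms[, c("x", "y", "z")]), spec$box, 0)

  ## site anchors: a point 2.5 angstrom radially inward of a marker atom, so
  ## a ligand placed there is unambiguously in contact (<= 3.5 angstrom)
  anchor_from <- function(resid, atom) {
    t(vapply(seq_len(spec$n_subunits), function(k) {
      idx <- residue_atoms(topo, chains[k], resid, atom)
      x <- frame$xyz[idx[1], ]
      r <- sqrt(sum(x[1:2]^2))
      c(x[1:2] * (1 - 2.5 / r), x[3])
    }, numeric(3)))
  }
  meta <- list(spec = spec, chains = chains, subunit_angles = angles,
               m2_residues = 221:244, gate_lattice = lattice,
               water_park = park,
               anchors = list(TM1 = anchor_from(202L, "CA"),
                              TM2 = anchor_from(254L, "OH")))
  topo$meta <- meta
  list(topology = topo, frame = frame)
}

.lig_anchor <- function(spec, i, phase) {
  ang <- 360 * (i - 1) / max(1, spec$n_ligands) + 15
  if (phase == "aqueous") .cyl(30, ang, 40 + 1.5 * (i - 1))
  else .cyl(30, ang, 0)  # membrane midplane, far from protein
}

#' Define a binding-event script
#'
#' Ground truth for scripted trajectories: which ligand occupies which site
#' on which subunit over which time interval, and which phase (aqueous or
#' membrane) it sits in between events.
#'
#' @param events data frame with columns `ligand_id`, `site_name`,
#'   `subunit_id`, `t_start`, `t_end` (ps). Intervals of one ligand must not
#'   overlap.
#' @param phases named character vector ligand_id -> `"aqueous"`/`"membrane"`
#'   for the unbound intervals; unlisted ligands default to aqueous.
#' @return object of class `event_script`.
#' @export
event_script <- function(events = NULL, phases = character(0)) {
  if (is.null(events))
    events <- data.frame(ligand_id = character(0), site_name = character(0),
                         subunit_id = character(0), t_start = numeric(0),
                         t_end = numeric(0))
  need <- c("ligand_id", "site_name", "subunit_id", "t_start", "t_end")
  if (!all(need %in% names(events)))
    stop("event script needs columns: ", paste(need, collapse = ", "))
  if (any(events$t_end <= events$t_start))
    stop("event t_end must exceed t_start")
  for (lg in unique(events$ligand_id)) {
    e <- events[events$ligand_id == lg, ]
    e <- e[order(e$t_start), ]
    if (nrow(e) > 1 && any(e$t_start[-1] < e$t_end[-nrow(e)]))
      stop("overlapping events for ligand ", lg)
  }
  bad <- setdiff(phases, c("aqueous", "membrane"))
  if (length(bad) > 0) stop("unknown phase label(s): ",
                            paste(bad, collapse = ", "))
  structure(list(events = events, phases = phases), class = "event_script")
}

#' Generate a scripted trajectory with known ground truth
#'
#' Ligands follow the event script exactly (at the site anchor during bound
#' intervals, at their phase anchor otherwise, plus isotropic Gaussian noise
#' of `noise_amplitude` per coordinate). The M2 pseudo-helices are rigidly
#' tilted toward the pore axis per the tilt program, and gate waters are
#' moved in/out to realize the hydration program. Same seed, same output.
#'
#' @param topology toy topology from [build_toy_channel()].
#' @param base the matching base `channel_frame`.
#' @param script an [event_script()], or `NULL` for no binding.
#' @param tilt_program tilt angles in degrees: `NULL`, a vector over frames
#'   (applied to all subunits), or a frames x subunits matrix. Angles above
#'   60 degrees are rejected (the toy geometry breaks).
#' @param hydration_program integer gate-water counts: `NULL`, a scalar, or a
#'   vector over frames.
#' @param noise_amplitude Gaussian positional noise sigma (angstrom) applied
#'   to ligand coordinates.
#' @param seed RNG seed.
#' @param dt frame interval in ps.
#' @param n_frames number of frames; inferred from the script or programs
#'   when `NULL`.
#' @return list with `trajectory` (a `channel_trajectory`) and `truth`
#'   (events, per-frame phases, tilt matrix, hydration counts, times).
#' @export
script_trajectory <- function(topology, base, script = NULL,
                              tilt_program = NULL, hydration_program = NULL,
                              noise_amplitude = 0, seed = 1, dt = 1000,
                              n_frames = NULL) {
  meta <- topology$meta
  if (is.null(meta)) stop("topology must come from build_toy_channel()")
  if (is.null(script)) script <- event_script()
  if (is.null(n_frames)) {
    n_frames <- max(c(1, ceiling(script$events$t_end / dt) + 1,
                      length(hydration_program),
                      if (is.matrix(tilt_program)) nrow(tilt_program)
                      else length(tilt_program)))
  }
  times <- (seq_len(n_frames) - 1) * dt
  ns <- meta$spec$n_subunits
  lids <- ligand_ids(topology)
  unknown <- setdiff(script$events$ligand_id, lids)
  if (length(unknown) > 0)
    stop("script names unknown ligand(s): ", paste(unknown, collapse = ", "))

  ## tilt program -> frames x subunits matrix
  tilt <- matrix(0, n_frames, ns)
  if (!is.null(tilt_program)) {
    if (is.matrix(tilt_program)) {
      if (ncol(tilt_program) != ns) stop("tilt matrix needs ", ns, " columns")
      tilt <- tilt_program[rep_len(seq_len(nrow(tilt_program)), n_frames), ,
                           drop = FALSE]
    } else tilt <- matrix(rep_len(tilt_program, n_frames), n_frames, ns)
  }
  if (any(abs(tilt) > 60)) stop("tilt angles above 60 degrees break the toy geometry")

  ## hydration program -> integer vector
  hyd <- NULL
  if (!is.null(hydration_program)) {
    hyd <- as.integer(rep_len(hydration_program, n_frames))
    wox <- water_oxygens(topology)
    if (any(hyd < 0) || any(hyd > length(wox)))
      stop("hydration program outside 0..", length(wox))
    if (any(hyd > nrow(meta$gate_lattice)))
      stop("hydration program exceeds gate capacity (",
           nrow(meta$gate_lattice), ")")
  }

  ## per-subunit M2 atom indices and rotation frames
  a <- topology$atoms
  m2_idx <- lapply(meta$chains, function(ch)
    which(a$subunit_id == ch & a$role == "protein" &
            a$residue_seq %in% meta$m2_residues))
  ang <- meta$subunit_angles * pi / 180
  tang <- cbind(-sin(ang), cos(ang), 0)  # tangential axis per subunit
  pivots <- t(vapply(seq_len(ns), function(k) {
    idx <- m2_idx[[k]][a$residue_seq[m2_idx[[k]]] == 221L]
    colMeans(base$xyz[idx, , drop = FALSE])
  }, numeric(3)))

  set.seed(seed)
  lig_idx <- lapply(lids, function(id) ligand_atoms(topology, id,
                                                    heavy_only = FALSE))
  ev <- script$events
  phase_default <- vapply(lids, function(id) {
    p <- script$phases[id]
    if (is.na(p)) "aqueous" else unname(p)
  }, character(1))
  phase_truth <- matrix(NA_character_, n_frames, length(lids),
                        dimnames = list(NULL, lids))

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- base$xyz
    t_now <- times[f]
    for (k in seq_len(ns)) {
      if (tilt[f, k] != 0)
        xyz[m2_idx[[k]], ] <- rotate_about(xyz[m2_idx[[k]], , drop = FALSE],
                                           tang[k, ], -tilt[f, k],
                                           pivots[k, ])
    }
    if (!is.null(hyd)) {
      wox <- water_oxygens(topology)
      m <- hyd[f]
      if (m > 0) xyz[wox[seq_len(m)], ] <- meta$gate_lattice[seq_len(m), ]
      if (m < length(wox))
        xyz[wox[(m + 1):length(wox)], ] <-
          meta$water_park[(m + 1):length(wox), , drop = FALSE]
    }
    for (li in seq_along(lids)) {
      hit <- which(ev$ligand_id == lids[li] & ev$t_start <= t_now &
                     t_now < ev$t_end)
      if (length(hit) > 0) {
        e <- ev[hit[1], ]
        anc <- meta$anchors[[e$site_name]]
        if (is.null(anc)) stop("no anchor for site ", e$site_name)
        sk <- match(e$subunit_id, meta$chains)
        if (is.na(sk)) stop("unknown subunit in script: ", e$subunit_id)
        pos <- anc[sk, ]
        phase_truth[f, li] <- "protein"
      } else {
        pos <- .lig_anchor(meta$spec, li, phase_default[li])
        phase_truth[f, li] <- phase_default[li]
      }
      idx <- lig_idx[[li]]
      off <- if (noise_amplitude > 0)
        matrix(stats::rnorm(3 * length(idx), 0, noise_amplitude),
               length(idx), 3) else 0
      xyz[idx, ] <- matrix(pos, length(idx), 3, byrow = TRUE) + off
    }
    frames[[f]] <- channel_frame(xyz, base$box, t_now)
  }
  traj <- channel_trajectory(topology, frames)
  truth <- list(times = times, dt = dt, events = ev, phases = phase_truth,
                tilt = tilt, hydration = hyd, seed = seed,
                noise_amplitude = noise_amplitude)
  list(trajectory = traj, truth = truth)
}

#' Serialize a scripted ground-truth record to JSON
#' @param truth ground truth from [script_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
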
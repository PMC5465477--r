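# Structure and trajectory input/output. PDB parsing is delegated to bio3d;
# this module assigns roles, wraps coordinates into frame/trajectory
# containers, and provides a multi-MODEL PDB and XYZ-series trajectory
# dialect with per-frame times stored in REMARK/comment lines.

#' Construct a single coordinate frame
#'
#' @param xyz N x 3 coordinate matrix (angstrom).
#' @param box length-3 orthorhombic box (angstrom).
#' @param time frame time in ps.
#' @return object of class `channel_frame`.
#' @export
channel_frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("frame coordinates must be N x 3")
  dimnames(xyz) <- NULL
  if (length(box) != 3 || any(box <= 0)) stop("box components must be > 0")
  structure(list(xyz = xyz, box = as.numeric(box), time = as.numeric(time)),
            class = "channel_frame")
}

#' Construct a trajectory from frames
#'
#' @param topology a `channel_topology`.
#' @param frames list of `channel_frame` objects with strictly increasing
#'   times and atom counts matching the topology.
#' @return object of class `channel_trajectory` with fields `topology`,
#'   `coords` (N x 3 x n_frames array), `box` (n_frames x 3), `times` (ps)
#'   and `frame_interval` (ps, from the first two frames).
#' @export
channel_trajectory <- function(topology, frames) {
  if (length(frames) == 0) stop("trajectory must contain at least one frame")
  n <- n_atoms(topology)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$xyz) != n)
      stop("frame ", i, ": atom count ", nrow(frames[[i]]$xyz),
           " does not match topology (", n, ")")
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  coords <- array(NA_real_, c(n, 3, length(frames)))
  box <- matrix(NA_real_, length(frames), 3)
  for (i in seq_along(frames)) {
    coords[, , i] <- frames[[i]]$xyz
    box[i, ] <- frames[[i]]$box
  }
  structure(list(topology = topology, coords = coords, box = box,
                 times = times,
                 frame_interval = if (length(times) > 1)
                   times[2] - times[1] else NA_real_),
            class = "channel_trajectory")
}

#' @export
print.channel_trajectory <- function(x, ...) {
  cat("channel_trajectory:", dim(x$coords)[3], "frames,",
      dim(x$coords)[1], "atoms, t =", x$times[1], "..",
      x$times[length(x$times)], "ps (interval", x$frame_interval, "ps)\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `channel_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame from a trajectory
#' @param traj a `channel_trajectory`.
#' @param i frame index (1-based).
#' @return a `channel_frame`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  channel_frame(traj$coords[, , i], traj$box[i, ], traj$times[i])
}

#' Frame indices sampled every `stride` ps
#' @param traj a `channel_trajectory`.
#' @param stride sampling interval in ps; must be >= the frame interval.
#' @return integer frame indices.
#' @export
sample_frames <- function(traj, stride = NULL) {
  if (is.null(stride)) return(seq_len(n_frames(traj)))
  if (!is.na(traj$frame_interval) && stride < traj$frame_interval)
    stop("stride (", stride, " ps) is below the frame interval (",
         traj$frame_interval, " ps)")
  t0 <- traj$times[1]
  keep <- c(TRUE, diff(floor((traj$times - t0) / stride)) >= 1)
  which(keep)
}

#' Load a structure file (PDB)
#'
#' Reads a PDB file via bio3d, assigns a role to every atom from residue-name
#' rules, and returns the topology together with the single coordinate frame.
#' The box is taken from the CRYST1 record when present, otherwise from
#' `default_box`.
#'
#' @param path PDB file path.
#' @param role_rules named character vector residue name -> role; defaults to
#'   [default_role_rules()]. A residue name with no rule is an error.
#' @param default_box fallback box when the file has no CRYST1 record.
#' @return list with elements `topology` and `frame`.
#' @export
load_structure <- function(path, role_rules = default_role_rules(),
                           default_box = c(116, 115, 130)) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  resname <- trimws(at$resid)
  role <- unname(role_rules[resname])
  unknown <- unique(resname[is.na(role)])
  if (length(unknown) > 0)
    stop("no role rule for residue name(s): ", paste(unknown, collapse = ", "))
  elem <- trimws(at$elesy)
  bad <- is.na(elem) | elem == ""
  elem[bad] <- .element_from_name(at$elety[bad])
  elem[elem %in% c("Na", "NA")] <- "NA."
  elem[elem %in% c("Cl", "CL")] <- "CL"
  chain <- at$chain
  chain[is.na(chain)] <- " "
  if (any(role == "protein" & chain == " "))
    stop("protein atoms must carry a chain identifier")
  topo <- channel_topology(data.frame(
    atom_name = trimws(at$elety), element = elem,
    residue_seq = at$resno, residue_name = resname,
    subunit_id = chain, role = role, stringsAsFactors = FALSE))
  box <- default_box
  cryst <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cryst) > 0) {
    b <- suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                       substr(cryst[1], 16, 24),
                                       substr(cryst[1], 25, 33))))
    if (!anyNA(b) && all(b > 0)) box <- b
  }
  list(topology = topo,
       frame = channel_frame(cbind(at$x, at$y, at$z), box, time = 0))
}

#' Load a trajectory
#'
#' Supported dialects: `"multi-pdb"` (multi-MODEL PDB; per-frame times and
#' boxes read from `REMARK 300 TIME=`/`BOX=` lines when present), `"xyz"`
#' (XYZ series with `time=`/`box=` in the comment line), and `"dcd"`
#' (binary DCD via bio3d; times assigned from `frame_interval`).
#'
#' @param topology a `channel_topology` the frames must match.
#' @param path trajectory file.
#' @param dialect one of `"multi-pdb"`, `"xyz"`, `"dcd"`.
#' @param frame_interval fallback time step in ps when the file carries no
#'   per-frame times.
#' @param default_box fallback box when the file carries none.
#' @return a `channel_trajectory`.
#' @export
load_trajectory <- function(topology, path,
                            dialect = c("multi-pdb", "xyz", "dcd"),
                            frame_interval = 1000,
                            default_box = c(116, 115, 130)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  n <- n_atoms(topology)
  frames <- switch(dialect,
    "multi-pdb" = .read_multipdb_frames(path, n, frame_interval, default_box),
    "xyz" = .read_xyz_frames(path, n, frame_interval, default_box),
    "dcd" = .read_dcd_frames(path, n, frame_interval, default_box))
  if (length(frames) == 0) stop("trajectory file contains no frames: ", path)
  channel_trajectory(topology, frames)
}

.read_multipdb_frames <- function(path, n, dt, default_box) {
  lines <- readLines(path, warn = FALSE)
  if (length(grep("^(ATOM|HETATM)", lines)) == 0) return(list())
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) model_starts <- 1L
  model_ends <- c(model_starts[-1] - 1L, length(lines))
  frames <- vector("list", length(model_starts))
  for (i in seq_along(model_starts)) {
    chunk <- lines[model_starts[i]:model_ends[i]]
    at <- grep("^(ATOM|HETATM)", chunk, value = TRUE)
    if (length(at) != n)
      stop("frame ", i, ": atom count ", length(at),
           " does not match topology (", n, ")")
    bad <- which(nchar(at) < 54)
    if (length(bad) > 0)
      stop("frame ", i, ": truncated coordinate record at line ", bad[1])
    xyz <- cbind(as.numeric(substr(at, 31, 38)),
                 as.numeric(substr(at, 39, 46)),
                 as.numeric(substr(at, 47, 54)))
    if (anyNA(xyz)) stop("frame ", i, ": unparseable coordinates")
    tm <- .remark_value(chunk, "TIME=")
    bx <- .remark_values(chunk, "BOX=")
    frames[[i]] <- channel_frame(xyz,
                                 if (is.null(bx)) default_box else bx,
                                 if (is.null(tm)) (i - 1) * dt else tm)
  }
  .check_times(frames)
}

.remark_value <- function(chunk, key) {
  v <- .remark_values(chunk, key)
  if (is.null(v)) NULL else v[1]
}

.remark_values <- function(chunk, key) {
  ln <- grep(paste0("^REMARK 300 ", key), chunk, value = TRUE)
  if (length(ln) == 0) return(NULL)
  as.numeric(strsplit(trimws(sub(paste0("^REMARK 300 ", key), "", ln[1])),
                      "\\s+")[[1]])
}

.read_xyz_frames <- function(path, n, dt, default_box) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L; fr <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    fr <- fr + 1L
    if (is.na(nat)) stop("frame ", fr, ": bad atom-count line ", i)
    if (nat != n) stop("frame ", fr, ": atom count ", nat,
                       " does not match topology (", n, ")")
    comment <- lines[i + 1L]
    tm <- .kv_num(comment, "time")
    bx <- .kv_nums(comment, "box")
    rows <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(rows), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("frame ", fr, ": unparseable coordinates")
    frames[[fr]] <- channel_frame(xyz,
                                  if (is.null(bx)) default_box else bx,
                                  if (is.null(tm)) (fr - 1) * dt else tm)
    i <- i + 2L + nat
  }
  .check_times(frames)
}

.kv_num <- function(s, key) { v <- .kv_nums(s, key); if (is.null(v)) NULL else v[1] }

.kv_nums <- function(s, key) {
  m <- regmatches(s, regexpr(paste0(key, "=[-0-9.eE, ]+"), s))
  if (length(m) == 0) return(NULL)
  v <- strsplit(trimws(sub(paste0(key, "="), "", m)), "[, ]+")[[1]]
  as.numeric(v[v != ""])
}

.read_dcd_frames <- function(path, n, dt, default_box) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  lapply(seq_len(nrow(xyz)), function(i) {
    channel_frame(matrix(xyz[i, ], ncol = 3, byrow = TRUE),
                  default_box, (i - 1) * dt)
  })
}

.check_times <- function(frames) {
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times are not strictly increasing")
  frames
}

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz, element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial %% 100000, nm, substr(resname, 1, 4), chain, resno %% 10000,
          xyz[1], xyz[2], xyz[3], substr(sub("\\.$", "", element), 1, 2))
}

.frame_pdb_lines <- function(topology, xyz) {
  a <- topology$atoms
  vapply(seq_len(nrow(a)), function(i) {
    .pdb_atom_line(i, a$atom_name[i], a$residue_name[i], a$subunit_id[i],
                   a$residue_seq[i], xyz[i, ], a$element[i])
  }, character(1))
}

#' Write a structure to a PDB file
#' @param topology a `channel_topology`.
#' @param frame a `channel_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, frame, path) {
  lines <- c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     frame$box[1], frame$box[2], frame$box[3]),
             .frame_pdb_lines(topology, frame$xyz), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory
#'
#' Multi-MODEL PDB frames carry `REMARK 300 TIME=` (ps) and `REMARK 300 BOX=`
#' (angstrom) records so that times and boxes round-trip; the XYZ dialect
#' stores them in the per-frame comment line.
#'
#' @param traj a `channel_trajectory`.
#' @param path output path.
#' @param dialect `"multi-pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, dialect = c("multi-pdb", "xyz")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (i in seq_len(nf)) {
    if (dialect == "multi-pdb") {
      writeLines(c(sprintf("MODEL %8d", i),
                   sprintf("REMARK 300 TIME= %.6f", traj$times[i]),
                   sprintf("REMARK 300 BOX= %.6f %.6f %.6f",
                           traj$box[i, 1], traj$box[i, 2], traj$box[i, 3]),
                   .frame_pdb_lines(traj$topology, traj$coords[, , i]),
                   "ENDMDL"), con)
    } else {
      a <- traj$topology$atoms
      writeLines(c(sprintf("%d", n_atoms(traj$topology)),
                   sprintf("time=%.6f box=%.6f,%.6f,%.6f", traj$times[i],
                           traj$box[i, 1], traj$box[i, 2], traj$box[i, 3]),
                   sprintf("%-4s %12.6f %12.6f %12.6f", a$element,
                           traj$coords[, 1, i], traj$coords[, 2, i],
                           traj$coords[, 3, i])), con)
    }
  }
  if (dialect == "multi-pdb") writeLines("END", con)
  invisible(path)
}
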
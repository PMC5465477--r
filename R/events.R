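# Binding/unbinding event detection with hysteresis, residence-time
# statistics, bound-ligand RMSF, named distance series, and site occupancy
# counts. The state machine enters the bound state when any ligand heavy
# atom comes within the site's contact cutoff (3.5 angstrom default) of a
# site atom, and leaves it only when the ligand moves more than the
# dissociation cutoff (5 angstrom default) from the whole protein; the
# enter/exit asymmetry suppresses boundary flicker.

#' Detect binding events of one ligand at a site
#'
#' @param traj a `channel_trajectory`.
#' @param ligand_id ligand id (see [ligand_ids()]).
#' @param site a `site_definition`.
#' @param min_duration_frames discard events spanning fewer frame intervals
#'   than this (default 2).
#' @param stride optional sampling interval in ps.
#' @param include_hydrogens use hydrogens in the distance criteria.
#' @param periodic minimum-image distances.
#' @return data frame of class `binding_events`: `ligand_id`, `site_name`,
#'   `subunit_id` (subunit of minimum site distance at entry; ties go to the
#'   alphabetically first and are recorded in the `ties` attribute),
#'   `t_start`, `t_end` (ps), `residence_ns`, and `censored` (event still
#'   bound at the last frame).
#' @export
detect_binding_events <- function(traj, ligand_id, site,
                                  min_duration_frames = 2, stride = NULL,
                                  include_hydrogens = FALSE, periodic = TRUE) {
  topo <- traj$topology
  heavy <- !include_hydrogens
  lig <- ligand_atoms(topo, ligand_id, heavy_only = heavy)
  site_atoms <- resolve_selection_all(topo, site, heavy_only = heavy)
  prot <- role_atoms(topo, "protein", heavy_only = heavy)
  fidx <- sample_frames(traj, stride)
  times <- traj$times[fidx]
  dt <- if (length(fidx) > 1) times[2] - times[1] else traj$frame_interval

  events <- list()
  ties <- list()
  bound <- FALSE
  t_start <- NA_real_; subunit <- NA_character_
  for (fi in seq_along(fidx)) {
    f <- fidx[fi]
    bx <- if (periodic) traj$box[f, ] else NULL
    xyz <- traj$coords[, , f]
    ligx <- xyz[lig, , drop = FALSE]
    dsite <- vapply(site_atoms, function(idx)
      min_distance(ligx, xyz[idx, , drop = FALSE], bx), numeric(1))
    if (!bound) {
      if (min(dsite) <= site$contact_enter_cutoff) {
        bound <- TRUE
        t_start <- times[fi]
        winners <- names(dsite)[dsite == min(dsite)]
        if (length(winners) > 1)
          ties[[length(ties) + 1]] <- list(time = times[fi],
                                           subunits = winners)
        subunit <- winners[1]
      }
    } else {
      dprot <- min_distance(ligx, xyz[prot, , drop = FALSE], bx)
      if (dprot > site$dissociation_cutoff) {
        events[[length(events) + 1]] <-
          data.frame(ligand_id = ligand_id, site_name = site$name,
                     subunit_id = subunit, t_start = t_start,
                     t_end = times[fi], censored = FALSE,
                     stringsAsFactors = FALSE)
        bound <- FALSE
      }
    }
  }
  if (bound)
    events[[length(events) + 1]] <-
      data.frame(ligand_id = ligand_id, site_name = site$name,
                 subunit_id = subunit, t_start = t_start,
                 t_end = times[length(times)], censored = TRUE,
                 stringsAsFactors = FALSE)
  out <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(ligand_id = character(0), site_name = character(0),
               subunit_id = character(0), t_start = numeric(0),
               t_end = numeric(0), censored = logical(0))
  out <- out[(out$t_end - out$t_start) >= min_duration_frames * dt - 1e-9, ,
             drop = FALSE]
  out$residence_ns <- (out$t_end - out$t_start) / 1000
  rownames(out) <- NULL
  out <- out[, c("ligand_id", "site_name", "subunit_id", "t_start", "t_end",
                 "residence_ns", "censored")]
  class(out) <- c("binding_events", "data.frame")
  attr(out, "ties") <- ties
  out
}

#' Detect binding events for every ligand
#' @inheritParams detect_binding_events
#' @return a `binding_events` data frame over all ligands.
#' @export
detect_all_binding_events <- function(traj, site, min_duration_frames = 2,
                                      stride = NULL,
                                      include_hydrogens = FALSE,
                                      periodic = TRUE) {
  out <- lapply(ligand_ids(traj$topology), detect_binding_events,
                traj = traj, site = site,
                min_duration_frames = min_duration_frames, stride = stride,
                include_hydrogens = include_hydrogens, periodic = periodic)
  res <- do.call(rbind, out)
  class(res) <- c("binding_events", "data.frame")
  rownames(res) <- NULL
  res
}

.event_frames <- function(traj, t_start, t_end, sample_interval) {
  in_window <- which(traj$times >= t_start - 1e-9 & traj$times < t_end - 1e-9)
  if (length(in_window) == 0) return(integer(0))
  t0 <- traj$times[in_window[1]]
  keep <- c(TRUE, diff(floor((traj$times[in_window] - t0) /
                               sample_interval)) >= 1)
  in_window[keep]
}

#' Root-mean-square fluctuation of a bound ligand
#'
#' Ligand coordinates are sampled every `sample_interval` over the event and
#' compared with their time-average: no superposition is applied (lab
#' frame), matching how loosely held ligands rattle inside a pocket. A
#' point ligand alternating between two positions d apart gives d/2; an
#' isotropic Gaussian wobble of sigma per coordinate gives sigma * sqrt(3).
#'
#' @param traj a `channel_trajectory`.
#' @param event one-row `binding_events` entry (or any list with
#'   `ligand_id`, `t_start`, `t_end`).
#' @param sample_interval sampling interval in ps (default 200, i.e. every
#'   0.2 ns).
#' @return RMSF in angstrom.
#' @export
bound_ligand_rmsf <- function(traj, event, sample_interval = 200) {
  lig <- ligand_atoms(traj$topology, event$ligand_id[1], heavy_only = TRUE)
  fidx <- .event_frames(traj, event$t_start[1], event$t_end[1],
                        sample_interval)
  if (length(fidx) < 2)
    stop("event spans fewer than 2 samples at interval ", sample_interval,
         " ps")
  x <- traj$coords[lig, , fidx, drop = FALSE]
  xbar <- apply(x, c(1, 2), mean)
  dev2 <- sweep(x, c(1, 2), xbar)^2
  sqrt(mean(apply(dev2, c(1, 3), sum)))
}

#' Per-event statistics: RMSF and a named pair distance
#'
#' Augments detected events with the bound-ligand RMSF and, when `pair` is
#' given, the mean distance between a named site atom of the event's subunit
#' (e.g. the Tyr-254 hydroxyl oxygen) and the ligand, sampled every
#' `sample_interval`.
#'
#' @param traj a `channel_trajectory`.
#' @param events a `binding_events` data frame.
#' @param pair `NULL` or list with `residue_seq` and `atom_name` naming the
#'   protein partner atom.
#' @param sample_interval ps (default 200).
#' @param periodic minimum-image distances.
#' @return `events` with `rmsf` and `mean_pair_distance` columns added.
#' @export
event_statistics <- function(traj, events, pair = NULL,
                             sample_interval = 200, periodic = TRUE) {
  events$rmsf <- NA_real_
  events$mean_pair_distance <- NA_real_
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    events$rmsf[i] <- tryCatch(
      bound_ligand_rmsf(traj, ev, sample_interval), error = function(e)
        NA_real_)
    if (!is.null(pair)) {
      patom <- residue_atoms(traj$topology, ev$subunit_id, pair$residue_seq,
                             pair$atom_name)
      if (length(patom) == 0)
        stop("pair atom not found: residue ", pair$residue_seq, " ",
             pair$atom_name, " in subunit ", ev$subunit_id)
      lig <- ligand_atoms(traj$topology, ev$ligand_id, heavy_only = TRUE)
      fidx <- .event_frames(traj, ev$t_start, ev$t_end, sample_interval)
      d <- vapply(fidx, function(f)
        min_distance(traj$coords[lig, , f, drop = FALSE],
                     traj$coords[patom, , f, drop = FALSE],
                     if (periodic) traj$box[f, ] else NULL), numeric(1))
      events$mean_pair_distance[i] <- mean(d)
    }
  }
  events
}

#' Aggregate per-replicate event reports
#'
#' Accepts either a list of `binding_events` data frames (one per replicate
#' simulation) or a plain vector of per-replicate event counts, and returns
#' per-replicate rows plus an `All` row whose count is the grand total.
#' Because the replicate-level and event-level averages of residence time
#' differ when replicates carry different event counts, both are reported:
#' `residence_mean`/`residence_sd` pool all events, and
#' `replicate_weighted_mean` averages the per-replicate means.
#'
#' @param replicates list of `binding_events` data frames, or numeric vector
#'   of event counts.
#' @return data frame with one row per replicate and a final `All` row.
#' @export
event_report <- function(replicates) {
  if (is.numeric(replicates)) {
    n <- as.integer(replicates)
    return(data.frame(replicate = c(as.character(seq_along(n)), "All"),
                      n_events = c(n, sum(n))))
  }
  rows <- lapply(seq_along(replicates), function(i) {
    ev <- replicates[[i]]
    data.frame(replicate = as.character(i), n_events = nrow(ev),
               residence_mean = mean(ev$residence_ns),
               residence_sd = stats::sd(ev$residence_ns),
               replicate_weighted_mean = mean(ev$residence_ns))
  })
  pooled <- do.call(rbind, lapply(replicates, as.data.frame))
  all_row <- data.frame(replicate = "All",
                        n_events = nrow(pooled),
                        residence_mean = mean(pooled$residence_ns),
                        residence_sd = stats::sd(pooled$residence_ns),
                        replicate_weighted_mean =
                          mean(vapply(replicates, function(e)
                            mean(e$residence_ns), numeric(1))))
  rbind(do.call(rbind, rows), all_row)
}

#' Distance time series between two atom selections
#'
#' The per-frame distance is the minimum over all selected atom pairs (a
#' single pair when both selectors name one atom). An optional centered
#' running mean with truncated edges smooths the series.
#'
#' @param traj a `channel_trajectory`.
#' @param a,b atom selectors (see [resolve_atoms()]).
#' @param stride sampling interval in ps.
#' @param running_window running-average window in ns, or `NULL`.
#' @param periodic minimum-image distances.
#' @return data frame `time` (ps), `distance` (angstrom) and, when
#'   requested, `running` (angstrom).
#' @export
distance_series <- function(traj, a, b, stride = NULL, running_window = NULL,
                            periodic = TRUE) {
  ia <- resolve_atoms(traj$topology, a)
  ib <- resolve_atoms(traj$topology, b)
  fidx <- sample_frames(traj, stride)
  d <- vapply(fidx, function(f)
    min_distance(traj$coords[ia, , f, drop = FALSE],
                 traj$coords[ib, , f, drop = FALSE],
                 if (periodic) traj$box[f, ] else NULL), numeric(1))
  out <- data.frame(time = traj$times[fidx], distance = d)
  if (!is.null(running_window))
    out$running <- running_average(out$distance, out$time,
                                   running_window * 1000)
  out
}

#' Bound-ligand count over time at a site
#'
#' Counts, at each sampled frame, the ligands within the site's contact
#' cutoff of any subunit's site atoms. The mean and standard deviation over
#' the series use the population (n) denominator by default since the series
#' is the complete simulation record, with `sd_type = "sample"` available.
#'
#' @param traj a `channel_trajectory`.
#' @param site a `site_definition`.
#' @param stride sampling interval in ps.
#' @param sd_type `"population"` or `"sample"`.
#' @param include_hydrogens use hydrogens in the contact criterion.
#' @param periodic minimum-image distances.
#' @return data frame of class `occupancy_series` (`time`, `n_bound`) with
#'   attributes `mean` and `sd`.
#' @export
occupancy_series <- function(traj, site, stride = NULL,
                             sd_type = c("population", "sample"),
                             include_hydrogens = FALSE, periodic = TRUE) {
  sd_type <- match.arg(sd_type)
  topo <- traj$topology
  lids <- ligand_ids(topo)
  if (length(lids) == 0) stop("topology contains no ligands")
  heavy <- !include_hydrogens
  site_atoms <- sort(unlist(resolve_selection_all(topo, site,
                                                  heavy_only = heavy)))
  ligs <- lapply(lids, ligand_atoms, topology = topo, heavy_only = heavy)
  fidx <- sample_frames(traj, stride)
  counts <- vapply(fidx, function(f) {
    bx <- if (periodic) traj$box[f, ] else NULL
    sx <- traj$coords[site_atoms, , f, drop = FALSE]
    sum(vapply(ligs, function(idx)
      min_distance(traj$coords[idx, , f, drop = FALSE], sx, bx) <=
        site$contact_enter_cutoff, logical(1)))
  }, numeric(1))
  out <- data.frame(time = traj$times[fidx], n_bound = as.integer(counts))
  m <- mean(counts)
  s <- if (sd_type == "population")
    sqrt(mean((counts - m)^2)) else stats::sd(counts)
  structure(out, mean = m, sd = s, sd_type = sd_type, site = site$name,
            class = c("occupancy_series", "data.frame"))
}
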
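# Helix-helix interface detection and 7x7 contact maps, separately for
# long-lived stable dimers and transient (dissociating) dimers.

#' Helix pairs at the dimer interface of one frame
#'
#' A residue of receptor 1 and a residue of receptor 2 are in contact when
#' any inter-bead minimum-image distance is below the contact cut-off
#' (0.5 nm); a helix pair is at the interface when at least one residue
#' contact joins the two helices. Contacts involving loop residues are
#' tallied separately and excluded from the 7x7 map.
#'
#' @param frame a \code{cg_frame}.
#' @param topology a \code{system_topology}.
#' @param config an \code{analysis_config}.
#' @return list(pairs = data.frame(helix_a, helix_b) of interface helix pairs
#'   (receptor 1 x receptor 2), loop_contacts = data.frame(label_a, label_b)
#'   of contacts involving a loop).
#' @export
interface_helices <- function(frame, topology, config = analysis_config()) {
  b <- topology$beads
  i1 <- which(b$molecule_kind == "receptor" & b$receptor_id == 1L)
  i2 <- which(b$molecule_kind == "receptor" & b$receptor_id == 2L)
  dm <- pbc_dist_matrix(frame$coords[i1, , drop = FALSE],
                        frame$coords[i2, , drop = FALSE], frame$box)
  hit <- which(dm < config$contact_cutoff, arr.ind = TRUE)
  la <- b$helix_label[i1][hit[, 1]]
  lb <- b$helix_label[i2][hit[, 2]]
  tm <- la %in% HELIX_LABELS & lb %in% HELIX_LABELS
  pairs <- unique(data.frame(helix_a = la[tm], helix_b = lb[tm]))
  rownames(pairs) <- NULL
  loops <- unique(data.frame(label_a = la[!tm], label_b = lb[!tm]))
  rownames(loops) <- NULL
  list(pairs = pairs, loop_contacts = loops)
}

# 7 x 7 x n_frames logical array of interface flags plus a loop-contact tally.
interface_flag_array <- function(traj, topology, frames,
                                 config = analysis_config()) {
  b <- topology$beads
  i1 <- which(b$molecule_kind == "receptor" & b$receptor_id == 1L)
  i2 <- which(b$molecule_kind == "receptor" & b$receptor_id == 2L)
  l1 <- b$helix_label[i1]; l2 <- b$helix_label[i2]
  tm1 <- l1 %in% HELIX_LABELS; tm2 <- l2 %in% HELIX_LABELS
  h1 <- match(l1, HELIX_LABELS); h2 <- match(l2, HELIX_LABELS)
  flags <- array(FALSE, c(7, 7, length(frames)),
                 dimnames = list(HELIX_LABELS, HELIX_LABELS, NULL))
  loop_tally <- list()
  for (k in seq_along(frames)) {
    fr <- traj$frames[[frames[k]]]
    dm <- pbc_dist_matrix(fr$coords[i1, , drop = FALSE],
                          fr$coords[i2, , drop = FALSE], fr$box)
    hit <- which(dm < config$contact_cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    is_tm <- tm1[hit[, 1]] & tm2[hit[, 2]]
    if (any(is_tm)) {
      idx <- cbind(h1[hit[is_tm, 1]], h2[hit[is_tm, 2]],
                   rep(k, sum(is_tm)))
      flags[idx] <- TRUE
    }
    if (any(!is_tm)) {
      lp <- unique(data.frame(label_a = l1[hit[!is_tm, 1]],
                              label_b = l2[hit[!is_tm, 2]]))
      loop_tally[[length(loop_tally) + 1L]] <- lp
    }
  }
  loops <- if (length(loop_tally)) {
    all <- do.call(rbind, loop_tally)
    stats::aggregate(list(n_frames = rep(1L, nrow(all))),
                     by = all[c("label_a", "label_b")], FUN = sum)
  } else data.frame(label_a = character(0), label_b = character(0),
                    n_frames = integer(0))
  list(flags = flags, loop_contacts = loops)
}

empty_contact_map <- function(kind, composition) {
  m <- matrix(0, 7, 7, dimnames = list(HELIX_LABELS, HELIX_LABELS))
  structure(list(matrix = m, raw = m, kind = kind, composition = composition,
                 n_events = 0L,
                 loop_contacts = data.frame(label_a = character(0),
                                            label_b = character(0),
                                            n_frames = integer(0))),
            class = "helix_contact_map")
}

contact_runs_check <- function(runs) {
  if (!is.null(runs$trajectory)) runs <- list(runs)
  for (r in runs) {
    if (is.null(r$trajectory) || is.null(r$topology) || is.null(r$segmentation))
      stop("each run needs $trajectory, $topology and $segmentation")
  }
  runs
}

#' Contact map of long-lived stable dimers
#'
#' For each stable event the per-pair fraction of event frames at the
#' interface is weighted by the event's share of its simulation (duration /
#' simulation length in frames), accumulated over events, and the matrix is
#' divided by its maximum so the dominant pair scores 1 (population
#' normalized by time of occurrence and simulation length). The raw
#' accumulator is retained so alternative normalizations can be applied post
#' hoc.
#'
#' @param runs a list of runs, each a list with \code{trajectory},
#'   \code{topology} and \code{segmentation}; a single run may be given
#'   directly.
#' @param config an \code{analysis_config}.
#' @return object of class \code{helix_contact_map} (fields: matrix, raw,
#'   kind, composition, n_events, loop_contacts).
#' @export
stable_contact_map <- function(runs, config = analysis_config()) {
  runs <- contact_runs_check(runs)
  comp <- runs[[1]]$trajectory$composition
  acc <- matrix(0, 7, 7, dimnames = list(HELIX_LABELS, HELIX_LABELS))
  loops <- list()
  n_events <- 0L
  for (r in runs) {
    ev <- r$segmentation$dimer_events
    ev <- ev[ev$class == "stable", , drop = FALSE]
    for (e in seq_len(nrow(ev))) {
      frames <- ev$start[e]:ev$end[e]
      fa <- interface_flag_array(r$trajectory, r$topology, frames, config)
      frac <- apply(fa$flags, c(1, 2), mean)
      weight <- length(frames) / length(r$trajectory$frames)
      acc <- acc + frac * weight
      loops[[length(loops) + 1L]] <- fa$loop_contacts
      n_events <- n_events + 1L
    }
  }
  if (n_events == 0L) {
    warning("stable_contact_map: no stable events")
    return(empty_contact_map("stable", comp))
  }
  structure(list(matrix = acc / max(acc), raw = acc, kind = "stable",
                 composition = comp, n_events = n_events,
                 loop_contacts = bind_loop_tallies(loops)),
            class = "helix_contact_map")
}

#' Contact map of transient dimers
#'
#' Each transient event contributes, per helix pair, its fraction of event
#' frames at the interface (occurrence normalized to the association period);
#' the accumulated matrix is divided by the maximum over pairs of the total
#' number of transient instances (events in which the pair appeared at all),
#' so values lie in [0, 1] and the most frequently dissociating pair scores 1.
#'
#' @inheritParams stable_contact_map
#' @return object of class \code{helix_contact_map}.
#' @export
transient_contact_map <- function(runs, config = analysis_config()) {
  runs <- contact_runs_check(runs)
  comp <- runs[[1]]$trajectory$composition
  acc <- matrix(0, 7, 7, dimnames = list(HELIX_LABELS, HELIX_LABELS))
  inst <- acc
  loops <- list()
  n_events <- 0L
  for (r in runs) {
    ev <- r$segmentation$dimer_events
    ev <- ev[ev$class == "transient", , drop = FALSE]
    for (e in seq_len(nrow(ev))) {
      frames <- ev$start[e]:ev$end[e]
      fa <- interface_flag_array(r$trajectory, r$topology, frames, config)
      frac <- apply(fa$flags, c(1, 2), mean)
      acc <- acc + frac
      inst <- inst + (frac > 0)
      loops[[length(loops) + 1L]] <- fa$loop_contacts
      n_events <- n_events + 1L
    }
  }
  if (n_events == 0L) {
    warning("transient_contact_map: no transient events")
    return(empty_contact_map("transient", comp))
  }
  structure(list(matrix = acc / max(inst), raw = acc, kind = "transient",
                 composition = comp, n_events = n_events,
                 instances = inst, loop_contacts = bind_loop_tallies(loops)),
            class = "helix_contact_map")
}

bind_loop_tallies <- function(loops) {
  loops <- loops[vapply(loops, nrow, 0L) > 0]
  if (!length(loops)) return(data.frame(label_a = character(0),
                                        label_b = character(0),
                                        n_frames = integer(0)))
  all <- do.call(rbind, loops)
  stats::aggregate(list(n_frames = all$n_frames),
                   by = all[c("label_a", "label_b")], FUN = sum)
}

#' Symmetrized (unordered) contact map
#'
#' Ordered receptor-1 x receptor-2 populations are folded into unordered
#' helix-pair populations (off-diagonal entries summed with their transpose)
#' and rescaled to a maximum of 1.
#'
#' @param map a \code{helix_contact_map}.
#' @return symmetric numeric matrix.
#' @export
symmetrize_contact_map <- function(map) {
  m <- map$raw
  s <- m + t(m)
  diag(s) <- diag(m)
  if (max(s) > 0) s <- s / max(s)
  s
}

#' @export
print.helix_contact_map <- function(x, ...) {
  cat(sprintf("%s helix contact map (%d%% cholesterol, %d event(s))\n",
              x$kind, x$composition, x$n_events))
  print(round(x$matrix, 3))
  invisible(x)
}
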
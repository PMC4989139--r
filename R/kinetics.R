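# Dimer/monomer kinetics: per-frame minimum inter-receptor distance,
# hysteresis segmentation into monomer/dimer regimes, stable/transient
# classification and dissociation-event counting.

#' Minimum inter-receptor distance of one frame
#'
#' Minimum over all pairs (transmembrane bead of receptor 1, transmembrane
#' bead of receptor 2) of the minimum-image distance. Loop beads are excluded:
#' the distance characterizes the transmembrane segments, and the third
#' intracellular loop would otherwise dominate close approaches.
#'
#' @param frame a \code{cg_frame}.
#' @param topology a \code{system_topology}.
#' @return distance in nm.
#' @export
min_distance <- function(frame, topology) {
  i1 <- tm_bead_indices(topology, 1L)
  i2 <- tm_bead_indices(topology, 2L)
  if (!length(i1) || !length(i2))
    stop("min_distance: a receptor has no transmembrane beads")
  pbc_min_dist(frame$coords[i1, , drop = FALSE],
               frame$coords[i2, , drop = FALSE], frame$box)
}

#' Per-frame minimum-distance series of a trajectory
#'
#' @param traj a \code{cg_trajectory}.
#' @param topology a \code{system_topology}.
#' @return object of class \code{distance_series}: list(times, min_distance).
#' @export
distance_series <- function(traj, topology) {
  i1 <- tm_bead_indices(topology, 1L)
  i2 <- tm_bead_indices(topology, 2L)
  if (!length(i1) || !length(i2))
    stop("distance_series: a receptor has no transmembrane beads")
  d <- vapply(traj$frames, function(fr)
    pbc_min_dist(fr$coords[i1, , drop = FALSE],
                 fr$coords[i2, , drop = FALSE], fr$box), 0)
  structure(list(times = trajectory_times(traj), min_distance = d,
                 label = traj$label, composition = traj$composition),
            class = "distance_series")
}

#' Segment a distance series into monomer/dimer regimes
#'
#' Hysteresis segmentation: a dimer interval opens at the first frame of at
#' least \code{min_dimer_frames} consecutive frames below \code{dimer_cutoff}
#' and closes at the first frame above \code{dissociation_threshold}
#' (distances in between continue the current regime). An interval reaching
#' the final frame unclosed is a stable dimer; a closed interval lasting at
#' least \code{min_transient_duration} ns is a transient dimer (one
#' dissociation event); shorter closed contacts are grazing and folded back
#' into the monomer regime.
#'
#' @param series a \code{distance_series}.
#' @param config an \code{analysis_config}.
#' @return object of class \code{regime_segmentation}: \code{intervals}
#'   (data.frame start, end, label; a partition with alternating labels) and
#'   \code{dimer_events} (data.frame interval, start, end, class).
#' @export
segment_regimes <- function(series, config = analysis_config()) {
  d <- series$min_distance
  tt <- series$times
  n <- length(d)
  if (!n) stop("segment_regimes: empty series")
  if (any(d < 0)) stop("segment_regimes: negative distances")
  below <- d < config$dimer_cutoff
  runs <- rle(below)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L

  is_dimer <- rep(FALSE, n)
  events <- list()
  i <- 1L
  while (i <= n) {
    if (below[i]) {
      ri <- which(run_start <= i & run_end >= i)
      runlen <- run_end[ri] - i + 1L
      if (runlen >= config$min_dimer_frames) {
        after <- which(d > config$dissociation_threshold)
        after <- after[after > i]
        if (!length(after)) {                      # persists to the end: stable
          is_dimer[i:n] <- TRUE
          events[[length(events) + 1L]] <-
            data.frame(start = i, end = n, class = "stable")
          break
        }
        j <- after[1]
        dur <- tt[j - 1L] - tt[i]
        if (dur >= config$min_transient_duration) {
          is_dimer[i:(j - 1L)] <- TRUE
          events[[length(events) + 1L]] <-
            data.frame(start = i, end = j - 1L, class = "transient")
        }
        i <- j
        next
      }
      i <- run_end[ri] + 1L
    } else i <- i + 1L
  }

  lab_runs <- rle(is_dimer)
  ends <- cumsum(lab_runs$lengths)
  starts <- ends - lab_runs$lengths + 1L
  intervals <- data.frame(start = starts, end = ends,
                          label = ifelse(lab_runs$values, "dimer", "monomer"))
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(start = integer(0), end = integer(0), class = character(0))
  ev$interval <- match(ev$start, intervals$start)
  structure(list(intervals = intervals,
                 dimer_events = ev[, c("interval", "start", "end", "class")],
                 n_frames = n, times = tt),
            class = "regime_segmentation")
}

#' @export
print.regime_segmentation <- function(x, ...) {
  ev <- x$dimer_events
  cat("Regime segmentation:", nrow(x$intervals), "intervals over",
      x$n_frames, "frames;", sum(ev$class == "transient"), "transient and",
      sum(ev$class == "stable"), "stable dimer event(s)\n")
  invisible(x)
}

#' Frames carrying a given regime label
#' @param seg a \code{regime_segmentation}.
#' @param label "monomer" or "dimer".
#' @return integer frame indices.
#' @export
regime_frames <- function(seg, label = c("dimer", "monomer")) {
  label <- match.arg(label)
  iv <- seg$intervals[seg$intervals$label == label, , drop = FALSE]
  if (!nrow(iv)) return(integer(0))
  sort(unlist(lapply(seq_len(nrow(iv)), function(i) iv$start[i]:iv$end[i])))
}

#' Count dissociation events
#'
#' A dissociation event is a closed (transient) dimer interval. Counts are
#' reported per composition and overall.
#'
#' @param segmentations list of \code{regime_segmentation}.
#' @param compositions optional vector (one per segmentation) of cholesterol
#'   percentages.
#' @return list(total, by_composition).
#' @export
count_dissociations <- function(segmentations, compositions = NULL) {
  nt <- vapply(segmentations, function(s)
    sum(s$dimer_events$class == "transient"), 0L)
  by <- NULL
  if (!is.null(compositions)) {
    by <- tapply(nt, compositions, sum)
    by <- stats::setNames(as.integer(by), names(by))
  }
  list(total = sum(nt), by_composition = by)
}

#' Distance heat-map classes
#'
#' Bins each simulation's minimum-distance series into the distance classes
#' used to visualize association/dissociation (< 0.5, 0.5-1, 1-2, 2-4,
#' > 4 nm), one row per simulation.
#'
#' @param series_list list of \code{distance_series}.
#' @param breaks bin edges in nm.
#' @return integer matrix (simulation x frame) of class indices, with
#'   attributes \code{breaks} and \code{labels}; shorter series are padded
#'   with NA.
#' @export
distance_heatmap <- function(series_list,
                             breaks = c(0, 0.5, 1, 2, 4, Inf)) {
  if (!length(series_list)) stop("distance_heatmap: no series")
  if (inherits(series_list, "distance_series")) series_list <- list(series_list)
  labels <- paste0(utils::head(breaks, -1), "-", utils::tail(breaks, -1))
  labels[length(labels)] <- paste0(">", breaks[length(breaks) - 1])
  labels[1] <- paste0("<", breaks[2])
  nmax <- max(vapply(series_list, function(s) length(s$min_distance), 0L))
  m <- matrix(NA_integer_, length(series_list), nmax)
  for (i in seq_along(series_list)) {
    d <- series_list[[i]]$min_distance
    m[i, seq_along(d)] <- as.integer(cut(d, breaks, right = FALSE))
  }
  rownames(m) <- vapply(series_list, function(s)
    if (is.null(s$label)) "sim" else s$label, "")
  colnames(m) <- seq_len(nmax)
  attr(m, "breaks") <- breaks
  attr(m, "labels") <- labels
  m
}
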
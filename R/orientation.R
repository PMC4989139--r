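# Rotational orientation of the two receptors in the dimer regime. The angle
# of a subject receptor is the signed four-point dihedral over the backbone
# beads 48-164-167 of the subject and 167 of the partner (P08908 numbering):
# the angle between the plane through the subject's three beads and the plane
# through the 164-167 axis and the partner's 167 bead.

#' Rotational angle of one receptor relative to the other
#'
#' @param frame a \code{cg_frame} (should lie in the dimer regime).
#' @param topology a \code{system_topology}.
#' @param subject receptor id (1 or 2) whose angle is computed.
#' @return signed angle in degrees in (-180, 180]; NA when the defining beads
#'   are collinear (degenerate plane).
#' @export
rotation_angle <- function(frame, topology, subject = 1L) {
  other <- if (subject == 1L) 2L else 1L
  p1 <- frame$coords[backbone_bead_index(topology, subject, 48L), ]
  p2 <- frame$coords[backbone_bead_index(topology, subject, 164L), ]
  p3 <- frame$coords[backbone_bead_index(topology, subject, 167L), ]
  p4 <- frame$coords[backbone_bead_index(topology, other, 167L), ]
  dihedral_angle(p1, p2, p3, p4, box = frame$box)
}

#' Orientation series over the dimer regime
#'
#' @param traj a \code{cg_trajectory}.
#' @param topology a \code{system_topology}.
#' @param seg a \code{regime_segmentation} (dimer frames taken from it), or an
#'   integer vector of frame indices.
#' @return data.frame (class \code{orientation_series}) with columns
#'   \code{frame}, \code{time}, \code{theta1}, \code{theta2}.
#' @export
orientation_series <- function(traj, topology, seg) {
  frames <- if (inherits(seg, "regime_segmentation"))
    regime_frames(seg, "dimer") else as.integer(seg)
  b1 <- c(backbone_bead_index(topology, 1L, 48L),
          backbone_bead_index(topology, 1L, 164L),
          backbone_bead_index(topology, 1L, 167L))
  b2 <- c(backbone_bead_index(topology, 2L, 48L),
          backbone_bead_index(topology, 2L, 164L),
          backbone_bead_index(topology, 2L, 167L))
  th1 <- th2 <- rep(NA_real_, length(frames))
  for (k in seq_along(frames)) {
    fr <- traj$frames[[frames[k]]]
    th1[k] <- dihedral_angle(fr$coords[b1[1], ], fr$coords[b1[2], ],
                             fr$coords[b1[3], ], fr$coords[b2[3], ],
                             box = fr$box)
    th2[k] <- dihedral_angle(fr$coords[b2[1], ], fr$coords[b2[2], ],
                             fr$coords[b2[3], ], fr$coords[b1[3], ],
                             box = fr$box)
  }
  out <- data.frame(frame = frames,
                    time = trajectory_times(traj)[frames],
                    theta1 = th1, theta2 = th2)
  class(out) <- c("orientation_series", "data.frame")
  out
}

#' Normalized 2-D orientation population density
#'
#' Histogram of (theta1, theta2) over dimer-regime frames, normalized to unit
#' sum. When a grouping vector is supplied and groups contribute unequal
#' numbers of series (simulations), every group is subsampled to the smallest
#' count (seeded by \code{config$seed}) so compositions with fewer dimerized
#' simulations are compared fairly.
#'
#' @param series an \code{orientation_series} or a list of them.
#' @param config an \code{analysis_config}; \code{angle_bin_width} sets the
#'   bins.
#' @param groups optional vector (one entry per series) used for the
#'   equal-count subsampling.
#' @return matrix of bin probabilities (rows theta1, columns theta2), dimnames
#'   holding bin centers; attribute \code{breaks}. Sums to 1; all-empty input
#'   yields an all-zero matrix with a warning.
#' @export
orientation_density <- function(series, config = analysis_config(),
                                groups = NULL) {
  if (inherits(series, "orientation_series")) series <- list(series)
  if (!length(series)) stop("orientation_density: no series")
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(series))
    counts <- table(groups)
    nmin <- min(counts)
    keep <- with_seed(config$seed, {
      unlist(lapply(split(seq_along(series), groups), function(idx) {
        if (length(idx) > nmin) sort(sample(idx, nmin)) else idx
      }), use.names = FALSE)
    })
    series <- series[sort(keep)]
  }
  w <- config$angle_bin_width
  breaks <- seq(-180, 180, by = w)
  nb <- length(breaks) - 1L
  centers <- breaks[-1] - w / 2
  counts <- matrix(0, nb, nb, dimnames = list(centers, centers))
  for (s in series) {
    ok <- !is.na(s$theta1) & !is.na(s$theta2)
    if (!any(ok)) next
    # 180 belongs to the last bin; breaks are left-closed otherwise
    i <- pmin(floor((s$theta1[ok] + 180) / w) + 1L, nb)
    j <- pmin(floor((s$theta2[ok] + 180) / w) + 1L, nb)
    for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1
  }
  tot <- sum(counts)
  if (tot == 0) {
    warning("orientation_density: empty dimer regime everywhere")
    return(structure(counts, breaks = breaks))
  }
  structure(counts / tot, breaks = breaks)
}

# --- conformer regions ------------------------------------------------------

#' Conformer regions in (theta1, theta2) space
#'
#' Axis-aligned rectangles labelling the broad dimer conformations A (a
#' symmetric site-1 homodimer around the origin), A' (a flexible ring around
#' A at site 1), B (site-2 homointerfaces) and C (site-1/site-2
#' heterointerfaces). Rectangles are left/bottom-closed, right/top-open
#' (closed at the +180 domain edge), must stay in (-180, 180] and must not
#' overlap. The defaults are a declared calibration on the packaged synthetic
#' template geometry, shipped as an editable YAML file.
#'
#' @param path YAML file with records label/xmin/xmax/ymin/ymax.
#' @return data.frame of class \code{conformer_regions}.
#' @export
read_conformer_regions <- function(path) {
  obj <- yaml::read_yaml(path)
  regions <- do.call(rbind, lapply(obj$regions, function(r)
    data.frame(label = r$label, xmin = r$xmin, xmax = r$xmax,
               ymin = r$ymin, ymax = r$ymax)))
  validate_conformer_regions(regions)
}

#' @rdname read_conformer_regions
#' @export
default_conformer_regions <- function() {
  read_conformer_regions(system.file("extdata", "conformer_regions.yaml",
                                     package = "dimerlens", mustWork = TRUE))
}

validate_conformer_regions <- function(regions) {
  stopifnot(all(c("label", "xmin", "xmax", "ymin", "ymax") %in% names(regions)))
  if (any(regions$xmin >= regions$xmax | regions$ymin >= regions$ymax))
    stop("conformer region with empty extent")
  if (any(regions$xmin < -180 | regions$xmax > 180 |
            regions$ymin < -180 | regions$ymax > 180))
    stop("conformer regions must lie within (-180, 180]")
  n <- nrow(regions)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (regions$xmin[i] < regions$xmax[j] && regions$xmin[j] < regions$xmax[i] &&
        regions$ymin[i] < regions$ymax[j] && regions$ymin[j] < regions$ymax[i])
      stop("overlapping conformer regions: ", regions$label[i], " row ", i,
           " and ", regions$label[j], " row ", j)
  }
  class(regions) <- c("conformer_regions", "data.frame")
  regions
}

#' Assign conformer labels to orientation points
#'
#' @param theta1,theta2 numeric vectors (degrees).
#' @param regions a \code{conformer_regions} table (default: packaged
#'   calibration).
#' @return character vector of labels, \code{"unassigned"} for points in no
#'   region.
#' @export
assign_conformer <- function(theta1, theta2,
                             regions = default_conformer_regions()) {
  regions <- validate_conformer_regions(regions)
  out <- rep("unassigned", length(theta1))
  for (i in seq_len(nrow(regions))) {
    xhit <- theta1 >= regions$xmin[i] &
      (theta1 < regions$xmax[i] | (regions$xmax[i] == 180 & theta1 == 180))
    yhit <- theta2 >= regions$ymin[i] &
      (theta2 < regions$ymax[i] | (regions$ymax[i] == 180 & theta2 == 180))
    hit <- !is.na(xhit) & !is.na(yhit) & xhit & yhit
    out[hit] <- regions$label[i]
  }
  out[is.na(theta1) | is.na(theta2)] <- NA_character_
  out
}
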
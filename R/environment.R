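# Lipid environment of the receptor: residue-wise maximum lipid occupancy
# (longest normalized single-molecule residence) and the normalized
# bilayer-thickness map around the monomeric receptor.

#' Residue-wise maximum lipid occupancy
#'
#' For each receptor residue and each lipid molecule of the requested kind,
#' the longest run of consecutive regime frames in which any bead of the
#' lipid lies within the lipid contact cut-off of any bead of the residue is
#' found; the occupancy of the residue is the longest such run across
#' molecules divided by the regime length in frames. Runs are counted on the
#' concatenated regime-frame sequence, so a molecule resident through an
#' entire (possibly multi-interval) regime scores exactly 1. A single frame
#' outside the cut-off breaks a run (zero gap tolerance).
#'
#' @param traj a \code{cg_trajectory}.
#' @param topology a \code{system_topology}.
#' @param frames integer vector of regime frames (e.g. from
#'   \code{\link{regime_frames}}).
#' @param lipid_kind "CHOL" or "POPC".
#' @param config an \code{analysis_config}.
#' @param average_receptors average the per-receptor profiles by residue
#'   (mirroring per-monomer averaging over simulations).
#' @param normalize divide the profile by its maximum.
#' @param regime label stored in the result's metadata.
#' @return data.frame of class \code{occupancy_profile} with columns
#'   \code{residue_index}, \code{occupancy} (plus \code{occupancy_r1} /
#'   \code{occupancy_r2} when averaging); attributes \code{lipid_kind},
#'   \code{regime}, \code{n_frames}, \code{normalized}.
#' @export
residue_occupancy <- function(traj, topology, frames, lipid_kind,
                              config = analysis_config(),
                              average_receptors = TRUE, normalize = FALSE,
                              regime = "monomer") {
  stopifnot(lipid_kind %in% c("CHOL", "POPC"))
  if (!length(frames)) stop("residue_occupancy: empty regime")
  b <- topology$beads
  lip <- which(b$molecule_kind == lipid_kind)
  rec <- which(b$molecule_kind == "receptor")
  res_key <- paste(b$receptor_id[rec], b$residue_index[rec], sep = ":")
  res_groups <- unique(res_key)
  gi <- match(res_key, res_groups)
  mol_ids <- unique(b$molecule_id[lip])
  mi <- match(b$molecule_id[lip], mol_ids)
  n_res <- length(res_groups)
  n_mol <- length(mol_ids)
  if (!n_mol) {
    warning("residue_occupancy: no ", lipid_kind, " molecules in topology")
    resdf <- unique(data.frame(
      receptor_id = b$receptor_id[rec], residue_index = b$residue_index[rec]))
    out <- data.frame(residue_index = sort(unique(resdf$residue_index)),
                      occupancy = 0)
    class(out) <- c("occupancy_profile", "data.frame")
    return(out)
  }

  nf <- length(frames)
  contact <- array(FALSE, c(n_res, n_mol, nf))
  cutoff <- config$lipid_contact_cutoff
  for (k in seq_len(nf)) {
    fr <- traj$frames[[frames[k]]]
    dm <- pbc_dist_matrix(fr$coords[rec, , drop = FALSE],
                          fr$coords[lip, , drop = FALSE], fr$box)
    hitmat <- dm < cutoff
    # residue x molecule: any bead-bead contact
    byres <- rowsum(hitmat + 0, gi, reorder = FALSE)
    bymol <- t(rowsum(t(byres), mi, reorder = FALSE))
    contact[, , k] <- bymol > 0
  }
  # reorder groups: rowsum(..., reorder = FALSE) keeps first-appearance order,
  # which matches res_groups / mol_ids construction
  longest_run <- function(v) {
    r <- rle(v)
    if (!any(r$values)) 0L else max(r$lengths[r$values])
  }
  occ_rm <- matrix(0, n_res, n_mol)
  for (i in seq_len(n_res)) for (j in seq_len(n_mol))
    occ_rm[i, j] <- longest_run(contact[i, j, ])
  occ_res <- apply(occ_rm, 1, max) / nf

  key_split <- strsplit(res_groups, ":", fixed = TRUE)
  rid <- as.integer(vapply(key_split, `[`, "", 1))
  resi <- as.integer(vapply(key_split, `[`, "", 2))
  per <- data.frame(receptor_id = rid, residue_index = resi,
                    occupancy = occ_res)
  if (average_receptors) {
    wide <- merge(per[per$receptor_id == 1, c("residue_index", "occupancy")],
                  per[per$receptor_id == 2, c("residue_index", "occupancy")],
                  by = "residue_index", all = TRUE,
                  suffixes = c("_r1", "_r2"))
    wide$occupancy <- rowMeans(wide[, c("occupancy_r1", "occupancy_r2")],
                               na.rm = TRUE)
    out <- wide[order(wide$residue_index),
                c("residue_index", "occupancy", "occupancy_r1", "occupancy_r2")]
  } else {
    out <- per[order(per$receptor_id, per$residue_index), ]
  }
  rownames(out) <- NULL
  if (normalize && max(out$occupancy) > 0)
    out$occupancy <- out$occupancy / max(out$occupancy)
  class(out) <- c("occupancy_profile", "data.frame")
  attr(out, "lipid_kind") <- lipid_kind
  attr(out, "regime") <- regime
  attr(out, "n_frames") <- nf
  attr(out, "normalized") <- normalize
  attr(out, "lipid_contact_cutoff") <- cutoff
  out
}

#' Normalized bilayer-thickness map around a receptor
#'
#' Frames are transformed into the receptor body frame (origin at the
#' transmembrane centroid, +x toward the helix-I centroid) so helix sectors
#' are fixed directions in the map. Per grid cell the thickness is the mean
#' upper-leaflet phosphate z minus the mean lower-leaflet phosphate z over
#' frames; leaflets are assigned per frame by the sign of z relative to the
#' phosphate median. The map is normalized by the mean thickness over
#' far-field cells (farther than \code{farfield_min_distance} from any
#' receptor bead), so 1 means the unperturbed bilayer, >1 local thickening
#' (positive hydrophobic mismatch) and <1 local thinning.
#'
#' @param traj a \code{cg_trajectory}.
#' @param topology a \code{system_topology}.
#' @param frames integer vector of (monomer-regime) frames.
#' @param config an \code{analysis_config} (grid_bin, farfield_min_distance).
#' @param receptor receptor id the map is centred on.
#' @return object of class \code{thickness_map}: list(grid (normalized, NA
#'   where a leaflet has no samples), n_samples, x, y (cell centers),
#'   farfield_thickness (nm), farfield_cells, receptor_max_radius).
#' @export
thickness_map <- function(traj, topology, frames,
                          config = analysis_config(), receptor = 1L) {
  if (!length(frames)) stop("thickness_map: no frames")
  b <- topology$beads
  ph <- which(b$molecule_kind == "POPC" & b$bead_role == "phosphate")
  if (!length(ph)) stop("thickness_map: no phosphate beads in topology")
  rec <- which(b$molecule_kind == "receptor" & b$receptor_id == receptor)
  tm <- rec[b$helix_label[rec] %in% HELIX_LABELS]
  hI <- rec[!is.na(b$helix_label[rec]) & b$helix_label[rec] == "I"]
  box <- traj$frames[[1]]$box
  ext <- max(box[1], box[2]) / 2 + 1
  bin <- config$grid_bin
  nb <- ceiling(2 * ext / bin)
  centers <- -ext + (seq_len(nb) - 0.5) * bin

  idx_up <- list(); idx_lo <- list(); z_up <- list(); z_lo <- list()
  max_rad <- 0
  for (k in seq_along(frames)) {
    fr <- traj$frames[[frames[k]]]
    ctm <- fr$coords[tm, , drop = FALSE]
    # unwrap the receptor about its first bead before averaging
    ref <- ctm[1, ]
    for (d in 1:2) ctm[, d] <- ref[d] +
        (ctm[, d] - ref[d]) - box[d] * round((ctm[, d] - ref[d]) / box[d])
    cen <- colMeans(ctm[, 1:2, drop = FALSE])
    chI <- fr$coords[hI, 1:2, drop = FALSE]
    for (d in 1:2) chI[, d] <- cen[d] +
        (chI[, d] - cen[d]) - box[d] * round((chI[, d] - cen[d]) / box[d])
    axis <- colMeans(chI) - cen
    alpha <- atan2(axis[2], axis[1])
    max_rad <- max(max_rad, sqrt(max(rowSums(
      sweep(ctm[, 1:2, drop = FALSE], 2, cen)^2))))
    p <- fr$coords[ph, , drop = FALSE]
    dx <- p[, 1] - cen[1]; dx <- dx - box[1] * round(dx / box[1])
    dy <- p[, 2] - cen[2]; dy <- dy - box[2] * round(dy / box[2])
    ca <- cos(-alpha); sa <- sin(-alpha)
    bx <- ca * dx - sa * dy
    by <- sa * dx + ca * dy
    up <- p[, 3] > stats::median(p[, 3])
    ix <- pmin(pmax(floor((bx + ext) / bin) + 1L, 1L), nb)
    iy <- pmin(pmax(floor((by + ext) / bin) + 1L, 1L), nb)
    lin <- (iy - 1L) * nb + ix
    idx_up[[k]] <- lin[up]; z_up[[k]] <- p[up, 3]
    idx_lo[[k]] <- lin[!up]; z_lo[[k]] <- p[!up, 3]
  }
  acc <- function(idx, z) {
    idx <- unlist(idx); z <- unlist(z)
    s <- rowsum(z, idx)
    n <- rowsum(rep(1, length(idx)), idx)
    list(sum = s, n = n, cells = as.integer(rownames(s)))
  }
  au <- acc(idx_up, z_up); al <- acc(idx_lo, z_lo)
  mean_up <- rep(NA_real_, nb * nb); mean_lo <- rep(NA_real_, nb * nb)
  nobs <- matrix(0L, nb, nb)
  mean_up[au$cells] <- au$sum / au$n
  mean_lo[al$cells] <- al$sum / al$n
  nobs[au$cells] <- nobs[au$cells] + as.integer(au$n)
  nobs[al$cells] <- nobs[al$cells] + as.integer(al$n)
  thick <- matrix(mean_up - mean_lo, nb, nb)
  dimnames(thick) <- list(sprintf("%.2f", centers), sprintf("%.2f", centers))

  rho <- sqrt(outer(centers^2, centers^2, "+"))
  far <- rho > config$farfield_min_distance + max_rad
  far_vals <- thick[far & !is.na(thick)]
  if (!length(far_vals))
    stop("thickness_map: no sampled far-field cells; enlarge the box or lower farfield_min_distance")
  t_far <- mean(far_vals)
  structure(list(grid = thick / t_far, n_samples = nobs,
                 x = centers, y = centers,
                 farfield_thickness = t_far,
                 farfield_cells = far,
                 receptor_max_radius = max_rad,
                 n_frames = length(frames)),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("Thickness map: %dx%d cells, far-field thickness %.3f nm, %d frames\n",
              nrow(x$grid), ncol(x$grid), x$farfield_thickness, x$n_frames))
  invisible(x)
}
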
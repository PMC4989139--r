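# Shared, lazily generated analysis state. The four packaged scenarios are
# expensive enough that each is generated and segmented once per test run.

.run_cache <- new.env(parent = emptyenv())

ref_run <- function(i) {
  key <- paste0("run", i)
  if (!exists(key, envir = .run_cache)) {
    sc <- reference_scenarios()[[i]]
    run <- generate_trajectory(sc)
    run$series <- distance_series(run$trajectory, run$topology)
    run$segmentation <- segment_regimes(run$series)
    assign(key, run, envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# Micro-system with two static receptors and a handful of lipids whose
# contact pattern with chosen residues is planted frame by frame. Returns the
# trajectory, topology, and the planted per-lipid contact series.
make_micro_system <- function(n_frames, contact_patterns, residue = 160L,
                              n_popc = 2L, n_chol = 2L, box = c(20, 20, 10),
                              seed = 7L) {
  tpl <- build_receptor_template(seed)
  top <- template_topology(tpl, n_popc, n_chol)
  txyz <- as.matrix(tpl$beads[, c("x", "y", "z")])
  z_mid <- box[3] / 2
  r1 <- txyz; r1[, 1] <- r1[, 1] + 5; r1[, 2] <- r1[, 2] + 10
  r2 <- txyz; r2[, 1] <- r2[, 1] + 15; r2[, 2] <- r2[, 2] + 10
  r1[, 3] <- r1[, 3] + z_mid; r2[, 3] <- r2[, 3] + z_mid
  res_row <- which(tpl$beads$residue_index == residue &
                     tpl$beads$bead_role == "backbone")[1]
  target <- r1[res_row, ]
  ctr <- c(5, 10)
  u <- (target[1:2] - ctr); u <- u / sqrt(sum(u^2))
  near <- c(target[1] + 0.3 * u[1], target[2] + 0.3 * u[2], target[3])
  far_spots <- cbind(seq(0.5, by = 0.7, length.out = n_popc + n_chol),
                     seq(0.5, by = 0.9, length.out = n_popc + n_chol))
  nrb <- nrow(txyz)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    coords <- matrix(0, 2 * nrb + 3 * n_popc + 2 * n_chol, 3)
    coords[1:nrb, ] <- r1
    coords[(nrb + 1):(2 * nrb), ] <- r2
    li <- 0L
    for (m in seq_len(n_popc)) {
      base <- 2 * nrb + (m - 1) * 3
      li <- li + 1L
      pos <- if (isTRUE(contact_patterns[[li]][f])) near else
        c(far_spots[li, ], z_mid + 1.9)
      coords[base + 1, ] <- c(pos[1], pos[2], z_mid + 1.9)
      coords[base + 2, ] <- c(pos[1] + 0.05, pos[2], z_mid + 1.1)
      coords[base + 3, ] <- pos
    }
    for (m in seq_len(n_chol)) {
      base <- 2 * nrb + 3 * n_popc + (m - 1) * 2
      li <- li + 1L
      pos <- if (isTRUE(contact_patterns[[li]][f])) near else
        c(far_spots[li, ], z_mid + 1.5)
      coords[base + 1, ] <- c(pos[1], pos[2], z_mid + 1.5)
      coords[base + 2, ] <- pos
    }
    frames[[f]] <- structure(list(time = f - 1, box = box, coords = coords),
                             class = "cg_frame")
  }
  list(trajectory = trajectory(frames, label = "micro"),
       topology = top, residue = residue, template = tpl)
}
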
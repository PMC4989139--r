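# Residue-wise lipid occupancy and bilayer-thickness mapping.

test_that("occupancy equals the brute-force longest-run oracle on planted series", {
  n <- 1000L
  set.seed(31)
  patterns <- list(
    runif(n) < 0.4,                           # POPC 1: noisy
    rep(FALSE, n),                            # POPC 2: never
    {v <- rep(FALSE, n); v[101:400] <- TRUE   # CHOL 1: one long run + noise
     v[runif(n) < 0.1] <- TRUE; v},
    rep(c(TRUE, FALSE), length.out = n))      # CHOL 2: alternating
  ms <- make_micro_system(n, patterns)
  frames <- seq_len(n)
  for (kind in c("POPC", "CHOL")) {
    prof <- residue_occupancy(ms$trajectory, ms$topology, frames, kind,
                              average_receptors = TRUE)
    idx <- if (kind == "POPC") 1:2 else 3:4
    oracle <- max(vapply(patterns[idx], brute_longest_run, 0L)) / n
    got <- prof$occupancy_r1[prof$residue_index == ms$residue]
    expect_equal(got, oracle, tolerance = 1e-12)
    # receptor 2 never sees a lipid
    expect_equal(prof$occupancy_r2[prof$residue_index == ms$residue], 0)
  }
})

test_that("occupancy limits are exact: resident always = 1, alternating = 1/n of regime", {
  n <- 200L
  patterns <- list(rep(FALSE, n), rep(FALSE, n),
                   rep(TRUE, n),                       # CHOL 1 always bound
                   c(TRUE, rep(FALSE, n - 1L)))        # CHOL 2: single frame
  ms <- make_micro_system(n, patterns)
  prof <- residue_occupancy(ms$trajectory, ms$topology, seq_len(n), "CHOL")
  expect_identical(prof$occupancy_r1[prof$residue_index == ms$residue], 1)
  popc <- residue_occupancy(ms$trajectory, ms$topology, seq_len(n), "POPC")
  expect_identical(popc$occupancy_r1[popc$residue_index == ms$residue], 0)
  # the single-frame visitor scores exactly one frame fraction
  patterns2 <- list(rep(FALSE, n), rep(FALSE, n),
                    rep(c(TRUE, FALSE), length.out = n), rep(FALSE, n))
  ms2 <- make_micro_system(n, patterns2)
  prof2 <- residue_occupancy(ms2$trajectory, ms2$topology, seq_len(n), "CHOL")
  expect_equal(prof2$occupancy_r1[prof2$residue_index == ms2$residue], 1 / n)
})

test_that("runs are counted on the concatenated regime frames", {
  n <- 100L
  v <- rep(FALSE, n); v[11:30] <- TRUE; v[41:60] <- TRUE
  patterns <- list(rep(FALSE, n), rep(FALSE, n), v, rep(FALSE, n))
  ms <- make_micro_system(n, patterns)
  # regime that excludes the gap frames 31:40 -> the two runs concatenate
  frames <- c(1:30, 41:100)
  prof <- residue_occupancy(ms$trajectory, ms$topology, frames, "CHOL")
  expect_equal(prof$occupancy_r1[prof$residue_index == ms$residue],
               40 / length(frames))
  # extending a contact run never decreases occupancy (monotonicity)
  v2 <- v; v2[61] <- TRUE
  ms2 <- make_micro_system(n, list(rep(FALSE, n), rep(FALSE, n), v2,
                                   rep(FALSE, n)))
  prof2 <- residue_occupancy(ms2$trajectory, ms2$topology, frames, "CHOL")
  expect_gte(prof2$occupancy_r1[prof2$residue_index == ms2$residue],
             prof$occupancy_r1[prof$residue_index == ms$residue])
})

test_that("planted hotspot occupancies are recovered within one frame fraction", {
  run <- ref_run(2)
  seg <- run$segmentation
  hs <- run$truth$hotspots
  for (reg in unique(hs$regime)) {
    frames <- regime_frames(seg, reg)
    prof <- residue_occupancy(run$trajectory, run$topology, frames, "CHOL",
                              regime = reg)
    for (i in which(hs$regime == reg & hs$receptor_id == 1L)) {
      got <- prof$occupancy[prof$residue_index == hs$residue_index[i]]
      expect_equal(got, hs$target_occupancy[i],
                   tolerance = 1.5 / length(frames) + 1e-9)
    }
  }
})

test_that("a flat synthetic bilayer yields a uniform unit thickness map", {
  sc <- planted_scenario(n_frames = 250L, n_lipids = 160L, seed = 17L,
                         phosphate_z_noise = 0)
  run <- generate_trajectory(sc)
  cfg <- analysis_config(grid_bin = 0.4)
  tm <- thickness_map(run$trajectory, run$topology, seq_len(250L), cfg)
  vals <- tm$grid[!is.na(tm$grid)]
  expect_gt(length(vals), 100)
  expect_true(all(abs(vals - 1) < 1e-9))
  # far-field mean is exactly 1 after normalization
  ff <- tm$grid[tm$farfield_cells]
  expect_equal(mean(ff, na.rm = TRUE), 1, tolerance = 1e-6)
})

test_that("a planted thickening sector is recovered at its multiplier", {
  run <- ref_run(2)    # receptor 1, helix I: multiplier 1.10
  seg <- run$segmentation
  cfg <- analysis_config()
  tm <- thickness_map(run$trajectory, run$topology,
                      regime_frames(seg, "monomer"), cfg, receptor = 1L)
  cx <- tm$x
  sector <- outer(cx, cx, function(x, y) {
    r <- sqrt(x^2 + y^2); a <- atan2(y, x) * 180 / pi
    r > 1.7 & r < 2.4 & abs(a) < 12
  })
  in_sector <- mean(tm$grid[sector], na.rm = TRUE)
  expect_equal(in_sector, 1.10, tolerance = 0.02)
  expect_equal(mean(tm$grid[tm$farfield_cells], na.rm = TRUE), 1,
               tolerance = 1e-6)
  # thinning sector of receptor 2 (helix IV at 0.94) is recovered too
  tm2 <- thickness_map(run$trajectory, run$topology,
                       regime_frames(seg, "monomer"), cfg, receptor = 2L)
  tpl_ang <- run$template$helix_angles[["IV"]]
  sector2 <- outer(cx, cx, function(x, y) {
    r <- sqrt(x^2 + y^2); a <- atan2(y, x) * 180 / pi
    r > 1.7 & r < 2.4 & ang_diff(a, tpl_ang) < 12
  })
  expect_equal(mean(tm2$grid[sector2], na.rm = TRUE), 0.94, tolerance = 0.02)
})

test_that("rescaling z changes raw thickness but not the normalized map", {
  sc <- planted_scenario(n_frames = 120L, n_lipids = 120L, seed = 19L,
                         phosphate_z_noise = 0,
                         thickness_field = data.frame(
                           receptor_id = 1L, helix_label = "I",
                           multiplier = 1.2))
  run <- generate_trajectory(sc)
  cfg <- analysis_config(grid_bin = 0.4)
  frames <- seq_len(120L)
  tm1 <- thickness_map(run$trajectory, run$topology, frames, cfg)
  run2 <- run
  for (f in frames) {
    run2$trajectory$frames[[f]]$coords[, 3] <-
      run2$trajectory$frames[[f]]$coords[, 3] * 2
    run2$trajectory$frames[[f]]$box[3] <- run$trajectory$frames[[f]]$box[3] * 2
  }
  tm2 <- thickness_map(run2$trajectory, run2$topology, frames, cfg)
  expect_equal(tm2$farfield_thickness, 2 * tm1$farfield_thickness,
               tolerance = 1e-9)
  expect_equal(tm2$grid, tm1$grid, tolerance = 1e-9)
})

test_that("leaflet assignment is stable across frames in synthetic data", {
  run <- ref_run(1)
  b <- run$topology$beads
  ph <- which(b$molecule_kind == "POPC" & b$bead_role == "phosphate")
  sides <- vapply(run$trajectory$frames[seq(1, 1500, by = 50)], function(fr) {
    z <- fr$coords[ph, 3]
    sign(z - stats::median(z))
  }, numeric(length(ph)))
  expect_true(all(apply(sides, 1, function(s) length(unique(s)) == 1)))
})
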
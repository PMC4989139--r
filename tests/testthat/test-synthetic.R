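# The synthetic generator: template construction, determinism, planted
# features, and unsatisfiable-scenario errors.

test_that("receptor template is deterministic and owns disjoint helix sectors", {
  t1 <- build_receptor_template(42L)
  t2 <- build_receptor_template(42L)
  expect_identical(t1, t2)
  t3 <- build_receptor_template(43L)
  expect_false(identical(t1$beads, t3$beads))

  b <- t1$beads
  tm <- b[b$helix_label != "loop", ]
  expect_true(all(table(tm$helix_label[tm$bead_role == "backbone"]) >= 3))
  # angular sectors pairwise disjoint
  ang <- atan2(tm$y, tm$x) * 180 / pi
  rng <- tapply(ang, tm$helix_label, function(a) {
    ctr <- atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180))) * 180 / pi
    max(ang_diff(a, ctr))
  })
  expect_true(all(rng < 180 / 7))
  # anchor residues present with backbone beads
  expect_equal(b$helix_label[b$residue_index == 48 & b$bead_role == "backbone"], "I")
  expect_equal(b$helix_label[b$residue_index == 164 & b$bead_role == "backbone"], "IV")
  expect_equal(b$helix_label[b$residue_index == 167 & b$bead_role == "backbone"], "IV")
  # template topology passes full validation
  expect_s3_class(template_topology(t1, 4L, 2L), "system_topology")
})

test_that("identical scenarios regenerate bit-identical trajectories", {
  sc <- planted_scenario(n_frames = 40L, n_lipids = 20L, seed = 11L,
                         cholesterol_fraction = 9,
                         grazing = data.frame(start_frame = 15L, n_frames = 2L,
                                              distance = 0.8))
  r1 <- generate_trajectory(sc)
  r2 <- generate_trajectory(sc)
  expect_identical(lapply(r1$trajectory$frames, `[[`, "coords"),
                   lapply(r2$trajectory$frames, `[[`, "coords"))
  expect_identical(r1$truth, r2$truth)
})

test_that("a scenario with no dimer intervals keeps receptors beyond 1 nm", {
  sc <- planted_scenario(n_frames = 300L, n_lipids = 20L, seed = 5L)
  run <- generate_trajectory(sc)
  ser <- distance_series(run$trajectory, run$topology)
  expect_gte(mean(ser$min_distance > 1.0), 0.99)
  expect_identical(run$truth$transient_count, 0L)
})

test_that("hotspot with target occupancy 1 keeps its lipid in contact every regime frame", {
  sc <- planted_scenario(
    n_frames = 60L, n_lipids = 24L, seed = 8L, cholesterol_fraction = 30,
    lipid_hotspots = data.frame(receptor_id = 1L, residue_index = 358L,
                                lipid_kind = "CHOL", regime = "monomer",
                                target_occupancy = 1.0))
  run <- generate_trajectory(sc)
  cfg <- analysis_config()
  b <- run$topology$beads
  res <- which(b$receptor_id == 1L & b$residue_index == 358L)
  chol_mols <- unique(b$molecule_id[b$molecule_kind == "CHOL"])
  in_contact <- vapply(run$trajectory$frames, function(fr) {
    any(vapply(chol_mols, function(m) {
      li <- which(b$molecule_id == m)
      pbc_min_dist(fr$coords[res, , drop = FALSE],
                   fr$coords[li, , drop = FALSE], fr$box) <
        cfg$lipid_contact_cutoff
    }, TRUE))
  }, TRUE)
  expect_true(all(in_contact))
})

test_that("geometrically unsatisfiable scenarios fail before any frame is made", {
  # cholesterol hotspot in a cholesterol-free membrane
  expect_error(planted_scenario(
    cholesterol_fraction = 0,
    lipid_hotspots = data.frame(receptor_id = 1L, residue_index = 358L,
                                lipid_kind = "CHOL", regime = "monomer",
                                target_occupancy = 0.5)),
    "unsatisfiable")
  # planted angles incompatible with the planted interface helices
  sc <- planted_scenario(
    n_frames = 40L, n_lipids = 10L, seed = 3L,
    dimer_intervals = data.frame(start_frame = 10L, end_frame = 40L,
                                 helix_a = "I", helix_b = "I",
                                 theta1 = 90, theta2 = -90, stable = TRUE))
  expect_error(generate_trajectory(sc), "unsatisfiable")
  # overlapping planted intervals are rejected at construction
  expect_error(planted_scenario(
    dimer_intervals = rbind(
      data.frame(start_frame = 10L, end_frame = 60L, helix_a = "I",
                 helix_b = "I", theta1 = 0, theta2 = 0, stable = FALSE),
      data.frame(start_frame = 50L, end_frame = 90L, helix_a = "I",
                 helix_b = "I", theta1 = 0, theta2 = 0, stable = FALSE))),
    "non-overlapping")
  # stable interval not reaching the end
  expect_error(planted_scenario(
    n_frames = 100L,
    dimer_intervals = data.frame(start_frame = 10L, end_frame = 60L,
                                 helix_a = "I", helix_b = "I",
                                 theta1 = 0, theta2 = 0, stable = TRUE)),
    "extend to n_frames")
})

test_that("packaged reference scenarios cover the four compositions deterministically", {
  scs <- reference_scenarios()
  expect_length(scs, 4)
  expect_equal(vapply(scs, function(s) s$cholesterol_fraction, 0),
               c(0, 9, 30, 50))
  expect_true(all(vapply(scs, function(s) s$n_frames, 0L) <= 5000L))
  # the 0% scenario contains no cholesterol molecules
  run0 <- ref_run(1)
  expect_equal(sum(run0$topology$beads$molecule_kind == "CHOL"), 0)
  nb <- nrow(run0$topology$beads)
  expect_lte(nb, 5000)
  expect_equal(nrow(run0$trajectory$frames[[1]]$coords), nb)
})

test_that("planted dimer placements put only the planted helices in contact", {
  run <- ref_run(1)
  cfg <- analysis_config()
  tr <- run$truth$intervals
  for (i in seq_len(nrow(tr))) {
    mid <- floor((tr$start_frame[i] + tr$end_frame[i]) / 2)
    ih <- interface_helices(run$trajectory$frames[[mid]], run$topology, cfg)
    expect_equal(nrow(ih$pairs), 1)
    expect_equal(ih$pairs$helix_a, tr$helix_a[i])
    expect_equal(ih$pairs$helix_b, tr$helix_b[i])
  }
})
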
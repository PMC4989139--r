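# Minimum-distance computation and regime segmentation.

make_two_bead_frame <- function(p1, p2, box = c(10, 10, 10)) {
  tpl <- build_receptor_template(1L)
  top <- template_topology(tpl, 0L, 0L)
  # collapse each receptor onto a single point: all beads at p1 resp. p2
  n <- nrow(tpl$beads)
  coords <- rbind(matrix(p1, n, 3, byrow = TRUE),
                  matrix(p2, n, 3, byrow = TRUE))
  list(frame = structure(list(time = 0, box = box, coords = coords),
                         class = "cg_frame"),
       topology = top)
}

test_that("min_distance handles direct and periodic-image separations", {
  s <- make_two_bead_frame(c(1, 1, 1), c(2, 1, 1))
  expect_equal(min_distance(s$frame, s$topology), 1.0, tolerance = 1e-12)
  s <- make_two_bead_frame(c(0.2, 1, 1), c(9.9, 1, 1))
  expect_equal(min_distance(s$frame, s$topology), 0.3, tolerance = 1e-12)
})

test_that("min_distance equals the exhaustive all-pairs oracle on random frames", {
  tpl <- build_receptor_template(2L)
  top <- template_topology(tpl, 0L, 0L)
  n <- nrow(tpl$beads)
  tm1 <- dimerlens:::tm_bead_indices(top, 1L)
  tm2 <- dimerlens:::tm_bead_indices(top, 2L)
  set.seed(99)
  box <- c(8, 9, 10)
  for (k in 1:100) {
    coords <- matrix(runif(2 * n * 3, -5, 15), 2 * n, 3)
    fr <- structure(list(time = 0, box = box, coords = coords),
                    class = "cg_frame")
    expect_equal(min_distance(fr, top),
                 brute_min_dist(coords[tm1, ], coords[tm2, ], box),
                 tolerance = 1e-9)
  }
})

test_that("min_distance is invariant under whole-box translations", {
  run <- ref_run(1)
  fr <- run$trajectory$frames[[50]]
  d0 <- min_distance(fr, run$topology)
  for (shift in list(c(1, 0, 0), c(0, -2, 0), c(3, 1, -1))) {
    fr2 <- fr
    fr2$coords <- sweep(fr$coords, 2, shift * fr$box, "+")
    expect_equal(min_distance(fr2, run$topology), d0, tolerance = 1e-9)
  }
})

test_that("loop beads are excluded from the transmembrane minimum distance", {
  tpl <- build_receptor_template(1L)
  top <- template_topology(tpl, 0L, 0L)
  n <- nrow(tpl$beads)
  coords <- matrix(5, 2 * n, 3)
  coords[seq_len(n), 1] <- 2
  coords[n + seq_len(n), 1] <- 6
  # move the two loop beads of receptor 1 right next to receptor 2
  loops <- which(tpl$beads$helix_label == "loop")
  coords[loops, 1] <- 5.9
  fr <- structure(list(time = 0, box = c(20, 20, 20), coords = coords),
                  class = "cg_frame")
  expect_equal(min_distance(fr, top), 4.0, tolerance = 1e-12)
})

test_that("segmentation implements opening, closing and dwell rules", {
  cfg <- analysis_config()
  mk <- function(d) structure(list(times = (seq_along(d) - 1) * 15,
                                   min_distance = d), class = "distance_series")
  # constant monomer
  seg <- segment_regimes(mk(rep(2, 100)), cfg)
  expect_equal(nrow(seg$intervals), 1)
  expect_equal(seg$intervals$label, "monomer")
  expect_equal(nrow(seg$dimer_events), 0)
  # long closed contact -> one transient event with exact bounds
  d <- rep(2, 600); d[10:500] <- 0.4
  seg <- segment_regimes(mk(d), cfg)
  expect_equal(seg$dimer_events$class, "transient")
  expect_equal(seg$dimer_events$start, 10)
  expect_equal(seg$dimer_events$end, 500)
  # contact shorter than min_dimer_frames never opens
  d <- rep(2, 100); d[20:22] <- 0.4
  seg <- segment_regimes(mk(d), cfg)
  expect_equal(nrow(seg$dimer_events), 0)
  # closed contact below the transient dwell time is folded into monomer
  d <- rep(2, 100); d[20:25] <- 0.4   # 6 frames x 15 ns = 75 ns < 100 ns
  seg <- segment_regimes(mk(d), cfg)
  expect_equal(nrow(seg$dimer_events), 0)
  expect_equal(unique(seg$intervals$label), "monomer")
  # distances in (0.5, 1.5] continue the dimer regime (hysteresis)
  d <- rep(2, 300); d[10:200] <- 0.4; d[50:60] <- 1.2
  seg <- segment_regimes(mk(d), cfg)
  expect_equal(seg$dimer_events$start, 10)
  expect_equal(seg$dimer_events$end, 200)
  # reaching the last frame without closure -> stable
  d <- rep(2, 100); d[40:100] <- 0.4
  seg <- segment_regimes(mk(d), cfg)
  expect_equal(seg$dimer_events$class, "stable")
  expect_equal(seg$dimer_events$end, 100)
})

test_that("segmentation is idempotent and respects hysteresis ordering", {
  run <- ref_run(2)
  seg1 <- segment_regimes(run$series)
  seg2 <- segment_regimes(run$series)
  expect_identical(seg1$intervals, seg2$intervals)
  d <- run$series$min_distance
  cfg <- analysis_config()
  ev <- seg1$dimer_events
  for (i in seq_len(nrow(ev))) {
    expect_lt(d[ev$start[i]], cfg$dimer_cutoff)
    if (ev$class[i] == "transient") {
      expect_gt(d[ev$end[i] + 1], cfg$dissociation_threshold)
      expect_true(all(d[ev$start[i]:ev$end[i]] <= cfg$dissociation_threshold))
    }
  }
  # intervals partition the trajectory with alternating labels
  iv <- seg1$intervals
  expect_equal(iv$start[1], 1)
  expect_equal(iv$end[nrow(iv)], seg1$n_frames)
  if (nrow(iv) > 1) {
    expect_true(all(iv$start[-1] == iv$end[-nrow(iv)] + 1))
    expect_true(all(iv$label[-1] != iv$label[-nrow(iv)]))
  }
})

test_that("dissociation events are summed per composition", {
  expect_equal(count_dissociations(list())$total, 0)
  segs <- lapply(c(2, 0, 1), function(k) {
    d <- rep(2, 800)
    if (k >= 1) d[10:100] <- 0.4
    if (k >= 2) d[300:400] <- 0.4
    segment_regimes(structure(list(times = (seq_along(d) - 1) * 15,
                                   min_distance = d),
                              class = "distance_series"))
  })
  out <- count_dissociations(segs, compositions = c(0, 0, 9))
  expect_equal(out$total, 3)
  expect_equal(unname(out$by_composition[["0"]]), 2L)
  expect_equal(unname(out$by_composition[["9"]]), 1L)
})

test_that("distance heat-map bins follow the published distance classes", {
  mk <- function(d, lab) structure(list(times = seq_along(d) - 1,
                                        min_distance = d, label = lab),
                                   class = "distance_series")
  hm <- distance_heatmap(list(mk(rep(0.3, 10), "a")))
  expect_true(all(hm == 1))
  ramp <- mk(seq(0, 6, length.out = 50), "ramp")
  hm <- distance_heatmap(list(ramp))
  expect_true(!is.unsorted(hm[1, ]))
  expect_equal(sort(unique(as.vector(hm))), 1:5)
  # conservation: every frame lands in exactly one class
  hm <- distance_heatmap(list(mk(rep(0.3, 10), "a"), ramp))
  expect_equal(rowSums(!is.na(hm)), c(a = 10, ramp = 50))
})
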
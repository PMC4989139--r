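# Rotational angles: dihedral convention, rotation response, invariances,
# density normalization and conformer assignment.

test_that("the four-point dihedral follows the right-handed convention", {
  # canonical staircase: +90 degrees
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               90, tolerance = 1e-9)
  # coplanar configurations give exactly 0 or 180
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               0, tolerance = 1e-9)
  expect_equal(abs(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                  c(2, 1, 0))), 180, tolerance = 1e-9)
  # collinear plane definition is degenerate
  expect_true(is.na(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                   c(3, 1, 0))))
})

test_that("rotating the partner bead about the 164-167 axis shifts theta by that angle", {
  p1 <- c(0.3, 0.1, 0.0); p2 <- c(1.0, 0.2, 0.1)
  p3 <- c(1.1, 0.3, 1.0); p4 <- c(2.0, 0.8, 0.4)
  th0 <- dihedral_angle(p1, p2, p3, p4)
  for (delta in c(-30, 30, -90, 90, 170)) {
    p4r <- rodrigues_rotate(p4, p2, p3 - p2, delta)
    th <- dihedral_angle(p1, p2, p3, p4r)
    expect_equal(ang_diff(th, th0 + delta), 0, tolerance = 1e-6)
  }
  # rotating the first bead shifts theta the opposite way
  p1r <- rodrigues_rotate(p1, p2, p3 - p2, 40)
  expect_equal(ang_diff(dihedral_angle(p1r, p2, p3, p4), th0 - 40), 0,
               tolerance = 1e-6)
})

test_that("rotation angles are invariant under rigid-body motion and swap on relabelling", {
  run <- ref_run(1)
  fr <- run$trajectory$frames[[1000]]   # stable dimer regime
  top <- run$topology
  th1 <- rotation_angle(fr, top, 1L)
  th2 <- rotation_angle(fr, top, 2L)
  # global rotation about z plus translation; the frame is unwrapped first so
  # the rigid motion acts on contiguous coordinates (box enlarged after)
  ref <- fr$coords[1, ]
  unw <- sweep(pbc_displacement(matrix(ref, nrow(fr$coords), 3, byrow = TRUE),
                                fr$coords, fr$box), 2, ref, "+")
  fr2 <- fr
  fr2$box <- c(40, 40, 40)
  fr2$coords <- sweep(rotate_z(unw, 37.3), 2, c(11, 3, 2), "+")
  expect_equal(rotation_angle(fr2, top, 1L), th1, tolerance = 1e-9)
  expect_equal(rotation_angle(fr2, top, 2L), th2, tolerance = 1e-9)
  # exchanging receptor labels swaps (theta1, theta2)
  top_sw <- top
  rid <- top_sw$beads$receptor_id
  top_sw$beads$receptor_id <- ifelse(is.na(rid), rid,
                                     ifelse(rid == 1L, 2L, 1L))
  expect_equal(rotation_angle(fr, top_sw, 1L), th2, tolerance = 1e-9)
  expect_equal(rotation_angle(fr, top_sw, 2L), th1, tolerance = 1e-9)
})

test_that("orientation density is a probability over angle bins", {
  cfg <- analysis_config()
  one <- structure(data.frame(frame = 1L, time = 0, theta1 = 0.2,
                              theta2 = -0.3),
                   class = c("orientation_series", "data.frame"))
  dens <- orientation_density(one, cfg)
  expect_equal(sum(dens), 1, tolerance = 1e-12)
  expect_equal(sum(dens > 0), 1)
  # bin conservation for arbitrary samples and bin widths
  set.seed(4)
  s <- structure(data.frame(frame = 1:500, time = 1:500,
                            theta1 = runif(500, -180, 180),
                            theta2 = runif(500, -180, 180)),
                 class = c("orientation_series", "data.frame"))
  for (w in c(5, 10, 30)) {
    d <- orientation_density(s, analysis_config(angle_bin_width = w))
    expect_equal(sum(d), 1, tolerance = 1e-12)
  }
  # empty input warns and returns an all-zero density
  empty <- structure(data.frame(frame = integer(0), time = numeric(0),
                                theta1 = numeric(0), theta2 = numeric(0)),
                     class = c("orientation_series", "data.frame"))
  expect_warning(d0 <- orientation_density(empty, cfg), "empty")
  expect_equal(sum(d0), 0)
})

test_that("unequal composition groups are subsampled to the smallest count", {
  mk <- function(t1) structure(
    data.frame(frame = 1:10, time = 1:10, theta1 = t1, theta2 = t1),
    class = c("orientation_series", "data.frame"))
  series <- list(mk(5), mk(5), mk(5), mk(-175))
  groups <- c("a", "a", "a", "b")
  d <- orientation_density(series, analysis_config(seed = 1L), groups = groups)
  # one series per group: equal mass in the two occupied bins
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(max(d), 0.5, tolerance = 1e-12)
  # seeded: reproducible subsample
  d2 <- orientation_density(series, analysis_config(seed = 1L), groups = groups)
  expect_identical(d, d2)
})

test_that("conformer assignment uses the calibrated regions", {
  expect_equal(assign_conformer(0, 0), "A")
  expect_equal(assign_conformer(155, 155), "B")
  expect_equal(assign_conformer(-95, -95), "B")
  expect_equal(assign_conformer(155, -5), "C")
  expect_equal(assign_conformer(-5, 45), "Ap")
  expect_equal(assign_conformer(179, 0), "C")
  expect_equal(assign_conformer(-179, 179), "unassigned")
  expect_true(is.na(assign_conformer(NA, 0)))
  # overlapping regions are a configuration error
  bad <- data.frame(label = c("A", "B"), xmin = c(-10, -5), xmax = c(10, 5),
                    ymin = c(-10, -5), ymax = c(10, 5))
  expect_error(assign_conformer(0, 0, bad), "overlapping")
})

test_that("planted constant orientations put the modal bin at the planted angles", {
  run <- ref_run(1)
  seg <- run$segmentation
  os <- orientation_series(run$trajectory, run$topology, seg)
  dens <- orientation_density(os, analysis_config())
  tr <- run$truth$intervals
  stable <- tr[tr$stable, ]
  # stable interval dominates the density: modal bin contains its angles
  peak <- which(dens == max(dens), arr.ind = TRUE)
  brk <- attr(dens, "breaks")
  expect_true(brk[peak[1]] <= stable$theta1 && stable$theta1 < brk[peak[1] + 1])
  expect_true(brk[peak[2]] <= stable$theta2 && stable$theta2 < brk[peak[2] + 1])
  # per-frame angles match the planted values to solver precision
  sfr <- os[os$frame >= stable$start_frame, ]
  expect_lt(max(ang_diff(sfr$theta1, stable$theta1)), 0.6)
  expect_lt(max(ang_diff(sfr$theta2, stable$theta2)), 0.6)
})
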
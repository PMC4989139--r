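# Synthetic coarse-grain trajectory generator. Kinematic by design: receptors
# are rigid bead assemblies random-walking in the membrane plane; dimer
# intervals, grazing approaches, lipid hot-spots and bilayer deformations are
# *placed* so that every downstream analysis has exact ground truth.

# --- rigid-body helpers -----------------------------------------------------

template_xyz <- function(tpl) as.matrix(tpl$beads[, c("x", "y", "z")])

receptor_coords <- function(tpl_xyz, center_xy, psi, z_mid) {
  X <- rotate_z(tpl_xyz, psi)
  X[, 1] <- X[, 1] + center_xy[1]
  X[, 2] <- X[, 2] + center_xy[2]
  X[, 3] <- X[, 3] + z_mid
  X
}

# Min distance between bead subsets of two placed receptors (no PBC: the
# solver works in an unwrapped local frame).
placed_min_dist <- function(tpl_xyz, sel1, sel2, psi1, psi2, d) {
  A <- rotate_z(tpl_xyz, psi1)[sel1, , drop = FALSE]
  B <- rotate_z(tpl_xyz, psi2)[sel2, , drop = FALSE]
  B[, 1] <- B[, 1] + d
  min(sqrt(outer(A[, 1], B[, 1], "-")^2 +
             outer(A[, 2], B[, 2], "-")^2 +
             outer(A[, 3], B[, 3], "-")^2))
}

# Outer (largest) separation at which the chosen bead subsets meet `target`.
solve_separation <- function(tpl_xyz, sel1, sel2, psi1, psi2, target,
                             d_max = 9) {
  g <- function(d) placed_min_dist(tpl_xyz, sel1, sel2, psi1, psi2, d) - target
  grid <- seq(2.0, d_max, by = 0.05)
  vals <- vapply(grid, g, 0)
  neg <- which(vals < 0)
  if (!length(neg) || max(neg) == length(grid))
    stop("generation error: cannot realize contact distance ", target, " nm")
  lo <- grid[max(neg)]
  hi <- grid[max(neg) + 1L]
  while (g(hi) <= 0) hi <- hi + 0.05
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

# Dihedral-defining bead rows in the template (backbone beads).
theta_bead_rows <- function(tpl) {
  b <- tpl$beads
  bb <- function(res) which(b$residue_index == res & b$bead_role == "backbone")[1]
  c(r48 = bb(48L), r164 = bb(164L), r167 = bb(167L))
}

placed_thetas <- function(tpl_xyz, rows, psi1, psi2, d) {
  A <- rotate_z(tpl_xyz, psi1)
  B <- rotate_z(tpl_xyz, psi2)
  B[, 1] <- B[, 1] + d
  t1 <- dihedral_angle(A[rows["r48"], ], A[rows["r164"], ],
                       A[rows["r167"], ], B[rows["r167"], ])
  t2 <- dihedral_angle(B[rows["r48"], ], B[rows["r164"], ],
                       B[rows["r167"], ], A[rows["r167"], ])
  c(t1, t2)
}

#' Solve a dimer placement realizing a planted interface and orientation
#'
#' Finds in-plane receptor rotations and a center separation such that (i) the
#' requested helix pair is in contact at \code{contact_target} nm and is the
#' only helix pair within the contact cut-off, and (ii) the rotational angles
#' theta1/theta2 equal the requested values. Receptor rotations are
#' constrained to +/- 18 degrees about the face-to-face geometry so the
#' planted helices stay at the interface; angle requests incompatible with the
#' requested interface raise a generation error.
#'
#' @param template a \code{receptor_template}.
#' @param helix_a,helix_b planted interface pair (receptor 1, receptor 2).
#' @param theta1,theta2 planted rotational angles (degrees); NA leaves the
#'   angle at the natural face-to-face value of the template geometry (the
#'   achieved value is always returned and recorded in the ground truth).
#' @param config an \code{analysis_config} (contact cut-off used to verify
#'   interface uniqueness).
#' @param contact_target planted minimum bead distance (nm) of the interface.
#' @return list(psi1, psi2, d, theta1, theta2): rotations relative to a +x
#'   bearing, separation, and the achieved angles.
#' @export
solve_dimer_placement <- function(template, helix_a, helix_b, theta1, theta2,
                                  config = analysis_config(),
                                  contact_target = 0.42) {
  tpl_xyz <- template_xyz(template)
  b <- template$beads
  rows <- theta_bead_rows(template)
  phi <- template$helix_angles
  sel_a <- which(b$helix_label == helix_a)
  sel_b <- which(b$helix_label == helix_b)
  base1 <- -phi[[helix_a]]
  base2 <- 180 - phi[[helix_b]]
  tm <- which(b$helix_label %in% HELIX_LABELS)
  planted_mask <- outer(tm %in% sel_a, tm %in% sel_b, "&")
  other_min <- function(psi1, psi2, d) {
    A <- rotate_z(tpl_xyz, psi1); B <- rotate_z(tpl_xyz, psi2)
    B[, 1] <- B[, 1] + d
    dm <- sqrt(outer(A[tm, 1], B[tm, 1], "-")^2 +
                 outer(A[tm, 2], B[tm, 2], "-")^2 +
                 outer(A[tm, 3], B[tm, 3], "-")^2)
    min(dm[!planted_mask])
  }
  want <- c(theta1, theta2)
  free <- is.na(want)                 # NA: use the natural facing angles
  fn <- function(dpsi) {
    pen <- sum(pmax(0, abs(dpsi) - 18)^2) * 10
    psi1 <- base1 + dpsi[1]; psi2 <- base2 + dpsi[2]
    d <- tryCatch(
      solve_separation(tpl_xyz, sel_a, sel_b, psi1, psi2, contact_target),
      error = function(e) NA_real_)
    if (is.na(d)) return(1e6 + sum(dpsi^2))   # contact unreachable here
    th <- placed_thetas(tpl_xyz, rows, psi1, psi2, d)
    # keep every other helix pair clear of the contact cut-off
    pen <- pen + 500 * max(0, config$contact_cutoff + 0.05 -
                             other_min(psi1, psi2, d))^2
    sum(circ_diff(th[!free], want[!free])^2) + 0.001 * sum(dpsi[free]^2) + pen
  }
  best <- NULL
  for (st in list(c(0, 0), c(8, -8), c(-8, 8))) {
    o <- stats::optim(st, fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 400))
    if (is.null(best) || o$value < best$value) best <- o
  }
  dpsi <- best$par
  psi1 <- base1 + dpsi[1]; psi2 <- base2 + dpsi[2]
  d <- solve_separation(tpl_xyz, sel_a, sel_b, psi1, psi2, contact_target)
  th <- placed_thetas(tpl_xyz, rows, psi1, psi2, d)
  if (any(circ_diff(th[!free], want[!free]) > 0.5))
    stop("generation error: planted angles (", theta1, ", ", theta2,
         ") are unsatisfiable for interface (", helix_a, ", ", helix_b, ")")
  # interface uniqueness: no other helix pair within the contact cut-off
  tm <- which(b$helix_label %in% HELIX_LABELS)
  A <- rotate_z(tpl_xyz, psi1); B <- rotate_z(tpl_xyz, psi2); B[, 1] <- B[, 1] + d
  dm <- sqrt(outer(A[tm, 1], B[tm, 1], "-")^2 +
               outer(A[tm, 2], B[tm, 2], "-")^2 +
               outer(A[tm, 3], B[tm, 3], "-")^2)
  lab <- b$helix_label[tm]
  close_pairs <- unique(data.frame(
    a = lab[row(dm)[dm < config$contact_cutoff]],
    b = lab[col(dm)[dm < config$contact_cutoff]]))
  if (nrow(close_pairs) != 1 ||
      close_pairs$a[1] != helix_a || close_pairs$b[1] != helix_b)
    stop("generation error: placement for (", helix_a, ", ", helix_b,
         ") brings additional helix pairs into contact")
  list(psi1 = unname(psi1), psi2 = unname(psi2), d = d,
       theta1 = th[1], theta2 = th[2])
}

# --- motion planning --------------------------------------------------------

plan_receptor_motion <- function(template, sc, config) {
  n <- sc$n_frames
  tpl_xyz <- template_xyz(template)
  b <- template$beads
  tm_sel <- which(b$helix_label %in% HELIX_LABELS)
  box <- sc$box
  z_mid <- box[3] / 2
  step <- sqrt(2 * sc$diffusion_coefficient * sc$dt)
  minsep <- max(2 * template$max_radius + 1.25, 6.05)

  di <- sc$dimer_intervals
  n_di <- if (is.null(di)) 0L else nrow(di)
  placements <- vector("list", n_di)
  for (i in seq_len(n_di)) {
    placements[[i]] <- solve_dimer_placement(
      template, di$helix_a[i], di$helix_b[i], di$theta1[i], di$theta2[i],
      config)
  }
  folded_pl <- NULL
  if (!is.null(sc$folded_contacts) && nrow(sc$folded_contacts)) {
    sel2 <- which(b$helix_label == "II")
    psi <- c(-template$helix_angles[["II"]], 180 - template$helix_angles[["II"]])
    folded_pl <- list(psi1 = psi[1], psi2 = psi[2],
                      d = solve_separation(tpl_xyz, sel2, sel2, psi[1], psi[2],
                                           0.45))
  }

  frame_kind <- rep("monomer", n)      # monomer / dimer / folded / graze
  frame_event <- rep(NA_integer_, n)
  exit_target <- rep(NA_real_, n)      # forced separation on regime exits
  for (i in seq_len(n_di)) {
    fr <- di$start_frame[i]:di$end_frame[i]
    frame_kind[fr] <- "dimer"; frame_event[fr] <- i
    if (!di$stable[i] && di$end_frame[i] < n)
      exit_target[di$end_frame[i] + 1L] <- 1.8
  }
  fc <- sc$folded_contacts
  if (!is.null(fc)) for (i in seq_len(nrow(fc))) {
    fr <- fc$start_frame[i]:(fc$start_frame[i] + fc$n_frames[i] - 1L)
    frame_kind[fr] <- "folded"; frame_event[fr] <- i
    if (max(fr) < n) exit_target[max(fr) + 1L] <- 1.8
  }
  gz <- sc$grazing
  if (!is.null(gz)) for (i in seq_len(nrow(gz))) {
    fr <- gz$start_frame[i]:(gz$start_frame[i] + gz$n_frames[i] - 1L)
    frame_kind[fr] <- "graze"; frame_event[fr] <- i
    if (max(fr) < n) exit_target[max(fr) + 1L] <- 1.3
  }

  c1 <- matrix(0, n, 2); c2 <- matrix(0, n, 2)
  psi1 <- numeric(n); psi2 <- numeric(n)
  # initial placement: receptors 6.4 nm apart (surface separation ~3 nm)
  cur1 <- c(box[1] / 2 - 3.2, box[2] / 2)
  cur2 <- c(box[1] / 2 + 3.2, box[2] / 2)
  p1 <- stats::runif(1, -180, 180); p2 <- stats::runif(1, -180, 180)
  M <- NULL; gamma <- NULL; graze_d <- NULL

  sep2d <- function(a, b) {
    d <- b - a
    d <- d - box[1:2] * round(d / box[1:2])
    d
  }

  for (f in seq_len(n)) {
    kind <- frame_kind[f]
    new_regime <- f == 1L || frame_kind[f - 1L] != kind ||
      !identical(frame_event[f - 1L], frame_event[f])
    if (kind %in% c("dimer", "folded")) {
      pl <- if (kind == "dimer") placements[[frame_event[f]]] else folded_pl
      if (new_regime) {
        u <- sep2d(cur1, cur2)
        gamma <- atan2(u[2], u[1]) * 180 / pi
        M <- cur1 + u / 2
      } else {
        M <- M + stats::rnorm(2, 0, step)
        gamma <- gamma + stats::rnorm(1, 0, 2)
      }
      uvec <- c(cos(gamma * pi / 180), sin(gamma * pi / 180))
      cur1 <- M - uvec * pl$d / 2
      cur2 <- M + uvec * pl$d / 2
      p1 <- gamma + pl$psi1
      p2 <- gamma + pl$psi2
    } else if (kind == "graze") {
      p1 <- p1 + stats::rnorm(1, 0, 2)
      p2 <- p2 + stats::rnorm(1, 0, 2)
      u <- sep2d(cur1, cur2); u <- u / sqrt(sum(u^2))
      beta <- atan2(u[2], u[1]) * 180 / pi
      # solve in the bearing frame (separation along +x)
      graze_d <- solve_separation(tpl_xyz, tm_sel, tm_sel,
                                  p1 - beta, p2 - beta,
                                  gz$distance[frame_event[f]])
      cur2 <- cur1 + u * graze_d
    } else {
      p1 <- p1 + stats::rnorm(1, 0, 6)
      p2 <- p2 + stats::rnorm(1, 0, 6)
      if (!is.na(exit_target[f])) {
        u <- sep2d(cur1, cur2); u <- u / sqrt(sum(u^2))
        beta <- atan2(u[2], u[1]) * 180 / pi
        dex <- solve_separation(tpl_xyz, tm_sel, tm_sel,
                                p1 - beta, p2 - beta, exit_target[f])
        cur2 <- cur1 + u * dex
      } else {
        ok <- FALSE
        for (try in 1:20) {
          prop1 <- cur1 + stats::rnorm(2, 0, step)
          prop2 <- cur2 + stats::rnorm(2, 0, step)
          if (sqrt(sum(sep2d(prop1, prop2)^2)) >= minsep) { ok <- TRUE; break }
        }
        if (!ok) {
          u <- sep2d(prop1, prop2); u <- u / sqrt(sum(u^2))
          prop2 <- prop1 + u * minsep
        }
        cur1 <- prop1; cur2 <- prop2
      }
    }
    cur1 <- cur1 %% box[1:2]
    cur2 <- cur2 %% box[1:2]
    c1[f, ] <- cur1; c2[f, ] <- cur2
    psi1[f] <- p1; psi2[f] <- p2
  }
  list(c1 = c1, c2 = c2, psi1 = psi1, psi2 = psi2,
       frame_kind = frame_kind, frame_event = frame_event,
       placements = placements, z_mid = z_mid, minsep = minsep)
}

# --- bilayer thickness field ------------------------------------------------

# Local thickness multiplier at xy points (matrix n x 2) for one frame.
# Deviations from the two receptors add; each receptor perturbs an annular
# neighbourhood (<= 2.5 nm full strength, linear taper to 3.0 nm, exactly 1
# beyond), sectored by helix in the receptor body frame.
field_multiplier <- function(points, centers, psis, sector_mult, box,
                             helix_angles) {
  m <- rep(1, nrow(points))
  for (r in 1:2) {
    sm <- sector_mult[[r]]
    if (all(sm == 1)) next
    d <- points
    d[, 1] <- d[, 1] - centers[[r]][1]
    d[, 2] <- d[, 2] - centers[[r]][2]
    d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
    d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
    rho <- sqrt(d[, 1]^2 + d[, 2]^2)
    near <- which(rho < 3.0)
    if (!length(near)) next
    ang <- atan2(d[near, 2], d[near, 1]) * 180 / pi - psis[r]
    sector <- vapply(ang, function(a) which.min(circ_diff(a, helix_angles)), 0L)
    taper <- pmin(1, pmax(0, (3.0 - rho[near]) / 0.5))
    m[near] <- m[near] + (sm[sector] - 1) * taper
  }
  m
}

# --- the generator ----------------------------------------------------------

#' Generate a synthetic coarse-grain trajectory with known ground truth
#'
#' Produces a two-receptor bilayer trajectory realizing every planted feature
#' of the scenario: dimer intervals with the requested interface helices and
#' rotational angles, grazing approaches, short folded contacts, lipid
#' residence hot-spots with exact target occupancies, and a sectored
#' bilayer-thickness deformation field, flat in the far field. Identical
#' scenarios (same seed) regenerate bit-identical trajectories.
#'
#' @param scenario a \code{planted_scenario}.
#' @param config an \code{analysis_config}; its cut-offs define the planted
#'   contact geometry.
#' @return object of class \code{synthetic_run}: list(trajectory, topology,
#'   truth, scenario). \code{truth} records the planted intervals (with
#'   achieved angles), transient count, hot-spot run lengths and the
#'   thickness field.
#' @export
generate_trajectory <- function(scenario, config = analysis_config()) {
  validate_scenario(scenario)
  sc <- scenario
  with_seed(sc$seed, {
    tpl <- build_receptor_template(seed = sc$seed)
    tpl_xyz <- template_xyz(tpl)
    n_chol <- round(sc$cholesterol_fraction / 100 * sc$n_lipids)
    n_popc <- sc$n_lipids - n_chol
    top <- template_topology(tpl, n_popc, n_chol)
    n <- sc$n_frames
    box <- sc$box
    z_mid <- box[3] / 2

    plan <- plan_receptor_motion(tpl, sc, config)

    # ---- ground-truth frame sets
    di <- sc$dimer_intervals
    dimer_frames <- integer(0)
    if (!is.null(di) && nrow(di))
      dimer_frames <- sort(unique(unlist(lapply(seq_len(nrow(di)), function(i)
        di$start_frame[i]:di$end_frame[i]))))
    monomer_frames <- setdiff(seq_len(n), dimer_frames)

    # ---- receptor coordinates per frame
    nrb <- nrow(tpl_xyz)
    rec1 <- vector("list", n); rec2 <- vector("list", n)
    for (f in seq_len(n)) {
      rec1[[f]] <- receptor_coords(tpl_xyz, plan$c1[f, ], plan$psi1[f], z_mid)
      rec2[[f]] <- receptor_coords(tpl_xyz, plan$c2[f, ], plan$psi2[f], z_mid)
    }

    # ---- lipid bookkeeping
    n_lip <- n_popc + n_chol
    kind <- c(rep("POPC", n_popc), rep("CHOL", n_chol))
    leaflet <- stats::ave(seq_len(n_lip), kind,
                          FUN = function(i) rep_len(c(1, -1), length(i)))
    hs <- sc$lipid_hotspots
    n_hs <- if (is.null(hs)) 0L else nrow(hs)
    hs_lipid <- integer(n_hs)
    hs_bead_rows <- vector("list", n_hs)   # template rows of the residue beads
    hs_contact <- vector("list", n_hs)     # frames with planted contact
    hs_regime_len <- integer(n_hs)
    hs_run_len <- integer(n_hs)
    used <- logical(n_lip)
    if (n_hs) {
      for (i in seq_len(n_hs)) {
        res_rows <- which(tpl$beads$residue_index == hs$residue_index[i])
        if (!length(res_rows))
          stop("generation error: hotspot residue ", hs$residue_index[i],
               " not in template")
        hs_bead_rows[[i]] <- res_rows
        want_leaf <- if (tpl_xyz[res_rows[1], 3] >= 0) 1 else -1
        cand <- which(kind == hs$lipid_kind[i] & !used & leaflet == want_leaf)
        if (!length(cand))
          stop("generation error: no free ", hs$lipid_kind[i],
               " lipid available for hotspot on residue ", hs$residue_index[i])
        hs_lipid[i] <- cand[1]; used[cand[1]] <- TRUE
        regime <- if (hs$regime[i] == "monomer") monomer_frames else dimer_frames
        if (!length(regime))
          stop("generation error: hotspot requests empty ", hs$regime[i],
               " regime")
        L <- length(regime)
        run <- round(hs$target_occupancy[i] * L)
        hs_regime_len[i] <- L; hs_run_len[i] <- run
        if (run > 0) {
          s <- floor((L - run) / 2) + 1L
          hs_contact[[i]] <- regime[s:(s + run - 1L)]
        } else hs_contact[[i]] <- integer(0)
      }
    }
    contact_now <- matrix(FALSE, n, max(n_hs, 1L))
    if (n_hs) for (i in seq_len(n_hs)) contact_now[hs_contact[[i]], i] <- TRUE

    # per-receptor sector multipliers for the thickness field
    sector_mult <- list(rep(1, 7), rep(1, 7))
    names(sector_mult[[1]]) <- names(sector_mult[[2]]) <- HELIX_LABELS
    tf <- sc$thickness_field
    if (!is.null(tf)) for (i in seq_len(nrow(tf)))
      sector_mult[[tf$receptor_id[i]]][tf$helix_label[i]] <- tf$multiplier[i]

    # ---- per-frame lipid placement
    t0 <- sc$bilayer_thickness
    znoise <- sc$phosphate_z_noise
    lstep <- sqrt(2 * sc$lipid_diffusion * sc$dt)
    lip_xy <- cbind(stats::runif(n_lip, 0, box[1]),
                    stats::runif(n_lip, 0, box[2]))
    popc_idx <- which(kind == "POPC")
    chol_idx <- which(kind == "CHOL")
    n_beads_total <- 2L * nrb + 3L * n_popc + 2L * n_chol
    frames <- vector("list", n)
    times <- (seq_len(n) - 1) * sc$dt

    for (f in seq_len(n)) {
      lip_xy <- lip_xy + matrix(stats::rnorm(2 * n_lip, 0, lstep), n_lip, 2)
      lip_xy[, 1] <- lip_xy[, 1] %% box[1]
      lip_xy[, 2] <- lip_xy[, 2] %% box[2]

      # keep all lipids not in planted contact away from hotspot residues
      if (n_hs) {
        hs_pts <- do.call(rbind, lapply(seq_len(n_hs), function(i) {
          rec <- if (hs$receptor_id[i] == 1) rec1[[f]] else rec2[[f]]
          rec[hs_bead_rows[[i]], 1:2, drop = FALSE]
        }))
        free <- which(!(seq_len(n_lip) %in% hs_lipid[contact_now[f, ]]))
        dmin <- rep(Inf, n_lip)
        dx <- outer(lip_xy[free, 1], hs_pts[, 1], "-")
        dx <- dx - box[1] * round(dx / box[1])
        dy <- outer(lip_xy[free, 2], hs_pts[, 2], "-")
        dy <- dy - box[2] * round(dy / box[2])
        dmin[free] <- sqrt(apply(dx^2 + dy^2, 1, min))
        viol <- free[dmin[free] < 1.0]
        for (v in viol) {
          placed <- FALSE
          for (try in 1:10) {
            cand <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]))
            dd <- hs_pts
            dd[, 1] <- dd[, 1] - cand[1]; dd[, 2] <- dd[, 2] - cand[2]
            dd[, 1] <- dd[, 1] - box[1] * round(dd[, 1] / box[1])
            dd[, 2] <- dd[, 2] - box[2] * round(dd[, 2] / box[2])
            if (min(sqrt(dd[, 1]^2 + dd[, 2]^2)) >= 1.0) {
              lip_xy[v, ] <- cand; placed <- TRUE; break
            }
          }
          if (!placed) lip_xy[v, ] <- (lip_xy[v, ] + box[1:2] / 2) %% box[1:2]
        }
      }

      centers <- list(plan$c1[f, ], plan$c2[f, ])
      psis <- c(plan$psi1[f], plan$psi2[f])
      tmult <- field_multiplier(lip_xy, centers, psis, sector_mult, box,
                                tpl$helix_angles)
      t_loc <- t0 * tmult

      coords <- matrix(0, n_beads_total, 3)
      coords[1:nrb, ] <- rec1[[f]]
      coords[(nrb + 1):(2 * nrb), ] <- rec2[[f]]

      if (n_popc) {
        zp <- z_mid + leaflet[popc_idx] * t_loc[popc_idx] / 2 +
          stats::rnorm(n_popc, 0, znoise)
        base <- 2L * nrb
        po_rows <- base + (seq_len(n_popc) - 1L) * 3L + 1L
        coords[po_rows, ] <- cbind(lip_xy[popc_idx, ], zp)
        coords[po_rows + 1L, ] <- cbind(lip_xy[popc_idx, 1] + 0.08,
                                        lip_xy[popc_idx, 2],
                                        zp - leaflet[popc_idx] * 0.8)
        coords[po_rows + 2L, ] <- cbind(lip_xy[popc_idx, 1],
                                        lip_xy[popc_idx, 2] + 0.08,
                                        zp - leaflet[popc_idx] * 1.5)
      }
      if (n_chol) {
        zc <- z_mid + leaflet[chol_idx] * (t_loc[chol_idx] / 2 - 0.4)
        base <- 2L * nrb + 3L * n_popc
        ro_rows <- base + (seq_len(n_chol) - 1L) * 2L + 1L
        coords[ro_rows, ] <- cbind(lip_xy[chol_idx, ], zc)
        coords[ro_rows + 1L, ] <- cbind(lip_xy[chol_idx, 1] + 0.06,
                                        lip_xy[chol_idx, 2],
                                        zc - leaflet[chol_idx] * 0.6)
      }

      # planted hotspot contacts override the free placement
      if (n_hs) for (i in which(contact_now[f, ])) {
        li <- hs_lipid[i]
        rec <- if (hs$receptor_id[i] == 1) rec1[[f]] else rec2[[f]]
        ctr <- centers[[hs$receptor_id[i]]]
        p <- rec[hs_bead_rows[[i]][1], ]
        u <- p[1:2] - ctr
        u <- u - box[1:2] * round(u / box[1:2])
        u <- u / sqrt(sum(u^2))
        cp <- c(p[1] + 0.35 * u[1], p[2] + 0.35 * u[2], p[3])
        leaf <- leaflet[li]
        lip_xy[li, ] <- cp[1:2] %% box[1:2]
        if (kind[li] == "CHOL") {
          ci <- match(li, chol_idx)
          base <- 2L * nrb + 3L * n_popc + (ci - 1L) * 2L
          coords[base + 2L, ] <- cp                      # ring bead in contact
          coords[base + 1L, ] <- cp + c(0, 0, leaf * 0.55)
        } else {
          pi_ <- match(li, popc_idx)
          base <- 2L * nrb + (pi_ - 1L) * 3L
          coords[base + 3L, ] <- cp                      # tail bead in contact
          coords[base + 2L, ] <- cp + c(0, 0, leaf * 0.75)
          coords[base + 1L, ] <- c(cp[1], cp[2],
                                   z_mid + leaf * t_loc[li] / 2)
        }
      }

      frames[[f]] <- structure(list(time = times[f], box = box,
                                    coords = wrap_coords(coords, box)),
                               class = "cg_frame")
    }

    traj <- trajectory(frames, label = sc$label,
                       composition = sc$cholesterol_fraction)

    truth_int <- NULL
    if (!is.null(di) && nrow(di)) {
      truth_int <- di
      truth_int$theta1_achieved <-
        vapply(plan$placements, function(p) p$theta1, 0)
      truth_int$theta2_achieved <-
        vapply(plan$placements, function(p) p$theta2, 0)
    }
    truth_hs <- NULL
    if (n_hs) {
      truth_hs <- hs
      truth_hs$run_length <- hs_run_len
      truth_hs$regime_length <- hs_regime_len
      truth_hs$planted_occupancy <- hs_run_len / hs_regime_len
    }
    truth <- list(label = sc$label, composition = sc$cholesterol_fraction,
                  seed = sc$seed, intervals = truth_int,
                  grazing = sc$grazing, folded_contacts = sc$folded_contacts,
                  dimer_frames = dimer_frames, monomer_frames = monomer_frames,
                  transient_count = if (is.null(di)) 0L else sum(!di$stable),
                  hotspots = truth_hs, thickness_field = sc$thickness_field)
    structure(list(trajectory = traj, topology = top, truth = truth,
                   scenario = sc, template = tpl),
              class = "synthetic_run")
  })
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat("Synthetic run '", x$truth$label, "'\n", sep = "")
  print(x$trajectory)
  invisible(x)
}
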
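# Planted scenarios: full ground-truth specification for the synthetic
# trajectory generator. The generator is kinematic (placement + random walk),
# not a physics engine: ground-truth control is the point.

#' Define a planted scenario
#'
#' @param n_frames number of stored frames.
#' @param dt ns between stored frames.
#' @param box numeric(3) box lengths (nm); bilayer normal along z.
#' @param cholesterol_fraction mole percent, one of 0, 9, 30, 50.
#' @param dimer_intervals data.frame(start_frame, end_frame, helix_a, helix_b,
#'   theta1, theta2, stable). Intervals are 1-based, inclusive, ordered and
#'   non-overlapping; a stable interval must be last and reach n_frames.
#'   (helix_a, helix_b) is the planted interface pair (receptor 1 helix,
#'   receptor 2 helix); theta1/theta2 the planted rotational angles (degrees).
#' @param grazing data.frame(start_frame, n_frames, distance): brief close
#'   approaches at sub-dimer separations (0.6-0.9 nm), shorter than the dimer
#'   dwell criterion, exercising segmentation hysteresis.
#' @param folded_contacts data.frame(start_frame, n_frames): genuine sub-cutoff
#'   contacts too short to count as transient dimers (folded into monomer).
#' @param lipid_hotspots data.frame(receptor_id, residue_index, lipid_kind,
#'   regime, target_occupancy): one dedicated lipid per hotspot is kept within
#'   the lipid contact cut-off of the residue for a planted run of regime
#'   frames whose normalized length equals the target.
#' @param thickness_field data.frame(receptor_id, helix_label, multiplier):
#'   relative bilayer-thickness multiplier in the angular sector of that helix
#'   (annulus around the receptor, tapering to 1 before the far field).
#' @param n_lipids total lipid molecules (POPC + CHOL, split per composition).
#' @param bilayer_thickness unperturbed phosphate-to-phosphate distance (nm).
#' @param phosphate_z_noise sd (nm) of phosphate z placement noise.
#' @param diffusion_coefficient receptor in-plane diffusion (nm^2/ns).
#' @param lipid_diffusion lipid in-plane diffusion (nm^2/ns).
#' @param seed integer; the only source of randomness.
#' @param label scenario name.
#' @return object of class \code{planted_scenario}.
#' @export
planted_scenario <- function(n_frames = 1500L,
                             dt = 15,
                             box = c(12, 12, 10),
                             cholesterol_fraction = 0,
                             dimer_intervals = NULL,
                             grazing = NULL,
                             folded_contacts = NULL,
                             lipid_hotspots = NULL,
                             thickness_field = NULL,
                             n_lipids = 220L,
                             bilayer_thickness = 3.8,
                             phosphate_z_noise = 0.01,
                             diffusion_coefficient = 0.001,
                             lipid_diffusion = 0.005,
                             seed = 1L,
                             label = "scenario") {
  sc <- structure(list(
    n_frames = as.integer(n_frames), dt = dt, box = box,
    cholesterol_fraction = cholesterol_fraction,
    dimer_intervals = dimer_intervals, grazing = grazing,
    folded_contacts = folded_contacts, lipid_hotspots = lipid_hotspots,
    thickness_field = thickness_field, n_lipids = as.integer(n_lipids),
    bilayer_thickness = bilayer_thickness,
    phosphate_z_noise = phosphate_z_noise,
    diffusion_coefficient = diffusion_coefficient,
    lipid_diffusion = lipid_diffusion,
    seed = as.integer(seed), label = label), class = "planted_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "planted_scenario"))
  if (!sc$cholesterol_fraction %in% c(0, 9, 30, 50))
    stop("cholesterol_fraction must be one of 0, 9, 30, 50")
  if (sc$n_frames < 10) stop("scenario too short")
  if (any(sc$box <= 0)) stop("box lengths must be positive")
  di <- sc$dimer_intervals
  occupied <- integer(0)
  if (!is.null(di) && nrow(di)) {
    if (any(di$end_frame < di$start_frame)) stop("dimer interval with end < start")
    if (is.unsorted(di$start_frame, strictly = TRUE))
      stop("dimer intervals must be ordered")
    for (i in seq_len(nrow(di))) {
      if (i > 1 && di$start_frame[i] <= di$end_frame[i - 1] + 1)
        stop("dimer intervals must be non-overlapping (with a gap for the exit frame)")
      occupied <- c(occupied, di$start_frame[i]:min(di$end_frame[i] + 1, sc$n_frames))
    }
    if (any(di$stable[-nrow(di)]))
      stop("a stable interval must be the last interval")
    if (di$stable[nrow(di)] && di$end_frame[nrow(di)] != sc$n_frames)
      stop("a stable interval must extend to n_frames")
    bad <- !(di$helix_a %in% HELIX_LABELS) | !(di$helix_b %in% HELIX_LABELS)
    if (any(bad)) stop("unknown interface helix label in dimer_intervals")
  }
  for (nm in c("grazing", "folded_contacts")) {
    ev <- sc[[nm]]
    if (!is.null(ev) && nrow(ev)) {
      fr <- unlist(lapply(seq_len(nrow(ev)), function(i)
        ev$start_frame[i]:(ev$start_frame[i] + ev$n_frames[i])))
      if (any(fr %in% occupied) || any(fr > sc$n_frames))
        stop(nm, " events must fall in monomer stretches within the trajectory")
      occupied <- c(occupied, fr)
    }
  }
  hs <- sc$lipid_hotspots
  if (!is.null(hs) && nrow(hs)) {
    if (any(hs$target_occupancy < 0 | hs$target_occupancy > 1))
      stop("hotspot target_occupancy must lie in [0, 1]")
    if (any(!hs$regime %in% c("monomer", "dimer")))
      stop("hotspot regime must be 'monomer' or 'dimer'")
    if (any(hs$lipid_kind == "CHOL") && sc$cholesterol_fraction == 0)
      stop("scenario unsatisfiable: CHOL hotspot in a cholesterol-free bilayer")
  }
  tf <- sc$thickness_field
  if (!is.null(tf) && nrow(tf)) {
    if (any(tf$multiplier <= 0)) stop("thickness multipliers must be positive")
    if (any(!tf$helix_label %in% HELIX_LABELS))
      stop("unknown helix label in thickness_field")
  }
  invisible(sc)
}

#' @export
print.planted_scenario <- function(x, ...) {
  cat(sprintf("Planted scenario '%s': %d frames x %.0f ns, %d%% cholesterol, seed %d\n",
              x$label, x$n_frames, x$dt, x$cholesterol_fraction, x$seed))
  ndi <- if (is.null(x$dimer_intervals)) 0 else nrow(x$dimer_intervals)
  cat("  dimer intervals:", ndi,
      " hotspots:", if (is.null(x$lipid_hotspots)) 0 else nrow(x$lipid_hotspots), "\n")
  invisible(x)
}

di_row <- function(start, end, ha, hb, t1, t2, stable) {
  data.frame(start_frame = start, end_frame = end, helix_a = ha, helix_b = hb,
             theta1 = t1, theta2 = t2, stable = stable)
}

#' Packaged reference scenarios
#'
#' Four deterministic scenarios, one per membrane composition (0, 9, 30 and
#' 50 mole percent cholesterol), mirroring the qualitative findings of the
#' study they emulate: the helix I-I interface dominates in pure POPC and is
#' progressively lost with cholesterol, transient (dissociating) dimers
#' become more frequent at high cholesterol, cholesterol hot-spots sit on
#' helices IV-VI, and the bilayer deforms around the receptor. Each scenario
#' regenerates bit-identically from its seed.
#'
#' @return list of four \code{planted_scenario} objects.
#' @export
reference_scenarios <- function() {
  list(
    planted_scenario(
      label = "popc_00", seed = 101L, cholesterol_fraction = 0,
      dimer_intervals = rbind(
        di_row(200L, 330L, "IV", "I", 155, -5, FALSE),
        di_row(900L, 1500L, "I", "I", -4, -4, TRUE)),
      grazing = data.frame(start_frame = c(60L, 450L, 700L),
                           n_frames = c(3L, 2L, 4L),
                           distance = c(0.75, 0.8, 0.65)),
      folded_contacts = data.frame(start_frame = 520L, n_frames = 6L),
      lipid_hotspots = data.frame(
        receptor_id = c(1L, 2L), residue_index = c(48L, 48L),
        lipid_kind = "POPC", regime = "monomer",
        target_occupancy = c(0.7, 0.7))),
    planted_scenario(
      label = "chol_09", seed = 102L, cholesterol_fraction = 9,
      dimer_intervals = rbind(
        di_row(150L, 250L, "I", "I", -4, -4, FALSE),
        di_row(400L, 500L, "I", "I", -4, -4, FALSE),
        di_row(650L, 750L, "I", "I", -4, -4, FALSE),
        di_row(870L, 970L, "IV", "V", -155, -105, FALSE),
        di_row(1100L, 1500L, "IV", "IV", 155, 155, TRUE)),
      grazing = data.frame(start_frame = c(50L, 1020L),
                           n_frames = c(3L, 3L),
                           distance = c(0.7, 0.85)),
      lipid_hotspots = data.frame(
        receptor_id = c(1L, 2L, 1L, 2L, 1L, 2L),
        residue_index = c(358L, 358L, 204L, 204L, 160L, 160L),
        lipid_kind = "CHOL",
        regime = c("monomer", "monomer", "monomer", "monomer",
                   "dimer", "dimer"),
        target_occupancy = c(0.85, 0.85, 0.6, 0.6, 0.9, 0.9)),
      thickness_field = data.frame(
        receptor_id = c(1L, 2L), helix_label = c("I", "IV"),
        multiplier = c(1.10, 0.94))),
    planted_scenario(
      label = "chol_30", seed = 103L, cholesterol_fraction = 30,
      dimer_intervals = rbind(
        di_row(100L, 190L, "I", "I", -4, -4, FALSE),
        di_row(330L, 420L, "I", "I", -4, -4, FALSE),
        di_row(560L, 660L, "I", "II", -5, 45, FALSE),
        di_row(1050L, 1500L, "V", "V", -95, -95, TRUE)),
      grazing = data.frame(start_frame = 800L, n_frames = 3L, distance = 0.7),
      lipid_hotspots = data.frame(
        receptor_id = c(1L, 2L, 1L, 2L, 1L, 2L),
        residue_index = c(358L, 358L, 204L, 204L, 204L, 204L),
        lipid_kind = c("CHOL", "CHOL", "POPC", "POPC", "CHOL", "CHOL"),
        regime = c("monomer", "monomer", "monomer", "monomer",
                   "dimer", "dimer"),
        target_occupancy = c(0.8, 0.8, 0.65, 0.65, 0.88, 0.88)),
      thickness_field = data.frame(
        receptor_id = 1L, helix_label = "VI", multiplier = 1.12)),
    planted_scenario(
      label = "chol_50", seed = 104L, cholesterol_fraction = 50,
      dimer_intervals = rbind(
        di_row(80L, 170L, "I", "I", -4, -4, FALSE),
        di_row(260L, 350L, "I", "I", -4, -4, FALSE),
        di_row(440L, 530L, "I", "I", -4, -4, FALSE),
        di_row(620L, 710L, "IV", "VI", -165, -65, FALSE),
        di_row(800L, 890L, "V", "V", -95, -95, FALSE),
        di_row(1000L, 1500L, "I", "II", -5, 45, TRUE)),
      grazing = data.frame(start_frame = c(30L, 940L),
                           n_frames = c(2L, 3L),
                           distance = c(0.75, 0.7)),
      lipid_hotspots = data.frame(
        receptor_id = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
        residue_index = c(358L, 358L, 204L, 204L, 48L, 48L, 44L, 44L),
        lipid_kind = "CHOL",
        regime = c("monomer", "monomer", "monomer", "monomer",
                   "monomer", "monomer", "dimer", "dimer"),
        target_occupancy = c(0.9, 0.9, 0.85, 0.85, 0.8, 0.8, 0.85, 0.85)),
      thickness_field = data.frame(
        receptor_id = 1L, helix_label = "I", multiplier = 1.15)))
}
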
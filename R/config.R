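#' Analysis configuration
#'
#' Bundles every tunable cut-off used across the pipeline. Defaults follow the
#' published analysis of cholesterol-dependent GPCR dimerization: the dimer
#' regime is entered below 0.5 nm minimum inter-receptor distance, the monomer
#' regime corresponds to separations beyond 1 nm, and a dissociation event is
#' a subsequent excursion past 1.5 nm. Residue contacts at the dimer interface
#' use the same 0.5 nm cut-off. The lipid contact cut-off (0.6 nm) and the
#' dwell-time thresholds are declared package defaults, configurable and
#' recorded in every output's metadata.
#'
#' @param dimer_cutoff nm; a dimer interval opens below this distance.
#' @param monomer_threshold nm; separations beyond this are unambiguous
#'   monomer territory.
#' @param dissociation_threshold nm; a dimer interval closes above this.
#' @param contact_cutoff nm; residue-residue contact distance at the interface.
#' @param lipid_contact_cutoff nm; lipid bead-to-residue contact distance for
#'   occupancy runs.
#' @param min_dimer_frames consecutive sub-cutoff frames required to open a
#'   dimer interval (separates dimers from grazing close approaches).
#' @param min_transient_duration ns; closed intervals shorter than this are
#'   folded back into the monomer regime.
#' @param angle_bin_width degrees; bin width of the orientation density.
#' @param grid_bin nm; cell size of the bilayer thickness map.
#' @param farfield_min_distance nm; distance from any receptor bead beyond
#'   which the bilayer is considered unperturbed (normalization region).
#' @param occupancy_threshold normalized occupancy below which a helix is
#'   dropped from the interface occupancy score.
#' @param interface_probability_threshold interface probability below which a
#'   helix is dropped from the interface occupancy score.
#' @param seed integer seed used for any stochastic step (subsampling).
#' @return an object of class \code{analysis_config} (a validated list).
#' @export
analysis_config <- function(dimer_cutoff = 0.5,
                            monomer_threshold = 1.0,
                            dissociation_threshold = 1.5,
                            contact_cutoff = 0.5,
                            lipid_contact_cutoff = 0.6,
                            min_dimer_frames = 5L,
                            min_transient_duration = 100,
                            angle_bin_width = 10,
                            grid_bin = 0.2,
                            farfield_min_distance = 3.0,
                            occupancy_threshold = 0.7,
                            interface_probability_threshold = 0.7,
                            seed = 1L) {
  cfg <- list(
    dimer_cutoff = dimer_cutoff,
    monomer_threshold = monomer_threshold,
    dissociation_threshold = dissociation_threshold,
    contact_cutoff = contact_cutoff,
    lipid_contact_cutoff = lipid_contact_cutoff,
    min_dimer_frames = as.integer(min_dimer_frames),
    min_transient_duration = min_transient_duration,
    angle_bin_width = angle_bin_width,
    grid_bin = grid_bin,
    farfield_min_distance = farfield_min_distance,
    occupancy_threshold = occupancy_threshold,
    interface_probability_threshold = interface_probability_threshold,
    seed = as.integer(seed)
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  num <- c("dimer_cutoff", "monomer_threshold", "dissociation_threshold",
           "contact_cutoff", "lipid_contact_cutoff", "min_transient_duration",
           "angle_bin_width", "grid_bin", "farfield_min_distance")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("analysis_config: '", f, "' must be a single positive number")
  }
  if (!(cfg$dimer_cutoff < cfg$monomer_threshold &&
        cfg$monomer_threshold < cfg$dissociation_threshold))
    stop("analysis_config: need dimer_cutoff < monomer_threshold < dissociation_threshold")
  for (f in c("occupancy_threshold", "interface_probability_threshold")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("analysis_config: '", f, "' must lie in [0, 1]")
  }
  if (cfg$min_dimer_frames < 1) stop("analysis_config: min_dimer_frames must be >= 1")
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration (nm / ns / degrees):\n")
  for (f in names(x)) cat(sprintf("  %-32s %s\n", f, format(x[[f]])))
  invisible(x)
}

# Merge user overrides (a named list) into a config, re-validating.
modify_config <- function(cfg, overrides) {
  if (is.null(overrides) || !length(overrides)) return(cfg)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown analysis_config field(s): ",
                            paste(unknown, collapse = ", "))
  for (f in names(overrides)) cfg[[f]] <- overrides[[f]]
  cfg$min_dimer_frames <- as.integer(cfg$min_dimer_frames)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  cfg
}
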
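# Interface occupancy score: couples per-helix lipid occupancy in the dimer
# regime to each helix's probability of occurring at the dimer interface.

#' Per-helix lipid occupancy
#'
#' Aggregates a residue-wise occupancy profile to helices by taking, per
#' helix, the maximum residue occupancy over the helix's residue range, then
#' normalizing by the highest helix value.
#'
#' @param profile an \code{occupancy_profile} (dimer regime for the interface
#'   score).
#' @param topology a \code{system_topology} (helix residue ranges).
#' @return named numeric vector (helices I..VII) of normalized occupancies,
#'   with the unnormalized values in attribute \code{raw}.
#' @export
helix_occupancy <- function(profile, topology) {
  hd <- topology$helix_definitions
  raw <- stats::setNames(numeric(7), HELIX_LABELS)
  for (h in HELIX_LABELS) {
    rng <- hd[hd$helix == h, ]
    in_h <- profile$residue_index >= rng$from & profile$residue_index <= rng$to
    if (!any(in_h))
      stop("helix_occupancy: helix ", h, " has no residues in the profile")
    raw[h] <- max(profile$occupancy[in_h])
  }
  norm <- if (max(raw) > 0) raw / max(raw) else raw
  attr(norm, "raw") <- raw
  norm
}

#' Per-helix interface probability from a contact map
#'
#' Marginalizes a (stable) helix contact map to a per-helix probability of
#' occurring at the dimer interface: unordered helix-pair populations are
#' summed over partners and rescaled to a maximum of 1.
#'
#' @param map a \code{helix_contact_map}.
#' @return named numeric vector (helices I..VII) in [0, 1].
#' @export
interface_probabilities <- function(map) {
  s <- map$raw + t(map$raw)
  diag(s) <- diag(map$raw)
  p <- rowSums(s)
  if (max(p) > 0) p <- p / max(p)
  stats::setNames(p, HELIX_LABELS)
}

#' Interface occupancy score matrix
#'
#' Entry (h_occ, h_int) is the product of the normalized lipid occupancy of
#' helix h_occ (dimer regime) and the probability that helix h_int occurs at
#' the dimer interface. To reduce noise, entries are zeroed unless the
#' occupancy reaches \code{occupancy_threshold} (0.7) and the interface
#' probability reaches \code{interface_probability_threshold} (0.7); both
#' filters are applied to the finished entries. Diagonal elements read as
#' lipid occupancy at interface helices, off-diagonal elements as occupancy
#' away from the interface.
#'
#' @param helix_occ normalized per-helix occupancy
#'   (\code{\link{helix_occupancy}}).
#' @param iface_prob per-helix interface probability
#'   (\code{\link{interface_probabilities}}).
#' @param config an \code{analysis_config} (the two thresholds).
#' @param lipid_kind,composition metadata stored on the result.
#' @return 7x7 matrix of class \code{interface_occupancy_matrix} (rows: helix
#'   with occupancy; columns: helix at the interface) with attributes
#'   recording thresholds and metadata.
#' @export
interface_occupancy_matrix <- function(helix_occ, iface_prob,
                                       config = analysis_config(),
                                       lipid_kind = "CHOL",
                                       composition = NA) {
  stopifnot(length(helix_occ) == 7, length(iface_prob) == 7)
  m <- outer(as.numeric(helix_occ), as.numeric(iface_prob))
  dimnames(m) <- list(HELIX_LABELS, HELIX_LABELS)
  m[as.numeric(helix_occ) < config$occupancy_threshold, ] <- 0
  m[, as.numeric(iface_prob) < config$interface_probability_threshold] <- 0
  structure(m, class = c("interface_occupancy_matrix", "matrix", "array"),
            occupancy_threshold = config$occupancy_threshold,
            interface_probability_threshold =
              config$interface_probability_threshold,
            lipid_kind = lipid_kind, composition = composition)
}

#' @export
print.interface_occupancy_matrix <- function(x, ...) {
  cat(sprintf("Interface occupancy score (%s, %s%% cholesterol):\n",
              attr(x, "lipid_kind"), format(attr(x, "composition"))))
  print(round(unclass(x), 3))
  invisible(x)
}
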
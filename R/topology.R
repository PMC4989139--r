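# System topology: the structural frame of reference for every analysis.
# Beads map to (molecule, kind, receptor, residue, role, helix); helix
# definitions give inclusive residue ranges for transmembrane helices I-VII.
# Receptor residues are numbered according to UniProt P08908.

HELIX_LABELS <- c("I", "II", "III", "IV", "V", "VI", "VII")
BEAD_ROLES <- c("backbone", "sidechain", "phosphate", "other")
MOLECULE_KINDS <- c("receptor", "POPC", "CHOL")

#' Construct a system topology
#'
#' @param beads data.frame with columns \code{bead_id}, \code{molecule_id},
#'   \code{molecule_kind} (receptor/POPC/CHOL), \code{receptor_id} (1, 2 or NA),
#'   \code{residue_index} (NA for lipids), \code{bead_role}
#'   (backbone/sidechain/phosphate/other) and \code{helix_label}
#'   (I..VII, "loop", or NA for lipids).
#' @param helix_definitions data.frame with columns \code{helix}, \code{from},
#'   \code{to}: inclusive residue ranges of the seven transmembrane helices.
#' @param validate run \code{\link{validate_topology}}.
#' @param require_dimer require exactly two receptors (see
#'   \code{\link{validate_topology}}).
#' @return object of class \code{system_topology}.
#' @export
system_topology <- function(beads, helix_definitions, validate = TRUE,
                            require_dimer = TRUE) {
  need <- c("bead_id", "molecule_id", "molecule_kind", "receptor_id",
            "residue_index", "bead_role", "helix_label")
  missing <- setdiff(need, names(beads))
  if (length(missing))
    stop("topology beads table lacks column(s): ", paste(missing, collapse = ", "))
  beads <- as.data.frame(beads)[, need]
  beads$bead_id <- as.integer(beads$bead_id)
  beads$molecule_id <- as.integer(beads$molecule_id)
  beads$receptor_id <- as.integer(beads$receptor_id)
  beads$residue_index <- as.integer(beads$residue_index)
  hd <- as.data.frame(helix_definitions)
  if (!all(c("helix", "from", "to") %in% names(hd)))
    stop("helix_definitions needs columns helix, from, to")
  top <- structure(list(beads = beads, helix_definitions = hd),
                   class = "system_topology")
  if (validate) validate_topology(top, require_dimer = require_dimer)
  top
}

#' Validate a system topology
#'
#' Checks the invariants every analysis relies on: exactly two receptors when
#' dimer analyses are requested; helix ranges non-overlapping and consistent
#' with bead labels (each receptor residue maps to at most one helix, others
#' are "loop"); residue 48 in helix I and residues 164 and 167 in helix IV
#' (the rotational-angle definition is ill-founded otherwise); every POPC
#' molecule carries exactly one phosphate bead.
#'
#' @param top a \code{system_topology}.
#' @param require_dimer logical; require receptor ids \{1, 2\}.
#' @return the topology, invisibly; errors name the offending record.
#' @export
validate_topology <- function(top, require_dimer = TRUE) {
  stopifnot(inherits(top, "system_topology"))
  b <- top$beads
  hd <- top$helix_definitions
  if (anyDuplicated(b$bead_id))
    stop("topology: duplicated bead_id ", b$bead_id[duplicated(b$bead_id)][1])
  bad_kind <- !b$molecule_kind %in% MOLECULE_KINDS
  if (any(bad_kind))
    stop("topology: unknown molecule_kind '", b$molecule_kind[bad_kind][1],
         "' at bead_id ", b$bead_id[bad_kind][1])
  bad_role <- !b$bead_role %in% BEAD_ROLES
  if (any(bad_role))
    stop("topology: unknown bead_role '", b$bead_role[bad_role][1],
         "' at bead_id ", b$bead_id[bad_role][1])

  # helix definitions: all seven labels, non-overlapping inclusive ranges
  if (!setequal(hd$helix, HELIX_LABELS))
    stop("topology: helix_definitions must define exactly helices I..VII")
  hd <- hd[order(hd$from), ]
  if (any(hd$to < hd$from)) stop("topology: helix range with to < from")
  if (nrow(hd) > 1) {
    ov <- which(hd$from[-1] <= hd$to[-nrow(hd)])
    if (length(ov))
      stop("topology: overlapping helix ranges ", hd$helix[ov[1]], " (",
           hd$from[ov[1]], "-", hd$to[ov[1]], ") and ", hd$helix[ov[1] + 1],
           " (", hd$from[ov[1] + 1], "-", hd$to[ov[1] + 1], ")")
  }

  rec <- b[b$molecule_kind == "receptor", ]
  if (require_dimer) {
    ids <- sort(unique(rec$receptor_id))
    if (!identical(ids, c(1L, 2L)))
      stop("topology: dimer analyses need exactly receptor ids 1 and 2 (found: ",
           paste(ids, collapse = ", "), ")")
  }
  if (any(is.na(rec$residue_index)))
    stop("topology: receptor bead without residue_index (bead_id ",
         rec$bead_id[is.na(rec$residue_index)][1], ")")

  # bead helix labels must agree with the ranges
  expected <- helix_of_residue(rec$residue_index, hd)
  mismatch <- which(!is.na(rec$helix_label) & rec$helix_label != expected)
  if (length(mismatch))
    stop("topology: bead_id ", rec$bead_id[mismatch[1]], " (residue ",
         rec$residue_index[mismatch[1]], ") labelled '",
         rec$helix_label[mismatch[1]], "' but helix ranges say '",
         expected[mismatch[1]], "'")

  # anchor residues of the rotational-angle definition
  if (helix_of_residue(48L, hd) != "I")
    stop("topology: residue 48 must lie in helix I (theta definition)")
  if (any(helix_of_residue(c(164L, 167L), hd) != "IV"))
    stop("topology: residues 164 and 167 must lie in helix IV (theta definition)")

  # every POPC molecule has exactly one phosphate bead
  popc <- b[b$molecule_kind == "POPC", ]
  if (nrow(popc)) {
    nph <- tapply(popc$bead_role == "phosphate", popc$molecule_id, sum)
    bad <- names(nph)[nph != 1]
    if (length(bad))
      stop("topology: POPC molecule_id ", bad[1], " has ", nph[bad[1]],
           " phosphate beads (expected 1)")
  }
  invisible(top)
}

# Map residue indices to helix labels ("loop" when in no range).
helix_of_residue <- function(residues, helix_definitions) {
  hd <- helix_definitions
  out <- rep("loop", length(residues))
  for (i in seq_len(nrow(hd))) {
    out[residues >= hd$from[i] & residues <= hd$to[i]] <- hd$helix[i]
  }
  out
}

#' @export
print.system_topology <- function(x, ...) {
  b <- x$beads
  cat("System topology:", nrow(b), "beads,",
      length(unique(b$molecule_id)), "molecules\n")
  cat("  receptors:", length(unique(b$receptor_id[!is.na(b$receptor_id)])),
      " POPC:", length(unique(b$molecule_id[b$molecule_kind == "POPC"])),
      " CHOL:", length(unique(b$molecule_id[b$molecule_kind == "CHOL"])), "\n")
  invisible(x)
}

#' Read a topology file (TSV or JSON)
#'
#' TSV files carry the helix definitions as leading comment lines of the form
#' \code{#helix<TAB>I<TAB>37<TAB>62} followed by a tab-separated bead table.
#' JSON files hold \code{beads} and \code{helix_definitions} records.
#'
#' @param path file path; format chosen by extension (.json vs anything else).
#' @param require_dimer passed to \code{\link{validate_topology}}.
#' @return a validated \code{system_topology}.
#' @export
read_topology <- function(path, require_dimer = TRUE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    return(system_topology(obj$beads, obj$helix_definitions,
                           require_dimer = require_dimer))
  }
  lines <- readLines(path)
  hx <- grep("^#helix\t", lines, value = TRUE)
  if (!length(hx)) stop("topology TSV lacks '#helix' definition lines: ", path)
  parts <- strsplit(hx, "\t", fixed = TRUE)
  hd <- data.frame(helix = vapply(parts, `[`, "", 2),
                   from = as.integer(vapply(parts, `[`, "", 3)),
                   to = as.integer(vapply(parts, `[`, "", 4)))
  body <- lines[!startsWith(lines, "#")]
  beads <- utils::read.table(text = body, header = TRUE, sep = "\t",
                             na.strings = "NA", stringsAsFactors = FALSE)
  system_topology(beads, hd, require_dimer = require_dimer)
}

#' Write a topology as TSV (round-trips through \code{read_topology})
#' @param top a \code{system_topology}.
#' @param path output path.
#' @export
write_topology <- function(top, path) {
  stopifnot(inherits(top, "system_topology"))
  hd <- top$helix_definitions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#helix\t%s\t%d\t%d", hd$helix, hd$from, hd$to), con)
  utils::write.table(top$beads, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Indices (row numbers in beads) of transmembrane-helix beads of one receptor.
tm_bead_indices <- function(top, receptor) {
  b <- top$beads
  which(b$molecule_kind == "receptor" & b$receptor_id == receptor &
          b$helix_label %in% HELIX_LABELS)
}

# Row index of the backbone bead of a given residue on a given receptor.
backbone_bead_index <- function(top, receptor, residue) {
  b <- top$beads
  i <- which(b$molecule_kind == "receptor" & b$receptor_id == receptor &
               b$residue_index == residue & b$bead_role == "backbone")
  if (!length(i))
    stop("no backbone bead for residue ", residue, " of receptor ", receptor)
  i[1]
}
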
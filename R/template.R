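# Rigid coarse-grain receptor template used by the synthetic generator: seven
# transmembrane helices arranged on a ring, each a vertical stack of backbone
# beads plus one outward-facing sidechain bead, and two intracellular loop
# beads near the axis. Residue numbering follows the UniProt P08908 helix
# annotation so that residue 48 sits in helix I and 164/167 in helix IV.

TEMPLATE_HELIX_DEFS <- data.frame(
  helix = c("I", "II", "III", "IV", "V", "VI", "VII"),
  from = c(37L, 74L, 110L, 153L, 192L, 346L, 379L),
  to   = c(62L, 98L, 132L, 177L, 216L, 370L, 403L))

TEMPLATE_RESIDUES <- list(
  I   = c(40L, 44L, 48L, 52L, 56L),
  II  = c(78L, 82L, 86L, 90L, 94L),
  III = c(112L, 116L, 120L, 124L, 128L),
  IV  = c(156L, 160L, 164L, 167L, 172L),
  V   = c(196L, 200L, 204L, 208L, 212L),
  VI  = c(350L, 354L, 358L, 362L, 366L),
  VII = c(382L, 386L, 390L, 394L, 398L))

#' Build the rigid receptor bead template
#'
#' Seven helix clusters placed on a ring of radius 1.3 nm at angular positions
#' 360/7 degrees apart, so each helix owns a distinct outward-facing sector.
#' Each cluster holds five backbone beads stacked across the membrane span
#' (z in [-1.2, 1.2] nm about the bilayer midplane) with a small helical
#' twist, plus one sidechain bead at larger radius. Two loop beads (third
#' intracellular loop) sit near the symmetry axis below the membrane span.
#'
#' @param seed integer; seeds the small angular/radial jitter, so equal seeds
#'   give bit-identical templates.
#' @return object of class \code{receptor_template}: \code{beads}
#'   (residue_index, helix_label, bead_role, x, y, z in the body frame),
#'   \code{helix_definitions}, \code{helix_angles} (degrees), and
#'   \code{max_radius} (nm, largest transmembrane bead radius).
#' @export
build_receptor_template <- function(seed = 1L) {
  with_seed(seed, {
    phi <- (seq_len(7) - 1) * 360 / 7
    names(phi) <- HELIX_LABELS
    rows <- list()
    for (h in seq_len(7)) {
      lab <- HELIX_LABELS[h]
      res <- TEMPLATE_RESIDUES[[lab]]
      z <- seq(-1.2, 1.2, length.out = 5)
      twist <- seq(-6, 6, length.out = 5) + stats::runif(5, -1.5, 1.5)
      rad <- 1.3 + stats::runif(5, -0.04, 0.04)
      ang <- (phi[h] + twist) * pi / 180
      for (k in 1:5) {
        rows[[length(rows) + 1L]] <- data.frame(
          residue_index = res[k], helix_label = lab, bead_role = "backbone",
          x = rad[k] * cos(ang[k]), y = rad[k] * sin(ang[k]), z = z[k])
      }
      # one sidechain bead on the middle residue, pointing outward
      sa <- (phi[h] + stats::runif(1, -3, 3)) * pi / 180
      rows[[length(rows) + 1L]] <- data.frame(
        residue_index = res[3], helix_label = lab, bead_role = "sidechain",
        x = 1.55 * cos(sa), y = 1.55 * sin(sa), z = 0.05)
    }
    # third intracellular loop (between helices V and VI), near the axis
    for (lp in list(c(250L, 90), c(260L, 270))) {
      a <- lp[2] * pi / 180
      rows[[length(rows) + 1L]] <- data.frame(
        residue_index = lp[1], helix_label = "loop", bead_role = "backbone",
        x = 0.45 * cos(a), y = 0.45 * sin(a), z = -1.55)
    }
    beads <- do.call(rbind, rows)
    rownames(beads) <- NULL
    tm <- beads$helix_label != "loop"
    structure(list(beads = beads,
                   helix_definitions = TEMPLATE_HELIX_DEFS,
                   helix_angles = phi,
                   max_radius = max(sqrt(beads$x[tm]^2 + beads$y[tm]^2))),
              class = "receptor_template")
  })
}

#' Build the two-receptor + bilayer topology for a template
#'
#' Bead order: receptor 1, receptor 2, POPC molecules (phosphate, glycerol,
#' tail beads), CHOL molecules (hydroxyl head, ring bead). This order matches
#' the coordinate layout written by \code{\link{generate_trajectory}}.
#'
#' @param template a \code{receptor_template}.
#' @param n_popc,n_chol lipid counts.
#' @return a validated \code{system_topology}.
#' @export
template_topology <- function(template, n_popc, n_chol) {
  tb <- template$beads
  nrb <- nrow(tb)
  rec <- function(rid) data.frame(
    molecule_id = rid, molecule_kind = "receptor", receptor_id = rid,
    residue_index = tb$residue_index, bead_role = tb$bead_role,
    helix_label = tb$helix_label)
  parts <- list(rec(1L), rec(2L))
  mol <- 2L
  if (n_popc > 0) {
    for (m in seq_len(n_popc)) {
      parts[[length(parts) + 1L]] <- data.frame(
        molecule_id = mol + m, molecule_kind = "POPC", receptor_id = NA_integer_,
        residue_index = NA_integer_,
        bead_role = c("phosphate", "other", "other"),
        helix_label = NA_character_)
    }
    mol <- mol + n_popc
  }
  if (n_chol > 0) {
    for (m in seq_len(n_chol)) {
      parts[[length(parts) + 1L]] <- data.frame(
        molecule_id = mol + m, molecule_kind = "CHOL", receptor_id = NA_integer_,
        residue_index = NA_integer_, bead_role = c("other", "other"),
        helix_label = NA_character_)
    }
  }
  beads <- do.call(rbind, parts)
  beads$bead_id <- seq_len(nrow(beads))
  system_topology(beads, template$helix_definitions)
}

# GRO naming skeleton matching template_topology bead order.
topology_skeleton <- function(top) {
  b <- top$beads
  resname <- ifelse(b$molecule_kind == "receptor",
                    paste0("REC", b$receptor_id), b$molecule_kind)
  atomname <- rep("BB", nrow(b))
  atomname[b$bead_role == "sidechain"] <- "SC1"
  atomname[b$bead_role == "phosphate"] <- "PO4"
  within_mol <- stats::ave(seq_len(nrow(b)), b$molecule_id, FUN = seq_along)
  is_other <- b$bead_role == "other"
  atomname[is_other & b$molecule_kind == "POPC"] <-
    c("GL1", "C1A")[pmin(within_mol[is_other & b$molecule_kind == "POPC"] - 1L, 2L)]
  atomname[is_other & b$molecule_kind == "CHOL"] <-
    c("ROH", "R1")[within_mol[is_other & b$molecule_kind == "CHOL"]]
  data.frame(resid = b$molecule_id, resname = resname, atomname = atomname)
}
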
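# GROMACS GRO reader/writer. Fixed-column format, coordinates in nm to three
# decimals. Multi-frame files are plain concatenations of frame blocks:
#   title line (optionally containing "t= <time in ps>")
#   atom count
#   one fixed-width line per atom: resid(5) resname(5) atomname(5) atomnr(5)
#     x(8.3) y(8.3) z(8.3) [velocities ignored]
#   box line: "Lx Ly Lz" (orthorhombic; triclinic boxes are rejected)

#' Read a (multi-frame) GRO file
#'
#' @param path file path.
#' @return list with \code{frames} (list of \code{cg_frame}: \code{time} ns or
#'   NA, \code{box} nm, \code{coords} n x 3 matrix in nm) and \code{skeleton}
#'   (data.frame of resid/resname/atomname per bead, from the first frame).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  skeleton <- NULL
  i <- 1L
  n_total <- length(lines)
  while (i <= n_total) {
    if (!nzchar(trimws(lines[i])) && i == n_total) break
    title <- lines[i]
    if (i + 1L > n_total)
      stop("GRO parse error: truncated frame header at line ", i)
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 0)
      stop("GRO parse error: malformed atom count at line ", i + 1L)
    last <- i + 1L + natoms + 1L
    if (last > n_total)
      stop("GRO parse error: truncated frame (declared ", natoms,
           " atoms) starting at line ", i)
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    if (any(nchar(atom_lines) < 44))
      stop("GRO parse error: short atom line at line ",
           i + 1L + which(nchar(atom_lines) < 44)[1])
    x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("GRO parse error: unreadable coordinates at line ",
           i + 1L + which(is.na(x) | is.na(y) | is.na(z))[1])
    boxvals <- suppressWarnings(as.numeric(strsplit(trimws(lines[last]),
                                                    "\\s+")[[1]]))
    if (length(boxvals) < 3 || anyNA(boxvals[1:3]))
      stop("GRO parse error: malformed box line at line ", last)
    if (length(boxvals) > 3 && any(abs(boxvals[-(1:3)]) > 1e-9))
      stop("GRO parse error: triclinic box at line ", last,
           " (only orthorhombic boxes are supported)")
    if (any(boxvals[1:3] <= 0))
      stop("GRO parse error: non-positive box length at line ", last)
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    time_ns <- if (length(tm) == 2) as.numeric(tm[2]) / 1000 else NA_real_
    if (is.null(skeleton)) {
      skeleton <- data.frame(
        resid = as.integer(substr(atom_lines, 1, 5)),
        resname = trimws(substr(atom_lines, 6, 10)),
        atomname = trimws(substr(atom_lines, 11, 15)),
        stringsAsFactors = FALSE)
    }
    frames[[length(frames) + 1L]] <- structure(
      list(time = time_ns, box = boxvals[1:3],
           coords = cbind(x = x, y = y, z = z)),
      class = "cg_frame")
    i <- last + 1L
  }
  if (!length(frames)) stop("GRO parse error: no frames in ", path)
  list(frames = frames, skeleton = skeleton)
}

#' Write frames to a GRO file
#'
#' @param frames list of \code{cg_frame} objects (or a \code{cg_trajectory}).
#' @param path output path.
#' @param skeleton optional data.frame (resid, resname, atomname); defaulted
#'   from bead index when absent.
#' @export
write_gro <- function(frames, path, skeleton = NULL) {
  if (inherits(frames, "cg_trajectory")) frames <- frames$frames
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$coords)
    if (is.null(skeleton)) {
      sk <- data.frame(resid = seq_len(n), resname = "BEAD", atomname = "BB")
    } else sk <- skeleton
    t_ps <- if (is.na(fr$time)) 0 else fr$time * 1000
    writeLines(sprintf("dimerlens frame t= %.4f", t_ps), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       sk$resid %% 100000L, substr(sk$resname, 1, 5),
                       substr(sk$atomname, 1, 5),
                       seq_len(n) %% 100000L,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]),
               con)
  }
  invisible(path)
}

#' Assemble a trajectory from frames
#'
#' @param frames list of \code{cg_frame}.
#' @param label simulation identifier.
#' @param composition cholesterol mole percentage (0, 9, 30 or 50).
#' @param times optional numeric vector (ns) overriding frame times; defaults
#'   to the stored times, or 0, 1, 2, ... when those are absent.
#' @return object of class \code{cg_trajectory}.
#' @export
trajectory <- function(frames, label = "sim", composition = 0, times = NULL) {
  n <- length(frames)
  if (!n) stop("trajectory needs at least one frame")
  nb <- nrow(frames[[1]]$coords)
  for (k in seq_len(n)) {
    if (nrow(frames[[k]]$coords) != nb)
      stop("frame ", k, " has ", nrow(frames[[k]]$coords),
           " beads, expected ", nb)
  }
  if (!is.null(times)) {
    for (k in seq_len(n)) frames[[k]]$time <- times[k]
  } else if (anyNA(vapply(frames, function(f) f$time, 0))) {
    for (k in seq_len(n)) frames[[k]]$time <- k - 1
  }
  tt <- vapply(frames, function(f) f$time, 0)
  if (any(diff(tt) <= 0)) stop("trajectory times must be strictly increasing")
  structure(list(frames = frames, label = label, composition = composition),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  tt <- trajectory_times(x)
  cat(sprintf("Trajectory '%s': %d frames, %d beads, %.1f-%.1f ns, %d%% cholesterol\n",
              x$label, length(x$frames), nrow(x$frames[[1]]$coords),
              tt[1], tt[length(tt)], x$composition))
  invisible(x)
}

#' Frame times of a trajectory (ns)
#' @param traj a \code{cg_trajectory}.
#' @export
trajectory_times <- function(traj) vapply(traj$frames, function(f) f$time, 0)
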
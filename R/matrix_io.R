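# Labelled-matrix TSV I/O. Full double precision ("%.17g") so numeric output
# round-trips bit-exactly through the companion reader; NaN is written as NA.

#' Write a labelled numeric matrix as TSV
#'
#' First row holds column labels, first column row labels. An optional JSON
#' metadata side-car (same path + ".meta.json") records the analysis
#' configuration that produced the matrix, so figures are reproducible from
#' outputs alone.
#'
#' @param m numeric matrix with complete dimnames.
#' @param path output path.
#' @param metadata optional list written to the side-car.
#' @export
write_matrix <- function(m, path, metadata = NULL) {
  if (!is.matrix(m)) stop("write_matrix: not a matrix")
  if (is.null(colnames(m)) || (nrow(m) > 0 && is.null(rownames(m))))
    stop("write_matrix: row and column labels are required")
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"       # covers NA and NaN
    out[is.infinite(v)] <- ifelse(v[is.infinite(v)] > 0, "Inf", "-Inf")
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("label", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), con)
  }
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a matrix written by \code{\link{write_matrix}}
#' @param path TSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cn <- header[-1]
  if (length(lines) == 1) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(cn),
                dimnames = list(NULL, cn))
    return(m)
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  rn <- vapply(rows, `[`, "", 1)
  vals <- lapply(rows, function(r) {
    v <- r[-1]
    out <- suppressWarnings(as.numeric(v))
    out
  })
  m <- do.call(rbind, vals)
  dimnames(m) <- list(rn, cn)
  m
}
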
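# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: plain double loops and textbook formulas.

# Exhaustive all-pairs minimum-image distance (double loop, per-component
# folding).
brute_min_dist <- function(A, B, box) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- A[i, ] - B[j, ]
    d <- d - box * round(d / box)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# Rodrigues rotation of point p about the axis through `origin` with
# direction `axis` by `angle_deg`.
rodrigues_rotate <- function(p, origin, axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  v <- p - origin
  th <- angle_deg * pi / 180
  kxv <- c(k[2] * v[3] - k[3] * v[2],
           k[3] * v[1] - k[1] * v[3],
           k[1] * v[2] - k[2] * v[1])
  vr <- v * cos(th) + kxv * sin(th) + k * sum(k * v) * (1 - cos(th))
  origin + vr
}

# Longest TRUE run in a logical vector, by explicit scan.
brute_longest_run <- function(v) {
  best <- 0L; cur <- 0L
  for (x in v) {
    if (isTRUE(x)) { cur <- cur + 1L; best <- max(best, cur) } else cur <- 0L
  }
  best
}

# Smallest absolute circular difference in degrees.
ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
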
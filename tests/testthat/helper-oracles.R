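# Independent oracles used across the suite. They recompute quantities by
# brute force and must not call the implementation paths they check.

# Two-sample KS statistic by double-loop ECDF enumeration over every
# observed breakpoint.
ks_oracle_D <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  ecdf_at <- function(v, x) mean(v <= x)
  max(vapply(xs, function(x) abs(ecdf_at(a, x) - ecdf_at(b, x)), numeric(1)))
}

# Single-source shortest-path times by iterative edge relaxation
# (Bellman-Ford) on the grid cost graph, with edges and Tobler speeds
# recomputed from first principles. Planar grids, default hiking
# parameters only.
bellman_ford_times <- function(elev, cell_size_m, source_rc,
                               connectivity = 8) {
  nr <- nrow(elev); nc <- ncol(elev)
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  if (connectivity == 16)
    offs <- rbind(offs, cbind(dr = c(-2, -2, -1, -1, 1, 1, 2, 2),
                              dc = c(-1, 1, -2, 2, -2, 2, -1, 1)))
  acc <- list()
  for (k in seq_len(nrow(offs))) {
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      r2 <- r + offs[k, 1]; c2 <- cc + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(elev[r, cc]) || is.na(elev[r2, c2])) next
      d_m <- sqrt((offs[k, 1] * cell_size_m)^2 + (offs[k, 2] * cell_size_m)^2)
      slope <- (elev[r2, c2] - elev[r, cc]) / d_m
      speed <- 6 * exp(-3.5 * abs(slope + 0.05))
      acc[[length(acc) + 1L]] <- c((r - 1) * nc + cc,
                                   (r2 - 1) * nc + c2,
                                   (d_m / 1000) / speed)
    }
  }
  edges <- do.call(rbind, acc)
  dist <- rep(Inf, nr * nc)
  dist[(source_rc[1] - 1) * nc + source_rc[2]] <- 0
  repeat {
    cand <- dist[edges[, 1]] + edges[, 3]
    new <- dist
    for (i in seq_len(nrow(edges)))
      if (cand[i] < new[edges[i, 2]]) new[edges[i, 2]] <- cand[i]
    if (!any(new < dist - 1e-12)) break
    dist <- new
  }
  matrix(dist, nr, nc, byrow = TRUE)
}

# Exact two-sided binomial parity p-value (doubled tail, capped at 1).
binom_parity_p <- function(f, m) {
  n <- f + m
  if (f == m) return(1)
  k <- max(f, m)
  min(1, 2 * pbinom(k - 1, n, 0.5, lower.tail = FALSE))
}
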
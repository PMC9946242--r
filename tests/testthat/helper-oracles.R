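# Independent brute-force oracles. Deliberately written with plain loops and
# dense linear algebra so they share no code path with the package internals.

# Dense graph Laplacian of a cost matrix, built cell by cell.
dense_laplacian <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  n <- nr * nc
  id <- function(r, c) (c - 1L) * nr + r
  L <- matrix(0, n, n)
  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      for (o in offs) {
        r2 <- r + o[1]; c2 <- c + o[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        df <- if (abs(o[1]) + abs(o[2]) == 2) sqrt(2) else 1
        g <- 1 / (df * (m[r, c] + m[r2, c2]) / 2)
        a <- id(r, c); b <- id(r2, c2)
        L[a, b] <- L[a, b] - g
        L[b, a] <- L[b, a] - g
        L[a, a] <- L[a, a] + g
        L[b, b] <- L[b, b] + g
      }
    }
  }
  L
}

# Hard-ground dense solve: potentials with grounds eliminated at 0 V,
# then per-node current = (sum |edge currents| + |injection|) / 2.
dense_flow_oracle <- function(m, sources, grounds, injections,
                              connectivity = 8) {
  L <- dense_laplacian(m, connectivity)
  n <- nrow(L)
  i_full <- numeric(n)
  i_full[sources] <- injections
  unknown <- setdiff(seq_len(n), grounds)
  v <- numeric(n)
  v[unknown] <- solve(L[unknown, unknown], i_full[unknown])
  absorbed <- -(L %*% v)[grounds]
  i_full[grounds] <- -absorbed
  G <- -L
  diag(G) <- 0
  edge_cur <- G * outer(v, v, "-")  # row a, col b: current a -> b
  cur <- (rowSums(abs(edge_cur)) + abs(i_full)) / 2
  list(v = v, current = cur)
}

# Effective resistance through the Laplacian pseudo-inverse with all
# sources merged into one supernode and all grounds into another: sum the
# rows/columns of each merged set, then apply the two-point formula.
dense_reff_oracle <- function(m, sources, grounds, connectivity = 8) {
  L <- dense_laplacian(m, connectivity)
  n <- nrow(L)
  others <- setdiff(seq_len(n), c(sources, grounds))
  groups <- c(list(sources, grounds), as.list(others))
  k <- length(groups)
  M <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      M[a, b] <- sum(L[groups[[a]], groups[[b]]])
    }
  }
  Lp <- MASS::ginv(M)
  Lp[1, 1] + Lp[2, 2] - 2 * Lp[1, 2]
}

# Rank-then-Pearson Spearman.
spearman_oracle <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Modal category over explicit blocks.
block_mode_oracle <- function(m, fr, fc) {
  nr <- nrow(m) / fr; nc <- ncol(m) / fc
  out <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      blk <- m[((r - 1) * fr + 1):(r * fr), ((c - 1) * fc + 1):(c * fc)]
      tab <- sort(table(blk), decreasing = TRUE)
      best <- as.integer(names(tab)[tab == max(tab)])
      out[r, c] <- min(best)
    }
  }
  out
}

# Per-cell segment/rectangle intersection test (closed cells).
segment_hits_cell_oracle <- function(p, q, xmin, xmax, ymin, ymax) {
  # sample the segment very densely and check containment
  t <- seq(0, 1, length.out = 4001)
  x <- p[1] + t * (q[1] - p[1]); y <- p[2] + t * (q[2] - p[2])
  any(x >= xmin - 1e-12 & x <= xmax + 1e-12 &
      y >= ymin - 1e-12 & y <= ymax + 1e-12)
}

# Welch t statistic from the textbook formula.
welch_t_oracle <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}
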
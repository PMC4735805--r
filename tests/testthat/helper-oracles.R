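# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's optimized code paths.

# --- polygon-based ellipse overlap oracle -----------------------------------

oracle_ellipse_points <- function(e, n = 720) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- e[5] * pi / 180
  ct <- cos(t) * e[3]; st <- sin(t) * e[4]
  cbind(e[1] + ct * cos(th) - st * sin(th),
        e[2] + ct * sin(th) + st * cos(th))
}

oracle_in_ellipse <- function(px, py, e) {
  th <- e[5] * pi / 180
  dx <- px - e[1]; dy <- py - e[2]
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / e[3])^2 + (v / e[4])^2 <= 1
}

oracle_overlap <- function(e1, e2, n = 720) {
  p1 <- oracle_ellipse_points(e1, n)
  p2 <- oracle_ellipse_points(e2, n)
  any(oracle_in_ellipse(p1[, 1], p1[, 2], e2)) ||
    any(oracle_in_ellipse(p2[, 1], p2[, 2], e1)) ||
    oracle_in_ellipse(e2[1], e2[2], e1) ||
    oracle_in_ellipse(e1[1], e1[2], e2)
}

# --- brute-force nearest-neighbour scan -------------------------------------

oracle_nn_param <- function(query, reference) {
  qm <- as.matrix(query[, c("x", "y", "a", "b", "theta")])
  rm_ <- as.matrix(reference[, c("x", "y", "a", "b", "theta")])
  out <- lapply(seq_len(nrow(qm)), function(i) {
    edges <- vapply(seq_len(nrow(rm_)), function(j) {
      ellipse_edge_distance(qm[i, ], rm_[j, ])
    }, numeric(1))
    j <- which(edges == min(edges))[1]     # lowest id on ties
    data.frame(query_id = query$id[i], reference_id = reference$id[j],
               edge_nm = edges[j])
  })
  do.call(rbind, out)
}

# --- brute-force connected components (BFS) ---------------------------------

oracle_label_components <- function(mask, connectivity) {
  d <- dim(mask)
  nd <- length(d)
  offs <- expand.grid(dr = -1:1, dc = -1:1,
                      dz = if (nd == 3) -1:1 else 0)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity %in% c(4, 6)) offs <- offs[rowSums(abs(offs)) == 1, ]
  labels <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask != 0)
  for (s in idx_all) {
    if (labels[s] != 0) next
    nxt <- nxt + 1L
    queue <- s
    labels[s] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      pos <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        p <- pos + as.integer(offs[k, seq_len(nd)])
        if (any(p < 1) || any(p > d)) next
        lin <- p[1] + (p[2] - 1) * d[1] +
          if (nd == 3) (p[3] - 1) * d[1] * d[2] else 0
        if (mask[lin] != 0 && labels[lin] == 0) {
          labels[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# two labellings agree up to renaming if the partition of foreground pixels
# is identical
same_partition <- function(l1, l2) {
  f <- which(l1 != 0)
  if (!identical(f, which(l2 != 0))) return(FALSE)
  identical(as.integer(factor(l1[f], levels = unique(l1[f]))),
            as.integer(factor(l2[f], levels = unique(l2[f]))))
}

# --- arc-length quadrature for the sinusoid amplification -------------------

oracle_sinusoid_amplification <- function(amplitude, period) {
  stats::integrate(function(x) {
    sqrt(1 + (2 * pi * amplitude / period)^2 * cos(2 * pi * x / period)^2)
  }, 0, period, rel.tol = 1e-10)$value / period
}

# --- exact Markov chain for a single ligate, single channel -----------------
# Mirrors the engine's update rules (default model, one ligate so the
# exclusion flag is irrelevant): states are (site, free) plus (channel,
# bound). Returns the stationary distribution and bound probability.

oracle_walk_chain <- function(nx, ny, nz, chan_xy, p_bind, p_unbind,
                              attraction) {
  nsite <- nx * ny * nz
  chan_lin <- chan_xy[1] + nx * chan_xy[2] + 1   # 1-based linear index
  nstate <- nsite + 1                            # last state = bound
  site_of <- function(x, y, z) x + nx * y + nx * ny * z + 1
  coords <- function(s) {
    s0 <- s - 1
    c(s0 %% nx, (s0 %/% nx) %% ny, s0 %/% (nx * ny))
  }
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  move_kernel <- function(s) {
    p <- numeric(nstate)
    xyz <- coords(s)
    w <- numeric(6); dest <- integer(6)
    for (m in 1:6) {
      q <- xyz + dirs[m, ]
      if (q[1] < 0 || q[1] >= nx || q[2] < 0 || q[2] >= ny ||
          q[3] < 0 || q[3] >= nz) { w[m] <- 0; dest[m] <- NA; next }
      d <- site_of(q[1], q[2], q[3])
      w[m] <- if (d == chan_lin) attraction else 1
      dest[m] <- d
    }
    if (sum(w) == 0) { p[s] <- 1; return(p) }
    w <- w / sum(w)
    for (m in 1:6) if (!is.na(dest[m])) p[dest[m]] <- p[dest[m]] + w[m]
    p
  }
  P <- matrix(0, nstate, nstate)
  for (s in seq_len(nsite)) {
    if (s == chan_lin) {
      # free, standing on the channel site: bind attempt, else move
      P[s, nstate] <- p_bind
      P[s, ] <- P[s, ] + (1 - p_bind) * move_kernel(s)
    } else {
      P[s, ] <- move_kernel(s)
    }
  }
  # bound state: unbind and hop to a uniform in-lattice neighbour
  xyz <- coords(chan_lin)
  nb <- integer(0)
  for (m in 1:6) {
    q <- xyz + dirs[m, ]
    if (q[1] >= 0 && q[1] < nx && q[2] >= 0 && q[2] < ny &&
        q[3] >= 0 && q[3] < nz) {
      nb <- c(nb, site_of(q[1], q[2], q[3]))
    }
  }
  P[nstate, nstate] <- 1 - p_unbind
  for (d in nb) P[nstate, d] <- P[nstate, d] + p_unbind / length(nb)
  pi0 <- rep(1 / nstate, nstate)
  for (it in 1:20000) {
    pi1 <- as.vector(pi0 %*% P)
    if (max(abs(pi1 - pi0)) < 1e-13) { pi0 <- pi1; break }
    pi0 <- pi1
  }
  list(stationary = pi0, p_bound = pi0[nstate])
}

# evaluate code under a local seed, restoring the caller RNG state
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
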
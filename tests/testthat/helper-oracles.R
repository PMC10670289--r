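# Independent oracles and toy builders used across the suite. Every oracle
# deliberately takes the dumbest correct route (dense grids, double loops,
# exhaustive enumeration) so it shares no code path with the implementation.

ca_atoms <- function(n, resseq = seq_len(n)) {
  lipdyn:::.make_atom_table(seq_len(n), rep("CA", n), rep("C", n),
                            rep("GLY", n), resseq)
}

# trajectory from a list of n x 3 coordinate matrices (nm)
toy_traj <- function(frames, resseq = seq_len(nrow(frames[[1]]))) {
  n <- nrow(frames[[1]])
  md_trajectory(ca_atoms(n, resseq),
                array(unlist(frames), c(n, 3, length(frames))))
}

# small all-atom toy: N, CA, C per residue along a line
allatom_traj <- function(n_res, n_frames = 1) {
  nm <- rep(c("N", "CA", "C"), n_res)
  el <- rep(c("N", "C", "C"), n_res)
  rs <- rep(seq_len(n_res), each = 3)
  atoms <- lipdyn:::.make_atom_table(seq_along(nm), nm, el,
                                     rep("ALA", length(nm)), rs)
  xyz <- cbind(seq_along(nm) * 0.13, 0, 0)
  md_trajectory(atoms, array(rep(xyz, n_frames),
                             c(nrow(xyz), 3, n_frames)))
}

toy_dist <- function(m, resseq = seq_len(nrow(m))) {
  dimnames(m) <- list(resseq, resseq)
  structure(list(values = m, resseq = as.integer(resseq)),
            class = "distance_matrix")
}

# residue_graph straight from an (i, j, weight) edge table
toy_graph <- function(n, i, j, weight) {
  edges <- data.frame(i = as.integer(i), j = as.integer(j),
                      resseq_i = as.integer(i), resseq_j = as.integer(j),
                      dist = rep(1, length(i)), corr = exp(-weight),
                      weight = weight)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(resseq = seq_len(n)), edges = edges,
                 cutoff_used = 1.5), class = "residue_graph")
}

# ---- Kabsch oracle: Euler-angle grid search refined to 0.1 degree ----------
oracle_grid_rmsd <- function(P, Q, final_deg = 0.1) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot_zyz <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                             3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                             3, byrow = TRUE)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  eval_rmsd <- function(a, b, c)
    sqrt(mean(rowSums((Pc %*% t(rot_zyz(a, b, c)) - Qc)^2)))
  best <- c(0, 0, 0); best_val <- eval_rmsd(0, 0, 0)
  step <- 10 * pi / 180
  for (a in seq(0, 2 * pi, by = step)) for (b in seq(0, pi, by = step))
    for (c in seq(0, 2 * pi, by = step)) {
      v <- eval_rmsd(a, b, c)
      if (v < best_val) { best_val <- v; best <- c(a, b, c) }
    }
  while (step > final_deg * pi / 180) {
    prev <- step; step <- step / 5
    g <- seq(-prev, prev, by = step)
    repeat {  # re-center at this resolution until no improvement
      improved <- FALSE
      for (da in g) for (db in g) for (dc in g) {
        v <- eval_rmsd(best[1] + da, best[2] + db, best[3] + dc)
        if (v < best_val - 1e-12) {
          best_val <- v; best <- best + c(da, db, dc); improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  best_val
}

# ---- naive two-pass double-loop covariance oracle --------------------------
oracle_covariance <- function(coords) {
  n <- dim(coords)[1]; nf <- dim(coords)[3]
  mu <- apply(coords, c(1, 2), mean)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (f in seq_len(nf))
      s <- s + sum((coords[i, , f] - mu[i, ]) * (coords[j, , f] - mu[j, ]))
    C[i, j] <- s / nf
  }
  C
}

# ---- naive per-frame mean distance oracle ----------------------------------
oracle_mean_dist <- function(coords) {
  n <- dim(coords)[1]; nf <- dim(coords)[3]
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (f in seq_len(nf))
      s <- s + sqrt(sum((coords[i, , f] - coords[j, , f])^2))
    D[i, j] <- s / nf
  }
  D
}

# ---- dense-sampling SASA oracle for a 2-atom system ------------------------
oracle_sasa_two_atoms <- function(x1, x2, r1, r2, probe, n = 1e6) {
  pts <- sphere_points(n)
  area_one <- function(center, Rself, other, Rother) {
    P <- pts * Rself + matrix(center, n, 3, byrow = TRUE)
    free <- rowSums((P - matrix(other, n, 3, byrow = TRUE))^2) > Rother^2
    mean(free) * 4 * pi * Rself^2
  }
  area_one(x1, r1 + probe, x2, r2 + probe) +
    area_one(x2, r2 + probe, x1, r1 + probe)
}

# ---- exhaustive simple-path SPM oracle -------------------------------------
# edges: data.frame(i, j, weight). Returns list(node_usage, edge_usage,
# dist) matching shortest_path_map()'s counting rules (one lexicographically
# smallest min-weight path per ordered reachable pair; endpoints counted).
oracle_spm <- function(n, edges) {
  adj <- lapply(seq_len(n), function(u) {
    a <- which(edges$i == u); b <- which(edges$j == u)
    list(v = c(edges$j[a], edges$i[b]), w = c(edges$weight[a], edges$weight[b]),
         e = c(a, b))
  })
  node_usage <- numeric(n); edge_usage <- numeric(nrow(edges))
  dist_mat <- matrix(Inf, n, n); diag(dist_mat) <- 0
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    best_w <- Inf; best_path <- NULL; best_edges <- NULL
    walk <- function(u, visited, w, path, epath) {
      if (w > best_w + 1e-9) return()
      if (u == t) {
        # node labels are single digits (n <= 9), so string order on the
        # comma-joined sequence is lexicographic order on the sequence
        if (is.null(best_path) || w < best_w - 1e-9 ||
            (w <= best_w + 1e-9 &&
               paste(path, collapse = ",") < paste(best_path, collapse = ","))) {
          best_w <- min(best_w, w)
          best_w <<- best_w; best_path <<- path; best_edges <<- epath
        }
        return()
      }
      a <- adj[[u]]
      for (k in seq_along(a$v)) {
        v <- a$v[k]
        if (!visited[v])
          walk(v, replace(visited, v, TRUE), w + a$w[k],
               c(path, v), c(epath, a$e[k]))
      }
    }
    walk(s, replace(rep(FALSE, n), s, TRUE), 0, s, integer(0))
    if (!is.null(best_path)) {
      dist_mat[s, t] <- best_w
      node_usage[best_path] <- node_usage[best_path] + 1
      edge_usage[best_edges] <- edge_usage[best_edges] + 1
    }
  }
  list(node_usage = node_usage, edge_usage = edge_usage, dist = dist_mat)
}

# ---- brute-force correlated-region oracle ----------------------------------
oracle_regions <- function(M, threshold, min_block) {
  n <- nrow(M)
  sat <- function(i1, i2, j1, j2)
    i1 >= 1 && j2 <= n && i2 < j1 &&
      (i2 - i1 + 1) >= min_block && (j2 - j1 + 1) >= min_block &&
      mean(abs(M[i1:i2, j1:j2])) >= threshold
  out <- NULL
  for (i1 in 1:n) for (i2 in i1:n) for (j1 in 1:n) for (j2 in j1:n) {
    if (!sat(i1, i2, j1, j2)) next
    if (sat(i1 - 1, i2, j1, j2) || sat(i1, i2 + 1, j1, j2) ||
        sat(i1, i2, j1 - 1, j2) || sat(i1, i2, j1, j2 + 1)) next
    out <- rbind(out, c(i1, i2, j1, j2, mean(M[i1:i2, j1:j2])))
  }
  out
}

random_residue_graph <- function(n, p = 0.6) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  toy_graph(n, pairs[keep, 1], pairs[keep, 2],
            weight = runif(sum(keep), 0.05, 2))
}
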
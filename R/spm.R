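# Mean-distance matrix, correlation-weighted residue network, and the
# shortest-path map (SPM) summarizing internal communication.

#' Mean C-alpha distance matrix over a trajectory
#'
#' Entry `(i, j)` is the mean over frames of the Euclidean distance between
#' residues i and j. Distances are rigid-motion invariant, so no
#' superposition is applied.
#'
#' @param traj A C-alpha `md_trajectory`.
#' @return A `distance_matrix`: list with `values` (nm) and `resseq` labels.
#' @export
mean_distance_matrix <- function(traj) {
  nfr <- n_frames(traj)
  acc <- 0
  for (f in seq_len(nfr))
    acc <- acc + as.matrix(dist(traj$coords[, , f, drop = TRUE]))
  v <- acc / nfr
  dimnames(v) <- list(traj$atoms$resseq, traj$atoms$resseq)
  structure(list(values = v, resseq = traj$atoms$resseq),
            class = "distance_matrix")
}

#' Build the correlation-weighted residue graph
#'
#' An edge joins residues i != j when their mean distance is within `cutoff`
#' and their motional correlation satisfies `|c(i,j)| >= min_abs_corr`; its
#' weight is `-log(|c(i,j)|)`, so strongly correlated pairs give short paths.
#' The 1.5 nm default is the truncation distance used for residue networks
#' of this kind; `min_abs_corr` keeps weights finite where c is near 0.
#'
#' @param dist A `distance_matrix`.
#' @param dccm A normalized `xcorr_matrix` of matching shape.
#' @param cutoff Distance gate, nm (> 0).
#' @param min_abs_corr Correlation gate in (0, 1].
#' @param exclude_neighbors Drop edges between residues within this sequence
#'   separation (default 0 = keep all; 1 drops i,i+1, etc.).
#' @return A `residue_graph`: list with `nodes` (data.frame `resseq`) and
#'   `edges` (data.frame `i`, `j` 1-based indices with i < j, `resseq_i`,
#'   `resseq_j`, `dist`, `corr`, `weight`), plus `cutoff_used`.
#' @export
build_graph <- function(dist, dccm, cutoff = 1.5, min_abs_corr = 0.05,
                        exclude_neighbors = 0L) {
  stopifnot(inherits(dist, "distance_matrix"), inherits(dccm, "xcorr_matrix"))
  if (dccm$kind != "normalized") stop("dccm must be normalized")
  if (!all(dim(dist$values) == dim(dccm$values)))
    stop("shape mismatch between distance matrix and DCCM")
  if (cutoff <= 0) stop("cutoff must be positive")
  if (min_abs_corr <= 0 || min_abs_corr > 1) stop("min_abs_corr must be in (0, 1]")
  n <- nrow(dist$values)
  idx <- which(upper.tri(dist$values), arr.ind = TRUE)
  d <- dist$values[idx]; cc <- dccm$values[idx]
  keep <- d <= cutoff & abs(cc) >= min_abs_corr &
    (idx[, 2] - idx[, 1]) > exclude_neighbors
  edges <- data.frame(i = idx[keep, 1], j = idx[keep, 2],
                      resseq_i = dist$resseq[idx[keep, 1]],
                      resseq_j = dist$resseq[idx[keep, 2]],
                      dist = d[keep], corr = cc[keep],
                      weight = -log(pmin(abs(cc[keep]), 1)))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(resseq = dist$resseq),
                 edges = edges, cutoff_used = cutoff),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("residue_graph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (cutoff", x$cutoff_used, "nm)\n")
  invisible(x)
}

# Dijkstra from a single source over an adjacency list; O(n^2) scan with
# smallest-index tie-break on extraction. adj: list of data.frames (v, w, e).
.dijkstra <- function(adj, n, src) {
  dist <- rep(Inf, n); dist[src] <- 0
  done <- rep(FALSE, n)
  for (k in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    a <- adj[[u]]
    if (nrow(a) > 0L) {
      nd <- dist[u] + a$w
      upd <- nd < dist[a$v]
      dist[a$v[upd]] <- nd[upd]
    }
  }
  dist
}

#' Shortest-path map of a residue graph
#'
#' For every ordered source-target pair in the same connected component, one
#' minimum-total-weight path is found (Dijkstra distances plus greedy
#' reconstruction choosing, at each step, the smallest-index next node that
#' stays on a shortest path -- a deterministic tie-break). Each edge and node
#' on the path has its usage count incremented; counts are then normalized by
#' their maximum so weights lie in `[0, 1]`. Unreachable pairs contribute
#' nothing; an empty graph yields an empty map.
#'
#' @param graph A `residue_graph`.
#' @return An `spm_map`: list with `nodes` (resseq, usage, usage_norm) and
#'   `edges` (as in the graph, plus usage, usage_norm).
#' @export
shortest_path_map <- function(graph) {
  n <- nrow(graph$nodes)
  e <- graph$edges
  node_usage <- numeric(n)
  edge_usage <- numeric(nrow(e))
  if (n > 0L && nrow(e) > 0L) {
    adj <- lapply(seq_len(n), function(u) {
      a <- which(e$i == u); b <- which(e$j == u)
      data.frame(v = c(e$j[a], e$i[b]), w = c(e$weight[a], e$weight[b]),
                 e = c(a, b))
    })
    # one Dijkstra per target; reconstruct greedily from each source
    for (t in seq_len(n)) {
      dt <- .dijkstra(adj, n, t)
      for (s in seq_len(n)) {
        if (s == t || !is.finite(dt[s])) next
        u <- s
        visited <- rep(FALSE, n); visited[s] <- TRUE
        node_usage[s] <- node_usage[s] + 1
        while (u != t) {
          a <- adj[[u]]
          tol <- 1e-9 * max(1, dt[u])
          onpath <- !visited[a$v] & abs(a$w + dt[a$v] - dt[u]) <= tol
          if (!any(onpath))
            stop("internal error: shortest-path reconstruction stalled")
          k <- which(onpath)[which.min(a$v[onpath])]
          edge_usage[a$e[k]] <- edge_usage[a$e[k]] + 1
          u <- a$v[k]
          visited[u] <- TRUE
          node_usage[u] <- node_usage[u] + 1
        }
      }
    }
  }
  norm <- function(x) if (length(x) && max(x) > 0) x / max(x) else x
  nodes <- data.frame(resseq = graph$nodes$resseq, usage = node_usage,
                      usage_norm = norm(node_usage))
  edges <- cbind(e, usage = edge_usage, usage_norm = norm(edge_usage))
  structure(list(nodes = nodes, edges = edges), class = "spm_map")
}

#' @export
print.spm_map <- function(x, ...) {
  cat("spm_map:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges scored\n")
  invisible(x)
}

#' SPM density summary
#'
#' Counts the nodes and edges whose normalized shortest-path usage exceeds
#' `usage_floor`. Denser maps (more retained nodes/bonds) indicate a more
#' tightly coupled, conformationally stable ensemble; comparing counts across
#' temperature ensembles mirrors the usual stability reading of these maps.
#'
#' @param map An `spm_map`.
#' @param usage_floor Normalized-usage floor in `[0, 1)`.
#' @return List with `n_nodes_retained` and `n_edges_retained`.
#' @export
spm_density <- function(map, usage_floor = 0.2) {
  if (usage_floor < 0 || usage_floor >= 1)
    stop("usage_floor must be in [0, 1)")
  list(n_nodes_retained = sum(map$nodes$usage_norm > usage_floor),
       n_edges_retained = sum(map$edges$usage_norm > usage_floor))
}
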
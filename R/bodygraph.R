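#' Build a weighted body-part graph from a mean response field
#'
#' Correlates the rows of the mean body-part response field (Pearson, over
#' the 18 proximity entries) to obtain connection weights between body
#' parts, removes negative correlations, and then removes the lowest
#' `drop_fraction` of the remaining positive weights (weights tied with the
#' cutoff are removed; the count removed is `floor(drop_fraction * m)` for
#' `m` distinct positive edges). Connectivity of the thresholded graph is
#' checked; a disconnected result is reported as a warning.
#'
#' @param mu A `mean_response_field` (see [mean_body_part_prf()]) or a
#'   square matrix whose rows are mean proximity profiles.
#' @param drop_fraction Fraction of the lowest positive weights to remove.
#' @param labels Optional node labels.
#' @return Object of class `body_graph`: list with `w` (symmetric weight
#'   matrix, zero diagonal), `roi`, `labels` and a `threshold` record.
#' @export
body_graph <- function(mu, drop_fraction = 0.05, labels = NULL) {
  roi <- NA_character_
  if (inherits(mu, "mean_response_field")) {
    roi <- mu$roi
    mu <- mu$mu
  }
  mu <- as.matrix(mu)
  n <- nrow(mu)
  sds <- apply(mu, 1, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant mean response field row(s): %s",
                 paste(which(sds == 0), collapse = ", ")))
  if (is.null(labels))
    labels <- if (!is.null(rownames(mu))) rownames(mu)
              else paste0("part_", seq_len(n))
  w <- stats::cor(t(mu))
  diag(w) <- 0
  w[w < 0] <- 0
  # threshold the lowest drop_fraction of remaining positive edges
  ut <- upper.tri(w)
  pos <- w[ut & w > 0]
  k <- floor(drop_fraction * length(pos))
  cutoff <- NA_real_
  if (k > 0) {
    cutoff <- sort(pos)[k]
    w[w <= cutoff & w > 0] <- 0
  }
  dimnames(w) <- list(labels, labels)
  g <- structure(list(w = w, roi = roi, labels = labels,
                      threshold = list(drop_fraction = drop_fraction,
                                       cutoff = cutoff, n_removed = k)),
                 class = "body_graph")
  if (!graph_is_connected(w))
    warning(sprintf(
      "body graph%s is disconnected after thresholding",
      if (is.na(roi)) "" else paste0(" (", roi, ")")))
  g
}

graph_is_connected <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    nb <- which(w[u, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.body_graph <- function(x, ...) {
  ne <- sum(x$w[upper.tri(x$w)] > 0)
  cat(sprintf("Body-part graph%s: %d nodes, %d edges\n",
              if (is.na(x$roi)) "" else paste0(" (", x$roi, ")"),
              nrow(x$w), ne))
  if (!is.na(x$threshold$cutoff))
    cat(sprintf("  removed %d edge(s) at or below weight %.4f\n",
                x$threshold$n_removed, x$threshold$cutoff))
  invisible(x)
}

#' @export
plot.body_graph <- function(x, ...) {
  ig <- igraph::graph_from_adjacency_matrix(x$w, mode = "undirected",
                                            weighted = TRUE)
  plot(ig, edge.width = 4 * igraph::E(ig)$weight, ...)
  invisible(x)
}

as_weight_matrix <- function(g) {
  if (inherits(g, "body_graph")) g$w else as.matrix(g)
}

#' Weighted degree (connectivity)
#'
#' Node connectivity as the sum of incident edge weights.
#'
#' @param g A `body_graph` or symmetric weight matrix.
#' @param node Optional node index or label; all nodes if omitted.
#' @return Named numeric vector (or scalar for a single node).
#' @export
weighted_degree <- function(g, node = NULL) {
  w <- as_weight_matrix(g)
  k <- rowSums(w)
  if (is.null(node)) k else k[[node]]
}

#' Weighted clustering coefficient
#'
#' Geometric-mean triangle intensity around each node,
#' `t_i = 1/2 * sum_{j,h} (w_ij w_ih w_jh)^(1/3)`, normalised by the binary
#' neighbour count `k_i`: `C_i = 2 t_i / (k_i (k_i - 1))`, with `C_i = 0`
#' when a node has fewer than two neighbours. Weights are assumed in
#' `[0, 1]`, so `C_i` is bounded by 1.
#'
#' @inheritParams weighted_degree
#' @return Named numeric vector (or scalar for a single node).
#' @export
clustering_coefficient <- function(g, node = NULL) {
  w <- as_weight_matrix(g)
  a <- w^(1 / 3)
  t_i <- diag(a %*% a %*% a) / 2
  k_bin <- rowSums(w > 0)
  c_i <- ifelse(k_bin > 1, 2 * t_i / (k_bin * (k_bin - 1)), 0)
  names(c_i) <- rownames(w)
  if (is.null(node)) c_i else c_i[[node]]
}

# Dijkstra from one source over lengths 1/w, counting distinct shortest
# paths (Brandes sigma counts). Ties detected at relative tolerance.
dijkstra_counts <- function(w, source, rel_tol = 1e-12) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  dist <- rep(Inf, n)
  sigma <- rep(0, n)
  pred <- vector("list", n)
  dist[source] <- 0
  sigma[source] <- 1
  done <- logical(n)
  order_done <- integer(0)
  for (step in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    order_done <- c(order_done, u)
    for (v in which(len[u, ] < Inf)) {
      if (done[v]) next
      alt <- dist[u] + len[u, v]
      if (!is.finite(dist[v])) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        pred[[v]] <- u
        next
      }
      tol <- rel_tol * max(alt, dist[v], 1)
      if (alt < dist[v] - tol) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        pred[[v]] <- u
      } else if (abs(alt - dist[v]) <= tol) {
        sigma[v] <- sigma[v] + sigma[u]
        pred[[v]] <- c(pred[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, pred = pred, order = order_done)
}

#' Weighted shortest paths with path counts
#'
#' All-pairs shortest path lengths using edge length `1/weight` (Dijkstra),
#' together with the number of distinct minimal paths per pair (ties
#' detected at relative tolerance `1e-12`). Disconnected pairs have
#' infinite length and zero count.
#'
#' @inheritParams weighted_degree
#' @return List with `lengths` and `counts` (n x n matrices).
#' @export
shortest_paths_weighted <- function(g) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  cnt <- matrix(0, n, n)
  for (s in seq_len(n)) {
    res <- dijkstra_counts(w, s)
    d[s, ] <- res$dist
    cnt[s, ] <- res$sigma
  }
  cnt[!is.finite(d)] <- 0
  dimnames(d) <- dimnames(cnt) <- dimnames(w)
  list(lengths = d, counts = cnt)
}

#' Characteristic path length per node
#'
#' Mean shortest-path length from a node to all others,
#' `L_i = sum_{j != i} d_ij / (n - 1)`. Unreachable nodes yield an infinite
#' value with a warning.
#'
#' @inheritParams weighted_degree
#' @return Named numeric vector (or scalar for a single node).
#' @export
characteristic_path_length <- function(g, node = NULL) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  d <- shortest_paths_weighted(w)$lengths
  diag(d) <- NA
  L <- rowSums(d, na.rm = TRUE) / (n - 1)
  inf_rows <- apply(d, 1, function(r) any(is.infinite(r)))
  if (any(inf_rows)) {
    L[inf_rows] <- Inf
    warning("some nodes cannot reach the whole graph; infinite path length")
  }
  names(L) <- rownames(w)
  if (is.null(node)) L else L[[node]]
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between other node pairs that pass through a
#' node, normalised over unordered pairs:
#' `b_i = 1/((n-1)(n-2)) * sum_{h != j != i} rho_hj(i) / rho_hj`.
#' Computed with Brandes' dependency accumulation on weighted Dijkstra
#' searches.
#'
#' @inheritParams weighted_degree
#' @return Named numeric vector in `[0, 1]` (or scalar for a single node).
#' @export
betweenness_centrality <- function(g, node = NULL) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  b <- rep(0, n)
  for (s in seq_len(n)) {
    res <- dijkstra_counts(w, s)
    delta <- rep(0, n)
    for (v in rev(res$order)) {
      for (u in res$pred[[v]]) {
        delta[u] <- delta[u] + res$sigma[u] / res$sigma[v] * (1 + delta[v])
      }
      if (v != s) b[v] <- b[v] + delta[v]
    }
  }
  # each unordered pair {h, j} was accumulated from both endpoints;
  # the normalisation runs over unordered pairs with factor (n-1)(n-2)
  b <- (b / 2) / ((n - 1) * (n - 2))
  names(b) <- rownames(w)
  if (is.null(node)) b else b[[node]]
}

#' Weighted modularity of a partition
#'
#' Newman weighted modularity,
#' `Q = 1/l * sum_ij (w_ij - k_i k_j / l) delta(m_i, m_j)`, with `l` the
#' total weight counted over both directions and `k` the weighted degrees.
#'
#' @inheritParams weighted_degree
#' @param membership Integer module label per node.
#' @return Modularity Q.
#' @export
modularity_q <- function(g, membership) {
  w <- as_weight_matrix(g)
  stopifnot(length(membership) == nrow(w))
  l <- sum(w)
  if (l == 0) return(0)
  k <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - outer(k, k) / l) * same) / l
}

#' Louvain body-part modules
#'
#' Community detection by weighted-modularity Louvain, taking the best
#' partition over seeded restarts. The reported Q is a direct evaluation of
#' the modularity formula on the returned partition (see [modularity_q()]),
#' independent of the search.
#'
#' @inheritParams weighted_degree
#' @param seed Integer seed; restarts use `seed`, `seed + 1`, ...
#' @param restarts Number of restarts.
#' @return List with `membership` (named integer vector) and `q`.
#' @export
louvain_modules <- function(g, seed = 1L, restarts = 10L) {
  w <- as_weight_matrix(g)
  if (!nrow(w)) stop("empty graph")
  n <- nrow(w)
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    # vary the node processing order across restarts: the greedy sweep is
    # order-dependent, so permuting nodes explores more local optima
    perm <- if (r == 1L) seq_len(n) else sample(n)
    ig <- igraph::graph_from_adjacency_matrix(w[perm, perm],
                                              mode = "undirected",
                                              weighted = TRUE)
    cl <- igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight)
    m <- integer(n)
    m[perm] <- as.integer(igraph::membership(cl))
    cands <- list(refine_partition(w, m))
    if (r > 1L) {
      # a refined random partition widens the search beyond the greedy
      # Louvain basin (the sweep is order-dependent and can stall)
      k <- sample(2:max(2L, min(n - 1L, 4L)), 1L)
      cands <- c(cands, list(refine_partition(w, sample.int(k, n, TRUE))))
    }
    for (m in cands) {
      q <- modularity_q(w, m)
      if (is.null(best) || q > best$q)
        best <- list(membership = stats::setNames(m, rownames(w)), q = q)
    }
  }
  best
}

# greedy single-node refinement: move nodes between communities (or into a
# new singleton) while modularity improves; polishes the Louvain output
refine_partition <- function(w, m, max_sweeps = 20L) {
  n <- nrow(w)
  q <- modularity_q(w, m)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      cand <- unique(c(m[-i], max(m) + 1L))
      for (cc in setdiff(cand, m[i])) {
        m2 <- m
        m2[i] <- cc
        q2 <- modularity_q(w, m2)
        if (q2 > q + 1e-12) {
          m <- m2
          q <- q2
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  m
}

#' All node-level graph metrics for a body-part graph
#'
#' @inheritParams louvain_modules
#' @return Data.frame with one row per body part: `part`, `degree`,
#'   `clustering`, `betweenness`, `path_length`, `module`; the graph-level
#'   modularity is attached as attribute `q`.
#' @export
graph_metrics <- function(g, seed = 1L, restarts = 10L) {
  w <- as_weight_matrix(g)
  mods <- louvain_modules(g, seed = seed, restarts = restarts)
  out <- data.frame(
    part = if (!is.null(rownames(w))) rownames(w)
           else paste0("part_", seq_len(nrow(w))),
    degree = unname(weighted_degree(g)),
    clustering = unname(clustering_coefficient(g)),
    betweenness = unname(betweenness_centrality(g)),
    path_length = unname(characteristic_path_length(g)),
    module = unname(mods$membership),
    stringsAsFactors = FALSE)
  attr(out, "q") <- mods$q
  out
}
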
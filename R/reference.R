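#' Exhaustive reference graph metrics for small graphs
#'
#' Independent brute-force implementations of the weighted graph metrics,
#' intended as validation references on small graphs (n <= ~7): shortest
#' paths and path counts by full enumeration of simple paths, betweenness
#' by direct counting over those enumerated paths, clustering and degree by
#' explicit loops, and the maximum-modularity partition by enumerating all
#' set partitions. These are deliberately naive and independent of the
#' package's Dijkstra/Brandes code path.
#'
#' @param w Symmetric non-negative weight matrix with zero diagonal.
#' @param rel_tol Relative tolerance for shortest-path ties.
#' @return `reference_shortest_paths()`: list with `lengths`, `counts` and
#'   `paths` (per-pair list of all minimal paths). `reference_betweenness()`,
#'   `reference_clustering()`, `reference_degree()`,
#'   `reference_path_length()`: numeric vectors.
#'   `reference_best_partition()`: list with `membership` and `q`.
#' @name reference_metrics
NULL

# all simple paths between a and b, depth-first
enumerate_simple_paths <- function(w, a, b) {
  n <- nrow(w)
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == b) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in which(w[u, ] > 0)) {
      if (!(v %in% path)) walk(c(path, v))
    }
  }
  walk(a)
  paths
}

path_length_of <- function(w, path) {
  if (length(path) < 2) return(0)
  sum(1 / w[cbind(path[-length(path)], path[-1])])
}

#' @rdname reference_metrics
#' @export
reference_shortest_paths <- function(w, rel_tol = 1e-12) {
  w <- as_weight_matrix(w)
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  cnt <- matrix(0, n, n)
  diag(cnt) <- 1
  paths <- vector("list", n * n)
  dim(paths) <- c(n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    ps <- enumerate_simple_paths(w, a, b)
    if (!length(ps)) next
    lens <- vapply(ps, function(p) path_length_of(w, p), numeric(1))
    dmin <- min(lens)
    tol <- rel_tol * max(dmin, 1)
    keep <- which(lens <= dmin + tol)
    d[a, b] <- dmin
    cnt[a, b] <- length(keep)
    paths[[a, b]] <- ps[keep]
  }
  list(lengths = d, counts = cnt, paths = paths)
}

#' @rdname reference_metrics
#' @export
reference_betweenness <- function(w, rel_tol = 1e-12) {
  w <- as_weight_matrix(w)
  n <- nrow(w)
  sp <- reference_shortest_paths(w, rel_tol)
  b <- rep(0, n)
  for (h in seq_len(n - 1)) for (j in (h + 1):n) {
    ps <- sp$paths[[h, j]]
    if (is.null(ps) || !length(ps)) next
    rho <- length(ps)
    for (i in seq_len(n)) {
      if (i == h || i == j) next
      through <- sum(vapply(ps, function(p) i %in% p, logical(1)))
      b[i] <- b[i] + through / rho
    }
  }
  b / ((n - 1) * (n - 2))
}

#' @rdname reference_metrics
#' @export
reference_degree <- function(w) {
  w <- as_weight_matrix(w)
  vapply(seq_len(nrow(w)), function(i) {
    s <- 0
    for (j in seq_len(ncol(w))) s <- s + w[i, j]
    s
  }, numeric(1))
}

#' @rdname reference_metrics
#' @export
reference_clustering <- function(w) {
  w <- as_weight_matrix(w)
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    t_i <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      t_i <- t_i + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    t_i <- t_i / 2
    k <- sum(w[i, ] > 0)
    if (k > 1) 2 * t_i / (k * (k - 1)) else 0
  }, numeric(1))
}

#' @rdname reference_metrics
#' @export
reference_path_length <- function(w, rel_tol = 1e-12) {
  w <- as_weight_matrix(w)
  n <- nrow(w)
  d <- reference_shortest_paths(w, rel_tol)$lengths
  vapply(seq_len(n), function(i) sum(d[i, -i]) / (n - 1), numeric(1))
}

# enumerate all set partitions of 1..n (restricted growth strings)
set_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_label) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      rec(c(labels, lab), max(next_label, lab + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

#' @rdname reference_metrics
#' @export
reference_modularity <- function(w, membership) {
  w <- as_weight_matrix(w)
  n <- nrow(w)
  l <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) l <- l + w[i, j]
  if (l == 0) return(0)
  k <- reference_degree(w)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j])
      q <- q + w[i, j] - k[i] * k[j] / l
  }
  q / l
}

#' @rdname reference_metrics
#' @export
reference_best_partition <- function(w) {
  w <- as_weight_matrix(w)
  n <- nrow(w)
  parts <- set_partitions(n)
  qs <- vapply(parts, function(m) reference_modularity(w, m), numeric(1))
  best <- which.max(qs)
  list(membership = parts[[best]], q = qs[best])
}
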
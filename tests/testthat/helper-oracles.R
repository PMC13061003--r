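# Independent oracles used to cross-check package implementations.
# Everything here is deliberately naive: adjacency lists + hand BFS/DFS,
# eigen-decomposition, exhaustive enumeration. None of it calls the package
# functions it is used to verify.

# adjacency list from a two-column character edge matrix (undirected)
adj_list <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(as.vector(edges)))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# plain breadth-first search distances from one source
bfs_distances <- function(adj, source) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[source] <- 0
  queue <- source
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# literal evaluation of the closest-proximity formula from BFS distances
oracle_closest_proximity <- function(targets, disease, adj) {
  per_target <- vapply(targets, function(t) {
    d <- bfs_distances(adj, t)
    min(d[disease])
  }, numeric(1))
  mean(per_target)
}

# stationary distribution as the leading left eigenvector
oracle_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# exhaustive DFS enumeration of simple drug->target->...->disease-gene paths
# of at most max_edges edges (drug->target is edge 1); mediators that are
# disease genes are skipped for 3-edge paths, mirroring the reporting rule
oracle_paths <- function(targets, disease, adj, max_edges = 3,
                         exclude_disease_mediators = TRUE) {
  rows <- list()
  for (t in intersect(targets, names(adj))) {
    if (t %in% disease) {
      rows[[length(rows) + 1]] <- c(target = t, mediator = NA, gene = t, n = 1)
    }
    if (max_edges >= 2) {
      for (g in intersect(adj[[t]], disease)) {
        if (g != t) rows[[length(rows) + 1]] <- c(target = t, mediator = NA, gene = g, n = 2)
      }
    }
    if (max_edges >= 3) {
      for (m in setdiff(adj[[t]], t)) {
        if (exclude_disease_mediators && m %in% disease) next
        for (g in intersect(adj[[m]], disease)) {
          if (g != t && g != m) {
            rows[[length(rows) + 1]] <- c(target = t, mediator = m, gene = g, n = 3)
          }
        }
      }
    }
  }
  if (length(rows) == 0) return(character(0))
  sort(vapply(rows, paste, character(1), collapse = "|"))
}

# brute-force modified Kendall distance by literal case analysis per pair
oracle_kendall <- function(a, b, p, k) {
  ta <- head(a, k); tb <- head(b, k)
  u <- union(ta, tb)
  if (length(u) < 2) return(0)
  total <- 0; npair <- 0
  for (i in seq_along(u)[-length(u)]) for (j in (i + 1):length(u)) {
    x <- u[i]; y <- u[j]; npair <- npair + 1
    ax <- match(x, ta); ay <- match(y, ta)
    bx <- match(x, tb); by <- match(y, tb)
    in_ax <- !is.na(ax); in_ay <- !is.na(ay)
    in_bx <- !is.na(bx); in_by <- !is.na(by)
    if (in_ax && in_ay && in_bx && in_by) {
      total <- total + as.numeric((ax < ay) != (bx < by))
    } else if (in_ax && in_ay && xor(in_bx, in_by)) {
      total <- total + as.numeric(if (in_bx) ay < ax else ax < ay)
    } else if (in_bx && in_by && xor(in_ax, in_ay)) {
      total <- total + as.numeric(if (in_ax) by < bx else bx < by)
    } else if ((in_ax && !in_ay && !in_bx && in_by) ||
               (!in_ax && in_ay && in_bx && !in_by)) {
      total <- total + 1
    } else {
      total <- total + p  # both in one top-k, neither in the other
    }
  }
  total / npair
}

# all permutations of a small vector
all_permutations <- function(items) {
  if (length(items) == 1) return(list(items))
  out <- list()
  for (i in seq_along(items)) {
    for (rest in all_permutations(items[-i])) {
      out[[length(out) + 1]] <- c(items[i], rest)
    }
  }
  out
}

# random connected-ish Erdos-Renyi style test graph as an igraph + edge matrix
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}
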
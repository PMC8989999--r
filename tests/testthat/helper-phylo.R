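# Tree-oracle helpers: exhaustive unrooted-topology enumeration with a
# least-squares branch-length fit, independent of the NJ implementation.
# Trees here are plain integer edge matrices over node ids (tips 1..n,
# internals > n), so the oracle shares no code with the package.

# all unrooted binary topologies on n labelled tips (n >= 3)
enum_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- list(list(edges = rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)),
                    next_node = n + 2L))
  trees <- base
  for (tip in seq_len(n)[-(1:3)]) {
    out <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        w <- tr$next_node
        u <- tr$edges[e, 1]; v <- tr$edges[e, 2]
        edges <- rbind(tr$edges[-e, , drop = FALSE],
                       c(u, w), c(w, v), c(w, tip))
        out[[length(out) + 1L]] <- list(edges = edges, next_node = w + 1L)
      }
    }
    trees <- out
  }
  lapply(trees, `[[`, "edges")
}

.adjacency <- function(edges) {
  nmax <- max(edges)
  adj <- vector("list", nmax)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    adj[[u]] <- rbind(adj[[u]], c(v, i))
    adj[[v]] <- rbind(adj[[v]], c(u, i))
  }
  adj
}

# edge indices on the path between two tips
.path_edges <- function(adj, from, to) {
  prev <- integer(length(adj)); prev_edge <- integer(length(adj))
  seen <- logical(length(adj)); seen[from] <- TRUE
  q <- from
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    if (v == to) break
    for (r in seq_len(nrow(adj[[v]] %||% matrix(0, 0, 2)))) {
      w <- adj[[v]][r, 1]
      if (!seen[w]) {
        seen[w] <- TRUE; prev[w] <- v; prev_edge[w] <- adj[[v]][r, 2]
        q <- c(q, w)
      }
    }
  }
  path <- integer(0); v <- to
  while (v != from) { path <- c(path, prev_edge[v]); v <- prev[v] }
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# least-squares branch lengths for a fixed topology; returns RSS and the
# fitted tip-to-tip distances
ls_fit_topology <- function(edges, d) {
  n <- nrow(d)
  adj <- .adjacency(edges)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (p in seq_len(nrow(pairs))) {
    pe <- .path_edges(adj, pairs[p, 1], pairs[p, 2])
    A[p, pe] <- 1
  }
  b <- d[upper.tri(d)]
  coef <- qr.coef(qr(A), b)
  coef[is.na(coef)] <- 0
  fit <- A %*% coef
  list(rss = sum((fit - b)^2), fitted = fit, b = b, coef = coef)
}

# canonical internal splits of an edge-matrix tree, as sorted label strings
splits_of_edges <- function(edges, labels) {
  n <- length(labels)
  adj <- .adjacency(edges)
  out <- character(0)
  for (e in seq_len(nrow(edges))) {
    # tips reachable from edges[e,1] without crossing edge e
    seen <- logical(length(adj)); seen[edges[e, 1]] <- TRUE
    q <- edges[e, 1]
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      av <- adj[[v]]
      for (r in seq_len(nrow(av %||% matrix(0, 0, 2)))) {
        if (av[r, 2] == e) next
        w <- av[r, 1]
        if (!seen[w]) { seen[w] <- TRUE; q <- c(q, w) }
      }
    }
    side <- sort(labels[which(seen[seq_len(n)])])
    if (length(side) >= 2 && length(side) <= n - 2) {
      ref <- sort(labels)[1]
      if (!ref %in% side) side <- sort(setdiff(labels, side))
      out <- c(out, paste(side, collapse = "|"))
    }
  }
  sort(unique(out))
}

# canonical internal splits of an ape phylo tree
splits_of_phylo <- function(tr) {
  labels <- tr$tip.label
  n <- length(labels)
  edges <- tr$edge
  splits_of_edges(edges, labels)
}

# best topology by exhaustive least squares (n <= 6 to stay fast)
ls_best_tree <- function(d) {
  n <- nrow(d)
  stopifnot(n <= 6)
  topos <- enum_topologies(n)
  rss <- vapply(topos, function(e) ls_fit_topology(e, d)$rss, numeric(1))
  best <- which.min(rss)
  list(edges = topos[[best]],
       splits = splits_of_edges(topos[[best]], rownames(d)),
       rss = rss[best])
}

# random tree with strictly positive branch lengths and its additive matrix
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  d <- ape::cophenetic.phylo(tr)
  d <- d[sort(rownames(d)), sort(rownames(d))]
  list(tree = tr, d = d)
}
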
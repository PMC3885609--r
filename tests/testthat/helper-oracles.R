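# Independent oracles, deliberately implemented apart from the code paths
# they check.

# ---- brute-force pattern embedding enumeration ----
# counts automorphism-distinct embeddings (distinct image atom sets) of a
# rule's pattern in a target by exhaustive enumeration of injective
# assignments, re-implementing the match semantics directly from the rule's
# pattern table
oracle_embedding_count <- function(rule, target) {
  pat <- rule$pattern
  pb <- rule$pattern_bonds
  np <- nrow(pat)
  nt <- nrow(target$atoms)
  if (np > nt) return(0L)
  inring <- rpe:::.ring_atoms(target)
  bond_order <- matrix(0L, nt, nt)
  if (nrow(target$bonds)) {
    for (k in seq_len(nrow(target$bonds))) {
      i <- target$bonds$a1[k]; j <- target$bonds$a2[k]
      bond_order[i, j] <- bond_order[j, i] <- target$bonds$order[k]
    }
  }
  atom_ok <- function(p, t) {
    target$atoms$element[t] == pat$element[p] &&
      target$atoms$aromatic[t] == pat$aromatic[p] &&
      inring[t] == pat$inring[p] &&
      (!pat$is_center[p] ||
         (target$atoms$charge[t] == pat$charge[p] &&
            target$atoms$hcount[t] == pat$hcount[p]))
  }
  images <- character(0)
  assign <- integer(np)
  rec <- function(p) {
    if (p > np) {
      images <<- c(images, paste(sort(assign), collapse = ","))
      return(invisible(NULL))
    }
    for (t in seq_len(nt)) {
      if (t %in% assign[seq_len(p - 1L)]) next
      if (!atom_ok(p, t)) next
      ok <- TRUE
      if (nrow(pb)) {
        for (k in seq_len(nrow(pb))) {
          q <- NULL
          if (pb$i[k] == p && pb$j[k] < p) q <- pb$j[k]
          if (pb$j[k] == p && pb$i[k] < p) q <- pb$i[k]
          if (!is.null(q) && bond_order[t, assign[q]] != pb$order[k]) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      assign[p] <<- t
      rec(p + 1L)
      assign[p] <<- 0L
    }
    invisible(NULL)
  }
  rec(1L)
  length(unique(images))
}

# ---- brute-force tree topology search ----
# enumerate all unrooted binary topologies on the given taxa by sequential
# leaf insertion; each topology is an edge list over nodes (tips 1..n,
# internals n+1..)
oracle_all_topologies <- function(n) {
  # start from the 3-taxon star: internal node n+1
  start <- list(edges = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
                next_node = n + 2)
  trees <- list(start)
  for (leaf in seq_len(n)[-(1:3)]) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        ed <- tr$edges
        u <- tr$next_node
        a <- ed[e, 1]; b <- ed[e, 2]
        ed2 <- rbind(ed[-e, , drop = FALSE], c(a, u), c(u, b), c(u, leaf))
        nxt[[length(nxt) + 1L]] <- list(edges = ed2, next_node = u + 1)
      }
    }
    trees <- nxt
  }
  trees
}

# least-squares fit of edge lengths for a topology against a distance
# matrix; returns the residual sum of squares (0 for the true topology of an
# exactly additive matrix)
oracle_ls_residual <- function(topology, d) {
  n <- nrow(d)
  ed <- topology$edges
  ne <- nrow(ed)
  nn <- max(ed)
  adj <- vector("list", nn)
  for (k in seq_len(ne)) {
    adj[[ed[k, 1]]] <- rbind(adj[[ed[k, 1]]], c(ed[k, 2], k))
    adj[[ed[k, 2]]] <- rbind(adj[[ed[k, 2]]], c(ed[k, 1], k))
  }
  path_edges <- function(from, to) {
    # BFS recording the edge sequence
    prev <- rep(NA_integer_, nn); prev_edge <- rep(NA_integer_, nn)
    queue <- from; seen <- logical(nn); seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == to) break
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1]
        if (!seen[w]) {
          seen[w] <- TRUE; prev[w] <- v; prev_edge[w] <- nb[r, 2]
          queue <- c(queue, w)
        }
      }
    }
    out <- integer(0); v <- to
    while (!is.na(prev[v])) { out <- c(out, prev_edge[v]); v <- prev[v] }
    out
  }
  pairs <- utils::combn(n, 2)
  X <- matrix(0, ncol(pairs), ne)
  y <- numeric(ncol(pairs))
  for (c0 in seq_len(ncol(pairs))) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    X[c0, path_edges(i, j)] <- 1
    y[c0] <- d[i, j]
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# canonical split-set key of a topology (for comparing topologies)
oracle_topology_splits <- function(topology, labels) {
  n <- length(labels)
  ed <- topology$edges
  adj <- vector("list", max(ed))
  for (k in seq_len(nrow(ed))) {
    adj[[ed[k, 1]]] <- c(adj[[ed[k, 1]]], ed[k, 2])
    adj[[ed[k, 2]]] <- c(adj[[ed[k, 2]]], ed[k, 1])
  }
  reach <- function(start, blocked) {
    seen <- c(start); queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (w == blocked && v == start) next
        if (!(w %in% seen) && !(v == start && w == blocked)) {
          seen <- c(seen, w); queue <- c(queue, w)
        }
      }
    }
    seen
  }
  keys <- character(0)
  ref <- sort(labels)[1]
  for (k in seq_len(nrow(ed))) {
    a <- ed[k, 1]; b <- ed[k, 2]
    if (a <= n || b <= n) next  # pendant edge -> trivial split
    # tips on b's side of edge (a,b)
    seen <- b; queue <- b
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == b && w == a) next
        if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
      }
    }
    tips <- labels[sort(seen[seen <= n])]
    side <- if (ref %in% tips) setdiff(labels, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  paste(sort(unique(keys)), collapse = " ;; ")
}

# split-set key of an rpe gene tree (via the package's split extractor is
# avoided: recompute from the phylo edge matrix directly)
oracle_phylo_splits <- function(phy) {
  n <- length(phy$tip.label)
  labels <- phy$tip.label
  ref <- sort(labels)[1]
  keys <- character(0)
  for (node in (n + 1L):(n + phy$Nnode)) {
    stack <- node; tips <- integer(0)
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      kids <- phy$edge[phy$edge[, 1] == v, 2]
      tips <- c(tips, kids[kids <= n])
      stack <- c(stack, kids[kids > n])
    }
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    tl <- labels[sort(tips)]
    side <- if (ref %in% tl) setdiff(labels, tl) else tl
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  paste(sort(unique(keys)), collapse = " ;; ")
}

# additive distance matrix from a random binary tree on n labeled taxa
oracle_random_additive <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n, tip.label = paste0("t", sprintf("%02d", seq_len(n))))
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.5, 2)
  d <- ape::cophenetic.phylo(phy)
  ord <- order(rownames(d))
  list(d = d[ord, ord], phy = ape::unroot(phy))
}
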
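# Shared fixtures and brute-force oracles built in code at test time.

make_table <- function(m, samples = NULL, otus = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(m)))
  if (is.null(otus)) otus <- paste0("OTU_", seq_len(ncol(m)))
  dimnames(m) <- list(samples, otus)
  otu_table(m)
}

labelled_dist <- function(pts, ids = NULL) {
  d <- as.matrix(dist(pts))
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  d
}

random_interaction <- function(nr, nc, lambda = 3, zero_frac = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(nr * nc, lambda), nr, nc)
    m[sample(nr * nc, round(zero_frac * nr * nc))] <- 0L
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      return(interaction_matrix(m))
    }
  }
}

# Enumerate every nonnegative integer table with the given marginals.
enumerate_tables <- function(r, cc) {
  out <- list()
  compositions <- function(total, caps) {
    if (length(caps) == 1L) {
      if (total <= caps) return(list(total)) else return(list())
    }
    res <- list()
    for (v in 0:min(total, caps[1])) {
      for (rest in compositions(total - v, caps[-1])) {
        res[[length(res) + 1L]] <- c(v, rest)
      }
    }
    res
  }
  rec <- function(rows_left, cc_rem, acc) {
    if (length(rows_left) == 0L) {
      out[[length(out) + 1L]] <<- do.call(rbind, acc)
      return(invisible())
    }
    for (row in compositions(rows_left[1], cc_rem)) {
      rec(rows_left[-1], cc_rem - row, c(acc, list(row)))
    }
  }
  rec(r, cc, list())
  out
}

table_entropy <- function(w) {
  p <- w[w > 0] / sum(w)
  -sum(p * log(p))
}

# All set partitions of n items as restricted-growth strings.
set_partitions <- function(n) {
  out <- list()
  rec <- function(s, mx) {
    if (length(s) == n) {
      out[[length(out) + 1L]] <<- s
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(s, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Barber bipartite modularity of a fixed joint partition.
barber_q <- function(w, g) {
  W <- sum(w)
  b <- w / W - outer(rowSums(w), colSums(w)) / W^2
  np <- nrow(w)
  sum(b * outer(g[seq_len(np)], g[-seq_len(np)], `==`))
}

# Brute-force patristic distance: sum of branch lengths on the tip-to-tip
# path through the rooted tree, found by walking both tips to the root.
path_distance <- function(tree, a, b) {
  parent_edge <- function(node) which(tree$edge[, 2] == node)
  to_root <- function(tip) {
    node <- which(tree$tip.label == tip)
    path <- numeric(0)
    nodes <- node
    repeat {
      e <- parent_edge(node)
      if (length(e) == 0L) break
      path <- c(path, tree$edge.length[e])
      node <- tree$edge[e, 1]
      nodes <- c(nodes, node)
    }
    list(nodes = nodes, cum = cumsum(c(0, path)))
  }
  pa <- to_root(a)
  pb <- to_root(b)
  shared <- intersect(pa$nodes, pb$nodes)
  mrca <- shared[1L]
  pa$cum[match(mrca, pa$nodes)] + pb$cum[match(mrca, pb$nodes)]
}
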
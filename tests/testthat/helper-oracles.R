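# Independent oracles used by the tests. These re-derive expected values by
# brute force / exhaustive dynamic programming and never call the package
# code paths they check.

# exhaustive affine-gap semi-global DP: pattern aligned end to end, free
# end gaps in the subject. Gap of length L costs open + (L-1)*extend.
oracle_semiglobal_score <- function(pattern, subject,
                                    match = 1, mismatch = -2,
                                    open = 6, extend = 1) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  np <- length(p); ns <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, np + 1L, ns + 1L)  # p_i aligned to s_j
  P <- matrix(NEG, np + 1L, ns + 1L)  # p_i aligned to gap
  Q <- matrix(NEG, np + 1L, ns + 1L)  # s_j aligned to gap (internal del)
  M[1L, ] <- 0                        # free leading subject
  for (i in 1L:np) {
    P[i + 1L, 1L] <- max(M[i, 1L] - open, P[i, 1L] - extend)
    for (j in seq_len(ns)) {
      sub <- if (p[i] == s[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], P[i, j], Q[i, j]) + sub
      P[i + 1L, j + 1L] <- max(M[i, j + 1L] - open, P[i, j + 1L] - extend,
                               Q[i, j + 1L] - open)
      Q[i + 1L, j + 1L] <- max(M[i + 1L, j] - open, Q[i + 1L, j] - extend,
                               P[i + 1L, j] - open)
    }
  }
  max(M[np + 1L, ], P[np + 1L, ])     # trailing subject free
}

# per-column brute-force variant tally (substitutions only), independent of
# find_candidate_variants
oracle_column_tally <- function(m, parent, min_support) {
  out <- list()
  for (pos in seq_along(parent)) {
    if (!parent[pos] %in% c("A", "C", "G", "T")) next
    for (b in setdiff(c("A", "C", "G", "T"), parent[pos])) {
      supp <- sum(m[, pos] == b)
      if (supp >= min_support) {
        out[[length(out) + 1L]] <- data.frame(pos = pos, alt = b,
                                              support = supp)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(), alt = character(), support = integer())
}

# exact minimum Steiner tree cost for haplotypes over binary characters:
# Dreyfus-Wagner over the whole weighted hypercube {0,1}^k
oracle_steiner_cost <- function(term_states, weights) {
  k <- ncol(term_states)
  stopifnot(k <= 10)
  V <- 2^k
  bitsm <- t(vapply(0:(V - 1L), function(v) as.integer(intToBits(v))[1:k],
                    integer(k)))
  D <- matrix(0, V, V)
  for (j in 1:k) D <- D + weights[j] * outer(bitsm[, j], bitsm[, j], "!=")
  tid <- apply(term_states, 1L, function(r) sum(r * 2^(0:(k - 1L)))) + 1L
  tid <- unique(tid)
  if (length(tid) <= 1L) return(0)
  root <- tid[1L]; terms <- tid[-1L]; tt <- length(terms)
  S <- matrix(Inf, 2^tt - 1L, V)
  for (i in seq_len(tt)) S[2^(i - 1L), ] <- D[terms[i], ]
  masks <- order(vapply(1:(2^tt - 1L), function(m) sum(as.integer(intToBits(m))),
                        integer(1)))
  for (mask in masks) {
    if (sum(as.integer(intToBits(mask))) < 2L) next
    tmp <- rep(Inf, V)
    sub <- bitwAnd(mask - 1L, mask)
    while (sub > 0L) {
      other <- mask - sub
      if (sub < other) { sub <- bitwAnd(sub - 1L, mask); next }  # each split once
      tmp <- pmin(tmp, S[sub, ] + S[other, ])
      sub <- bitwAnd(sub - 1L, mask)
    }
    ## metric relaxation (D is the exact hypercube metric)
    S[mask, ] <- apply(tmp + D, 2L, min)
  }
  S[2^tt - 1L, root]
}

# random compatible binary character data: characters mark the edges of a
# random rooted tree, taxa are a subset of its nodes
make_compatible_matrix <- function(n_taxa, n_chars) {
  nodes <- list(rep(0L, n_chars))
  for (ch in seq_len(n_chars)) {
    parent <- nodes[[sample.int(length(nodes), 1L)]]
    child <- parent
    child[ch] <- 1L
    nodes[[length(nodes) + 1L]] <- child
  }
  keys <- vapply(nodes, paste, character(1), collapse = "")
  nodes <- nodes[!duplicated(keys)]
  pick <- sample.int(length(nodes), min(n_taxa, length(nodes)))
  mat <- do.call(rbind, nodes[pick])
  rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  mat
}

# Kruskal MST cost on a distance matrix (independent of the package Prim)
oracle_mst_cost <- function(D) {
  n <- nrow(D)
  if (n <= 1L) return(0)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  o <- order(D[upper.tri(D)])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  total <- 0; used <- 0L
  for (idx in o) {
    u <- find(pairs[idx, 1L]); v <- find(pairs[idx, 2L])
    if (u != v) {
      parent[u] <- v
      total <- total + D[pairs[idx, 1L], pairs[idx, 2L]]
      used <- used + 1L
      if (used == n - 1L) break
    }
  }
  total
}

# all spanning trees of a small graph (edge data.frame from/to/weight over
# vertex ids); returns list of edge-index vectors
oracle_spanning_trees <- function(edges, vertices) {
  n <- length(vertices)
  if (n <= 1L) return(list(integer()))
  combos <- utils::combn(nrow(edges), n - 1L, simplify = FALSE)
  Filter(function(sel) {
    sub <- edges[sel, , drop = FALSE]
    parent <- stats::setNames(vertices, vertices)
    find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
    for (e in seq_len(nrow(sub))) {
      u <- find(as.character(sub$from[e])); v <- find(as.character(sub$to[e]))
      if (u == v) return(FALSE)
      parent[[u]] <- v
    }
    TRUE
  }, combos)
}

# weighted shortest-path distances by Floyd-Warshall on a haplotype network
oracle_graph_distances <- function(net) {
  n <- nrow(net$nodes)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (e in seq_len(nrow(net$links))) {
    i <- net$links$from[e]; j <- net$links$to[e]
    D[i, j] <- D[j, i] <- min(D[i, j], net$links$weight[e])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  }
  D
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
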
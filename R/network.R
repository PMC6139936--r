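#' Condense aligned sequences into a character matrix
#'
#' Removes constant columns, merges identical columns (summing their
#' weights) and collapses identical sequences into haplotypes with
#' multiplicities. Gaps (`-`) are a fifth character state, so a shared
#' deletion separates haplotypes exactly like a substitution.
#'
#' @param sequences named character vector of equal-length aligned
#'   sequences
#' @param weights optional per-column weights (default 1)
#' @return a `character_matrix`: list with `hap` (haplotype x condensed
#'   column state matrix), `weights`, `col_pos` (original positions backing
#'   each condensed column), `taxa`, `hap_of_taxon`, `multiplicity`
#' @export
condense_characters <- function(sequences, weights = NULL) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("sequences must be of equal length")
  m <- do.call(rbind, lapply(sequences, seq_chars))
  if (is.null(weights)) weights <- rep(1, ncol(m))
  stopifnot(length(weights) == ncol(m))
  variable <- apply(m, 2L, function(col) length(unique(col)) > 1L)
  mv <- m[, variable, drop = FALSE]
  wv <- weights[variable]
  pos <- which(variable)
  ## merge identical columns
  key <- apply(mv, 2L, paste, collapse = "")
  groups <- split(seq_along(key), key)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  cond <- vapply(groups, function(g) mv[, g[1L]], character(nrow(mv)))
  if (nrow(mv) == 1L) cond <- matrix(cond, nrow = 1L)
  w <- vapply(groups, function(g) sum(wv[g]), numeric(1))
  col_pos <- lapply(groups, function(g) pos[g])
  ## collapse identical sequences
  hkey <- apply(cond, 1L, paste, collapse = "")
  hgroups <- split(seq_along(hkey), hkey)
  hgroups <- hgroups[order(vapply(hgroups, min, integer(1)))]
  hap <- do.call(rbind, lapply(hgroups, function(g) cond[g[1L], , drop = TRUE]))
  if (ncol(cond) == 0L) hap <- matrix(character(), length(hgroups), 0L)
  if (ncol(cond) == 1L) hap <- matrix(hap, ncol = 1L)
  hap_names <- vapply(hgroups, function(g)
    paste(names(sequences)[g], collapse = ","), character(1))
  rownames(hap) <- hap_names
  hap_of_taxon <- setNames(rep(hap_names, vapply(hgroups, length, integer(1))),
                           names(sequences)[unlist(hgroups)])
  structure(list(hap = hap, weights = unname(w), col_pos = col_pos,
                 taxa = names(sequences),
                 hap_of_taxon = hap_of_taxon[names(sequences)],
                 multiplicity = setNames(vapply(hgroups, length, integer(1)),
                                         hap_names)),
            class = "character_matrix")
}

## weighted Hamming distance matrix between rows of a state matrix
state_dist <- function(states, weights) {
  n <- nrow(states)
  D <- matrix(0, n, n)
  for (j in seq_len(ncol(states))) {
    D <- D + weights[j] * outer(states[, j], states[, j], "!=")
  }
  D
}

## Prim MST total cost on a full distance matrix
mst_cost <- function(D) {
  n <- nrow(D)
  if (n <= 1L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1L, ]
  total <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    total <- total + best[j]
    in_tree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  total
}

## minimum spanning network at tolerance epsilon: edge (u,v) kept iff
## d(u,v) <= connection level of u,v + epsilon (epsilon = 0 gives the union
## of all minimum spanning trees)
msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  if (n <= 1L) return(data.frame(from = integer(), to = integer(),
                                 weight = numeric()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  conn <- matrix(Inf, n, n)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  o <- order(D[upper.tri(D)])
  comp_members <- as.list(seq_len(n))
  for (idx in o) {
    u <- pairs[idx, 1L]; v <- pairs[idx, 2L]
    ru <- find(u); rv <- find(v)
    if (ru != rv) {
      for (a in comp_members[[ru]]) for (b in comp_members[[rv]]) {
        conn[a, b] <- conn[b, a] <- D[u, v]
      }
      parent[rv] <- ru
      comp_members[[ru]] <- c(comp_members[[ru]], comp_members[[rv]])
    }
  }
  keep <- which(upper.tri(D) & D <= conn + epsilon, arr.ind = TRUE)
  data.frame(from = keep[, 1L], to = keep[, 2L],
             weight = D[keep])
}

## quasi-median(s) of three state vectors: per-column majority where one
## exists, else every observed state (combinations enumerated)
quasi_medians <- function(u, v, w) {
  cols <- lapply(seq_along(u), function(j) {
    s <- c(u[j], v[j], w[j])
    tab <- table(s)
    if (max(tab) >= 2L) names(tab)[which.max(tab)] else sort(unique(s))
  })
  grid <- expand.grid(cols, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.character(unlist(grid[i, ])))
}

#' Median-joining network construction
#'
#' Builds the minimum spanning network of the haplotypes at tolerance
#' `epsilon`, then repeatedly evaluates quasi-median (Steiner) vectors of
#' linked triplets and adds, one at a time, the median vector that most
#' reduces the total cost of connecting all current nodes, until no
#' candidate improves it; obsolete median vectors are purged and the
#' minimum spanning network of the final node set is returned. Epsilon 0
#' and uniform weights reproduce a "default settings" run. Deterministic:
#' triplets are evaluated in sorted order and ties broken on the state
#' string.
#'
#' @param cm a `character_matrix` from [condense_characters()]
#' @param epsilon non-negative tolerance (default 0)
#' @param max_medians hard cap on median vectors (default 10000; exceeding
#'   it is an error)
#' @return a `haplotype_network`: list with `nodes` (data.frame `id`,
#'   `label`, `sampled`, `states`), `states` matrix, `links` (data.frame
#'   `from`, `to`, `weight` in weighted character differences), `weights`,
#'   `epsilon`
#' @export
median_joining <- function(cm, epsilon = 0, max_medians = 10000L) {
  stopifnot(inherits(cm, "character_matrix"), epsilon >= 0)
  states <- cm$hap
  n_sampled <- nrow(states)
  if (n_sampled < 2L) stop("need at least 2 haplotypes")
  labels <- rownames(states)
  sampled <- rep(TRUE, n_sampled)
  w <- cm$weights
  n_median <- 0L

  repeat {
    D <- state_dist(states, w)
    edges <- msn_edges(D, epsilon)
    cur_cost <- mst_cost(D)
    ## connected triplets: u - v - w sharing the middle node v
    adj <- lapply(seq_len(nrow(states)), function(i)
      sort(unique(c(edges$to[edges$from == i], edges$from[edges$to == i]))))
    seen <- character()
    node_keys <- apply(states, 1L, paste, collapse = "")
    best_cost <- cur_cost; best_m <- NULL; best_key <- ""
    cands <- list()
    for (v in seq_len(nrow(states))) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      for (a in seq_along(nb)) for (b in seq_along(nb)) {
        if (a >= b) next
        for (m in quasi_medians(states[nb[a], ], states[v, ], states[nb[b], ])) {
          key <- paste(m, collapse = "")
          if (key %in% seen || key %in% node_keys) next
          seen <- c(seen, key)
          cands[[key]] <- m
          new_cost <- mst_cost(state_dist(rbind(states, m), w))
          if (new_cost < cur_cost - 1e-9 &&
              (new_cost < best_cost - 1e-9 ||
               (abs(new_cost - best_cost) < 1e-9 && key < best_key))) {
            best_cost <- new_cost; best_m <- m; best_key <- key
          }
        }
      }
    }
    add <- if (!is.null(best_m)) list(best_m) else NULL
    if (is.null(add) && length(cands) >= 2L && length(cands) <= 80L &&
        nrow(states) <= 60L) {
      ## two-step lookahead: a pair of median vectors can reduce the cost
      ## where neither does alone (two Steiner points supporting each other)
      keys <- sort(names(cands))
      pair_cost <- cur_cost; pair <- NULL
      for (i in seq_along(keys)) for (j in seq_along(keys)) {
        if (i >= j) next
        nc <- mst_cost(state_dist(rbind(states, cands[[keys[i]]],
                                        cands[[keys[j]]]), w))
        if (nc < pair_cost - 1e-9) {
          pair_cost <- nc
          pair <- list(cands[[keys[i]]], cands[[keys[j]]])
        }
      }
      add <- pair
    }
    if (is.null(add)) break
    for (m in add) {
      n_median <- n_median + 1L
      if (n_median > max_medians) stop("median vector cap exceeded")
      states <- rbind(states, m)
      labels <- c(labels, sprintf("mv%d", n_median))
      sampled <- c(sampled, FALSE)
    }
    rownames(states) <- labels
  }

  ## purge: drop any median whose removal does not raise the connection cost
  repeat {
    D <- state_dist(states, w)
    total <- mst_cost(D)
    drop <- NULL
    for (i in which(!sampled)) {
      if (mst_cost(D[-i, -i, drop = FALSE]) <= total + 1e-9) { drop <- i; break }
    }
    if (is.null(drop)) break
    states <- states[-drop, , drop = FALSE]
    labels <- labels[-drop]
    sampled <- sampled[-drop]
  }

  D <- state_dist(states, w)
  links <- msn_edges(D, epsilon)
  structure(list(nodes = data.frame(id = seq_len(nrow(states)),
                                    label = labels, sampled = sampled,
                                    states = apply(states, 1L, paste,
                                                   collapse = "")),
                 states = states, links = links, weights = w,
                 epsilon = epsilon, root = NA_integer_),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$sampled), "sampled ),", nrow(x$links), "links\n")
  invisible(x)
}

## all subsets of a vector (including the empty set)
all_subsets <- function(x) {
  if (!length(x)) return(list(integer()))
  unlist(lapply(0:length(x), function(k)
    if (k == 0L) list(integer()) else
      apply(combn(x, k), 2L, identity, simplify = FALSE)), recursive = FALSE)
}

## minimum Steiner forestry within the network: for every subset of median
## vectors, the MST of the induced subgraph (network links only); returns
## the minimal cost and, for each achieving subset, the links lying on at
## least one minimum spanning tree of that induced subgraph
steiner_within <- function(net) {
  terminals <- which(net$nodes$sampled)
  medians <- which(!net$nodes$sampled)
  if (length(medians) > 18L) {
    stop("mp post-processing supports at most 18 median vectors (got ",
         length(medians), ")")
  }
  links <- net$links
  best_cost <- Inf; kept_links <- logical(nrow(links)); kept_nodes <- logical(nrow(net$nodes))
  for (S in all_subsets(medians)) {
    vs <- c(terminals, S)
    sel <- which(links$from %in% vs & links$to %in% vs)
    if (length(sel) < length(vs) - 1L) next
    sub <- links[sel, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = match(sub$from, vs), to = match(sub$to, vs),
                 weight = sub$weight),
      directed = FALSE, vertices = data.frame(name = seq_along(vs)))
    if (igraph::components(g)$no > 1L) next
    mstg <- igraph::mst(g, weights = igraph::E(g)$weight)
    cost <- sum(igraph::E(mstg)$weight)
    if (cost < best_cost - 1e-9) {
      best_cost <- cost
      kept_links[] <- FALSE; kept_nodes[] <- FALSE
    }
    if (cost <= best_cost + 1e-9) {
      ## an edge lies on some MST iff its endpoints are in different
      ## components of the strictly-lighter subgraph
      for (e in seq_along(sel)) {
        lighter <- sub[sub$weight < sub$weight[e] - 1e-9, , drop = FALSE]
        gl <- igraph::graph_from_data_frame(
          data.frame(from = match(lighter$from, vs), to = match(lighter$to, vs)),
          directed = FALSE, vertices = data.frame(name = seq_along(vs)))
        comp <- igraph::components(gl)$membership
        if (comp[match(sub$from[e], vs)] != comp[match(sub$to[e], vs)]) {
          kept_links[sel[e]] <- TRUE
        }
      }
      kept_nodes[vs] <- TRUE
    }
  }
  list(cost = best_cost, kept_links = kept_links, kept_nodes = kept_nodes)
}

#' Maximum-parsimony post-processing of a median-joining network
#'
#' Retains exactly the links and median vectors that lie on at least one
#' most-parsimonious (minimum total weight) tree connecting the sampled
#' haplotypes within the network; sampled haplotypes are never removed and
#' the length of the shortest spanning tree within the network is
#' unchanged.
#'
#' @param net a `haplotype_network`
#' @return the pruned `haplotype_network`
#' @export
mp_postprocess <- function(net) {
  sw <- steiner_within(net)
  keep <- which(sw$kept_nodes | net$nodes$sampled)
  remap <- match(seq_len(nrow(net$nodes)), keep)
  links <- net$links[sw$kept_links, , drop = FALSE]
  links$from <- remap[links$from]
  links$to <- remap[links$to]
  structure(list(nodes = transform(net$nodes[keep, , drop = FALSE],
                                   id = seq_along(keep)),
                 states = net$states[keep, , drop = FALSE],
                 links = links[order(links$from, links$to), , drop = FALSE],
                 weights = net$weights, epsilon = net$epsilon,
                 root = NA_integer_),
            class = "haplotype_network")
}

#' Root a haplotype network on an outgroup
#'
#' Flags the node containing the outgroup taxon as the root and orients
#' every link from the endpoint closer to the root (weighted graph
#' distance); the topology is unchanged.
#'
#' @param net a `haplotype_network`
#' @param outgroup_label taxon name of the outgroup (must be a sampled
#'   haplotype)
#' @return the network with `root` set, a `dist_to_root` node column and
#'   oriented links (`from` is the rootward endpoint)
#' @export
root_network <- function(net, outgroup_label) {
  hit <- which(vapply(strsplit(net$nodes$label, ","), function(x)
    outgroup_label %in% x, logical(1)) & net$nodes$sampled)
  if (!length(hit)) stop("outgroup '", outgroup_label,
                         "' is not a sampled haplotype in the network")
  root <- hit[1L]
  g <- as_igraph(net)
  d <- igraph::distances(g, v = root, weights = igraph::E(g)$weight)[1L, ]
  links <- net$links
  flip <- d[links$to] < d[links$from]
  tmp <- links$from[flip]; links$from[flip] <- links$to[flip]; links$to[flip] <- tmp
  net$links <- links
  net$root <- root
  net$nodes$dist_to_root <- as.numeric(d)
  net
}

#' Convert a haplotype network to an igraph graph
#' @param net a `haplotype_network`
#' @return an igraph object with `weight` edge attribute
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$links, directed = FALSE,
                                vertices = net$nodes[, c("id", "label", "sampled")])
}

#' Export network links as a TSV edge list
#' @param net a `haplotype_network`
#' @param path output TSV path
#' @export
write_network_tsv <- function(net, path) {
  el <- data.frame(from = net$nodes$label[net$links$from],
                   to = net$nodes$label[net$links$to],
                   weight = net$links$weight)
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#' @param net a `haplotype_network`
#' @param path output GraphML path
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
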
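#' Sorting parameters for subfamily classification
#'
#' Defaults mirror the published sorting criteria: at least two shared
#' substitutions distinguish a root-level subfamily from the reference, a
#' nested subfamily needs one additional diagnostic, and a group must have
#' at least 10 members to count as a subfamily. Hallmark deletions (the
#' 20-bp SINE-R and 11-bp Alu-like deletions) are admitted as diagnostics by
#' default; insertions are recorded but never diagnostic.
#'
#' @param min_shared_root diagnostics required at the root level (default 2)
#' @param min_shared_nested diagnostics required for a nested subfamily
#'   (default 1)
#' @param min_members minimum subfamily size (default 10)
#' @param coverage_min minimum covered fraction of the reference (default 0.5)
#' @param use_deletions admit deletion events as diagnostics (default TRUE)
#' @param use_insertions admit insertions as diagnostics (default FALSE;
#'   not implemented as diagnostics)
#' @param whitelist subfamily names exempt from `min_members` when a tree is
#'   validated (mirrors manually retained small groups)
#' @param max_depth recursion guard
#' @return list of parameters
#' @export
sorting_params <- function(min_shared_root = 2L, min_shared_nested = 1L,
                           min_members = 10L, coverage_min = 0.5,
                           use_deletions = TRUE, use_insertions = FALSE,
                           whitelist = character(), max_depth = 25L) {
  stopifnot(min_shared_root >= 1L, min_shared_nested >= 1L, min_members >= 1L,
            coverage_min > 0, coverage_min <= 1)
  list(min_shared_root = as.integer(min_shared_root),
       min_shared_nested = as.integer(min_shared_nested),
       min_members = as.integer(min_members),
       coverage_min = coverage_min,
       use_deletions = isTRUE(use_deletions),
       use_insertions = isTRUE(use_insertions),
       whitelist = whitelist, max_depth = as.integer(max_depth))
}

## ---- candidate variants ---------------------------------------------------

## deletion runs of one state row relative to a parent state vector,
## keyed "start:length"; runs touching missing data are dropped for carrier
## purposes (handled by the caller through the missing matrix)
rel_del_runs <- function(states, parent) {
  runs_of(states == STATE_DEL & parent != STATE_DEL)
}

#' Enumerate candidate diagnostic variants
#'
#' Scans a profile state matrix for substitutions and deletion events
#' relative to a parent consensus and reports every variant carried by at
#' least `min_support` elements. Missing calls never count for or against a
#' variant.
#'
#' @param m character state matrix from [profile_matrix()] (rows elements,
#'   columns reference positions)
#' @param parent parent consensus state vector (the reference, at the root)
#' @param min_support minimum carrier count (default 2)
#' @param use_deletions include deletion events
#' @return list with `variants` (data.frame `kind`, `pos`, `len`, `alt`,
#'   `support`), `M` (logical carrier matrix) and `X` (logical missing
#'   matrix), both elements x variants
#' @export
find_candidate_variants <- function(m, parent, min_support = 2L,
                                    use_deletions = TRUE) {
  if (is.character(parent) && length(parent) == 1L) parent <- seq_chars(parent)
  stopifnot(ncol(m) == length(parent))
  n <- nrow(m)
  empty <- list(variants = data.frame(kind = character(), pos = integer(),
                                      len = integer(), alt = character(),
                                      support = integer()),
                M = matrix(FALSE, n, 0), X = matrix(FALSE, n, 0))
  if (n == 0L) return(empty)

  vars <- list(); Ms <- list(); Xs <- list()
  miss <- m == STATE_MISSING
  for (b in DNA_BASES4) {
    cols <- which(is_base_state(parent) & parent != b)
    if (!length(cols)) next
    Mb <- m[, cols, drop = FALSE] == b
    supp <- colSums(Mb)
    keep <- which(supp >= min_support)
    if (!length(keep)) next
    vars[[b]] <- data.frame(kind = "sub", pos = cols[keep], len = 1L,
                            alt = b, support = supp[keep])
    Ms[[b]] <- Mb[, keep, drop = FALSE]
    Xs[[b]] <- miss[, cols[keep], drop = FALSE]
  }
  if (use_deletions) {
    row_runs <- lapply(seq_len(n), function(i) rel_del_runs(m[i, ], parent))
    keys <- unlist(lapply(row_runs, function(r)
      if (nrow(r)) paste(r$start, r$length, sep = ":") else character()))
    if (length(keys)) {
      tab <- table(keys)
      keep <- names(tab)[tab >= min_support]
      if (length(keep)) {
        parts <- do.call(rbind, strsplit(keep, ":", fixed = TRUE))
        st <- as.integer(parts[, 1]); ln <- as.integer(parts[, 2])
        Md <- matrix(FALSE, n, length(keep))
        Xd <- matrix(FALSE, n, length(keep))
        for (j in seq_along(keep)) {
          span <- st[j]:(st[j] + ln[j] - 1L)
          Md[, j] <- vapply(row_runs, function(r)
            any(r$start == st[j] & r$length == ln[j]), logical(1))
          Xd[, j] <- rowSums(miss[, span, drop = FALSE]) > 0L & !Md[, j]
        }
        vars[["del"]] <- data.frame(kind = "del", pos = st, len = ln,
                                    alt = "-", support = as.integer(tab[keep]))
        Ms[["del"]] <- Md
        Xs[["del"]] <- Xd
      }
    }
  }
  if (!length(vars)) return(empty)
  variants <- do.call(rbind, vars)
  M <- do.call(cbind, Ms)
  X <- do.call(cbind, Xs)
  ## deterministic ordering: by position, kind, length, alt
  o <- order(variants$pos, variants$kind, variants$len, variants$alt)
  variants <- variants[o, , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, M = M[, o, drop = FALSE], X = X[, o, drop = FALSE])
}

## membership of elements (rows of M/X) in a variant set S (column indices):
## all covered diagnostics match and at least min(2, |S|) are covered
members_of_set <- function(M, X, S, need = 2L) {
  Msub <- M[, S, drop = FALSE]
  Xsub <- X[, S, drop = FALSE]
  viol <- rowSums(!Msub & !Xsub)
  covered_match <- rowSums(Msub)
  which(viol == 0L & covered_match >= min(need, length(S)))
}

## greedy search for the variant set of size >= min_shared with the largest
## joint carrier set (a carrier matches every covered variant of
## the set and covers at least min(2, |set|) of them). Seeded with the best
## pair (or single variant when min_shared is 1), then grown by
## hill-climbing: each step adds the variant that keeps the carrier count
## highest, which lets a set absorb all co-segregating diagnostics -- a
## larger set is *more* tolerant of truncated members, which only need two
## covered matches. Ties prefer more variants, then lowest positions.
best_variant_set <- function(cand, min_shared, min_members = 2L) {
  M <- cand$M; X <- cand$X; v <- cand$variants
  V <- !M & !X                   # covered and contradicting
  k <- ncol(M)
  if (k < min_shared) return(NULL)
  carrier_count <- function(S) length(members_of_set(M, X, S))
  if (min_shared >= 2L) {
    cp <- crossprod(M)           # joint carriers for every pair
    diag(cp) <- -1L
    best <- max(cp)
    if (best < 1L) return(NULL)
    idx <- which(cp == best, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    ## deterministic seed among ties: lowest position pair
    o <- order(v$pos[idx[, 1]], v$pos[idx[, 2]], v$alt[idx[, 1]], v$alt[idx[, 2]])
    S <- as.integer(idx[o[1], ])
  } else {
    supp <- colSums(M)
    best <- max(supp)
    if (best < 1L) return(NULL)
    S <- which(supp == best)[1L]
  }
  repeat {
    violS <- rowSums(V[, S, drop = FALSE])
    cmS <- rowSums(M[, S, drop = FALSE])
    ok <- violS == 0L
    n_now <- sum(ok & cmS >= min(2L, length(S)))
    ## carrier count after adding each remaining candidate, vectorized
    rest <- setdiff(seq_len(k), S)
    if (!length(rest)) break
    Mr <- M[ok, rest, drop = FALSE]
    Vr <- V[ok, rest, drop = FALSE]
    counts <- colSums(!Vr & (cmS[ok] + Mr >= 2L))
    ## a new diagnostic must be carried by at least half the current members
    carried <- colSums(Mr)
    eligible <- counts >= n_now & carried >= n_now / 2
    if (!any(eligible)) break
    jbest <- rest[which(eligible)[which.max(counts[eligible])]]
    S <- sort(c(S, jbest))
  }
  S
}

## ---- consensus ------------------------------------------------------------

#' Majority-rule consensus of member profiles
#'
#' Per position the most frequent non-missing state wins; ties resolve to
#' the parent-consensus state, as does a position at which every member is
#' missing. Deletion is a state, so a deletion shared by the members is
#' carried into the consensus.
#'
#' @param m state matrix of the members (rows elements)
#' @param parent parent consensus state vector
#' @return consensus state vector (bases and `"-"`)
#' @export
build_consensus <- function(m, parent) {
  if (is.character(parent) && length(parent) == 1L) parent <- seq_chars(parent)
  stopifnot(nrow(m) >= 1L, ncol(m) == length(parent))
  states <- c(DNA_BASES4, STATE_DEL)
  counts <- vapply(states, function(s) colSums(m == s),
                   numeric(ncol(m)))                      # positions x states
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, states))
  apply_majority(counts, parent, states)
}

apply_majority <- function(counts, parent, states) {
  top <- apply(counts, 1L, max)
  cons <- parent
  for (i in which(top > 0L)) {
    winners <- states[counts[i, ] == top[i]]
    cons[i] <- if (parent[i] %in% winners) parent[i] else winners[1L]
  }
  cons
}

## consensus state vector -> DNA sequence (deletions collapsed)
#' @export
#' @rdname build_consensus
#' @param states a consensus state vector
consensus_sequence <- function(states) {
  chars_seq(states[states != STATE_DEL & states != STATE_MISSING])
}

## ---- the sort -------------------------------------------------------------

#' Sort elements into hierarchical subfamilies by diagnostic substitutions
#'
#' Greedy-recursive automation of manual diagnostic-residue sorting: find
#' the set of shared variants (relative to the current consensus) whose
#' joint carrier set is largest; if the carriers number at least
#' `min_members`, they form a subfamily whose majority-rule consensus then
#' serves as the reference for sorting inside it (one additional diagnostic
#' suffices at nested levels); the remainder of the group is searched again
#' at the same level. Deterministic: identical input yields an identical
#' tree.
#'
#' @param profiles named list of `aligned_profile`s (or a state matrix from
#'   [profile_matrix()])
#' @param reference root reference DNA string
#' @param params see [sorting_params()]
#' @param species optional named character vector (element id -> species
#'   tag) used in subfamily naming
#' @param root_name label of the tree root (default `"root"`)
#' @return a `subfamily_tree`: list with `root`, `reference` (state vector),
#'   `subfamilies` (each: `name`, `parent`, `diagnostics` data.frame,
#'   `members`, `consensus` state vector, `support`), and `assignment`
#'   (element id -> deepest subfamily name)
#' @export
sort_subfamilies <- function(profiles, reference, params = sorting_params(),
                             species = NULL, root_name = "root") {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  ref_states <- seq_chars(reference)
  stopifnot(ncol(m) == length(ref_states))
  ids <- rownames(m)
  if (is.null(species)) species <- setNames(sub("_.*$", "", ids), ids)

  env <- new.env(parent = emptyenv())
  env$subfamilies <- list()
  env$assignment <- setNames(rep(root_name, nrow(m)), ids)
  env$counter <- list()

  recurse <- function(rows, parent_states, parent_name, min_shared, depth) {
    if (depth > params$max_depth || length(rows) < params$min_members) return()
    remaining <- rows
    repeat {
      if (length(remaining) < params$min_members) break
      cand <- find_candidate_variants(m[remaining, , drop = FALSE],
                                      parent_states,
                                      min_support = max(2L, params$min_members),
                                      use_deletions = params$use_deletions)
      if (ncol(cand$M) == 0L) break
      S <- best_variant_set(cand, min_shared)
      if (is.null(S)) break
      mem_local <- members_of_set(cand$M, cand$X, S, need = 2L)
      if (length(mem_local) < params$min_members) break
      members <- remaining[mem_local]
      cons <- build_consensus(m[members, , drop = FALSE], parent_states)
      vs <- cand$variants[S, , drop = FALSE]
      diagnostics <- data.frame(kind = vs$kind, pos = vs$pos, len = vs$len,
                                ref = vapply(seq_len(nrow(vs)), function(i)
                                  if (vs$kind[i] == "sub") parent_states[vs$pos[i]]
                                  else chars_seq(parent_states[vs$pos[i] + seq_len(vs$len[i]) - 1L]),
                                  character(1)),
                                alt = vs$alt)
      ## name: species tag if pure, else "shared"
      sp <- unique(species[ids[members]])
      tag <- if (length(sp) == 1L) sp else "shared"
      n_prev <- env$counter[[parent_name]]
      ord <- if (is.null(n_prev)) 1L else n_prev + 1L
      env$counter[[parent_name]] <- ord
      name <- paste0(tag, "_", parent_name, ".", ord)
      env$subfamilies[[name]] <- list(name = name, parent = parent_name,
                                      diagnostics = diagnostics,
                                      members = ids[members],
                                      consensus = cons,
                                      support = length(members))
      env$assignment[ids[members]] <- name
      recurse(members, cons, name, params$min_shared_nested, depth + 1L)
      remaining <- setdiff(remaining, members)
    }
  }

  recurse(seq_len(nrow(m)), ref_states, root_name, params$min_shared_root, 1L)
  structure(list(root = root_name, reference = ref_states,
                 subfamilies = env$subfamilies,
                 assignment = env$assignment, params = params),
            class = "subfamily_tree")
}

#' @export
print.subfamily_tree <- function(x, ...) {
  cat("subfamily_tree:", length(x$subfamilies), "subfamilies,",
      length(x$assignment), "elements, root:", x$root, "\n")
  for (sf in x$subfamilies) {
    cat(sprintf("  %s  <- %s  (n=%d, diagnostics=%s)\n", sf$name, sf$parent,
                sf$support,
                paste0(sf$diagnostics$pos,
                       ifelse(sf$diagnostics$kind == "del",
                              paste0("del", sf$diagnostics$len),
                              paste0(sf$diagnostics$ref, ">", sf$diagnostics$alt)),
                       collapse = ",")))
  }
  invisible(x)
}

#' Assign one element profile to its deepest subfamily
#'
#' Walks the tree from the root, descending into a child only when all of
#' the child's diagnostics that the profile covers match and at least
#' `min(2, n_diagnostics)` of them are covered; a profile truncated down to
#' one covered diagnostic of a two-diagnostic subfamily therefore stays at
#' the parent.
#'
#' @param profile an `aligned_profile` (aligned to the tree's root
#'   reference), or its state vector
#' @param tree a `subfamily_tree`
#' @return the deepest subfamily name reached (the root name, or
#'   `"unassigned"` for an unalignable profile)
#' @export
assign_element <- function(profile, tree) {
  states <- if (is.list(profile)) {
    if (isTRUE(profile$unalignable)) return("unassigned")
    profile$states
  } else profile
  stopifnot(length(states) == length(tree$reference))
  children_of <- split(names(tree$subfamilies),
                       vapply(tree$subfamilies, `[[`, character(1), "parent"))
  node <- tree$root
  repeat {
    kids <- children_of[[node]]
    if (is.null(kids)) return(node)
    nxt <- NULL
    for (k in sort(kids)) {
      if (satisfies_diagnostics(states, tree$subfamilies[[k]]$diagnostics)) {
        nxt <- k; break
      }
    }
    if (is.null(nxt)) return(node)
    node <- nxt
  }
}

satisfies_diagnostics <- function(states, diag_df) {
  carried <- 0L
  for (i in seq_len(nrow(diag_df))) {
    if (diag_df$kind[i] == "sub") {
      s <- states[diag_df$pos[i]]
      if (s == STATE_MISSING) next
      if (s != diag_df$alt[i]) return(FALSE)
      carried <- carried + 1L
    } else {                       # deletion event: exact run
      span <- diag_df$pos[i] + seq_len(diag_df$len[i]) - 1L
      s <- states[span]
      if (any(s == STATE_MISSING)) next
      if (!all(s == STATE_DEL)) return(FALSE)
      ## maximality at the boundaries
      lo <- diag_df$pos[i] - 1L; hi <- diag_df$pos[i] + diag_df$len[i]
      if (lo >= 1L && states[lo] == STATE_DEL) return(FALSE)
      if (hi <= length(states) && states[hi] == STATE_DEL) return(FALSE)
      carried <- carried + 1L
    }
  }
  carried >= min(2L, nrow(diag_df))
}

#' Subfamily table
#'
#' @param tree a `subfamily_tree`
#' @return data.frame with one row per subfamily (`name`, `parent`,
#'   `support`, `diagnostics` as a `pos:ref>alt` / `pos:del<len>` list)
#' @export
subfamily_table <- function(tree) {
  if (!length(tree$subfamilies)) {
    return(data.frame(name = character(), parent = character(),
                      support = integer(), diagnostics = character()))
  }
  do.call(rbind, lapply(tree$subfamilies, function(sf) {
    d <- sf$diagnostics
    data.frame(name = sf$name, parent = sf$parent, support = sf$support,
               diagnostics = paste0(d$pos, ":",
                                    ifelse(d$kind == "del",
                                           paste0("del", d$len),
                                           paste0(d$ref, ">", d$alt)),
                                    collapse = ","),
               row.names = NULL)
  }))
}
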
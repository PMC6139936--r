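## convert a consensus (sequence string or state vector) to a state vector
## in the coordinates of `reference`
to_states <- function(x, reference, scoring = alignment_scoring()) {
  if (length(x) == nchar(reference) && any(nchar(x) == 1L)) return(x)
  p <- align_to_reference(x, reference, scoring, element_id = "consensus")
  if (p$unalignable) stop("consensus could not be aligned to the reference")
  p$states
}

#' Diagnostic distance between two consensus sequences
#'
#' Counts the positions/events at which two consensuses differ once both
#' are projected onto a common reference: base-vs-base differences count
#' one each, and a deletion present in one but not the other counts once
#' per maximal run (a 20-bp hallmark deletion is one event, not twenty).
#' Missing positions are ignored.
#'
#' @param consensus_a,consensus_b consensus sequences (strings) or state
#'   vectors in reference coordinates
#' @param reference the common reference string
#' @return integer event count
#' @export
diagnostic_distance <- function(consensus_a, consensus_b, reference) {
  a <- to_states(consensus_a, reference)
  b <- to_states(consensus_b, reference)
  informative <- a != STATE_MISSING & b != STATE_MISSING
  base_diff <- informative & is_base_state(a) & is_base_state(b) & a != b
  del_xor <- informative & xor(a == STATE_DEL, b == STATE_DEL)
  sum(base_diff) + nrow(runs_of(del_xor))
}

#' Check sequential acquisition of diagnostics along a subfamily tree
#'
#' Diagnostic substitutions are inherited from a source element and are
#' acquired sequentially: a child subfamily's diagnostics extend, and never
#' revert, those of its ancestors. A child diagnostic that mutates a
#' position back to the state it had before an ancestor's diagnostic is
#' reported as a violation (the back-mutation argument that disqualifies a
#' proposed ancestry).
#'
#' @param tree a `subfamily_tree` (from [sort_subfamilies()] or assembled
#'   by hand with the same structure)
#' @return data.frame of violations (`subfamily`, `pos`, `alt`,
#'   `reverts_to`), empty when acquisition is strictly sequential
#' @export
sequentiality_check <- function(tree) {
  out <- list()
  for (sf in tree$subfamilies) {
    path <- ancestor_path(tree, sf$parent)
    ## state history per position along the ancestor path
    hist <- list()                      # pos -> stack of states (oldest first)
    state_at <- function(pos) {
      h <- hist[[as.character(pos)]]
      if (is.null(h)) tree$reference[pos] else h[length(h)]
    }
    for (anc in path) {
      d <- tree$subfamilies[[anc]]$diagnostics
      for (i in which(d$kind == "sub")) {
        key <- as.character(d$pos[i])
        hist[[key]] <- c(hist[[key]], d$alt[i])
      }
    }
    d <- sf$diagnostics
    for (i in which(d$kind == "sub")) {
      key <- as.character(d$pos[i])
      h <- hist[[key]]
      if (!is.null(h)) {
        prior <- c(tree$reference[d$pos[i]], h)
        before_last <- prior[length(prior) - 1L]
        if (d$alt[i] == before_last) {
          out[[length(out) + 1L]] <- data.frame(
            subfamily = sf$name, pos = d$pos[i], alt = d$alt[i],
            reverts_to = before_last)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(subfamily = character(), pos = integer(),
                      alt = character(), reverts_to = character()))
  }
  do.call(rbind, out)
}

ancestor_path <- function(tree, node) {
  path <- character()
  while (node != tree$root) {
    path <- c(node, path)
    node <- tree$subfamilies[[node]]$parent
  }
  path
}

#' Assemble a subfamily tree by hand
#'
#' Mainly for checking externally derived subfamily hypotheses with
#' [sequentiality_check()].
#'
#' @param reference root reference string
#' @param subfamilies list of lists with `name`, `parent`, `diagnostics`
#'   (data.frame `kind`, `pos`, `len`, `ref`, `alt`)
#' @param root_name root label
#' @return a `subfamily_tree`
#' @export
manual_tree <- function(reference, subfamilies, root_name = "root") {
  names(subfamilies) <- vapply(subfamilies, `[[`, character(1), "name")
  structure(list(root = root_name, reference = seq_chars(reference),
                 subfamilies = subfamilies,
                 assignment = setNames(character(), character())),
            class = "subfamily_tree")
}

#' Scan consensus sequences for co-segregating variant groups
#'
#' Projects each consensus onto the reference, lists every variant present
#' in at least two consensuses, and partitions those shared variants into
#' groups that always co-occur (identical carrier sets). Groups of a single
#' variant are not reported; co-segregation needs company.
#'
#' @param consensuses named list (or named character vector) of consensus
#'   sequences, or a named list of state vectors
#' @param reference common reference string
#' @return data.frame with one row per group: `positions` (comma-joined),
#'   `variants` (`pos:ref>alt` labels), `carriers` (comma-joined consensus
#'   names), `n_variants`, `n_carriers`
#' @export
cosegregation_scan <- function(consensuses, reference) {
  empty <- data.frame(positions = character(), variants = character(),
                      carriers = character(), n_variants = integer(),
                      n_carriers = integer())
  if (length(consensuses) < 2L) return(empty)
  ref <- seq_chars(reference)
  st <- lapply(consensuses, to_states, reference = reference)
  ## variant key -> carrier names
  carrier_map <- list()
  for (nm in names(st)) {
    s <- st[[nm]]
    subs <- which(is_base_state(s) & is_base_state(ref) & s != ref)
    keys <- paste0(subs, ":", ref[subs], ">", s[subs])
    delr <- runs_of(s == STATE_DEL)
    if (nrow(delr)) keys <- c(keys, paste0(delr$start, ":del", delr$length))
    for (k in keys) carrier_map[[k]] <- c(carrier_map[[k]], nm)
  }
  shared <- carrier_map[vapply(carrier_map, length, integer(1)) >= 2L]
  if (length(shared) < 2L) return(empty)
  sig <- vapply(shared, function(cs) paste(sort(cs), collapse = ","), character(1))
  groups <- split(names(shared), sig)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (!length(groups)) return(empty)
  rows <- lapply(names(groups), function(g) {
    keys <- groups[[g]]
    pos <- as.integer(sub(":.*$", "", keys))
    o <- order(pos)
    data.frame(positions = paste(pos[o], collapse = ","),
               variants = paste(keys[o], collapse = ","),
               carriers = g,
               n_variants = length(keys),
               n_carriers = length(strsplit(g, ",")[[1]]))
  })
  out <- do.call(rbind, rows)
  out[order(as.integer(sub(",.*$", "", out$positions))), , drop = FALSE]
}
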
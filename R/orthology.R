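#' Matching parameters for flank-based orthology
#'
#' @param seed_k exact k-mer seed length shared by candidate flank pairs
#'   (default 16)
#' @param min_identity minimum flank identity for a match, both flanks
#'   (default 0.9)
#' @param max_shift maximum insertion-point offset searched, nt (default 5)
#' @param offset_tol offsets larger than this split loci into distinct
#'   integration sites (default 0: the exact same site or nothing)
#' @return list of parameters
#' @export
orthology_params <- function(seed_k = 16L, min_identity = 0.9,
                             max_shift = 5L, offset_tol = 0L) {
  list(seed_k = as.integer(seed_k), min_identity = min_identity,
       max_shift = as.integer(max_shift), offset_tol = as.integer(offset_tol))
}

kmer_set <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character())
  km <- unique(substring(x, 1:(n - k + 1L), k:n))
  ## low-complexity masking: near-homopolymer seeds (A-tract context) would
  ## seed every locus against every other
  keep <- vapply(km, function(s) {
    max(table(strsplit(s, "")[[1]])) <= 0.8 * k
  }, logical(1))
  km[keep]
}

## ungapped comparison of two flank frames at a signed shift; identity over
## the overlap
shift_identity <- function(a, b, shift) {
  ## b is displaced by `shift` nt downstream relative to a
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (shift >= 0) {
    la <- length(ca) - shift
    ov <- min(la, length(cb))
    if (ov <= 0) return(0)
    mean(ca[shift + seq_len(ov)] == cb[seq_len(ov)])
  } else {
    shift_identity(b, a, -shift)
  }
}

## best shift (by combined identity of both flanks) between two loci;
## positive offset means locus b's insertion point lies downstream of a's
best_offset <- function(a5, a3, b5, b3, max_shift) {
  shifts <- -max_shift:max_shift
  ## an insertion point displaced s nt downstream shifts the 3' frame by
  ## +s and the junction-anchored (reversed) 5' frame by -s
  score <- vapply(shifts, function(s) {
    (shift_identity_rev(a5, b5, -s) + shift_identity(a3, b3, s)) / 2
  }, numeric(1))
  i <- which.max(score)
  list(offset = shifts[i],
       id5 = shift_identity_rev(a5, b5, -shifts[i]),
       id3 = shift_identity(a3, b3, shifts[i]))
}

## 5' flanks are anchored at their right end (the junction): compare after
## reversing so the shift convention matches the 3' side
shift_identity_rev <- function(a, b, shift) {
  ra <- chars_seq(rev(seq_chars(a)))
  rb <- chars_seq(rev(seq_chars(b)))
  shift_identity(ra, rb, shift)
}

#' Match insertion loci across species by flanking sequence
#'
#' A cross-species locus pair is matched when both the 5' and 3' flanks
#' exceed the identity threshold at the best common offset and the pair is
#' a reciprocal best hit in both species; a flank with several equally
#' good partners is flagged unresolvable rather than guessed. The offset is
#' the displacement of the two insertion points within the aligned flank
#' frames: orthologous insertions sit at offset 0, near-miss integrations
#' at offset >= 1.
#'
#' @param loci data.frame with `id`, `species`, `flank5`, `flank3`
#' @param params see [orthology_params()]
#' @return list with `matches` (data.frame `id_a`, `id_b`, `species_a`,
#'   `species_b`, `identity5`, `identity3`, `offset`) and `unresolvable`
#'   (ids flagged for ambiguous multi-hits)
#' @export
match_loci <- function(loci, params = orthology_params()) {
  stopifnot(all(c("id", "species", "flank5", "flank3") %in% names(loci)))
  stopifnot(all(nchar(loci$flank5) >= params$seed_k),
            all(nchar(loci$flank3) >= params$seed_k))
  n <- nrow(loci)
  ## seed index on 3' flank k-mers (5' agreement checked at scoring time)
  seeds <- lapply(seq_len(n), function(i)
    c(kmer_set(loci$flank3[i], params$seed_k),
      kmer_set(loci$flank5[i], params$seed_k)))
  index <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(n)) {
    for (km in seeds[[i]]) assign(km, c(mget(km, index, ifnotfound = list(integer()))[[1]], i), index)
  }
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- unique(unlist(lapply(seeds[[i]], function(km)
      mget(km, index, ifnotfound = list(integer()))[[1]])))
    cand[[i]] <- setdiff(hits[loci$species[hits] != loci$species[i]], i)
  }
  ## score candidate pairs once (i < j)
  pair_rows <- list()
  scored <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(n)) for (j in cand[[i]]) {
    a <- min(i, j); b <- max(i, j)
    key <- paste0(a, "_", b)
    if (!is.null(scored[[key]])) next
    off <- best_offset(loci$flank5[a], loci$flank3[a],
                       loci$flank5[b], loci$flank3[b], params$max_shift)
    scored[[key]] <- c(a = a, b = b, id5 = off$id5, id3 = off$id3,
                       offset = off$offset)
  }
  sc <- do.call(rbind, as.list(scored))
  if (is.null(sc)) sc <- matrix(numeric(), 0, 5,
                                dimnames = list(NULL, c("a", "b", "id5", "id3", "offset")))
  sc <- sc[order(sc[, "a"], sc[, "b"]), , drop = FALSE]
  ok <- sc[, "id5"] >= params$min_identity & sc[, "id3"] >= params$min_identity
  sc <- sc[ok, , drop = FALSE]
  ## reciprocal best hit per (locus, partner species), ambiguity flagged
  unresolvable <- character()
  best_of <- function(i, sp) {
    rows <- which((sc[, "a"] == i & loci$species[sc[, "b"]] == sp) |
                  (sc[, "b"] == i & loci$species[sc[, "a"]] == sp))
    if (!length(rows)) return(NA_integer_)
    tot <- sc[rows, "id5"] + sc[rows, "id3"]
    top <- unname(rows[abs(tot - max(tot)) < 1e-12])
    if (length(top) > 1L) return(-1L)      # ambiguous
    top
  }
  matches <- list()
  for (r in seq_len(nrow(sc))) {
    a <- sc[r, "a"]; b <- sc[r, "b"]
    ba <- best_of(a, loci$species[b]); bb <- best_of(b, loci$species[a])
    if (isTRUE(ba == -1L)) unresolvable <- c(unresolvable, loci$id[a])
    if (isTRUE(bb == -1L)) unresolvable <- c(unresolvable, loci$id[b])
    if (isTRUE(ba == r) && isTRUE(bb == r)) {
      matches[[length(matches) + 1L]] <- data.frame(
        id_a = loci$id[a], id_b = loci$id[b],
        species_a = loci$species[a], species_b = loci$species[b],
        identity5 = sc[r, "id5"], identity3 = sc[r, "id3"],
        offset = as.integer(sc[r, "offset"]))
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(id_a = character(), id_b = character(),
               species_a = character(), species_b = character(),
               identity5 = numeric(), identity3 = numeric(),
               offset = integer())
  list(matches = matches, unresolvable = unique(unresolvable))
}

#' Cluster matched loci and call presence per species
#'
#' Loci joined by matches at offset within tolerance form orthologous-site
#' clusters (transitive closure); matches with larger offsets are distinct
#' integration sites and never merge clusters. Each cluster gets presence
#' flags per species and a parsimony history call on the fixed tree
#' `((hs, pt), gg)`.
#'
#' @param loci data.frame with `id`, `species`
#' @param matches the `matches` data.frame from [match_loci()]
#' @param species_set the configured species tags
#' @param offset_tol see [orthology_params()]
#' @return data.frame, one row per cluster: `cluster`, `members`, presence
#'   flags (one logical column per species), `call` and `loss_lineage`
#'   from [parsimony_history()]
#' @export
classify_presence <- function(loci, matches, species_set = c("gg", "pt", "hs"),
                              offset_tol = 0L) {
  same_site <- matches[abs(matches$offset) <= offset_tol, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    same_site[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = loci$id))
  comp <- igraph::components(g)$membership
  clusters <- split(loci$id, comp[loci$id])
  rows <- lapply(seq_along(clusters), function(k) {
    ids <- clusters[[k]]
    sp_present <- unique(loci$species[loci$id %in% ids])
    flags <- setNames(species_set %in% sp_present, species_set)
    hist <- parsimony_history(flags)
    cbind(data.frame(cluster = sprintf("cluster_%04d", k),
                     members = paste(sort(ids), collapse = ",")),
          as.data.frame(as.list(flags)),
          data.frame(call = hist$call, loss_lineage = hist$loss_lineage))
  })
  do.call(rbind, rows)
}

#' Most-parsimonious presence/absence history on the hominine tree
#'
#' Dollo-style logic on the fixed rooted tree `((hs, pt), gg)`: presence in
#' species spanning the root (gorilla plus human and/or chimpanzee) makes
#' the insertion ancestral-hominine; an ancestral insertion absent from one
#' species was lost there -- by incomplete lineage sorting or, less likely,
#' precise deletion; presence in human and chimpanzee only maps to their
#' common ancestor; a single species means a lineage-specific insertion.
#'
#' @param flags named logical vector over `gg`, `pt`, `hs`
#' @return list with `call` (one of `ancestral_hominine`,
#'   `hs_pt_ancestral`, `<sp>_specific`, `absent`) and `loss_lineage`
#'   (species inferred to have lost an ancestral insertion, or `""`)
#' @export
parsimony_history <- function(flags) {
  gg <- isTRUE(flags[["gg"]]); pt <- isTRUE(flags[["pt"]]); hs <- isTRUE(flags[["hs"]])
  if (gg && pt && hs) return(list(call = "ancestral_hominine", loss_lineage = ""))
  if (gg && hs && !pt) return(list(call = "ancestral_hominine", loss_lineage = "pt"))
  if (gg && pt && !hs) return(list(call = "ancestral_hominine", loss_lineage = "hs"))
  if (!gg && pt && hs) return(list(call = "hs_pt_ancestral", loss_lineage = ""))
  if (hs) return(list(call = "hs_specific", loss_lineage = ""))
  if (pt) return(list(call = "pt_specific", loss_lineage = ""))
  if (gg) return(list(call = "gg_specific", loss_lineage = ""))
  list(call = "absent", loss_lineage = "")
}
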
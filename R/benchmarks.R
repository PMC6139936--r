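#' Subfamily-recovery benchmark on the default expansion
#'
#' Simulates the default hominine expansion (15 source lineages, 30-200
#' copies each), aligns every emitted copy to the root reference, drops
#' copies covering less than half of it, sorts the rest into subfamilies
#' and scores the recovered partition against the planted one. With
#' `noisy = FALSE` the post-insertion mutation rate and truncation are
#' switched off (the zero-noise limit, where recovery must be exact).
#'
#' @param seed integer seed
#' @param noisy simulate post-insertion divergence (0.5-2% by copy age)
#'   and 20% 5'-truncation (default TRUE)
#' @param ref_length SINE-R-scale reference length (default 490)
#' @return list with `ari`, `n`, `n_subfamilies`, `consensus_recovery`
#'   (fraction of planted source consensuses recovered exactly), `tree`,
#'   `truth`
#' @export
subfamily_recovery_benchmark <- function(seed, noisy = TRUE,
                                         ref_length = 490L) {
  cfg <- simulation_config(
    ref_length = ref_length, lineages = default_lineage_plan(),
    mut_rate = if (noisy) 0.005 else 0,
    trunc_prob = if (noisy) 0.2 else 0,
    seed = seed)
  sim <- simulate_expansion(cfg)
  profs <- align_set(sim$elements, cfg$reference)
  keep <- vapply(profs, coverage_ok, logical(1))
  tree <- sort_subfamilies(profile_matrix(profs[keep]), cfg$reference)
  truth <- setNames(sim$truth$lineage, sim$truth$id)[names(profs)[keep]]
  sc <- score_partition(tree$assignment, truth)
  src <- vapply(sim$sources, function(s) consensus_sequence(s$states), "")
  rec <- vapply(tree$subfamilies, function(sf) consensus_sequence(sf$consensus), "")
  list(ari = sc$ari, n = length(truth),
       n_subfamilies = length(tree$subfamilies),
       consensus_recovery = mean(src %in% rec),
       per_subfamily = sc$per_subfamily,
       tree = tree, truth = truth)
}

#' Orthology benchmark: presence calls and near-miss decoys
#'
#' Runs the default expansion plus cross-species decoy locus pairs whose
#' insertion points differ by one nucleotide, matches loci by flanking
#' sequence, clusters them and scores shared-vs-lineage-specific calls per
#' element against the simulation truth.
#'
#' @param seed integer seed
#' @param n_decoy_pairs planted 1-nt-offset decoy pairs (default 10)
#' @param scale divide the plan's copy numbers by this factor (default 1)
#' @return list with `accuracy`, `n`, `decoys_total`, `decoys_split`
#'   (decoy matches reported at non-zero offset), `clusters`
#' @export
orthology_benchmark <- function(seed, n_decoy_pairs = 10L, scale = 1) {
  plan <- default_lineage_plan()
  plan$n_copies <- pmax(5L, round(plan$n_copies / scale))
  cfg <- simulation_config(ref_length = 300L, lineages = plan,
                           n_decoy_pairs = n_decoy_pairs, seed = seed)
  sim <- simulate_expansion(cfg)
  loci <- sim$elements[, c("id", "species", "flank5", "flank3")]
  mm <- match_loci(loci)
  dec <- sim$truth$id[grepl("decoy", sim$truth$locus_id)]
  dm <- mm$matches[mm$matches$id_a %in% dec | mm$matches$id_b %in% dec, ,
                   drop = FALSE]
  pres <- classify_presence(loci, mm$matches)
  el2cl <- integer(0)
  for (k in seq_len(nrow(pres))) {
    ids <- strsplit(pres$members[k], ",")[[1]]
    el2cl[ids] <- k
  }
  multi <- vapply(seq_len(nrow(pres)), function(k)
    sum(unlist(pres[k, c("gg", "pt", "hs")])) > 1, TRUE)
  inf_shared <- multi[el2cl[sim$truth$id]]
  list(accuracy = mean(inf_shared == sim$truth$shared),
       n = nrow(sim$truth),
       decoys_total = n_decoy_pairs,
       decoys_split = sum(abs(dm$offset) >= 1L),
       decoy_matches = nrow(dm),
       clusters = pres)
}

#' Exon-capture benchmark
#'
#' Simulates a capture family (exon suffix spliced onto the retained 3'
#' part of the Alu-like domain) with a few canonical members, then runs
#' domain annotation, non-canonical 5' detection and exon-source
#' assignment on every copy.
#'
#' @param seed integer seed
#' @param n_copies family size (default 30, 3 of them canonical)
#' @return list with `n_capture`, `donor_correct`, `length_correct`,
#'   `acceptor_pass`, `false_positives`, `lengths` (deduplicated acquired
#'   lengths from [capture_length_distribution()])
#' @export
capture_benchmark <- function(seed, n_copies = 30L) {
  sva <- build_canonical_sva()
  with_substream(seed, "capture_bench", {
    exon <- random_dna(400L, gc = 0.6)
    decoy1 <- random_dna(350L, gc = 0.6)
    decoy2 <- random_dna(300L)
  })
  plan <- data.frame(name = "cap", parent = NA, branch = "pt", n_diag = 2,
                     del_len = 0, n_copies = n_copies, age = 0.5)
  cfg <- simulation_config(
    reference = sva$sequence, lineages = plan, trunc_prob = 0,
    mut_rate = 0,
    captures = list(list(lineage = "cap", exon_name = "donor_ex1",
                         exon_seq = exon, junction = sva$capture_junction,
                         acq_len_range = c(120L, 220L), n_canonical = 3L)),
    seed = seed)
  sim <- simulate_expansion(cfg)
  lib <- c(donor_ex1 = exon, decoy_ex1 = decoy1, decoy_ex2 = decoy2)
  n_cap <- 0L; donor <- 0L; len <- 0L; acc <- 0L; fp <- 0L
  calls <- list()
  for (i in seq_len(nrow(sim$elements))) {
    el <- sim$elements$sequence[i]
    tr <- sim$truth[i, ]
    ann <- annotate_domains(el, sva$refs)
    nc <- detect_noncanonical_5p(el, ann, sva$refs)
    if (!is.na(tr$capture_donor)) {
      n_cap <- n_cap + 1L
      if (!is.null(nc)) {
        if (isTRUE(nc$acceptor_ag == "pass")) acc <- acc + 1L
        call <- assign_exon_source(substr(el, nc$span[1], nc$span[2]), lib)
        if (inherits(call, "capture_call")) {
          calls[[length(calls) + 1L]] <- call
          donor <- donor + (call$exon == tr$capture_donor)
          len <- len + (call$acquired_len == tr$capture_len)
        }
      }
    } else if (!is.null(nc)) fp <- fp + 1L
  }
  list(n_capture = n_cap, donor_correct = donor, length_correct = len,
       acceptor_pass = acc, false_positives = fp,
       lengths = capture_length_distribution(calls))
}

#' Median-joining correctness benchmark
#'
#' Property battery for the network construction: random compatible binary
#' matrices must reproduce the perfect phylogeny (tree topology, parsimony
#' length, additive distances); small random haplotype sets must connect
#' their samples at exactly the exhaustive-Steiner cost computed by
#' Dreyfus-Wagner over the whole hypercube; and the final network must
#' always contain a spanning subtree of its samples no heavier than their
#' minimum spanning tree.
#'
#' @param seed integer seed
#' @param n_compatible number of compatible-matrix cases (default 100)
#' @param n_steiner number of exhaustive-Steiner cases (default 30)
#' @return list of counts: `compatible_ok`/`compatible_n`, `steiner_ok`/
#'   `steiner_n`, `mst_ok`/`mst_n`
#' @export
mj_benchmark <- function(seed, n_compatible = 100L, n_steiner = 30L) {
  comp_ok <- 0L; comp_n <- 0L
  st_ok <- 0L; st_n <- 0L
  mst_ok <- 0L; mst_n <- 0L
  with_substream(seed, "mj_bench", {
    for (i in seq_len(n_compatible)) {
      mat <- compatible_binary_matrix(sample(3:12, 1L), sample(3:20, 1L))
      seqs <- apply(mat, 1L, paste, collapse = "")
      if (length(unique(seqs)) < 2L) next
      cm <- condense_characters(setNames(seqs, rownames(mat)))
      net <- median_joining(cm)
      ok <- nrow(net$links) == nrow(net$nodes) - 1L &&
        isTRUE(all.equal(sum(net$links$weight), sum(cm$weights))) &&
        network_is_additive(net, cm)
      comp_n <- comp_n + 1L
      comp_ok <- comp_ok + ok
      mst_n <- mst_n + 1L
      mst_ok <- mst_ok + network_spans_mst(net, cm)
    }
    for (i in seq_len(n_steiner)) {
      n <- sample(3:5, 1L); k <- sample(3:8, 1L)
      mat <- matrix(sample(0:1, n * k, replace = TRUE), n, k)
      rownames(mat) <- paste0("t", seq_len(n))
      seqs <- apply(mat, 1L, paste, collapse = "")
      if (length(unique(seqs)) < 2L) next
      cm <- condense_characters(setNames(seqs, rownames(mat)))
      net <- median_joining(cm)
      sw <- steiner_within(net)
      target <- steiner_cost_exhaustive(mat[!duplicated(seqs), , drop = FALSE])
      st_n <- st_n + 1L
      st_ok <- st_ok + isTRUE(all.equal(sw$cost, target))
      mst_n <- mst_n + 1L
      mst_ok <- mst_ok + network_spans_mst(net, cm)
    }
  })
  list(compatible_ok = comp_ok, compatible_n = comp_n,
       steiner_ok = st_ok, steiner_n = st_n,
       mst_ok = mst_ok, mst_n = mst_n)
}

## random perfect-phylogeny data: each character marks one edge of a random
## rooted tree, taxa are a subset of its nodes
compatible_binary_matrix <- function(n_taxa, n_chars) {
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

## do network path lengths between samples equal weighted Hamming distances?
network_is_additive <- function(net, cm) {
  g <- as_igraph(net)
  smp <- which(net$nodes$sampled)
  d <- igraph::distances(g, v = smp, to = smp, weights = igraph::E(g)$weight)
  hd <- state_dist(net$states[smp, , drop = FALSE], cm$weights)
  isTRUE(all.equal(unname(d), unname(hd), tolerance = 1e-9))
}

## does the network contain a subtree spanning all samples at <= MST cost?
network_spans_mst <- function(net, cm) {
  sw <- steiner_within(net)
  D <- state_dist(cm$hap, cm$weights)
  is.finite(sw$cost) && sw$cost <= mst_cost(D) + 1e-9
}

## exact minimum Steiner tree cost over the binary hypercube
## (Dreyfus-Wagner; the reference answer for small haplotype sets)
steiner_cost_exhaustive <- function(term_states) {
  k <- ncol(term_states)
  stopifnot(k <= 10L)
  V <- 2L^k
  bitsm <- t(vapply(0:(V - 1L), function(v) as.integer(intToBits(v))[1:k],
                    integer(k)))
  D <- matrix(0, V, V)
  for (j in seq_len(k)) D <- D + outer(bitsm[, j], bitsm[, j], "!=")
  tid <- unique(apply(term_states, 1L, function(r) sum(r * 2L^(0:(k - 1L)))) + 1L)
  if (length(tid) <= 1L) return(0)
  root <- tid[1L]; terms <- tid[-1L]; tt <- length(terms)
  S <- matrix(Inf, 2L^tt - 1L, V)
  for (i in seq_len(tt)) S[2L^(i - 1L), ] <- D[terms[i], ]
  masks <- (1:(2L^tt - 1L))[order(vapply(1:(2L^tt - 1L), function(m)
    sum(as.integer(intToBits(m))), integer(1)))]
  for (mask in masks) {
    if (sum(as.integer(intToBits(mask))) < 2L) next
    tmp <- rep(Inf, V)
    sub <- bitwAnd(mask - 1L, mask)
    while (sub > 0L) {
      other <- mask - sub
      if (sub <= other) tmp <- pmin(tmp, S[sub, ] + S[other, ])
      sub <- bitwAnd(sub - 1L, mask)
    }
    S[mask, ] <- apply(tmp + D, 2L, min)
  }
  S[2L^tt - 1L, root]
}

#' Consensus-forensics benchmark on the synthetic panel
#'
#' Recomputes, on the synthetic SINE-R consensus panel, the quantities the
#' diagnostic-residue analysis rests on: the event distance between the DR
#' and D1 consensuses, the outgroup distance C vs D1, the length of the D2
#' hallmark deletion, and the co-segregating substitution pair of the A-G
#' subfamilies relative to DR.
#'
#' @param seed panel seed (default 104, the packaged panel)
#' @return list with `dr_d1_distance`, `c_d1_distance`,
#'   `d2_deletion_length`, `coseg_positions` (integer vector)
#' @export
consensus_forensics_benchmark <- function(seed = 104L) {
  pan <- synthetic_consensus_panel(seed)
  d2 <- align_to_reference(pan$sequences[["SVA_D2"]], pan$reference)
  dels <- call_variants(d2, pan$reference)
  dels <- dels[dels$kind == "del", ]
  ag <- pan$sequences[grep("^AG_", names(pan$sequences))]
  groups <- cosegregation_scan(as.list(ag), pan$dr)
  top <- groups[which.max(groups$n_carriers), ]
  list(dr_d1_distance = diagnostic_distance(pan$sequences[["SVA_DR"]],
                                            pan$sequences[["SVA_D1"]],
                                            pan$reference),
       c_d1_distance = diagnostic_distance(pan$sequences[["SVA_C"]],
                                           pan$sequences[["SVA_D1"]],
                                           pan$reference),
       d2_deletion_length = if (nrow(dels)) max(dels$len) else NA_integer_,
       coseg_positions = as.integer(strsplit(top$positions, ",")[[1]]))
}

#' Target-site worked examples
#'
#' The four printed TSD comparisons around the NPLOC4 insertion: the
#' orangutan 5' TSD vs the inferred pre-integration site, the 3' TSD vs
#' the same site, the two orangutan 5' alleles against each other, and the
#' human TSD vs the pre-integration site.
#'
#' @return list of `tsd_comparison` objects: `pabe_5p`, `tsd_3p`,
#'   `pabe_vs_ppyg`, `human`
#' @export
npl_tsd_examples <- function() {
  pis <- "AAAAATACAAAAAATT"        # AluY consensus target, Old World monkey state
  list(pabe_5p = compare_tsd("AAAAATACAGAAAATT", pis),
       tsd_3p = compare_tsd("AAAAAAAAAAAAAATT", pis),
       pabe_vs_ppyg = compare_tsd("AAAAATACAGAAAATT", "AAAAATAAAGAAAATT"),
       human = compare_tsd("AAAAACACAAAAAAT", pis))
}
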
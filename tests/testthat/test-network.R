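test_that("character condensation drops constant columns and merges haplotypes", {
  cm <- condense_characters(c(a = "ACGT", b = "ACGT"))
  expect_equal(ncol(cm$hap), 0L)
  expect_equal(nrow(cm$hap), 1L)
  expect_equal(unname(cm$multiplicity), 2L)
  cm2 <- condense_characters(c(x = "AAA", y = "AAT", z = "TAA"))
  expect_equal(ncol(cm2$hap), 2L)
  expect_error(condense_characters(c(a = "AC", b = "ACG")), "equal length")
})

test_that("condensed weighted distances reproduce pairwise Hamming distances", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:8, 1); len <- sample(10:30, 1)
    seqs <- setNames(vapply(seq_len(n), function(i) random_dna(len), ""),
                     paste0("s", seq_len(n)))
    cm <- condense_characters(seqs)
    D <- svatools:::state_dist(cm$hap, cm$weights)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      hi <- cm$hap_of_taxon[i]; hj <- cm$hap_of_taxon[j]
      expect_equal(D[match(hi, rownames(cm$hap)), match(hj, rownames(cm$hap))],
                   hamming(seqs[[i]], seqs[[j]]))
    }
  }
})

test_that("two haplotypes give a single link of their full distance", {
  net <- median_joining(condense_characters(c(a = "AACCG", b = "AATTG")))
  expect_equal(nrow(net$links), 1L)
  expect_equal(net$links$weight, 2)
  expect_equal(sum(net$nodes$sampled), 2L)
})

test_that("three pairwise-distant haplotypes meet at a median vector", {
  ## the 110/101/011 configuration: the median 111 turns cost 4 into 3
  net <- median_joining(condense_characters(c(x = "TTA", y = "TAT", z = "ATT")))
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(sum(!net$nodes$sampled), 1L)
  mv <- net$nodes$states[!net$nodes$sampled]
  expect_equal(mv, "TTT")
  expect_equal(nrow(net$links), 3L)
  expect_true(all(net$links$weight == 1))
})

test_that("compatible binary characters reproduce the perfect phylogeny", {
  set.seed(23)
  for (rep in 1:20) {
    mat <- make_compatible_matrix(sample(3:8, 1), sample(3:12, 1))
    seqs <- apply(mat, 1L, paste, collapse = "")
    if (length(unique(seqs)) < 2L) next
    cm <- condense_characters(setNames(seqs, rownames(mat)))
    net <- median_joining(cm)
    n <- nrow(net$nodes)
    ## a tree: connected with n-1 links
    expect_equal(nrow(net$links), n - 1L)
    g <- as_igraph(net)
    expect_equal(igraph::components(g)$no, 1L)
    ## total length equals the parsimony length (every character once)
    expect_equal(sum(net$links$weight), sum(cm$weights))
    ## graph distances between sampled haplotypes equal their (weighted)
    ## Hamming distances
    gd <- oracle_graph_distances(net)
    smp <- which(net$nodes$sampled)
    for (i in smp) for (j in smp) {
      di <- strsplit(net$nodes$states[i], "")[[1]] !=
            strsplit(net$nodes$states[j], "")[[1]]
      expect_equal(gd[i, j], sum(cm$weights[di]))
    }
  }
})

test_that("network connection cost is bracketed by Steiner optimum and MST", {
  ## the network's internal spanning cost can never beat the exhaustive
  ## Steiner optimum and never exceeds the sample MST; on most small
  ## instances it attains the optimum exactly (median joining is a
  ## heuristic, so occasional 1-unit misses on incompatible data are
  ## inherent to the published algorithm)
  set.seed(31)
  n_cases <- 0L; n_exact <- 0L
  for (rep in 1:12) {
    n <- sample(3:5, 1); k <- sample(3:7, 1)
    mat <- matrix(sample(0:1, n * k, replace = TRUE), n, k)
    rownames(mat) <- paste0("t", 1:n)
    seqs <- apply(mat, 1, paste, collapse = "")
    if (length(unique(seqs)) < 2) next
    cm <- condense_characters(setNames(seqs, rownames(mat)))
    net <- median_joining(cm)
    ## minimum cost of connecting the samples within the network
    sw <- svatools:::steiner_within(net)
    term_states <- mat[!duplicated(seqs), , drop = FALSE]
    opt <- oracle_steiner_cost(term_states, rep(1, k))
    D <- svatools:::state_dist(cm$hap, cm$weights)
    expect_gte(sw$cost, opt - 1e-9)
    expect_lte(sw$cost, oracle_mst_cost(D) + 1e-9)
    n_cases <- n_cases + 1L
    n_exact <- n_exact + (abs(sw$cost - opt) < 1e-9)
  }
  expect_gte(n_exact / n_cases, 0.9)
})

test_that("the network always spans its samples at no more than MST cost", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(4:9, 1); len <- sample(8:16, 1)
    seqs <- setNames(vapply(seq_len(n), function(i)
      paste(sample(c("A", "T"), len, replace = TRUE), collapse = ""), ""),
      paste0("s", seq_len(n)))
    if (length(unique(seqs)) < 2) next
    cm <- condense_characters(seqs)
    net <- median_joining(cm)
    ## all sampled haplotypes present, connected network
    expect_equal(sum(net$nodes$sampled), nrow(cm$hap))
    expect_equal(igraph::components(as_igraph(net))$no, 1L)
    ## spanning subtree within the network no heavier than the sample MST
    sw <- svatools:::steiner_within(net)
    D <- svatools:::state_dist(cm$hap, cm$weights)
    expect_lte(sw$cost, oracle_mst_cost(D))
  }
})

test_that("mp postprocessing keeps exactly the minimum-tree links", {
  ## tree input is unchanged
  net <- median_joining(condense_characters(c(x = "TTA", y = "TAT", z = "ATT")))
  pp <- mp_postprocess(net)
  expect_equal(nrow(pp$links), nrow(net$links))
  expect_equal(sort(pp$nodes$states), sort(net$nodes$states))
  ## idempotent
  pp2 <- mp_postprocess(pp)
  expect_equal(pp2$links$weight, pp$links$weight)
  expect_equal(pp2$nodes$states, pp$nodes$states)

  ## a 4-cycle (all four gametes) has two equally parsimonious paths: both
  ## retained
  net4 <- median_joining(condense_characters(
    c(a = "AA", b = "AT", c = "TA", d = "TT")))
  pp4 <- mp_postprocess(net4)
  expect_equal(nrow(pp4$links), 4L)

  ## a median vector on no minimum tree is removed; verify against
  ## brute-force spanning-tree enumeration on the same small network
  hand <- structure(list(
    nodes = data.frame(id = 1:4, label = c("a", "b", "c", "mv1"),
                       sampled = c(TRUE, TRUE, TRUE, FALSE),
                       states = c("AA", "AT", "TT", "GG")),
    states = rbind(c("A", "A"), c("A", "T"), c("T", "T"), c("G", "G")),
    links = data.frame(from = c(1L, 2L, 1L, 4L), to = c(2L, 3L, 4L, 3L),
                       weight = c(1, 1, 2, 2)),
    weights = c(1, 1), epsilon = 0, root = NA_integer_),
    class = "haplotype_network")
  pph <- mp_postprocess(hand)
  expect_false("mv1" %in% pph$nodes$label)
  expect_equal(nrow(pph$links), 2L)
  ## oracle: enumerate spanning structures over terminal-only vs with median
  trees_no_mv <- oracle_spanning_trees(hand$links[1:2, ], c("1", "2", "3"))
  expect_length(trees_no_mv, 1L)
})

test_that("rooting flags the outgroup and orients links by distance", {
  net <- median_joining(condense_characters(
    c(SVA_C = "AAAA", d1 = "AATA", dr = "AATT", e = "TATT")))
  r <- root_network(net, "SVA_C")
  expect_false(is.na(r$root))
  expect_true(grepl("SVA_C", r$nodes$label[r$root]))
  expect_equal(nrow(r$links), nrow(net$links))
  ## distances agree with a Floyd-Warshall oracle
  gd <- oracle_graph_distances(net)
  expect_equal(r$nodes$dist_to_root, gd[r$root, ])
  ## links point away from the root
  expect_true(all(r$nodes$dist_to_root[r$links$from] <=
                  r$nodes$dist_to_root[r$links$to]))
  expect_error(root_network(net, "nope"), "outgroup")
})

test_that("network export writes readable edge lists", {
  net <- median_joining(condense_characters(c(a = "AACC", b = "AATT")))
  tsv <- tempfile(fileext = ".tsv")
  write_network_tsv(net, tsv)
  el <- read.delim(tsv)
  expect_equal(nrow(el), 1L)
  expect_equal(el$weight, 2)
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  expect_true(file.exists(gml))
})
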
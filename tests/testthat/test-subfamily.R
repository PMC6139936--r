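# small fixtures are built with the simulator so planted truth is available

mini_sim <- function(plan, seed, ...) {
  cfg <- simulation_config(ref_length = 300, lineages = plan, seed = seed, ...)
  sim <- simulate_expansion(cfg)
  profs <- align_set(sim$elements, cfg$reference)
  list(cfg = cfg, sim = sim, m = profile_matrix(profs))
}

test_that("candidate variant support equals a brute-force column tally", {
  set.seed(5)
  ref <- strsplit(random_dna(60), "")[[1]]
  m <- matrix(rep(ref, each = 30), nrow = 30)
  for (i in 1:30) {
    at <- sample(60, 4)
    for (p in at) m[i, p] <- sample(c("A", "C", "G", "T", ".", "-"), 1)
  }
  rownames(m) <- paste0("e", 1:30)
  cand <- find_candidate_variants(m, ref, min_support = 2, use_deletions = FALSE)
  oracle <- oracle_column_tally(m, ref, 2)
  got <- cand$variants[cand$variants$kind == "sub",
                       c("pos", "alt", "support")]
  o1 <- got[order(got$pos, got$alt), ]
  o2 <- oracle[order(oracle$pos, oracle$alt), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  ## carriers below min_support are excluded
  cand10 <- find_candidate_variants(m, ref, min_support = 10)
  expect_true(all(cand10$variants$support >= 10))
})

test_that("majority consensus follows the stated rules", {
  parent <- c("A", "C", "G", "T")
  m <- rbind(c("A", "C", "G", "T"),
             c("A", "C", "G", "T"),
             c("A", "C", "T", "T"))
  expect_equal(build_consensus(m, parent), c("A", "C", "G", "T"))
  ## 5 vs 5 tie resolves to the parent state
  m2 <- rbind(matrix(rep(c("G", "C", "G", "T"), 5), 5, byrow = TRUE),
              matrix(rep(c("T", "C", "G", "T"), 5), 5, byrow = TRUE))
  expect_equal(build_consensus(m2, c("G", "C", "G", "T"))[1], "G")
  ## shared deletion becomes part of the consensus; all-missing -> parent
  m3 <- rbind(c("A", "-", "-", "."),
              c("A", "-", "-", "."),
              c("A", "-", "-", "."))
  expect_equal(build_consensus(m3, parent), c("A", "-", "-", "T"))
})

test_that("two planted subfamilies are recovered perfectly without noise", {
  plan <- rbind(
    data.frame(name = "sfA", parent = NA, branch = "hs", n_diag = 2,
               del_len = 0, n_copies = 50, age = 1),
    data.frame(name = "sfB", parent = NA, branch = "pt", n_diag = 2,
               del_len = 0, n_copies = 50, age = 1))
  ms <- mini_sim(plan, seed = 21, mut_rate = 0, trunc_prob = 0)
  tree <- sort_subfamilies(ms$m, ms$cfg$reference)
  expect_length(tree$subfamilies, 2L)
  truth <- setNames(ms$sim$truth$lineage, ms$sim$truth$id)
  expect_equal(score_partition(tree$assignment, truth)$ari, 1.0)
  ## diagnostics match the planted ones exactly
  planted <- lapply(ms$sim$sources, function(s) sort(s$diagnostics$pos))
  found <- lapply(tree$subfamilies, function(sf) sort(sf$diagnostics$pos))
  expect_setequal(unname(found), unname(planted))
})

test_that("groups below the membership or sharing thresholds stay at root", {
  ref <- random_dna(100)
  refc <- strsplit(ref, "")[[1]]
  ## 9 elements share 2 substitutions: below min_members = 10
  alt_of <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  m <- matrix(rep(refc, each = 20), nrow = 20)
  m[1:9, 10] <- alt_of(refc[10]); m[1:9, 20] <- alt_of(refc[20])
  rownames(m) <- paste0("hs_", 1:20)
  tree <- sort_subfamilies(m, ref)
  expect_length(tree$subfamilies, 0L)
  expect_true(all(tree$assignment == "root"))
  ## 30 elements share only 1 substitution: below min_shared_root = 2
  m2 <- matrix(rep(refc, each = 30), nrow = 30)
  m2[, 50] <- if (refc[50] == "A") "G" else "A"
  rownames(m2) <- paste0("hs_", 1:30)
  tree2 <- sort_subfamilies(m2, ref)
  expect_length(tree2$subfamilies, 0L)
})

test_that("assignment walks the tree and respects the coverage rule", {
  plan <- data.frame(name = "sf", parent = NA, branch = "hs", n_diag = 2,
                     del_len = 0, n_copies = 30, age = 1)
  ms <- mini_sim(plan, seed = 3, mut_rate = 0, trunc_prob = 0)
  tree <- sort_subfamilies(ms$m, ms$cfg$reference)
  expect_length(tree$subfamilies, 1L)
  leaf <- names(tree$subfamilies)[1]
  d <- tree$subfamilies[[leaf]]$diagnostics
  ## a profile carrying the full diagnostic set reaches the leaf
  states <- strsplit(ms$cfg$reference, "")[[1]]
  states[d$pos] <- d$alt
  expect_equal(assign_element(states, tree), leaf)
  ## masking one of two diagnostics leaves it at the parent
  states[d$pos[1]] <- "."
  expect_equal(assign_element(states, tree), "root")
  ## an unalignable profile is unassigned
  expect_equal(assign_element(list(unalignable = TRUE), tree), "unassigned")
  ## zero-noise assignment equals generator truth
  truth <- setNames(ms$sim$truth$lineage, ms$sim$truth$id)
  expect_equal(score_partition(tree$assignment, truth)$ari, 1.0)
})

test_that("membership is nested: children satisfy ancestor diagnostics", {
  plan <- rbind(
    data.frame(name = "P", parent = NA, branch = "hs", n_diag = 2,
               del_len = 0, n_copies = 40, age = 1),
    data.frame(name = "C", parent = "P", branch = "hs", n_diag = 2,
               del_len = 0, n_copies = 25, age = 0.5))
  ms <- mini_sim(plan, seed = 8, mut_rate = 0, trunc_prob = 0)
  tree <- sort_subfamilies(ms$m, ms$cfg$reference)
  expect_length(tree$subfamilies, 2L)
  kids <- Filter(function(sf) sf$parent != "root", tree$subfamilies)
  expect_length(kids, 1L)
  child <- kids[[1]]
  parent <- tree$subfamilies[[child$parent]]
  expect_true(all(child$members %in% parent$members))
  ## consensus differs from parent consensus exactly at the diagnostics
  diffs <- which(child$consensus != parent$consensus)
  expect_setequal(diffs, child$diagnostics$pos)
})

test_that("sorting is deterministic", {
  plan <- rbind(
    data.frame(name = "A", parent = NA, branch = "hs", n_diag = 2,
               del_len = 0, n_copies = 30, age = 1),
    data.frame(name = "B", parent = NA, branch = "pt", n_diag = 3,
               del_len = 0, n_copies = 30, age = 2))
  ms <- mini_sim(plan, seed = 13)
  t1 <- sort_subfamilies(ms$m, ms$cfg$reference)
  t2 <- sort_subfamilies(ms$m, ms$cfg$reference)
  expect_identical(subfamily_table(t1), subfamily_table(t2))
  expect_identical(t1$assignment, t2$assignment)
})

test_that("diagnostic distance counts events, deletions once", {
  ref <- random_dna(200)
  expect_equal(diagnostic_distance(ref, ref, ref), 0L)
  a <- strsplit(ref, "")[[1]]
  a[c(10, 50, 90)] <- vapply(a[c(10, 50, 90)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "x")
  expect_equal(diagnostic_distance(paste(a, collapse = ""), ref, ref), 3L)
  ## one 20-base deletion counts once
  b <- paste0(substr(ref, 1, 99), substr(ref, 120, 200))
  expect_equal(diagnostic_distance(b, ref, ref), 1L)
  ## random consensus pairs match a direct column scan
  set.seed(9)
  for (rep in 1:5) {
    x <- strsplit(ref, "")[[1]]; y <- strsplit(ref, "")[[1]]
    for (p in sample(200, 6)) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
    for (p in sample(200, 4)) y[p] <- setdiff(c("A", "C", "G", "T"), y[p])[2]
    expect_equal(
      diagnostic_distance(paste(x, collapse = ""), paste(y, collapse = ""), ref),
      sum(x != y))
  }
})

test_that("sequential acquisition holds for sorted trees and fails on reversion", {
  plan <- rbind(
    data.frame(name = "P", parent = NA, branch = "hs", n_diag = 2,
               del_len = 0, n_copies = 40, age = 1),
    data.frame(name = "C", parent = "P", branch = "hs", n_diag = 2,
               del_len = 0, n_copies = 25, age = 0.5))
  ms <- mini_sim(plan, seed = 8, mut_rate = 0, trunc_prob = 0)
  tree <- sort_subfamilies(ms$m, ms$cfg$reference)
  expect_equal(nrow(sequentiality_check(tree)), 0L)

  ## hand-built tree with a back-mutation G -> A at position 100
  ref <- random_dna(200)
  stopifnot(substr(ref, 100, 100) != "G")
  anc_state <- substr(ref, 100, 100)
  bad <- manual_tree(ref, list(
    list(name = "p", parent = "root",
         diagnostics = data.frame(kind = "sub", pos = 100L, len = 1L,
                                  ref = anc_state, alt = "G")),
    list(name = "c", parent = "p",
         diagnostics = data.frame(kind = "sub", pos = 100L, len = 1L,
                                  ref = "G", alt = anc_state))))
  v <- sequentiality_check(bad)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 100L)
  expect_equal(v$subfamily, "c")

  ## simulated lineage plans acquire diagnostics sequentially
  truth_tree <- manual_tree(ms$cfg$reference, lapply(ms$sim$sources, function(s)
    list(name = s$name,
         parent = if (s$name %in% plan$name[is.na(plan$parent)]) "root"
                  else plan$parent[plan$name == s$name],
         diagnostics = s$diagnostics)))
  expect_equal(nrow(sequentiality_check(truth_tree)), 0L)
})

test_that("co-segregating variant groups are recovered from consensuses", {
  ref <- random_dna(300)
  rc <- strsplit(ref, "")[[1]]
  alt_of <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  ## planted co-segregating triple at 40/80/120 in 4 of 6 consensuses,
  ## private variants elsewhere
  cons <- list()
  for (i in 1:6) {
    x <- rc
    if (i <= 4) for (p in c(40, 80, 120)) x[p] <- alt_of(x[p])
    x[200 + i] <- alt_of(x[200 + i])
    cons[[paste0("c", i)]] <- paste(x, collapse = "")
  }
  g <- cosegregation_scan(cons, ref)
  expect_equal(nrow(g), 1L)
  expect_equal(g$positions, "40,80,120")
  expect_equal(g$n_carriers, 4L)
  ## a single consensus yields no groups
  expect_equal(nrow(cosegregation_scan(cons[1], ref)), 0L)
})
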
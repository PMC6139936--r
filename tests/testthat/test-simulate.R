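test_that("simulation is deterministic given a seed and varies across seeds", {
  plan <- default_lineage_plan()[1:3, ]
  plan$n_copies <- c(12L, 10L, 10L)
  cfg <- function(s) simulation_config(ref_length = 200, lineages = plan,
                                       seed = s)
  a <- simulate_expansion(cfg(7))
  b <- simulate_expansion(cfg(7))
  expect_identical(a$elements, b$elements)
  expect_identical(a$truth, b$truth)
  c <- simulate_expansion(cfg(8))
  expect_false(identical(a$elements$sequence, c$elements$sequence))
})

test_that("a seed is mandatory and bad lineage plans are rejected", {
  expect_error(simulation_config(ref_length = 100), "seed")
  bad <- rbind(
    data.frame(name = "child", parent = "parent", branch = "hs", n_diag = 1,
               del_len = 0, n_copies = 5, age = 1),
    data.frame(name = "parent", parent = NA, branch = "hs", n_diag = 1,
               del_len = 0, n_copies = 5, age = 1))
  expect_error(simulation_config(ref_length = 100, lineages = bad, seed = 1),
               "before its parent")
})

test_that("zero mutation rate reproduces the source sequence exactly", {
  plan <- data.frame(name = "sf", parent = NA, branch = "hs", n_diag = 3,
                     del_len = 0, n_copies = 15, age = 2)
  cfg <- simulation_config(ref_length = 250, lineages = plan, mut_rate = 0,
                           trunc_prob = 0, untemplated_g_prob = 0, seed = 4)
  sim <- simulate_expansion(cfg)
  src <- consensus_sequence(sim$sources$sf$states)
  expect_true(all(sim$elements$sequence == src))
  expect_equal(nrow(sim$truth), 15L)
})

test_that("copy counts and species emission follow the plan", {
  plan <- rbind(
    data.frame(name = "anc", parent = NA, branch = "hominine", n_diag = 2,
               del_len = 0, n_copies = 10, age = 1),
    data.frame(name = "hc", parent = "anc", branch = "hc", n_diag = 1,
               del_len = 0, n_copies = 6, age = 1),
    data.frame(name = "solo", parent = NA, branch = "gg", n_diag = 2,
               del_len = 0, n_copies = 7, age = 1))
  cfg <- simulation_config(ref_length = 200, lineages = plan, loss_prob = 0,
                           seed = 2)
  sim <- simulate_expansion(cfg)
  tab <- table(sim$truth$lineage, sim$truth$species)
  expect_equal(unname(tab["anc", c("gg", "pt", "hs")]), c(10L, 10L, 10L))
  expect_equal(unname(tab["hc", c("pt", "hs")]), c(6L, 6L))
  expect_equal(sum(tab["hc", "gg"]), 0L)
  expect_equal(unname(tab["solo", "gg"]), 7L)
  ## shared flags and locus ids are consistent
  anc <- sim$truth[sim$truth$lineage == "anc", ]
  expect_true(all(anc$shared))
  expect_equal(length(unique(anc$locus_id)), 10L)
})

test_that("diagnostics accumulate sequentially along lineages", {
  plan <- default_lineage_plan()
  plan$n_copies <- rep(1L, nrow(plan))
  cfg <- simulation_config(ref_length = 490, lineages = plan, seed = 6)
  sim <- simulate_expansion(cfg)
  for (i in seq_len(nrow(plan))) {
    p <- plan$parent[i]
    if (is.na(p)) next
    child_full <- sim$sources[[plan$name[i]]]$full_diagnostics
    parent_full <- sim$sources[[p]]$full_diagnostics
    key <- function(d) paste(d$kind, d$pos, d$alt)
    expect_true(all(key(parent_full) %in% key(child_full)))
    expect_gt(nrow(child_full), nrow(parent_full))
    ## no position is ever touched twice (no reversions by construction)
    expect_equal(anyDuplicated(child_full$pos), 0L)
  }
  ## the truth lineage tree passes the sequentiality check
  tt <- manual_tree(cfg$reference, lapply(sim$sources, function(s)
    list(name = s$name,
         parent = if (is.na(plan$parent[plan$name == s$name])) "root"
                  else plan$parent[plan$name == s$name],
         diagnostics = s$diagnostics)))
  expect_equal(nrow(sequentiality_check(tt)), 0L)
})

test_that("within-subfamily divergence matches the Poisson expectation", {
  ## mean pairwise divergence ~ 2 x age x rate (substitutions per site)
  age <- 2; rate <- 0.01
  plan <- data.frame(name = "sf", parent = NA, branch = "hs", n_diag = 2,
                     del_len = 0, n_copies = 12, age = age)
  divs <- vapply(1:20, function(s) {
    cfg <- simulation_config(ref_length = 300, lineages = plan,
                             mut_rate = rate, trunc_prob = 0,
                             untemplated_g_prob = 0, seed = 100 + s)
    sim <- simulate_expansion(cfg)
    seqs <- sim$elements$sequence
    pairs <- utils::combn(length(seqs), 2)
    mean(vapply(seq_len(ncol(pairs)), function(k)
      hamming(seqs[pairs[1, k]], seqs[pairs[2, k]]) / nchar(seqs[1]),
      numeric(1)))
  }, numeric(1))
  expected <- 2 * age * rate
  se <- sd(divs) / sqrt(length(divs))
  expect_lt(abs(mean(divs) - expected), 3 * se + 0.002)
})

test_that("partition scoring behaves like an adjusted Rand index", {
  truth <- setNames(rep(letters[1:4], each = 25), paste0("e", 1:100))
  expect_equal(score_partition(truth, truth)$ari, 1.0)
  one <- setNames(rep("x", 100), names(truth))
  expect_lt(abs(score_partition(one, truth)$ari), 1e-9)
  ## permutation null: |ARI| stays near zero
  set.seed(30)
  null_ari <- vapply(1:100, function(i) {
    perm <- setNames(sample(unname(truth)), names(truth))
    adjusted_rand(perm, truth)
  }, numeric(1))
  expect_lt(max(abs(null_ari)), 0.2)
  expect_lt(abs(mean(null_ari)), 0.05)
  ## agreement with the mclust implementation on random labelings
  for (i in 1:10) {
    x <- sample(letters[1:5], 60, replace = TRUE)
    y <- sample(letters[1:4], 60, replace = TRUE)
    expect_equal(adjusted_rand(x, y), mclust::adjustedRandIndex(x, y))
  }
  expect_error(score_partition(one[1:50], truth), "universes")
})

test_that("presence scoring reports accuracy and confusion", {
  truth <- data.frame(locus_id = paste0("l", 1:10),
                      call = rep(c("shared", "specific"), c(4, 6)))
  expect_equal(score_presence(truth, truth)$accuracy, 1.0)
  base <- truth; base$call <- "specific"
  sc <- score_presence(base, truth)
  expect_equal(sc$accuracy, 0.6)
  expect_equal(unname(sc$per_class["shared"]), 0)
  expect_error(score_presence(base[1:3, ], truth), "universes")
})
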
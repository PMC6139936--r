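sva <- build_canonical_sva()

test_that("canonical domain structure is annotated at the planted spans", {
  ann <- annotate_domains(sva$sequence, sva$refs)
  expect_true(ann$is_sva)
  expect_setequal(ann$spans$domain,
                  c("hexamer", "alu_like", "vntr", "sine_r", "polyA"))
  for (d in ann$spans$domain) {
    got <- ann$spans[ann$spans$domain == d, ]
    want <- sva$domains[sva$domains$domain == d, ]
    expect_lte(abs(got$start - want$start), 5)
    expect_lte(abs(got$end - want$end), 5)
  }
  ## spans are ordered and non-overlapping
  sp <- ann$spans[order(ann$spans$start), ]
  expect_true(all(diff(sp$start) > 0))
  expect_true(all(sp$end[-nrow(sp)] < sp$start[-1]))
  expect_true(all(sp$end <= nchar(sva$sequence)))
})

test_that("5'-truncated elements lose the hexamer but keep the rest", {
  tr <- substr(sva$sequence, 40, nchar(sva$sequence))
  ann <- annotate_domains(tr, sva$refs)
  expect_true(ann$is_sva)
  expect_true("hexamer" %in% ann$absent)
  expect_true("sine_r" %in% ann$spans$domain)
})

test_that("random sequence is not an SVA", {
  set.seed(20)
  ann <- annotate_domains(random_dna(1200), sva$refs)
  expect_false(ann$is_sva)
  expect_true("sine_r" %in% ann$absent)
})

test_that("planted captures recover donor exon and acquired length", {
  set.seed(21)
  exon <- random_dna(400, gc = 0.6)
  plan <- data.frame(name = "pt_D6", parent = NA, branch = "pt", n_diag = 2,
                     del_len = 0, n_copies = 30, age = 0.5)
  cfg <- simulation_config(
    reference = sva$sequence, lineages = plan, trunc_prob = 0,
    mut_rate = 0.002,
    captures = list(list(lineage = "pt_D6", exon_name = "STK40_ex1",
                         exon_seq = exon, junction = sva$capture_junction,
                         acq_len_range = c(120L, 220L), n_canonical = 3L)),
    seed = 9)
  sim <- simulate_expansion(cfg)
  lib <- c(STK40_ex1 = exon, MAST2_ex1 = random_dna(350, gc = 0.6),
           other = random_dna(300))
  n_cap <- 0L; donor_ok <- 0L; len_ok <- 0L; acceptor_ok <- 0L
  for (i in seq_len(nrow(sim$elements))) {
    el <- sim$elements$sequence[i]
    tr <- sim$truth[i, ]
    ann <- annotate_domains(el, sva$refs)
    nc <- detect_noncanonical_5p(el, ann, sva$refs)
    if (!is.na(tr$capture_donor)) {
      n_cap <- n_cap + 1L
      expect_false(is.null(nc))
      if (isTRUE(nc$acceptor_ag == "pass")) acceptor_ok <- acceptor_ok + 1L
      call <- assign_exon_source(substr(el, nc$span[1], nc$span[2]), lib)
      if (inherits(call, "capture_call")) {
        donor_ok <- donor_ok + (call$exon == tr$capture_donor)
        len_ok <- len_ok + (call$acquired_len == tr$capture_len)
      }
    } else {
      ## canonical members of a capture family are never flagged
      expect_null(nc)
    }
  }
  expect_equal(n_cap, 27L)
  expect_gte(donor_ok / n_cap, 0.95)
  expect_gte(len_ok / n_cap, 0.95)
  expect_gte(acceptor_ok / n_cap, 0.95)
})

test_that("canonical elements with post-insertion divergence never fire", {
  plan <- data.frame(name = "d", parent = NA, branch = "hs", n_diag = 2,
                     del_len = 0, n_copies = 15, age = 4)
  cfg <- simulation_config(reference = sva$sequence, lineages = plan,
                           mut_rate = 0.005, trunc_prob = 0, seed = 33)
  sim <- simulate_expansion(cfg)                 # ~2% divergence copies
  for (i in seq_len(nrow(sim$elements))) {
    el <- sim$elements$sequence[i]
    ann <- annotate_domains(el, sva$refs)
    expect_null(detect_noncanonical_5p(el, ann, sva$refs))
  }
})

test_that("the splice criterion gates exon assignment", {
  set.seed(22)
  exon <- random_dna(400, gc = 0.6)
  lib <- c(ex1 = exon, ex2 = random_dna(300, gc = 0.6))
  ## exact 180-nt suffix of a library exon
  seg <- substr(exon, 221, 400)
  call <- assign_exon_source(seg, lib)
  expect_s3_class(call, "capture_call")
  expect_equal(call$exon, "ex1")
  expect_equal(call$acquired_len, 180L)
  expect_null(call$transduction_span)
  ## segment matching the exon interior, not its 3' end: unassigned
  expect_null(assign_exon_source(substr(exon, 100, 300), lib))
  ## no library hit
  expect_null(assign_exon_source(random_dna(180), lib))
  ## two identical library exons: ambiguous
  expect_equal(assign_exon_source(seg, c(a = exon, b = exon)), "ambiguous")
  ## sequence 5' of the exon match is additional transduction
  seg2 <- paste0(random_dna(60), substr(exon, 251, 400))
  call2 <- assign_exon_source(seg2, lib)
  expect_s3_class(call2, "capture_call")
  expect_equal(call2$transduction_span[1], 1L)
  ## chance agreement at the boundary may extend the exon match by a base
  expect_lte(abs(call2$transduction_span[2] - 60L), 1L)
})

test_that("capture length histograms deduplicate identical lengths", {
  expect_equal(capture_length_distribution(c(120, 120, 85)), c(85L, 120L))
  expect_equal(capture_length_distribution(numeric()), integer())
  expect_equal(capture_length_distribution(c(70, 85, 120)), c(70L, 85L, 120L))
})
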
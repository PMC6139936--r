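#' Default source-lineage plan
#'
#' Fifteen source lineages on the hominine tree `((hs, pt), gg)`:
#' a basal lineage with shared expansion before the splits, a derived
#' lineage acquiring three further diagnostics, a 20-bp-deletion founder,
#' an 11-bp-deletion founder on the chimpanzee-human branch whose human
#' descendant is the major expanding lineage, and species-specific
#' lineages in all three species. Diagnostic counts (2-3 per lineage) and
#' copy numbers (30-200) follow the ranges seen in real SVA_D subfamily
#' tables; ages are relative units chosen so that copies carry 0.5-2%
#' post-insertion divergence at the default mutation rate.
#'
#' Branches: `hominine` (before both splits; copies emitted in all three
#' species), `hc` (chimpanzee-human ancestor), `gg`/`pt`/`hs` (terminal).
#'
#' @return data.frame with columns `name`, `parent` (`NA` = root
#'   reference), `branch`, `n_diag`, `del_len` (0 = none), `n_copies`,
#'   `age`
#' @export
default_lineage_plan <- function() {
  plan <- rbind(
    data.frame(name = "D1",     parent = NA,       branch = "hominine", n_diag = 3, del_len = 0,  n_copies = 140, age = 4),
    data.frame(name = "D2",     parent = "D1",     branch = "hominine", n_diag = 1, del_len = 20, n_copies = 90,  age = 3.5),
    data.frame(name = "DR",     parent = "D1",     branch = "hominine", n_diag = 3, del_len = 0,  n_copies = 130, age = 3),
    data.frame(name = "gg_DR1", parent = "DR",     branch = "gg",       n_diag = 3, del_len = 0,  n_copies = 170, age = 2),
    data.frame(name = "gg_DR2", parent = "gg_DR1", branch = "gg",       n_diag = 2, del_len = 0,  n_copies = 90,  age = 1),
    data.frame(name = "pt_DR1", parent = "DR",     branch = "pt",       n_diag = 3, del_len = 0,  n_copies = 150, age = 2),
    data.frame(name = "pt_DR2", parent = "pt_DR1", branch = "pt",       n_diag = 2, del_len = 0,  n_copies = 70,  age = 1),
    data.frame(name = "hs_DR1", parent = "DR",     branch = "hs",       n_diag = 3, del_len = 0,  n_copies = 80,  age = 1.5),
    data.frame(name = "F",      parent = "DR",     branch = "hc",       n_diag = 2, del_len = 11, n_copies = 50,  age = 2.5),
    data.frame(name = "hs_F",   parent = "F",      branch = "hs",       n_diag = 3, del_len = 0,  n_copies = 180, age = 1),
    data.frame(name = "pt_F",   parent = "F",      branch = "pt",       n_diag = 2, del_len = 0,  n_copies = 60,  age = 1),
    data.frame(name = "gg_D3",  parent = "D1",     branch = "gg",       n_diag = 3, del_len = 0,  n_copies = 110, age = 2.5),
    data.frame(name = "hs_D4",  parent = "D1",     branch = "hs",       n_diag = 2, del_len = 0,  n_copies = 50,  age = 1.5),
    data.frame(name = "pt_D4",  parent = "D1",     branch = "pt",       n_diag = 2, del_len = 0,  n_copies = 45,  age = 1.5),
    data.frame(name = "hs_E",   parent = "hs_DR1", branch = "hs",       n_diag = 2, del_len = 0,  n_copies = 30,  age = 1))
  plan
}

BRANCH_SPECIES <- list(hominine = c("gg", "pt", "hs"),
                       hc = c("pt", "hs"),
                       gg = "gg", pt = "pt", hs = "hs")

#' Simulation configuration
#'
#' @param reference root reference sequence; generated at random
#'   (`ref_length` nt) when `NULL`
#' @param ref_length length of a generated reference (default 1000)
#' @param lineages source-lineage plan, see [default_lineage_plan()]
#' @param mut_rate post-insertion substitution rate per site per age unit
#'   (default 0.005: an age-4 copy carries ~2% divergence)
#' @param trunc_prob probability that a copy is 5'-truncated (default 0.2)
#' @param trunc_max maximal truncated fraction (default 0.5, so truncated
#'   copies keep at least half of the reference)
#' @param tsd_len_range target-site-duplication length range (default 8-18)
#' @param untemplated_g_prob probability of an untemplated 5' G (default
#'   0.15)
#' @param loss_prob per-species loss probability for copies inserted before
#'   a split (incomplete-lineage-sorting proxy, default 0.1)
#' @param flank_len flank length recorded per locus (default 50)
#' @param n_decoy_pairs cross-species locus pairs planted at the same
#'   context with insertion points offset by 1 nt (default 0)
#' @param captures list of capture events: each a list with `lineage`,
#'   `exon_name`, `exon_seq`, `junction` (reference position where the
#'   retained element part starts), `acq_len_range`, and optional
#'   `n_canonical` (copies of the lineage left canonical)
#' @param seed mandatory integer seed
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(reference = NULL, ref_length = 1000L,
                              lineages = default_lineage_plan(),
                              mut_rate = 0.005, trunc_prob = 0.2,
                              trunc_max = 0.5, tsd_len_range = c(8L, 18L),
                              untemplated_g_prob = 0.15, loss_prob = 0.1,
                              flank_len = 50L, n_decoy_pairs = 0L,
                              captures = list(), seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(mut_rate >= 0, mut_rate <= 1, trunc_prob >= 0, trunc_prob <= 1,
            loss_prob >= 0, loss_prob <= 1, all(lineages$n_copies >= 0))
  ## parents must be defined before their children
  for (i in seq_len(nrow(lineages))) {
    p <- lineages$parent[i]
    if (!is.na(p) && !(p %in% lineages$name[seq_len(i - 1L)])) {
      stop("lineage plan lists child '", lineages$name[i],
           "' before its parent '", p, "'")
    }
  }
  if (is.null(reference)) {
    reference <- with_substream(seed, "reference", random_dna(ref_length))
  }
  structure(list(reference = toupper(reference), lineages = lineages,
                 mut_rate = mut_rate, trunc_prob = trunc_prob,
                 trunc_max = trunc_max, tsd_len_range = tsd_len_range,
                 untemplated_g_prob = untemplated_g_prob,
                 loss_prob = loss_prob, flank_len = flank_len,
                 n_decoy_pairs = n_decoy_pairs, captures = captures,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## assign each lineage its source state vector and diagnostic set:
## diagnostics accumulate sequentially along the lineage path and are never
## placed at a position an ancestor already changed (no reversions)
plan_sources <- function(config) {
  ref <- seq_chars(config$reference)
  L <- length(ref)
  lineages <- config$lineages
  sources <- list()
  with_substream(config$seed, "lineage", {
    for (i in seq_len(nrow(lineages))) {
      nm <- lineages$name[i]
      parent <- lineages$parent[i]
      if (is.na(parent)) {
        states <- ref; used <- integer(); diags <- empty_diag()
      } else {
        states <- sources[[parent]]$states
        used <- sources[[parent]]$used
        diags <- empty_diag()
      }
      free <- setdiff(which(states != STATE_DEL), used)
      if (lineages$del_len[i] > 0L) {
        len <- lineages$del_len[i]
        ok <- FALSE
        while (!ok) {
          st <- sample(free[free <= L - len], 1L)
          span <- st:(st + len - 1L)
          ok <- all(states[span] != STATE_DEL) && !any(span %in% used)
        }
        states[span] <- STATE_DEL
        used <- c(used, span)
        diags <- rbind(diags, data.frame(kind = "del", pos = st, len = len,
                                         ref = chars_seq(ref[span]), alt = "-"))
        free <- setdiff(free, span)
      }
      if (lineages$n_diag[i] > 0L) {
        pos <- sort(sample(free, lineages$n_diag[i]))
        for (p in pos) {
          alt <- sample(setdiff(DNA_BASES4, states[p]), 1L)
          diags <- rbind(diags, data.frame(kind = "sub", pos = p, len = 1L,
                                           ref = states[p], alt = alt))
          states[p] <- alt
        }
        used <- c(used, pos)
      }
      sources[[nm]] <- list(name = nm, states = states, used = used,
                            diagnostics = diags,
                            full_diagnostics = if (is.na(parent)) diags
                              else rbind(sources[[parent]]$full_diagnostics, diags))
    }
  })
  sources
}

empty_diag <- function() data.frame(kind = character(), pos = integer(),
                                    len = integer(), ref = character(),
                                    alt = character())

## one insertion locus: A-rich target context with the insertion point a
## short distance downstream of an A-tract, plus the TSD duplicated on
## integration
make_locus <- function(flank_len, tsd_len_range, locus_id) {
  a_len <- sample(6:14, 1L)
  gap <- sample(0:2, 1L)                     # nt between tract end and site
  left <- random_dna(flank_len + 10L)
  right <- random_dna(flank_len + 30L)
  context <- paste0(left, strrep("A", a_len), random_dna(gap), right)
  ip <- nchar(left) + a_len + gap + 1L       # insertion point (1-based)
  tl <- sample(tsd_len_range[1]:tsd_len_range[2], 1L)
  tsd <- substr(context, ip, ip + tl - 1L)
  list(locus_id = locus_id, context = context, ip = ip, tsd = tsd,
       a_tract_gap = gap)
}

locus_flanks <- function(locus, flank_len) {
  up <- substr(locus$context, 1L, locus$ip - 1L)
  down <- substr(locus$context, locus$ip, nchar(locus$context))
  list(flank5 = paste0(substr(up, max(1L, nchar(up) - (flank_len - nchar(locus$tsd)) + 1L), nchar(up)), locus$tsd),
       flank3 = substr(paste0(locus$tsd, down), 1L, flank_len))
}

mutate_seq <- function(x, n_sub) {
  if (n_sub == 0L || !nzchar(x)) return(x)
  ch <- seq_chars(x)
  pos <- sample(length(ch), min(n_sub, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES4, ch[p]), 1L)
  chars_seq(ch)
}

#' Forward-simulate an SVA-like subfamily expansion
#'
#' Source elements acquire their diagnostic variants sequentially along the
#' planned lineages (never reverting an ancestor's diagnostic); every copy
#' is its source plus `Poisson(age x rate x length)` random post-insertion
#' substitutions; insertions land in A-rich target contexts with exact
#' target-site duplications; copies on pre-split branches are emitted in
#' every descendant species (each instance mutating and losing copies
#' independently); 5' truncation, untemplated 5' G and exon-capture
#' founders follow the configuration. Deterministic given the seed.
#'
#' @param config a [simulation_config()]
#' @return list with `elements` (an `element_set` with flanks and locus
#'   labels), `truth` (one row per emitted element: species, lineage,
#'   locus, TSD, truncation, capture, sharing), `loci` (one row per planted
#'   locus) and `sources` (per-lineage source state vectors and diagnostic
#'   sets)
#' @export
simulate_expansion <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sources <- plan_sources(config)
  lineages <- config$lineages
  L <- nchar(config$reference)
  flank_len <- config$flank_len

  ## plan loci and species emissions
  rows <- list(); loci <- list(); locus_n <- 0L
  with_substream(config$seed, "placement", {
    for (i in seq_len(nrow(lineages))) {
      nm <- lineages$name[i]
      spp <- BRANCH_SPECIES[[lineages$branch[i]]]
      for (cp in seq_len(lineages$n_copies[i])) {
        locus_n <- locus_n + 1L
        loc <- make_locus(flank_len, config$tsd_len_range,
                          sprintf("locus_%04d", locus_n))
        loci[[locus_n]] <- loc
        present <- if (length(spp) > 1L) {
          keep <- runif(length(spp)) >= config$loss_prob
          spp[keep]
        } else spp
        for (sp in present) {
          rows[[length(rows) + 1L]] <- list(
            lineage = nm, species = sp, copy = cp, locus = loc,
            age = lineages$age[i], shared = length(present) > 1L)
        }
      }
    }
    ## decoy pairs: same context, insertion points 1 nt apart, two species
    if (config$n_decoy_pairs > 0L) {
      decoy_lineage <- lineages$name[1L]
      for (d in seq_len(config$n_decoy_pairs)) {
        locus_n <- locus_n + 1L
        loc <- make_locus(flank_len, config$tsd_len_range,
                          sprintf("decoy_%03d_a", d))
        loc2 <- loc
        loc2$locus_id <- sprintf("decoy_%03d_b", d)
        loc2$ip <- loc$ip + 1L
        loc2$tsd <- substr(loc2$context, loc2$ip,
                           loc2$ip + nchar(loc$tsd) - 1L)
        loci[[locus_n]] <- loc
        loci[[locus_n + 1L]] <- loc2
        locus_n <- locus_n + 1L
        rows[[length(rows) + 1L]] <- list(lineage = decoy_lineage,
                                          species = "hs", copy = 0L,
                                          locus = loc, age = 1, shared = FALSE)
        rows[[length(rows) + 1L]] <- list(lineage = decoy_lineage,
                                          species = "pt", copy = 0L,
                                          locus = loc2, age = 1, shared = FALSE)
      }
    }
  })

  ## capture plan lookup
  cap_by_lineage <- list()
  for (cv in config$captures) cap_by_lineage[[cv$lineage]] <- cv

  el <- list(); tr <- list()
  counters <- list()
  with_substream(config$seed, "mutation", {
    for (r in rows) {
      src <- sources[[r$lineage]]
      states <- src$states
      alive <- which(states != STATE_DEL)
      n_mut <- rpois(1L, r$age * config$mut_rate * length(alive))
      if (n_mut > 0L) {
        mp <- sample(alive, min(n_mut, length(alive)))
        for (p in mp) states[p] <- sample(setdiff(DNA_BASES4, states[p]), 1L)
      }
      seqc <- consensus_sequence(states)

      ## exon capture: replace everything 5' of the junction by an exon
      ## suffix of the planned acquired length
      cap <- cap_by_lineage[[r$lineage]]
      cap_donor <- NA_character_; cap_len <- NA_integer_
      if (!is.null(cap)) {
        n_canon <- if (is.null(cap$n_canonical)) 0L else cap$n_canonical
        if (r$copy > n_canon) {
          keep_from <- sum(seq_chars(config$reference)[seq_len(cap$junction - 1L)] %in% DNA_BASES4)
          acq <- sample(cap$acq_len_range[1]:cap$acq_len_range[2], 1L)
          acq <- min(acq, nchar(cap$exon_seq))
          exon_part <- substr(cap$exon_seq, nchar(cap$exon_seq) - acq + 1L,
                              nchar(cap$exon_seq))
          body_keep <- sum(states[cap$junction:L] %in% c(DNA_BASES4))
          seqc <- paste0(exon_part,
                         substr(seqc, nchar(seqc) - body_keep + 1L, nchar(seqc)))
          cap_donor <- cap$exon_name; cap_len <- acq
        }
      }

      ## untemplated 5' G from reverse transcription of the cap
      has_g <- runif(1L) < config$untemplated_g_prob
      if (has_g) seqc <- paste0("G", seqc)

      ## 5' truncation
      trunc_len <- 0L
      if (runif(1L) < config$trunc_prob) {
        trunc_len <- floor(runif(1L, 0, config$trunc_max) * nchar(seqc))
        if (trunc_len > 0L) seqc <- substr(seqc, trunc_len + 1L, nchar(seqc))
      }

      ## flanks with independently aged TSD copies and flank drift
      fl <- locus_flanks(r$locus, flank_len)
      tlen <- nchar(r$locus$tsd)
      f5 <- mutate_seq(fl$flank5, rpois(1L, r$age * config$mut_rate * flank_len))
      f3 <- mutate_seq(fl$flank3, rpois(1L, r$age * config$mut_rate * flank_len))

      ckey <- paste(r$species, r$lineage, sep = ".")
      counters[[ckey]] <- (if (is.null(counters[[ckey]])) 0L
                           else counters[[ckey]]) + 1L
      id <- sprintf("%s_%s_%03d", r$species, r$lineage, counters[[ckey]])
      el[[length(el) + 1L]] <- data.frame(
        id = id, species = r$species, sequence = seqc,
        flank5 = f5, flank3 = f3, locus_label = r$locus$locus_id)
      tr[[length(tr) + 1L]] <- data.frame(
        id = id, species = r$species, lineage = r$lineage,
        locus_id = r$locus$locus_id, shared = r$shared, age = r$age,
        trunc_len = trunc_len, tsd = r$locus$tsd,
        tsd5 = substr(f5, nchar(f5) - tlen + 1L, nchar(f5)),
        tsd3 = substr(f3, 1L, tlen),
        untemplated_g = has_g, capture_donor = cap_donor,
        capture_len = cap_len)
    }
  })

  loci_df <- do.call(rbind, lapply(loci, function(l) data.frame(
    locus_id = l$locus_id, context = l$context, ip = l$ip, tsd = l$tsd,
    a_tract_gap = l$a_tract_gap)))
  list(elements = element_set(do.call(rbind, el)),
       truth = do.call(rbind, tr),
       loci = loci_df,
       sources = sources)
}
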
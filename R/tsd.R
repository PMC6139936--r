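#' Extract the target-site duplication from a locus
#'
#' The TSD is the longest suffix of the 5' flank that matches a prefix of
#' the 3' flank within `max_mismatch` mismatches; ties go to the longer
#' duplication, then to fewer mismatches. Freshly inserted elements carry
#' two identical copies; older ones accumulate independent mutations.
#'
#' @param flank5,flank3 flanking sequences (element excluded)
#' @param min_len minimum reported TSD length (default 5)
#' @param max_len maximum searched length (default 30)
#' @param max_mismatch tolerated mismatches between the copies (default 1)
#' @return a `tsd_pair` (list with `tsd5`, `tsd3`, `length`,
#'   `mismatch_positions` 1-based from the TSD 5' end) or `NULL` when no
#'   duplication qualifies
#' @export
extract_tsd <- function(flank5, flank3, min_len = 5L, max_len = 30L,
                        max_mismatch = 1L) {
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  top <- min(max_len, nchar(flank5), nchar(flank3))
  best <- NULL
  for (len in seq(top, min_len)) {
    t5 <- substr(flank5, nchar(flank5) - len + 1L, nchar(flank5))
    t3 <- substr(flank3, 1L, len)
    mm <- which(seq_chars(t5) != seq_chars(t3))
    if (length(mm) <= max_mismatch) {
      best <- structure(list(tsd5 = t5, tsd3 = t3, length = len,
                             mismatch_positions = mm), class = "tsd_pair")
      break                     # lengths scanned longest-first
    }
  }
  best
}

#' Compare an observed TSD to an inferred pre-integration site
#'
#' End-gap tolerant: the shorter sequence is slid against the longer one,
#' the placement with the fewest internal substitutions wins (ties keep
#' the gap at the 3' end), and the terminal length difference is reported
#' separately from the substitutions -- a TSD one base shorter than the
#' ancestral site still counts a single mutation if one internal base
#' changed. A single extra base extending a homopolymer run (length >= 3)
#' is reported as replication slippage rather than a substitution.
#'
#' @param observed observed TSD sequence
#' @param ancestral inferred ancestral (pre-integration) site sequence
#' @return a `tsd_comparison`: list with `substitutions` (data.frame
#'   `pos` 1-based from the TSD 5' end, `ancestral`, `observed`), `count`,
#'   `length_diff` (observed minus ancestral, nt), `slippage` (TRUE when
#'   the length difference is a homopolymer expansion)
#' @export
compare_tsd <- function(observed, ancestral) {
  obs <- toupper(observed); anc <- toupper(ancestral)
  lo <- nchar(obs); la <- nchar(anc)
  short <- if (lo <= la) obs else anc
  long <- if (lo <= la) anc else obs
  ns <- nchar(short); nl <- nchar(long)
  ## slide the shorter sequence; terminal gaps only
  placements <- 0:(nl - ns)
  subs_at <- lapply(placements, function(off) {
    lw <- substr(long, off + 1L, off + ns)
    which(seq_chars(lw) != seq_chars(short)) + off
  })
  counts <- lengths(subs_at)
  ## prefer fewest substitutions; ties keep the gap at the 3' end (offset 0)
  best <- placements[order(counts, placements)][1L]
  idx <- which(placements == best)
  pos <- subs_at[[idx]]
  anc_b <- seq_chars(anc); obs_b <- seq_chars(obs)
  off_a <- if (lo <= la) 0L else best    # offset of ancestral within observed
  off_o <- if (lo <= la) best else 0L
  subs <- data.frame(pos = pos,
                     ancestral = anc_b[pos - off_a],
                     observed = obs_b[pos - off_o])
  slip <- FALSE
  if (abs(lo - la) == 1L && counts[idx] == 0L) {
    slip <- is_homopolymer_expansion(short, long)
  }
  structure(list(substitutions = subs, count = nrow(subs),
                 length_diff = lo - la, slippage = slip),
            class = "tsd_comparison")
}

## does `long` equal `short` with one extra base inside a homopolymer run
## of length >= 3?
is_homopolymer_expansion <- function(short, long) {
  cs <- seq_chars(short); cl <- seq_chars(long)
  for (i in seq_along(cl)) {
    if (chars_seq(cl[-i]) == short) {
      run <- cl[i]
      left <- i - 1L; while (left >= 1L && cl[left] == run) left <- left - 1L
      right <- i + 1L; while (right <= length(cl) && cl[right] == run) right <- right + 1L
      if ((right - left - 1L) >= 3L) return(TRUE)
    }
  }
  FALSE
}

#' Detect an untemplated 5' guanosine
#'
#' An extra G at the element 5' end that the duplicated target site does
#' not account for is the signature of reverse transcription running into
#' the SVA RNA cap. The element's leading G run is compared with the
#' trailing bases of the resolved target-site copy at the junction.
#'
#' @param element_5p the element's first bases (a short prefix suffices)
#' @param target_site the resolved target-site/TSD sequence 5' of the
#'   element, or `NA` when unresolved
#' @return list with `untemplated` (TRUE/FALSE, or `NA` = undetermined
#'   when the target site is unresolved) and `count` of untemplated Gs
#' @export
detect_untemplated_g <- function(element_5p, target_site) {
  if (is.na(target_site) || !nzchar(target_site)) {
    return(list(untemplated = NA, count = NA_integer_))
  }
  el <- seq_chars(element_5p)
  lead_g <- 0L
  while (lead_g < length(el) && el[lead_g + 1L] == "G") lead_g <- lead_g + 1L
  if (lead_g == 0L) return(list(untemplated = FALSE, count = 0L))
  ts <- seq_chars(toupper(target_site))
  trail_g <- 0L
  while (trail_g < length(ts) && ts[length(ts) - trail_g] == "G") trail_g <- trail_g + 1L
  count <- max(0L, lead_g - trail_g)
  list(untemplated = count > 0L, count = count)
}

#' Distance from the nearest upstream A-tract to an insertion point
#'
#' SVA integration shows a preference for sites at or just downstream of
#' A-tracts (a hotspot described for Alu-into-Alu insertion). Scans a
#' window upstream of the insertion point for the nearest run of >=
#' `min_tract_len` adenines and reports the distance from the run's 3' end
#' to the insertion point (0 = directly adjacent).
#'
#' @param target_context pre-integration sequence
#' @param insertion_point 1-based position before which the element
#'   inserted (the first base of the downstream flank / TSD)
#' @param min_tract_len minimum A-tract length (default 6)
#' @param window searched upstream distance in nt (default 50)
#' @return integer distance in nt, or `NULL` when no tract lies in the
#'   window
#' @export
a_tract_distance <- function(target_context, insertion_point,
                             min_tract_len = 6L, window = 50L) {
  ctx <- seq_chars(target_context)
  stopifnot(insertion_point >= 1L, insertion_point <= length(ctx) + 1L)
  lo <- max(1L, insertion_point - window)
  up <- ctx[lo:(insertion_point - 1L)]
  runs <- runs_of(up == "A")
  runs <- runs[runs$length >= min_tract_len, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  tract_end <- max(runs$start + runs$length - 1L) + lo - 1L
  as.integer(insertion_point - 1L - tract_end)
}
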
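#' Alignment scoring parameters
#'
#' Affine scheme: a gap of length L costs `gap_open + (L - 1) * gap_extend`.
#' Defaults (match +1, mismatch -2, open -6, extend -1) are adequate for
#' element copies at >= 90% identity to their reference and are configurable.
#'
#' @param match,mismatch,gap_open,gap_extend scoring values (penalties
#'   positive)
#' @param identity_floor alignments below this identity are flagged
#'   unalignable (after trying both strands)
#' @return list of scoring parameters
#' @export
alignment_scoring <- function(match = 1, mismatch = -2,
                              gap_open = 6, gap_extend = 1,
                              identity_floor = 0.6) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       identity_floor = identity_floor)
}

## substitution matrix over the IUPAC alphabet: ambiguity codes and N are
## scored 0 against everything so they neither support nor penalize a column
iupac_submat <- function(scoring) {
  letters <- c(DNA_BASES4, "M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "N")
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  m[DNA_BASES4, DNA_BASES4] <- scoring$mismatch
  diag(m)[1:4] <- scoring$match
  m
}

#' Align one element to a reference consensus
#'
#' Semi-global alignment: the element is aligned end to end against the best
#' matching window of the reference, so reference positions beyond the
#' element's ends are *missing*, never deleted. Internal gaps in the element
#' are deletions; extra element sequence is recorded as insertions. If the
#' forward-strand identity falls below the floor, the reverse complement is
#' tried and the better orientation kept.
#'
#' @param element element DNA string (or 1-row of an `element_set`)
#' @param reference reference DNA string
#' @param scoring see [alignment_scoring()]
#' @param element_id id stored in the profile
#' @return an `aligned_profile`: list with `element_id`, `states` (per
#'   reference position: base, `"-"` deleted, `"."` missing), `insertions`
#'   data.frame (`anchor`, `inserted`), `covered_fraction`, `identity`,
#'   `strand`, `unalignable`
#' @export
align_to_reference <- function(element, reference,
                               scoring = alignment_scoring(),
                               element_id = "element") {
  stopifnot(nzchar(element), nzchar(reference))
  p <- align_one(toupper(element), toupper(reference), scoring)
  if (p$identity < scoring$identity_floor) {
    p_rc <- align_one(revcomp(element), toupper(reference), scoring)
    if (p_rc$score > p$score) {
      p <- p_rc
      p$strand <- "-"
    }
  }
  p$unalignable <- p$identity < scoring$identity_floor
  p$element_id <- element_id
  class(p) <- "aligned_profile"
  p
}

align_one <- function(element, reference, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(element),
    subject = Biostrings::DNAString(reference),
    type = "global-local",
    substitutionMatrix = iupac_submat(scoring),
    gapOpening = scoring$gap_open - scoring$gap_extend,
    gapExtension = scoring$gap_extend)
  profile_from_alignment(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)),
    ref_start = Biostrings::start(Biostrings::subject(aln)),
    ref_len = nchar(reference),
    score = Biostrings::score(aln))
}

## walk alignment columns and project the element onto reference coordinates
profile_from_alignment <- function(ap, as_, ref_start, ref_len, score) {
  pat <- seq_chars(ap)
  sub <- seq_chars(as_)
  subgap <- sub == "-"                    # insertion columns
  rp <- ref_start - 1L + cumsum(!subgap)  # reference position per column
  states <- rep(STATE_MISSING, ref_len)
  cols <- which(!subgap)
  pc <- pat[cols]
  st <- ifelse(pc == STATE_DEL, STATE_DEL,
               ifelse(pc %in% DNA_BASES4, pc, STATE_MISSING))
  states[rp[cols]] <- st
  nmatch <- sum(pc %in% DNA_BASES4 & pc == sub[cols])
  insr <- runs_of(subgap)
  ins <- if (nrow(insr)) {
    data.frame(anchor = rp[insr$start],
               inserted = vapply(seq_len(nrow(insr)), function(i)
                 chars_seq(pat[insr$start[i] + seq_len(insr$length[i]) - 1L]),
                 character(1)))
  } else data.frame(anchor = integer(), inserted = character())
  list(states = states,
       insertions = ins,
       covered_fraction = mean(states != STATE_MISSING),
       identity = if (length(pat) > 0L) nmatch / length(pat) else 0,
       score = score,
       strand = "+")
}

#' Align a whole element set to a reference
#'
#' One vectorized alignment pass over the whole set; elements whose
#' forward-strand identity falls below the floor are retried individually
#' on the reverse complement.
#'
#' @param elements an `element_set`
#' @param reference reference DNA string
#' @param scoring see [alignment_scoring()]
#' @return named list of `aligned_profile`s (names = element ids)
#' @export
align_set <- function(elements, reference, scoring = alignment_scoring()) {
  reference <- toupper(reference)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(toupper(elements$sequence)),
    subject = Biostrings::DNAString(reference),
    type = "global-local",
    substitutionMatrix = iupac_submat(scoring),
    gapOpening = scoring$gap_open - scoring$gap_extend,
    gapExtension = scoring$gap_extend)
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  starts <- Biostrings::start(Biostrings::subject(aln))
  scores <- Biostrings::score(aln)
  profiles <- lapply(seq_len(nrow(elements)), function(i) {
    p <- profile_from_alignment(ap[i], as_[i], starts[i], nchar(reference),
                                scores[i])
    if (p$identity < scoring$identity_floor) {
      return(align_to_reference(elements$sequence[i], reference, scoring,
                                element_id = elements$id[i]))
    }
    p$unalignable <- FALSE
    p$element_id <- elements$id[i]
    class(p) <- "aligned_profile"
    p
  })
  setNames(profiles, elements$id)
}

#' Call variant events from an aligned profile
#'
#' Substitutions and deletions are read off the per-position state vector
#' relative to the reference; deletions are maximal contiguous runs reported
#' as single events; insertions were recorded at alignment time. Positions
#' with `N`/IUPAC calls are missing and never yield a substitution.
#'
#' @param profile an `aligned_profile`
#' @param reference the reference DNA string the profile was aligned to
#' @return data.frame with columns `kind` (`sub`/`del`/`ins`), `pos`
#'   (1-based reference position; deletion start; insertion anchor), `len`,
#'   `ref`, `alt`
#' @export
call_variants <- function(profile, reference) {
  ref <- seq_chars(reference)
  states <- profile$states
  stopifnot(length(states) == length(ref))
  subs_idx <- which(is_base_state(states) & states != ref)
  subs <- data.frame(kind = rep("sub", length(subs_idx)), pos = subs_idx,
                     len = rep(1L, length(subs_idx)),
                     ref = ref[subs_idx], alt = states[subs_idx])
  delr <- runs_of(states == STATE_DEL)
  dels <- data.frame(kind = rep("del", nrow(delr)), pos = delr$start,
                     len = delr$length,
                     ref = vapply(seq_len(nrow(delr)), function(i)
                       chars_seq(ref[delr$start[i] + seq_len(delr$length[i]) - 1L]),
                       character(1)),
                     alt = rep("-", nrow(delr)))
  ins <- profile$insertions
  insd <- data.frame(kind = rep("ins", nrow(ins)), pos = ins$anchor,
                     len = nchar(ins$inserted), ref = rep("-", nrow(ins)),
                     alt = ins$inserted)
  ev <- rbind(subs, dels, insd)
  ev[order(ev$pos, ev$kind), , drop = FALSE]
}

#' Coverage filter
#'
#' Elements lacking more than `1 - min_fraction` of the reference are
#' excluded from sorting; exactly the boundary is kept (the published filter
#' drops elements missing *more than* half of the SINE-R).
#'
#' @param profile an `aligned_profile`
#' @param min_fraction minimum covered fraction, default 0.5
#' @return TRUE iff `covered_fraction >= min_fraction`
#' @export
coverage_ok <- function(profile, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  profile$covered_fraction >= min_fraction
}

#' Stack profiles into a state matrix
#'
#' @param profiles list of `aligned_profile`s over the same reference
#' @return character matrix, rows = elements, columns = reference positions
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) > 0L)
  n <- length(profiles[[1]]$states)
  m <- t(vapply(profiles, function(p) {
    stopifnot(length(p$states) == n)
    p$states
  }, character(n)))
  rownames(m) <- vapply(profiles, `[[`, character(1), "element_id")
  m
}
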
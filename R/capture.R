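#' Annotate canonical SVA domain structure
#'
#' Locates, 5' to 3': the TCTCCC hexameric repeat region (>= 2 tandem
#' units, one mismatch per unit tolerated), the Alu-like domain, the VNTR
#' (the tandem-repeat region between Alu-like and SINE-R), the SINE-R and
#' the polyA tail. Domains are found by local alignment against the domain
#' references; a missing domain is flagged absent. Without a SINE-R hit
#' the element is not an SVA.
#'
#' @param element element sequence
#' @param refs list with `hexamer_unit` (default `"TCTCCC"`), `alu_like`
#'   and `sine_r` reference sequences
#' @param min_identity identity floor for a domain hit (default 0.6)
#' @return a `domain_annotation`: list with `spans` (data.frame `domain`,
#'   `start`, `end`, 1-based inclusive), `absent` (character vector),
#'   `is_sva`
#' @export
annotate_domains <- function(element, refs, min_identity = 0.6) {
  stopifnot(!is.null(refs$alu_like), !is.null(refs$sine_r))
  hex_unit <- if (is.null(refs$hexamer_unit)) "TCTCCC" else refs$hexamer_unit
  element <- toupper(element)
  n <- nchar(element)
  spans <- list(); absent <- character()

  sr <- domain_hit(element, refs$sine_r, min_identity)
  if (is.null(sr)) {
    return(structure(list(spans = data.frame(domain = character(),
                                             start = integer(), end = integer()),
                          absent = c("hexamer", "alu_like", "vntr", "sine_r", "polyA"),
                          is_sva = FALSE),
                     class = "domain_annotation"))
  }

  upstream <- substr(element, 1L, sr$start - 1L)
  al <- if (nchar(upstream) >= 20L) domain_hit(upstream, refs$alu_like, min_identity) else NULL

  hex <- hexamer_span(element, hex_unit,
                      limit = if (!is.null(al)) al$start - 1L else sr$start - 1L)
  if (!is.null(hex)) spans$hexamer <- c(hex$start, hex$end) else absent <- c(absent, "hexamer")
  if (!is.null(al)) spans$alu_like <- c(al$start, al$end) else absent <- c(absent, "alu_like")

  ## VNTR: tandem-repeat region between the Alu-like 3' end and SINE-R
  vn_lo <- if (!is.null(al)) al$end + 1L else 1L
  vn_hi <- sr$start - 1L
  vn <- if (vn_hi - vn_lo + 1L >= 40L)
    tandem_region(substr(element, vn_lo, vn_hi)) else NULL
  if (!is.null(vn)) spans$vntr <- c(vn_lo + vn$start - 1L, vn_lo + vn$end - 1L)
  else absent <- c(absent, "vntr")

  spans$sine_r <- c(sr$start, sr$end)

  ## polyA: trailing A-run after the SINE-R
  tail_seq <- seq_chars(substr(element, sr$end + 1L, n))
  pa <- runs_of(tail_seq == "A")
  pa <- pa[pa$length >= 5L, , drop = FALSE]
  if (nrow(pa)) {
    spans$polyA <- c(sr$end + pa$start[1L], sr$end + pa$start[1L] + pa$length[1L] - 1L)
  } else absent <- c(absent, "polyA")

  sp <- data.frame(domain = names(spans),
                   start = vapply(spans, `[`, numeric(1), 1L),
                   end = vapply(spans, `[`, numeric(1), 2L), row.names = NULL)
  sp <- sp[order(sp$start), , drop = FALSE]
  structure(list(spans = sp, absent = absent, is_sva = TRUE),
            class = "domain_annotation")
}

## best local placement of a domain reference within a sequence; NULL when
## identity of the aligned region is below the floor
domain_hit <- function(x, ref, min_identity) {
  if (!nzchar(x)) return(NULL)
  sc <- alignment_scoring()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref), subject = Biostrings::DNAString(x),
    type = "local", substitutionMatrix = iupac_submat(sc),
    gapOpening = sc$gap_open - sc$gap_extend, gapExtension = sc$gap_extend)
  if (Biostrings::nchar(aln) == 0L) return(NULL)
  pid <- Biostrings::pid(aln) / 100
  cov <- Biostrings::nchar(aln) / nchar(ref)
  if (pid < min_identity || cov < 0.5) return(NULL)
  list(start = Biostrings::start(Biostrings::subject(aln)),
       end = Biostrings::end(Biostrings::subject(aln)),
       identity = pid, coverage = cov)
}

## leading tandem hexamer units (<= 1 mismatch each), anywhere within the
## first few bases (tolerates an untemplated G)
hexamer_span <- function(element, unit, limit) {
  k <- nchar(unit)
  uc <- seq_chars(unit)
  best <- NULL
  for (offset in 0:4) {
    start <- offset + 1L
    units <- 0L
    while (start + (units + 1L) * k - 1L <= min(limit, nchar(element))) {
      w <- seq_chars(substr(element, start + units * k, start + (units + 1L) * k - 1L))
      if (sum(w != uc) <= 1L) units <- units + 1L else break
    }
    if (units >= 2L && (is.null(best) || units > best$units)) {
      best <- list(start = start, end = start + units * k - 1L, units = units)
    }
  }
  best
}

## largest region explained by a short repeating period: scans periods and
## keeps the span where shifted self-identity is high
tandem_region <- function(x) {
  n <- nchar(x)
  ch <- seq_chars(x)
  for (p in 10:60) {
    if (p >= n / 2) break
    same <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    if (mean(same) >= 0.6) {
      r <- runs_of(same)
      r <- r[which.max(r$length), , drop = FALSE]
      if (r$length + p >= 2L * p) {
        return(list(start = r$start, end = min(n, r$start + r$length - 1L + p),
                    period = p))
      }
    }
  }
  NULL
}

#' Detect a non-canonical (foreign) 5' end
#'
#' Returns the maximal 5' region upstream of the first recognizable SVA
#' domain anchor that fails to align to the hexamer/Alu-like references --
#' the signature of elements whose hexameric repeats and 5' Alu-like
#' portion were replaced by captured exon sequence. The junction is
#' checked for a splice-acceptor `AG` immediately preceding the retained
#' Alu-like position in the Alu-like reference.
#'
#' @param element element sequence
#' @param annotation a `domain_annotation` for the element
#' @param refs domain references (see [annotate_domains()])
#' @param min_identity identity floor below which the 5' region counts as
#'   foreign (default 0.6)
#' @param min_len minimal reported foreign length (default 30)
#' @return `NULL` for a canonical element, else a list with `span`
#'   (`c(start, end)` of the foreign segment), `junction` (element
#'   position where SVA sequence resumes), `alu_junction` (matching
#'   position in the Alu-like reference, `NA` if the anchor is not the
#'   Alu-like domain) and `acceptor_ag` (`"pass"`/`"fail"`/`NA`)
#' @export
detect_noncanonical_5p <- function(element, annotation, refs,
                                   min_identity = 0.6, min_len = 30L) {
  if (!annotation$is_sva) return(NULL)
  sp <- annotation$spans
  if ("hexamer" %in% sp$domain) return(NULL)   # canonical 5' start
  anchor <- min(sp$start)
  alu_junction <- NA_integer_
  junction <- anchor
  if ("alu_like" %in% sp$domain) {
    ## full Alu-like present: the junction is its start
    ar <- sp[sp$domain == "alu_like", , drop = FALSE]
    junction <- ar$start
    hit <- local_hit(substr(element, junction, ar$end), refs$alu_like)
    if (!is.null(hit)) alu_junction <- hit$ref_start - hit$start + 1L
  } else {
    ## look for a retained Alu-like tail upstream of the anchor: exon
    ## capture typically keeps the 3' end of the Alu-like domain
    upstream <- substr(element, 1L, anchor - 1L)
    hit <- local_hit(upstream, refs$alu_like)
    if (!is.null(hit) && hit$len >= 20L && hit$identity >= 0.7) {
      junction <- hit$start
      alu_junction <- hit$ref_start
      ## the exact junction is ambiguous wherever donor and Alu-like
      ## sequence agree by chance at the boundary; anchor it on the
      ## nearest downstream splice-acceptor AG when one exists
      for (o in 0:min(8L, hit$len - 20L)) {
        aj <- alu_junction + o
        if (aj >= 3L && substr(refs$alu_like, aj - 2L, aj - 1L) == "AG") {
          junction <- junction + o
          alu_junction <- aj
          break
        }
      }
    }
  }
  if (junction - 1L < min_len) return(NULL)
  seg <- substr(element, 1L, junction - 1L)
  ## foreign only if the region matches neither hexamer array nor Alu-like
  hex_id <- prefix_hexamer_fraction(seg, if (is.null(refs$hexamer_unit)) "TCTCCC" else refs$hexamer_unit)
  al_hit <- domain_hit(seg, refs$alu_like, min_identity)
  if (hex_id >= min_identity || !is.null(al_hit)) return(NULL)

  acceptor <- if (!is.na(alu_junction)) {
    if (alu_junction >= 3L &&
        substr(refs$alu_like, alu_junction - 2L, alu_junction - 1L) == "AG")
      "pass" else "fail"
  } else NA_character_
  list(span = c(1L, junction - 1L), junction = junction,
       alu_junction = alu_junction, acceptor_ag = acceptor)
}

## best local alignment of a query against a reference; coordinates on both
local_hit <- function(x, ref) {
  if (nchar(x) < 10L) return(NULL)
  sc <- alignment_scoring()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(x)),
    subject = Biostrings::DNAString(toupper(ref)),
    type = "local", substitutionMatrix = iupac_submat(sc),
    gapOpening = sc$gap_open - sc$gap_extend, gapExtension = sc$gap_extend)
  if (Biostrings::nchar(aln) == 0L) return(NULL)
  list(start = Biostrings::start(Biostrings::pattern(aln)),
       end = Biostrings::end(Biostrings::pattern(aln)),
       ref_start = Biostrings::start(Biostrings::subject(aln)),
       ref_end = Biostrings::end(Biostrings::subject(aln)),
       len = Biostrings::nchar(aln),
       identity = Biostrings::pid(aln) / 100)
}

prefix_hexamer_fraction <- function(seg, unit) {
  reps <- strrep(unit, ceiling(nchar(seg) / nchar(unit)))
  mean(seq_chars(seg) == seq_chars(substr(reps, 1L, nchar(seg))))
}

#' Assign a foreign 5' segment to a donor exon
#'
#' Aligns the segment locally to an exon library and calls a capture when
#' the segment's 3' end coincides (within `junction_tol` nt) with an
#' exon's 3' end -- the splice criterion: acquisition by splicing joins the
#' exon exactly at its donor site. Sequence 5' of the exon match is
#' reported as an additional upstream transduction.
#'
#' @param segment foreign 5' segment sequence
#' @param exon_library named character vector of exon sequences (3' ends =
#'   annotated exon ends)
#' @param min_identity minimum identity of the exon match (default 0.9)
#' @param junction_tol tolerance at both 3' ends, nt (default 2)
#' @return a `capture_call` (list with `exon`, `acquired_len` = matched
#'   exon suffix length, `segment_match` span, `transduction_span` or
#'   `NULL`, `identity`) or the string `"ambiguous"` (several equally good
#'   donors) or `NULL` (unassigned)
#' @export
assign_exon_source <- function(segment, exon_library, min_identity = 0.9,
                               junction_tol = 2L) {
  stopifnot(length(exon_library) >= 1L, !is.null(names(exon_library)))
  sc <- alignment_scoring()
  hits <- lapply(names(exon_library), function(nm) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(toupper(segment)),
      subject = Biostrings::DNAString(toupper(exon_library[[nm]])),
      type = "local", substitutionMatrix = iupac_submat(sc),
      gapOpening = sc$gap_open - sc$gap_extend, gapExtension = sc$gap_extend)
    list(exon = nm, score = Biostrings::score(aln),
         pid = Biostrings::pid(aln) / 100,
         seg_start = Biostrings::start(Biostrings::pattern(aln)),
         seg_end = Biostrings::end(Biostrings::pattern(aln)),
         exon_start = Biostrings::start(Biostrings::subject(aln)),
         exon_end = Biostrings::end(Biostrings::subject(aln)),
         exon_len = nchar(exon_library[[nm]]))
  })
  ok <- Filter(function(h) {
    h$pid >= min_identity &&
      (h$exon_len - h$exon_end) <= junction_tol &&
      (nchar(segment) - h$seg_end) <= junction_tol
  }, hits)
  if (!length(ok)) return(NULL)
  scores <- vapply(ok, `[[`, numeric(1), "score")
  top <- which(abs(scores - max(scores)) < 1e-9)
  if (length(top) > 1L) return("ambiguous")
  h <- ok[[top]]
  acquired <- h$exon_len - h$exon_start + 1L
  structure(list(exon = h$exon, acquired_len = acquired,
                 segment_match = c(h$seg_start, h$seg_end),
                 transduction_span = if (h$seg_start > 1L) c(1L, h$seg_start - 1L) else NULL,
                 identity = h$pid),
            class = "capture_call")
}

#' Deduplicated capture-length distribution
#'
#' Identical acquired lengths within a capture family are represented only
#' once; the distinct lengths are returned sorted.
#'
#' @param calls list of `capture_call`s (or a numeric vector of acquired
#'   lengths)
#' @return sorted integer vector of distinct acquired lengths
#' @export
capture_length_distribution <- function(calls) {
  lens <- if (is.numeric(calls)) calls else
    vapply(Filter(function(x) inherits(x, "capture_call"), calls),
           `[[`, numeric(1), "acquired_len")
  sort(unique(as.integer(lens)))
}
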
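#' Build a synthetic canonical SVA element
#'
#' A full-length synthetic element with the canonical domain layout --
#' TCTCCC hexameric repeats, Alu-like domain, VNTR, SINE-R, polyA tail --
#' for testing domain annotation and capture detection. The Alu-like
#' domain carries a splice-acceptor `AG` dinucleotide immediately 5' of
#' the canonical capture junction. Deterministic given the seed. All
#' sequence content is synthetic; only the domain grammar follows the real
#' element.
#'
#' @param seed integer seed
#' @param n_hexamer number of hexamer units (default 4)
#' @param alu_len,sine_r_len domain lengths (defaults 330 / 490)
#' @param vntr_unit_len,vntr_copies VNTR repeat unit length and copy
#'   number (defaults 37 / 11)
#' @return list with `sequence`, `domains` (data.frame of spans, 1-based
#'   inclusive), `refs` (list `hexamer_unit`, `alu_like`, `sine_r` for
#'   [annotate_domains()]) and `capture_junction` (element coordinate where
#'   the retained Alu-like part of a capture element starts, aligned to the
#'   acceptor) and `alu_junction` (same point in Alu-like coordinates)
#' @export
build_canonical_sva <- function(seed = 7L, n_hexamer = 4L, alu_len = 330L,
                                sine_r_len = 490L, vntr_unit_len = 37L,
                                vntr_copies = 11L) {
  hex_unit <- "TCTCCC"
  with_substream(seed, "canonical_sva", {
    alu <- seq_chars(random_dna(alu_len, gc = 0.55))
    ## retained tail of the Alu-like domain starts 60 nt before its end,
    ## preceded by the splice acceptor AG
    alu_junction <- alu_len - 59L
    alu[(alu_junction - 2L):(alu_junction - 1L)] <- c("A", "G")
    alu <- chars_seq(alu)
    vntr_unit <- random_dna(vntr_unit_len, gc = 0.6)
    sine_r <- random_dna(sine_r_len, gc = 0.45)
  })
  hexamer <- strrep(hex_unit, n_hexamer)
  vntr <- strrep(vntr_unit, vntr_copies)
  polyA <- strrep("A", 16L)
  parts <- c(hexamer = hexamer, alu_like = alu, vntr = vntr,
             sine_r = sine_r, polyA = polyA)
  ends <- cumsum(nchar(parts))
  starts <- ends - nchar(parts) + 1L
  list(sequence = paste(parts, collapse = ""),
       domains = data.frame(domain = names(parts), start = starts, end = ends,
                            row.names = NULL),
       refs = list(hexamer_unit = hex_unit, alu_like = alu, sine_r = sine_r),
       capture_junction = unname(starts["alu_like"] + alu_junction - 1L),
       alu_junction = alu_junction)
}

#' Synthetic SINE-R consensus panel
#'
#' A panel of subfamily consensus sequences constructed to encode the key
#' published relationships between the SVA_D subfamily consensuses while
#' using synthetic sequence: the basal subfamily D1 is separated from the
#' outgroup SVA_C by 12 substitutions; three additional substitutions lie
#' on the path from D1 to DR; D2 derives from D1 by the hallmark 20-bp
#' SINE-R deletion; and a set of derived subfamilies shares the hallmark
#' co-segregating A/G substitutions at positions 228 and 242 relative to
#' the DR consensus, each with one private diagnostic of its own.
#'
#' @param seed integer seed
#' @param sine_r_len SINE-R consensus length (default 490)
#' @param n_ag number of A-G subfamilies (default 6)
#' @return list with `sequences` (named character vector: `SVA_C`,
#'   `SVA_D1`, `SVA_DR`, `SVA_D2`, `AG_1`..), `reference` (the D1
#'   consensus used as projection reference), `dr` (the DR consensus),
#'   `positions` (list of the planted diagnostic positions)
#' @export
synthetic_consensus_panel <- function(seed = 104L, sine_r_len = 490L,
                                      n_ag = 6L) {
  stopifnot(sine_r_len >= 300L)
  with_substream(seed, "consensus_panel", {
    d1 <- seq_chars(random_dna(sine_r_len))
    d1[228L] <- "G"
    d1[242L] <- "A"
    taken <- c(228L, 242L)
    draw <- function(n) {
      pos <- sample(setdiff(seq_len(sine_r_len), taken), n)
      taken <<- c(taken, pos)
      sort(pos)
    }
    mutate_at <- function(x, pos) {
      for (p in pos) x[p] <- sample(setdiff(DNA_BASES4, x[p]), 1L)
      x
    }
    c_pos <- draw(12L)
    sva_c <- mutate_at(d1, c_pos)
    dr_pos <- draw(3L)
    dr <- mutate_at(d1, dr_pos)
    del_start <- 301L
    stopifnot(!any(del_start:(del_start + 19L) %in% taken))
    d2 <- d1[-(del_start:(del_start + 19L))]
    ag <- list()
    ag_priv <- list()
    for (i in seq_len(n_ag)) {
      x <- dr
      x[228L] <- "A"
      x[242L] <- "G"
      priv <- draw(sample(1:2, 1L))
      ag[[paste0("AG_", i)]] <- chars_seq(mutate_at(x, priv))
      ag_priv[[paste0("AG_", i)]] <- priv
    }
    sequences <- c(SVA_C = chars_seq(sva_c), SVA_D1 = chars_seq(d1),
                   SVA_DR = chars_seq(dr), SVA_D2 = chars_seq(d2),
                   unlist(ag))
    list(sequences = sequences, reference = chars_seq(d1),
         dr = chars_seq(dr),
         positions = list(c_vs_d1 = c_pos, dr_vs_d1 = dr_pos,
                          d2_deletion = c(start = del_start, length = 20L),
                          ag_shared = c(228L, 242L), ag_private = ag_priv))
  })
}
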
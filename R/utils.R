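#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois runif setNames aggregate
#' @importFrom utils read.delim write.table head combn
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

## state codes used in aligned profiles and consensus state vectors:
##   A/C/G/T  called base
##   "-"      deleted relative to the reference
##   "."      missing (unaligned end, N or IUPAC ambiguity)
STATE_DEL <- "-"
STATE_MISSING <- "."

is_base_state <- function(x) x %in% DNA_BASES4

#' Reverse-complement a DNA string
#' @param x character scalar over the DNA alphabet
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Split a DNA string into a character vector of single bases
#' @keywords internal
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

#' Collapse a character vector of bases into a string
#' @keywords internal
chars_seq <- function(x) paste(x, collapse = "")

#' Random DNA sequence
#'
#' @param n length in nucleotides
#' @param gc GC content in `[0, 1]` (default 0.42, roughly genomic)
#' @return character scalar
#' @export
random_dna <- function(n, gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars_seq(sample(names(p), n, replace = TRUE, prob = p))
}

## maximal runs of TRUE in a logical vector -> data.frame(start, length)
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

## derive a bounded substream seed from a master seed and a stage name;
## keeps results reproducible while letting stages vary independently
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 99991L)) %% 2147483562L
}

with_substream <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, stage))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
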
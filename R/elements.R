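#' Read retrotransposon element sequences from FASTA
#'
#' One record per genomic copy. The species tag is parsed from the FASTA
#' header: by default the part of the id before the first underscore
#' (`gg_17` has species `gg`); a `species_map` overrides this, mapping
#' element ids to species tags.
#'
#' @param fasta_path path to a FASTA file
#' @param species_map optional named character vector, `id -> species tag`
#' @param species_set allowed species tags; parsed tags outside this set are
#'   an error. `NULL` accepts anything.
#' @return a data.frame with columns `id`, `species`, `sequence`
#'   (class `element_set`)
#' @export
read_elements <- function(fasta_path, species_map = NULL,
                          species_set = c("gg", "pt", "hs")) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) {
    warning("empty FASTA: ", fasta_path)
    return(element_set(data.frame(id = character(), species = character(),
                                  sequence = character())))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  element_set(data.frame(id = ids,
                         species = parse_species(ids, species_map, species_set),
                         sequence = as.character(seqs)))
}

parse_species <- function(ids, species_map, species_set) {
  sp <- if (!is.null(species_map)) {
    unname(species_map[ids])
  } else {
    sub("_.*$", "", ids)
  }
  if (anyNA(sp)) stop("no species mapping for ids: ",
                      paste(ids[is.na(sp)], collapse = ", "))
  if (!is.null(species_set) && !all(sp %in% species_set)) {
    bad <- unique(sp[!sp %in% species_set])
    stop("species tags outside configured set: ", paste(bad, collapse = ", "))
  }
  sp
}

#' Construct / validate an element set
#'
#' @param df data.frame with at least `id`, `species`, `sequence`; optional
#'   `flank5`, `flank3`, `locus_label`
#' @return the validated data.frame with class `element_set`
#' @export
element_set <- function(df) {
  stopifnot(all(c("id", "species", "sequence") %in% names(df)))
  if (anyDuplicated(df$id)) {
    stop("duplicate element ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (nrow(df) > 0L && any(!nzchar(df$sequence))) {
    stop("empty sequence for ids: ", paste(df$id[!nzchar(df$sequence)], collapse = ", "))
  }
  class(df) <- c("element_set", "data.frame")
  df
}

#' Write an element set to FASTA
#'
#' @param elements an `element_set` data.frame
#' @param fasta_path output path
#' @export
write_elements <- function(elements, fasta_path) {
  x <- Biostrings::DNAStringSet(setNames(elements$sequence, elements$id))
  Biostrings::writeXStringSet(x, fasta_path)
  invisible(fasta_path)
}

#' Read a locus table (TSV)
#'
#' Tab-separated with header `id`, `species`, `flank5`, `flank3`,
#' `locus_label`.
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_locus_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "flank5", "flank3")
  if (!all(need %in% names(df))) {
    stop("locus table must have columns ", paste(need, collapse = ", "))
  }
  df
}

#' Write a locus table (TSV)
#' @param loci data.frame with locus columns
#' @param path output path
#' @export
write_locus_table <- function(loci, path) {
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read named reference/consensus sequences from FASTA
#'
#' @param fasta_path path to FASTA of references (consensus sequences,
#'   domain references). Names must be unique, sequences non-empty.
#' @return named character vector of sequences (class `reference_set`)
#' @export
read_references <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  reference_set(setNames(as.character(seqs), sub("\\s.*$", "", names(seqs))))
}

#' Construct / validate a reference set
#' @param x named character vector of DNA sequences
#' @return `x` with class `reference_set`; coordinates in all reports are
#'   1-based inclusive
#' @export
reference_set <- function(x) {
  stopifnot(is.character(x), !is.null(names(x)))
  if (anyDuplicated(names(x))) stop("duplicate reference names")
  if (any(!nzchar(x))) stop("empty reference sequence")
  class(x) <- "reference_set"
  x
}
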
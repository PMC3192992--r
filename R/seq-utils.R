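#' Construct a sequence table
#'
#' The package represents every set of sequences (reads, contigs, reference
#' databases, consensuses) as an ordinary tibble with one row per sequence:
#' an `id` column, a `seq` column, and optionally a `qual` list-column of
#' per-base integer Phred scores.  All pipeline verbs take and return this
#' shape so stages chain with the pipe.
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param seq Character vector of sequences.  Nucleotide sequences use
#'   `A`,`C`,`G`,`T`,`N` (lowercase marks soft-masked positions, `-` marks an
#'   alignment gap); amino-acid sequences use the IUPAC one-letter code.
#' @param qual Optional list of integer vectors, one per sequence, each the
#'   same length as its sequence.
#' @param source Optional provenance tag (recycled).
#' @return A tibble with columns `id`, `seq`, and optionally `qual`, `source`.
#' @examples
#' seq_tbl(c("a", "b"), c("ACGT", "GGGT"))
#' @export
seq_tbl <- function(id, seq, qual = NULL, source = NULL) {
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq)) {
    abort("`id` and `seq` must have the same length.")
  }
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  if (any(!nzchar(id))) abort("sequence ids must be non-empty.")
  out <- tibble(id = id, seq = seq)
  if (!is.null(qual)) {
    stopifnot(length(qual) == length(seq))
    bad <- which(lengths(qual) != nchar(seq))
    if (length(bad) > 0) {
      abort(paste0("quality length differs from sequence length for id(s): ",
                   paste(id[bad], collapse = ", ")))
    }
    out$qual <- lapply(qual, as.integer)
  }
  if (!is.null(source)) out$source <- as.character(source)
  out
}

assert_seq_tbl <- function(x, arg = deparse(substitute(x))) {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort(paste0("`", arg, "` must be a data frame with `id` and `seq` columns."))
  }
  invisible(x)
}

#' Reverse-complement nucleotide sequences
#'
#' Case is preserved so that soft-masked (lowercase) positions stay masked.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AACGTt")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    comp <- chartr("ACGTUNacgtun-", "TGCAANtgcaan-", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Codon table for the standard genetic code; '*' is a stop.
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Translate a nucleotide sequence in a given reading frame
#'
#' Frames follow the BLAST convention: `+1..+3` count from the 5' end of the
#' forward strand, `-1..-3` from the 5' end of the reverse complement.
#' Trailing bases that do not fill a codon are dropped.  Codons containing
#' `N` (or any non-ACGT base) translate to `X`; stop codons translate to `*`.
#' Soft-masking is carried through: a codon with any lowercase base yields a
#' lowercase residue.
#'
#' @param x A single nucleotide sequence.
#' @param frame Integer in `c(-3:-1, 1:3)`.
#' @return A single amino-acid string.
#' @examples
#' translate_frame("ATGAAATAA", 1)
#' @export
translate_frame <- function(x, frame = 1L) {
  stopifnot(length(x) == 1, frame %in% c(-3:-1, 1:3))
  s <- if (frame < 0) revcomp(x) else x
  off <- abs(frame)
  n <- nchar(s)
  if (n < off + 2) return("")
  s <- substr(s, off, n)
  n_cod <- nchar(s) %/% 3
  if (n_cod == 0) return("")
  codons <- substring(s, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  up <- toupper(codons)
  aa <- .codon_table[up]
  aa[is.na(aa)] <- "X"
  masked <- codons != up
  aa[masked] <- tolower(aa[masked])
  paste(aa, collapse = "")
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# IUPAC ambiguity code for a set of nucleotide bases (used for majority ties).
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  key <- paste(bases, collapse = "")
  map <- Biostrings::IUPAC_CODE_MAP
  hit <- names(map)[match(key, vapply(names(map), function(n) {
    paste(sort(chars(map[[n]])), collapse = "")
  }, character(1)))]
  if (length(hit) == 1 && !is.na(hit)) hit else "N"
}

is_nt <- function(x) {
  !str_detect(toupper(x), "[^ACGTUN\\-]")
}
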
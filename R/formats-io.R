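#' Read a FASTA file into a sequence table
#'
#' Wraps [Biostrings::readBStringSet()] and returns the tidy sequence-table
#' shape used throughout the package.  Order is preserved; duplicate
#' identifiers are an error (downstream stages key on the id).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` or `"aa"`; with `"nt"` illegal characters are
#'   rejected with the offending record named.
#' @return A tibble with columns `id`, `seq` (see [seq_tbl()]).
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                     conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (alphabet == "nt") {
    bad <- which(!is_nt(seqs))
    if (length(bad) > 0) {
      abort(paste0("illegal nucleotide characters in record '", ids[bad[1]],
                   "' of ", path))
    }
  }
  seq_tbl(ids, unname(seqs))
}

#' Read a FASTQ file (Sanger offset 33) into a sequence table
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `id`, `seq`, `qual` (list of integer Phred
#'   scores).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  quals <- lapply(as.character(S4Vectors::mcols(set)$qualities), function(q) {
    as.integer(utf8ToInt(q) - 33L)
  })
  seq_tbl(ids, unname(as.character(set)), qual = quals)
}

#' Write a sequence table to FASTA
#'
#' @param seqs A sequence table ([seq_tbl()]).
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  assert_seq_tbl(seqs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$seq[i]
    if (nzchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

.blast_cols <- c("query_id", "subject_id", "pct_identity", "align_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "e_value", "bit_score")

#' Parse similarity hits in 12-column tabular format
#'
#' Reads the standard tab-separated hit table (the `-outfmt 6` dialect:
#' query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score), with an optional
#' 13th column carrying the query frame of a translated search.  Coordinates
#' are kept 1-based inclusive exactly as in the file; a minus-strand subject
#' is represented, as in the source format, by `s_start > s_end` and is
#' surfaced in a derived `strand` column.
#'
#' @param path Path to a tabular hit file.
#' @return A tibble of hits with the columns named above plus `frame`
#'   (integer or `NA`) and `strand` (`"+"`/`"-"`).
#' @export
parse_blast_tabular <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(hit_tbl())
  fields <- str_split(lines, "\t")
  nf <- lengths(fields)
  bad <- which(nf != 12L & nf != 13L)
  if (length(bad) > 0) {
    abort(paste0("expected 12 or 13 tab-separated columns, got ", nf[bad[1]],
                 " on line ", bad[1], " of ", path))
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:12]))
  out <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), align_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    frame = vapply(fields, function(f) {
      if (length(f) >= 13) as.integer(f[13]) else NA_integer_
    }, integer(1))
  )
  if (anyNA(out$pct_identity) || anyNA(out$q_start)) {
    abort(paste0("non-numeric field in ", path))
  }
  if (any(out$q_start > out$q_end)) {
    abort("q_start > q_end is not a legal hit record")
  }
  out$strand <- ifelse(out$s_start > out$s_end, "-", "+")
  out
}

#' @rdname parse_blast_tabular
#' @param hits A hit tibble.
#' @export
write_blast_tabular <- function(hits, path) {
  stopifnot(all(.blast_cols %in% names(hits)))
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    base <- c(hits$query_id[i], hits$subject_id[i],
              format(hits$pct_identity[i], nsmall = 2, trim = TRUE),
              hits$align_length[i], hits$mismatches[i], hits$gap_opens[i],
              hits$q_start[i], hits$q_end[i], hits$s_start[i], hits$s_end[i],
              format(hits$e_value[i], digits = 3, scientific = TRUE, trim = TRUE),
              format(hits$bit_score[i], nsmall = 1, trim = TRUE))
    if (!is.na(hits$frame[i])) base <- c(base, hits$frame[i])
    paste(base, collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Empty hit tibble with the full column contract.
hit_tbl <- function() {
  tibble(query_id = character(), subject_id = character(),
         pct_identity = numeric(), align_length = integer(),
         mismatches = integer(), gap_opens = integer(),
         q_start = integer(), q_end = integer(),
         s_start = integer(), s_end = integer(),
         e_value = numeric(), bit_score = numeric(),
         frame = integer(), strand = character())
}

#' Read gene features from a GFF3 file
#'
#' Reads the subset of GFF3 this pipeline consumes: `gene`, `CDS`, `tRNA`,
#' `rRNA` and `control_region` rows annotating a (mitochondrial) reference.
#' Coordinates stay 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @param keep_types Feature types to retain.
#' @return A tibble with columns `seq_id`, `gene_name`, `start`, `end`,
#'   `strand`, `feature_class`.
#' @export
read_gff3_features <- function(path,
                               keep_types = c("gene", "CDS", "tRNA", "rRNA",
                                              "control_region")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- str_split(lines, "\t")
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0) {
    abort(paste0("expected 9 tab-separated columns on line ", bad[1],
                 " of ", path))
  }
  m <- do.call(rbind, fields)
  start <- as.integer(m[, 4]); end <- as.integer(m[, 5])
  if (any(end < start)) {
    abort(paste0("feature end < start on line ", which(end < start)[1],
                 " of ", path))
  }
  name <- vapply(m[, 9], function(attr) {
    kv <- str_split(str_split(attr, ";")[[1]], "=")
    kv <- kv[lengths(kv) == 2]
    vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    vals[["Name"]] %||% vals[["gene"]] %||% vals[["ID"]] %||% NA_character_
  }, character(1), USE.NAMES = FALSE)
  out <- tibble(seq_id = m[, 1], gene_name = name, start = start, end = end,
                strand = m[, 7], feature_class = m[, 3])
  out[out$feature_class %in% keep_types, ]
}

#' Write a gene-feature table as GFF3
#'
#' @param features Feature tibble as returned by [read_gff3_features()].
#' @param path Output path.
#' @export
write_gff3_features <- function(features, path) {
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(features)), function(i) {
               paste(features$seq_id[i], "txcascade", features$feature_class[i],
                     features$start[i], features$end[i], ".",
                     features$strand[i], ".",
                     paste0("Name=", features$gene_name[i]),
                     sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
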
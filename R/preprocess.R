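#' Adaptor specification
#'
#' Describes the library adaptors to excise from raw reads.  The defaults are
#' the SMART/CAP amplification oligos used for full-length cDNA library
#' construction; the second oligo is the reverse complement of the first, and
#' both orientations of every adaptor are searched.
#'
#' @param adaptors Character vector of adaptor sequences (each >= 10 bp).
#' @param max_mismatches Mismatch tolerance of a "near-exact" full-length
#'   match (no indels), default 2.
#' @param end_window Distance (bp) from either read end within which a match
#'   counts as terminal; default is the longest adaptor length + 5.
#' @param min_part_len Fragments shorter than this after excision are
#'   discarded (default 30 bp).
#' @param min_partial Minimum length of a partial adaptor match overhanging a
#'   read end that is still trimmed (truncated terminal adaptors, default 10).
#' @return A list with class `adaptor_spec`.
#' @export
adaptor_spec <- function(adaptors = c(
                           OligoI = "AAGCAGTGGTATCAACGCAGAGTAC",
                           OligoII = "GTACTCTGCGTTGATACCACTGCTT"),
                         max_mismatches = 2L,
                         end_window = NULL,
                         min_part_len = 30L,
                         min_partial = 10L) {
  adaptors <- toupper(adaptors)
  if (length(adaptors) == 0 || any(nchar(adaptors) < 10)) {
    abort("each adaptor must be at least 10 bp")
  }
  if (max_mismatches >= min(nchar(adaptors)) / 2) {
    abort("max_mismatches must be < shortest adaptor length / 2")
  }
  structure(list(
    adaptors = adaptors,
    max_mismatches = as.integer(max_mismatches),
    end_window = as.integer(end_window %||% (max(nchar(adaptors)) + 5L)),
    min_part_len = as.integer(min_part_len),
    min_partial = as.integer(min_partial)
  ), class = "adaptor_spec")
}

# All near-exact full-length occurrences (no indels) of `pattern` in `x`,
# as an IRanges-like matrix of start/end, allowing `max_mm` mismatches.
.find_fulllen_matches <- function(x, pattern, max_mm) {
  if (nchar(x) < nchar(pattern)) return(NULL)
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(x),
                                   max.mismatch = max_mm, with.indels = FALSE)
  if (length(hits) == 0) return(NULL)
  cbind(start = Biostrings::start(hits), end = Biostrings::end(hits))
}

# Partial terminal matches: a prefix of the read matching an adaptor suffix,
# or a read suffix matching an adaptor prefix, length >= min_partial.
.find_partial_terminal <- function(x, pattern, max_mm, min_partial) {
  n <- nchar(x); L <- nchar(pattern)
  out <- NULL
  kmax <- min(n, L - 1L)
  if (kmax >= min_partial) {
    xs <- chars(x); ps <- chars(pattern)
    for (k in kmax:min_partial) {
      # read prefix vs adaptor suffix (adaptor runs off the 5' end)
      if (sum(xs[1:k] != ps[(L - k + 1):L]) <= max_mm) {
        out <- rbind(out, c(start = 1L, end = k)); break
      }
    }
    for (k in kmax:min_partial) {
      # read suffix vs adaptor prefix (adaptor runs off the 3' end)
      if (sum(xs[(n - k + 1):n] != ps[1:k]) <= max_mm) {
        out <- rbind(out, c(start = n - k + 1L, end = n)); break
      }
    }
  }
  out
}

# Merge overlapping/adjacent intervals given as a 2-column start/end matrix.
.merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(NULL)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[i, 1] <= merged[last, 2] + 1L) {
      merged[last, 2] <- max(merged[last, 2], iv[i, 2])
    } else {
      merged <- rbind(merged, iv[i, , drop = FALSE])
    }
  }
  merged
}

# Adaptor occurrence intervals in one read (both orientations of each
# adaptor, full-length near-exact anywhere, partial matches at the ends).
.adaptor_intervals <- function(x, spec) {
  pats <- unique(c(spec$adaptors, revcomp(spec$adaptors)))
  iv <- NULL
  xu <- toupper(x)
  for (p in pats) {
    iv <- rbind(iv, .find_fulllen_matches(xu, p, spec$max_mismatches))
    iv <- rbind(iv, .find_partial_terminal(xu, p, spec$max_mismatches,
                                           spec$min_partial))
  }
  .merge_intervals(iv)
}

#' Excise adaptor occurrences from reads
#'
#' Every full-length adaptor occurrence within the mismatch tolerance is
#' excised together with its quality values.  Occurrences at the read ends
#' (within `end_window`, including truncated adaptors overhanging an end)
#' trim the read; internal occurrences split it into two parts, named
#' `<id>/1`, `<id>/2`.  Fragments shorter than `min_part_len` are discarded.
#' A read may legally vanish entirely.
#'
#' @param reads A sequence table ([seq_tbl()]), optionally with `qual`.
#' @param spec An [adaptor_spec()].
#' @return A list with elements `reads` (the surviving fragments, a sequence
#'   table with a `parent_id` column) and `report` (a one-row accounting
#'   tibble: `reads_in`, `reads_out`, `reads_discarded`, `splits`,
#'   `bases_removed`; `reads_out = reads_in - reads_discarded + splits`).
#' @export
remove_adaptors <- function(reads, spec = adaptor_spec()) {
  assert_seq_tbl(reads)
  has_qual <- "qual" %in% names(reads)
  out <- vector("list", nrow(reads))
  splits <- 0L; discarded <- 0L; bases_removed <- 0L
  for (i in seq_len(nrow(reads))) {
    x <- reads$seq[i]
    iv <- .adaptor_intervals(x, spec)
    if (is.null(iv)) {
      out[[i]] <- tibble(id = reads$id[i], seq = x,
                         qual = if (has_qual) reads$qual[i] else NULL,
                         parent_id = reads$id[i])
      next
    }
    bases_removed <- bases_removed + sum(iv[, 2] - iv[, 1] + 1L)
    # complement of the excised intervals, in order
    bounds <- c(0L, as.vector(t(iv)), nchar(x) + 1L)
    keep_start <- bounds[seq(1, length(bounds), by = 2)] + 1L
    keep_end <- bounds[seq(2, length(bounds), by = 2)] - 1L
    frag_seq <- substring(x, keep_start, keep_end)
    ok <- nchar(frag_seq) >= spec$min_part_len
    frags <- frag_seq[ok]
    if (length(frags) == 0) {
      discarded <- discarded + 1L
      next
    }
    ids <- if (length(frags) == 1) reads$id[i] else
      paste0(reads$id[i], "/", seq_along(frags))
    if (length(frags) > 1) splits <- splits + (length(frags) - 1L)
    q <- NULL
    if (has_qual) {
      q <- map2(keep_start[ok], keep_end[ok], function(s, e) {
        reads$qual[[i]][seq.int(s, e)]
      })
    }
    out[[i]] <- tibble(id = ids, seq = frags,
                       qual = if (has_qual) q else NULL,
                       parent_id = reads$id[i])
  }
  res <- list_rbind(out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0) {
    res <- tibble(id = character(), seq = character(), parent_id = character())
  }
  report <- tibble(reads_in = nrow(reads), reads_out = nrow(res),
                   reads_discarded = discarded, splits = splits,
                   bases_removed = bases_removed)
  list(reads = res, report = report)
}

#' Trim terminal polyA / polyT runs
#'
#' Removes a trailing A-run (polyA tail) or a leading T-run (the tail seen in
#' reverse complement) of at least `min_run` bases, tolerating up to
#' `max_impurity` non-A (non-T) content within the run.  Reads left empty are
#' dropped.
#'
#' @param reads A sequence table.
#' @param min_run Minimum run length to trim (default 10).
#' @param max_impurity Maximum tolerated fraction of other bases (default 0.1).
#' @return The trimmed sequence table.
#' @export
trim_polya <- function(reads, min_run = 10L, max_impurity = 0.1) {
  assert_seq_tbl(reads)
  has_qual <- "qual" %in% names(reads)

  # Longest terminal run ending in `base` whose impurity stays within
  # tolerance.  A genuine terminal base identical to the tail base is, by
  # construction, part of the run.
  run_len <- function(s, base, from_end) {
    cs <- chars(toupper(s))
    if (from_end) cs <- rev(cs)
    k <- seq_along(cs)
    ok <- (cumsum(cs != base) <= k * max_impurity) & (cs == base)
    best <- if (any(ok)) max(which(ok)) else 0L
    if (best >= min_run) best else 0L
  }

  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    if (!nzchar(s)) next
    tail_a <- run_len(s, "A", from_end = TRUE)
    if (tail_a > 0) {
      s <- substr(s, 1L, nchar(s) - tail_a)
      if (has_qual) reads$qual[[i]] <- head(reads$qual[[i]], nchar(s))
    }
    lead_t <- if (nzchar(s)) run_len(s, "T", from_end = FALSE) else 0L
    if (lead_t > 0) {
      if (has_qual) reads$qual[[i]] <- tail(reads$qual[[i]], nchar(s) - lead_t)
      s <- substr(s, lead_t + 1L, nchar(s))
    }
    reads$seq[i] <- s
  }
  reads[nzchar(reads$seq), ]
}

#' Quality-trim read 3' ends
#'
#' Classic 3' sliding-window trimming: the read is shortened until the mean
#' Phred quality of its trailing `window` bases reaches `min_mean_q`.  Reads
#' shorter than `min_len` after trimming are discarded.
#'
#' @param reads A sequence table with a `qual` list-column.
#' @param window Window size in bp (default 10).
#' @param min_mean_q Minimum mean Phred quality of the trailing window
#'   (default 20).
#' @param min_len Minimum surviving read length (default 30).
#' @return The trimmed sequence table.
#' @export
quality_trim <- function(reads, window = 10L, min_mean_q = 20, min_len = 30L) {
  assert_seq_tbl(reads)
  if (!"qual" %in% names(reads)) {
    abort("quality_trim() requires a `qual` column of per-base scores")
  }
  keep <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    q <- reads$qual[[i]]
    n <- length(q)
    while (n >= window && mean(q[(n - window + 1L):n]) < min_mean_q) {
      n <- n - 1L
    }
    if (n < window && n > 0 && mean(q[1:n]) < min_mean_q) n <- 0L
    reads$seq[i] <- substr(reads$seq[i], 1L, n)
    reads$qual[[i]] <- q[seq_len(n)]
    keep[i] <- n >= min_len
  }
  reads[keep, ]
}

#' Soft-mask low-complexity regions
#'
#' A DUST-style filter: in sliding windows the triplet-composition score
#' `sum(c_t * (c_t - 1) / 2) / (n_triplets - 1)` is computed; windows scoring
#' above `threshold` are lowercased.  Masked (lowercase) positions are
#' excluded from seed words by [search_db()] but remain in the sequence, so
#' coordinates are unchanged.
#'
#' @param x Character vector of nucleotide sequences.
#' @param window Window size in bp (default 64).
#' @param step Window step (default half the window).
#' @param threshold Masking threshold on the triplet score (default 2).
#' @return The sequences with low-complexity windows lowercased.
#' @export
mask_low_complexity <- function(x, window = 64L, step = window %/% 2L,
                                threshold = 2) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n < 6) return(s)
    up <- toupper(s)
    cs <- chars(up)
    mask <- logical(n)
    starts <- unique(c(seq(1L, max(1L, n - window + 1L), by = step),
                       max(1L, n - window + 1L)))
    for (st in starts) {
      en <- min(st + window - 1L, n)
      ntrip <- en - st - 1L
      if (ntrip < 2) next
      trip <- paste0(cs[st:(en - 2)], cs[(st + 1):(en - 1)], cs[(st + 2):en])
      ct <- table(trip)
      score <- sum(ct * (ct - 1) / 2) / (ntrip - 1)
      if (score > threshold) mask[st:en] <- TRUE
    }
    if (!any(mask)) return(s)
    cs_out <- chars(s)
    cs_out[mask] <- tolower(cs_out[mask])
    paste(cs_out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Run the full read-cleaning stage
#'
#' Applies, in order: adaptor excision (with in-read splitting), polyA/polyT
#' trimming, and (if qualities are present) 3' quality trimming, and reports
#' the accounting of every step.
#'
#' @param reads A sequence table, optionally with `qual`.
#' @param spec An [adaptor_spec()].
#' @param min_run,max_impurity See [trim_polya()].
#' @param window,min_mean_q See [quality_trim()].
#' @return A list with `reads` (clean fragments) and `report` (one-row
#'   accounting tibble).
#' @export
preprocess_reads <- function(reads, spec = adaptor_spec(),
                             min_run = 10L, max_impurity = 0.1,
                             window = 10L, min_mean_q = 20) {
  ad <- remove_adaptors(reads, spec)
  out <- trim_polya(ad$reads, min_run = min_run, max_impurity = max_impurity)
  if ("qual" %in% names(out)) {
    out <- quality_trim(out, window = window, min_mean_q = min_mean_q,
                        min_len = spec$min_part_len)
  }
  out <- out[nchar(out$seq) >= spec$min_part_len, ]
  report <- ad$report
  report$reads_out <- nrow(out)
  report$reads_discarded <- report$reads_in + report$splits - nrow(out)
  list(reads = out, report = report)
}
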
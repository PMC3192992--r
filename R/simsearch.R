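#' Similarity-search settings
#'
#' Parameter bundle for the built-in seed-and-extend local search engine.
#' The defaults are the nucleotide settings used throughout the annotation
#' cascade (word size 11, match +2 / mismatch -1, gap open 5 / extend 1,
#' e-value cutoff 10); `translated` mode (a tblastx-style 6x6-frame search)
#' defaults to word size 3, BLOSUM45 scoring and gap 11/1.
#'
#' @param mode `"nucleotide"` or `"translated"`.
#' @param word_size Exact-word seed length (>= 3; in residues for translated
#'   mode).
#' @param match,mismatch Nucleotide match award / mismatch penalty.
#' @param matrix_name Amino-acid substitution matrix for translated mode
#'   (only `"BLOSUM45"` and `"BLOSUM62"` are shipped).
#' @param gap_open,gap_extend Affine gap penalties (cost of a length-k gap is
#'   `gap_open + k * gap_extend`).
#' @param evalue_max Hits with larger e-value are dropped (default 10).
#' @param mask_queries If `TRUE` (default), soft-masked (lowercase) query
#'   positions never seed, though extensions may run through them.
#' @return A list with class `search_settings`.
#' @export
search_settings <- function(mode = c("nucleotide", "translated"),
                            word_size = NULL,
                            match = 2L, mismatch = -1L,
                            matrix_name = "BLOSUM45",
                            gap_open = NULL, gap_extend = 1L,
                            evalue_max = 10,
                            mask_queries = TRUE) {
  mode <- match.arg(mode)
  word_size <- word_size %||% if (mode == "nucleotide") 11L else 3L
  gap_open <- gap_open %||% if (mode == "nucleotide") 5L else 11L
  if (word_size < 3) abort("word_size must be >= 3")
  if (gap_open < gap_extend || gap_extend < 0) {
    abort("gap penalties must satisfy gap_open >= gap_extend >= 0")
  }
  structure(list(mode = mode, word_size = as.integer(word_size),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 matrix_name = matrix_name,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend),
                 evalue_max = evalue_max, mask_queries = mask_queries),
            class = "search_settings")
}

#' Hit-acceptance filter
#'
#' The cascade's per-round acceptance rule: a hit survives iff its alignment
#' length and percent identity both reach the minima.  The inequalities are
#' non-strict, i.e. boundary hits (exactly 50 bp / exactly 50% identity) are
#' kept, mirroring the strict "<" rejection rule they complement.
#'
#' @param min_align_length Minimum alignment length (bp for nucleotide
#'   rounds, aa for translated rounds).
#' @param min_identity Minimum percent identity, 0-100.
#' @param length_units `"bp"` or `"aa"` (bookkeeping; must match the search
#'   mode).
#' @return A list with class `hit_filter`.
#' @export
hit_filter <- function(min_align_length = 50L, min_identity = 50,
                       length_units = c("bp", "aa")) {
  length_units <- match.arg(length_units)
  if (min_identity < 0 || min_identity > 100) {
    abort("min_identity must lie in [0, 100]")
  }
  structure(list(min_align_length = as.integer(min_align_length),
                 min_identity = min_identity, length_units = length_units),
            class = "hit_filter")
}

#' @rdname hit_filter
#' @param hits A hit tibble (see [parse_blast_tabular()]).
#' @param filter A `hit_filter`.
#' @export
filter_hits <- function(hits, filter) {
  stopifnot(inherits(filter, "hit_filter"))
  hits[hits$align_length >= filter$min_align_length &
         hits$pct_identity >= filter$min_identity, ]
}

# ---- scoring machinery -----------------------------------------------------

# Robinson & Robinson (1991) amino-acid background frequencies, the standard
# composition used for ungapped Karlin-Altschul parameters.
.aa_freqs <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

.nt_matrix <- function(settings) {
  Biostrings::nucleotideSubstitutionMatrix(match = settings$match,
                                           mismatch = settings$mismatch,
                                           baseOnly = FALSE)
}

.aa_matrix <- function(matrix_name) {
  m <- switch(matrix_name,
    BLOSUM45 = get(utils::data("BLOSUM45", package = "Biostrings",
                               envir = environment())),
    BLOSUM62 = get(utils::data("BLOSUM62", package = "Biostrings",
                               envir = environment())),
    abort(paste0("unknown substitution matrix: ", matrix_name)))
  # Forbid extensions through stop codons: a local alignment can never
  # profitably include a '*' column.
  m["*", ] <- -1000
  m[, "*"] <- -1000
  m["*", "*"] <- -1000
  m
}

# Ungapped Karlin-Altschul lambda for a scoring scheme: the positive root of
# sum_ij p_i p_j exp(lambda * s_ij) = 1.  K is kept as a fixed constant; the
# resulting e-values rank and threshold consistently but are not comparable
# with gapped statistics of external engines.
.karlin_lambda <- function(scores, freqs) {
  p2 <- outer(freqs, freqs)
  f <- function(l) sum(p2 * exp(l * scores)) - 1
  uniroot(f, c(1e-6, 10), tol = 1e-9)$root
}

.karlin_cache <- new.env(parent = emptyenv())

.karlin_params <- function(settings) {
  key <- paste(settings$mode, settings$match, settings$mismatch,
               settings$matrix_name, sep = "|")
  if (!is.null(.karlin_cache[[key]])) return(.karlin_cache[[key]])
  if (settings$mode == "nucleotide") {
    freqs <- c(A = .25, C = .25, G = .25, T = .25)
    s <- matrix(settings$mismatch, 4, 4,
                dimnames = list(names(freqs), names(freqs)))
    diag(s) <- settings$match
  } else {
    freqs <- .aa_freqs
    full <- .aa_matrix(settings$matrix_name)
    s <- full[names(freqs), names(freqs)]
  }
  par <- list(lambda = .karlin_lambda(s, freqs), K = 0.1)
  .karlin_cache[[key]] <- par
  par
}

.bit_score <- function(raw, par) (par$lambda * raw - log(par$K)) / log(2)

.e_value <- function(bits, m, n) m * n * 2^(-bits)

# ---- seeding ---------------------------------------------------------------


# ---- pairwise alignment core ----------------------------------------------

# Best local (or global) alignment of each string in `patterns` against
# `subject`, via the compiled Gotoh core; returns a tibble of
# score/coordinates/identity.  Case is ignored for scoring (soft-masking
# affects seeding only).
.align_block <- function(patterns, subject, submat, gap_open, gap_extend,
                         local = TRUE, keep_alignment = FALSE) {
  df <- .cpp_align(as.character(patterns), subject, submat,
                   gap_open, gap_extend, local)
  cols <- c("score", "q_start", "q_end", "s_start", "s_end",
            "align_length", "n_ident", "mismatches", "gap_opens")
  if (keep_alignment) cols <- c(cols, "q_aln", "s_aln")
  as_tibble(df[, cols])
}

#' Best local alignment score and coordinates for one pair
#'
#' Runs the engine's extension stage (affine-gap local alignment) on a single
#' query/subject pair, without seeding or e-value statistics.  Exposed mainly
#' so the alignment core can be validated against independent
#' implementations.
#'
#' @param query,subject Single sequences (nucleotide, or amino acid in
#'   translated mode).
#' @param settings A [search_settings()].
#' @return A one-row tibble with `score`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `align_length`, `n_ident`, `mismatches`, `gap_opens`.
#' @export
align_local <- function(query, subject, settings = search_settings()) {
  submat <- if (settings$mode == "nucleotide") .nt_matrix(settings)
            else .aa_matrix(settings$matrix_name)
  .align_block(query, subject, submat, settings$gap_open, settings$gap_extend)
}

# ---- the search engine -----------------------------------------------------

#' Search queries against a reference database
#'
#' The built-in similarity search: exact-word seeding on unmasked positions
#' (two word hits on a shared diagonal are required before extension, the
#' classic heuristic that suppresses chance seeds), affine-gap local
#' alignment of every seeded query/subject pair, ungapped Karlin-Altschul
#' e-values, and a deterministic output order (query input order, then
#' descending bit score, then subject id).  Nucleotide mode
#' searches both query strands; a minus-strand match is reported BLAST-style
#' with ascending query coordinates and `s_start > s_end`.  Translated mode
#' compares all six query frames with all six subject frames under the
#' amino-acid matrix, never extends through a stop codon, reports alignment
#' lengths in residues, and records the query frame of each hit.
#'
#' Only the single best alignment per query/subject pair (per query frame in
#' translated mode) is reported.
#'
#' @param queries,db Sequence tables ([seq_tbl()]).
#' @param settings A [search_settings()].
#' @return A hit tibble (see [parse_blast_tabular()] for columns).
#' @export
search_db <- function(queries, db, settings = search_settings()) {
  assert_seq_tbl(queries); assert_seq_tbl(db)
  if (nrow(db) == 0) abort("reference database is empty")
  if (nrow(queries) == 0) return(hit_tbl())
  if (!all(is_nt(queries$seq)) || !all(is_nt(db$seq))) {
    abort("search_db() takes nucleotide queries and database")
  }
  par <- .karlin_params(settings)
  n_db <- sum(nchar(db$seq))
  if (settings$mode == "nucleotide") {
    res <- .search_nt(queries, db, settings, par, n_db)
  } else {
    res <- .search_tx(queries, db, settings, par, n_db)
  }
  if (nrow(res) == 0) return(hit_tbl())
  res <- res[res$e_value <= settings$evalue_max & res$score > 0, ]
  # best alignment per query/subject(/frame), then deterministic order
  res <- res |>
    group_by(.data$query_id, .data$subject_id, .data$frame) |>
    arrange(desc(.data$bit_score), .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  res$.qord <- match(res$query_id, queries$id)
  res <- res |>
    arrange(.data$.qord, desc(.data$bit_score), .data$subject_id, .data$frame) |>
    select(-".qord")
  res$strand <- ifelse(res$s_start > res$s_end, "-", "+")
  res[, names(hit_tbl())]
}

.search_nt <- function(queries, db, settings, par, n_db) {
  k <- settings$word_size
  submat <- .nt_matrix(settings)
  s_idx <- lapply(lapply(db$seq, .word_pos, k = k, mask = FALSE),
                  .word_index)
  out <- list()
  for (ori in c("+", "-")) {
    qseq <- if (ori == "+") queries$seq else revcomp(queries$seq)
    q_wp <- lapply(qseq, .word_pos, k = k, mask = settings$mask_queries)
    # batch alignments per subject; extension requires two word hits on a
    # shared diagonal, which suppresses chance single-word seeds
    for (j in seq_len(nrow(db))) {
      qi <- which(vapply(q_wp, .two_hit_seeded, logical(1),
                         sidx = s_idx[[j]], k = k))
      if (length(qi) == 0) next
      blk <- .align_block(qseq[qi], db$seq[j], submat,
                          settings$gap_open, settings$gap_extend)
      blk$query_id <- queries$id[qi]
      blk$subject_id <- db$id[j]
      if (ori == "-") {
        n <- nchar(queries$seq[qi])
        qs <- n - blk$q_end + 1L; qe <- n - blk$q_start + 1L
        blk$q_start <- qs; blk$q_end <- qe
        tmp <- blk$s_start; blk$s_start <- blk$s_end; blk$s_end <- tmp
      }
      out[[length(out) + 1]] <- blk
    }
  }
  if (length(out) == 0) return(tibble())
  res <- list_rbind(out)
  res$frame <- NA_integer_
  .finish_hits(res, queries, par, n_db)
}

# nt coordinates (ascending) of aa positions a1..a2 in reading frame f of a
# sequence of length n.
.aa_to_nt <- function(a1, a2, f, n) {
  if (f > 0) {
    c(f + 3L * (a1 - 1L), f + 3L * a2 - 1L)
  } else {
    off <- -f
    rs <- off + 3L * (a1 - 1L); re <- off + 3L * a2 - 1L
    c(n - re + 1L, n - rs + 1L)
  }
}

# Words of length k with their positions (for diagonal two-hit seeding).
.word_pos <- function(s, k, mask = TRUE) {
  if (!mask) s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(NULL)
  w <- substring(s, 1:(n - k + 1), k:n)
  ok <- !str_detect(w, "[^A-Z]") & !str_detect(w, "[NX]")
  if (!any(ok)) return(NULL)
  list(w = w[ok], pos = which(ok))
}

# Subject-side seed index: word -> occurrence positions.
.word_index <- function(wp) {
  if (is.null(wp)) return(NULL)
  by_word <- split(wp$pos, wp$w)
  list(words = names(by_word), pos = unname(by_word))
}

# Two-hit seeding on a shared diagonal: short words recur by chance, so a
# candidate pair must share two *non-overlapping* word hits on one alignment
# diagonal before extension is attempted (the classic seeding heuristic that
# suppresses chance seeds; a single chance exact match of length ~2k-1 still
# only counts as one hit).
.two_hit_seeded <- function(qwp, sidx, k) {
  if (is.null(qwp) || is.null(sidx)) return(FALSE)
  m <- match(qwp$w, sidx$words)
  hit <- which(!is.na(m))
  if (length(hit) < 2) return(FALSE)
  d_all <- integer(0); q_all <- integer(0)
  for (a in hit) {
    sp <- sidx$pos[[m[a]]]
    d_all <- c(d_all, qwp$pos[a] - sp)
    q_all <- c(q_all, rep.int(qwp$pos[a], length(sp)))
  }
  if (anyDuplicated(d_all) == 0) return(FALSE)
  any(vapply(split(q_all, d_all), function(x) {
    length(x) > 1 && (max(x) - min(x)) >= k
  }, logical(1)))
}

.search_tx <- function(queries, db, settings, par, n_db) {
  k <- settings$word_size
  submat <- .aa_matrix(settings$matrix_name)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  tr_q <- lapply(queries$seq, function(s) {
    lapply(frames, function(f) translate_frame(s, f))
  })
  tr_s <- lapply(db$seq, function(s) {
    lapply(frames, function(f) translate_frame(s, f))
  })
  q_wp <- lapply(tr_q, function(fr_list) {
    lapply(fr_list, .word_pos, k = k, mask = settings$mask_queries)
  })
  s_idx <- lapply(tr_s, function(fr_list) {
    lapply(lapply(fr_list, .word_pos, k = k, mask = FALSE), .word_index)
  })
  out <- list()
  # batch all seeded query-frames against each subject-frame
  for (j in seq_len(nrow(db))) {
    for (fj in seq_along(frames)) {
      cand_i <- integer(0); cand_f <- integer(0)
      for (i in seq_len(nrow(queries))) {
        for (fi in seq_along(frames)) {
          if (.two_hit_seeded(q_wp[[i]][[fi]], s_idx[[j]][[fj]], k)) {
            cand_i <- c(cand_i, i); cand_f <- c(cand_f, fi)
          }
        }
      }
      if (length(cand_i) == 0) next
      pats <- vapply(seq_along(cand_i),
                     function(a) tr_q[[cand_i[a]]][[cand_f[a]]], character(1))
      blk <- .align_block(pats, tr_s[[j]][[fj]], submat,
                          settings$gap_open, settings$gap_extend)
      blk$query_id <- queries$id[cand_i]
      blk$subject_id <- db$id[j]
      blk$frame <- frames[cand_f]
      keep <- blk$score > 0
      if (!any(keep)) next
      blk <- blk[keep, ]
      qn <- nchar(queries$seq)[match(blk$query_id, queries$id)]
      sn <- nchar(db$seq[j])
      fs <- frames[fj]
      for (r in seq_len(nrow(blk))) {
        qc <- .aa_to_nt(blk$q_start[r], blk$q_end[r], blk$frame[r], qn[r])
        sc <- .aa_to_nt(blk$s_start[r], blk$s_end[r], fs, sn)
        blk$q_start[r] <- qc[1]; blk$q_end[r] <- qc[2]
        if (fs > 0) {
          blk$s_start[r] <- sc[1]; blk$s_end[r] <- sc[2]
        } else {
          blk$s_start[r] <- sc[2]; blk$s_end[r] <- sc[1]
        }
      }
      out[[length(out) + 1]] <- blk
    }
  }
  if (length(out) == 0) return(tibble())
  .finish_hits(list_rbind(out), queries, par, n_db)
}

.finish_hits <- function(res, queries, par, n_db) {
  res$pct_identity <- round(100 * res$n_ident / res$align_length, 2)
  res$bit_score <- round(.bit_score(res$score, par), 1)
  m <- nchar(queries$seq)[match(res$query_id, queries$id)]
  res$e_value <- signif(.e_value(res$bit_score, m, n_db), 3)
  res
}

#' Choose the best-scoring orientation of a query against a reference
#'
#' Scores the query and its reverse complement by local alignment against the
#' reference and returns the better orientation (ties go to `"forward"`).
#'
#' @param query,ref Single nucleotide sequences.
#' @param settings A nucleotide-mode [search_settings()].
#' @return A one-row tibble with `orientation` (`"forward"` or
#'   `"reverse_complement"`), `score`, and `oriented_seq`.
#' @export
best_orientation <- function(query, ref, settings = search_settings()) {
  stopifnot(settings$mode == "nucleotide")
  fwd <- align_local(query, ref, settings)$score
  rc_seq <- revcomp(query)
  rev <- align_local(rc_seq, ref, settings)$score
  if (fwd >= rev) {
    tibble(orientation = "forward", score = fwd, oriented_seq = query)
  } else {
    tibble(orientation = "reverse_complement", score = rev,
           oriented_seq = rc_seq)
  }
}
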
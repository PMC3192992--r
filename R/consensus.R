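# ---- reference-anchored projection ----------------------------------------
#
# The built-in multiple-alignment engine is reference-anchored: each member is
# pairwise-aligned to the reference and projected into the reference
# coordinate frame.  Insertions relative to the reference are kept as
# member-only columns placed after their anchoring reference position.

# Project one member onto the reference: returns res[ref_pos] (residue, "-"
# for a deletion, NA outside the aligned span) and a list of insertions
# keyed "pos.offset".
.project_one <- function(member, ref, submat, gap_open, gap_extend,
                         type = "local") {
  aln <- .align_block(member, ref, submat, gap_open, gap_extend,
                      local = (type == "local"), keep_alignment = TRUE)
  pa <- chars(aln$q_aln[1])
  sa <- chars(aln$s_aln[1])
  rp <- aln$s_start[1] - 1L
  p0 <- aln$q_start[1] - 1L
  res <- rep(NA_character_, nchar(ref))
  srcv <- rep(NA_integer_, nchar(ref))
  ins <- list()
  k <- 0L
  ai <- p0
  for (c in seq_along(sa)) {
    if (pa[c] != "-") ai <- ai + 1L
    if (sa[c] != "-") {
      rp <- rp + 1L; k <- 0L
      res[rp] <- pa[c]
      if (pa[c] != "-") srcv[rp] <- ai
    } else {
      k <- k + 1L
      ins[[paste0(rp, ".", k)]] <- list(char = pa[c], src = ai)
    }
  }
  list(res = res, srcv = srcv, ins = ins,
       span = c(aln$s_start[1], rp),
       q_start = p0 + 1L, q_end = ai)
}

# Project all members; returns a character matrix (members x columns), the
# column metadata (ref_pos, ins offset; ins == 0 marks a true reference
# column), and per-member source index matrix for back-translation.
.project_members <- function(members, ref, submat, gap_open, gap_extend,
                             type = "local") {
  projs <- lapply(members, .project_one, ref = ref, submat = submat,
                  gap_open = gap_open, gap_extend = gap_extend, type = type)
  L <- nchar(ref)
  ins_keys <- sort(unique(unlist(lapply(projs, function(p) names(p$ins)))))
  ins_pos <- as.integer(sub("\\..*$", "", ins_keys))
  ins_off <- as.integer(sub("^.*\\.", "", ins_keys))
  cols <- tibble(ref_pos = c(seq_len(L), ins_pos),
                 ins = c(rep(0L, L), ins_off))
  ord <- order(cols$ref_pos + ifelse(cols$ins > 0, 0.5, 0), cols$ins)
  cols <- cols[ord, ]
  key <- paste0(cols$ref_pos, ".", cols$ins)
  mat <- matrix(NA_character_, nrow = length(members), ncol = nrow(cols),
                dimnames = list(names(members), key))
  src <- matrix(NA_integer_, nrow = length(members), ncol = nrow(cols))
  for (i in seq_along(projs)) {
    p <- projs[[i]]
    refcols <- which(cols$ins == 0L)
    mat[i, refcols] <- p$res[cols$ref_pos[cols$ins == 0L]]
    src[i, refcols] <- p$srcv[cols$ref_pos[cols$ins == 0L]]
    # insertions this member carries
    for (keyname in names(p$ins)) {
      j <- match(keyname, key)
      mat[i, j] <- p$ins[[keyname]]$char
      src[i, j] <- as.integer(p$ins[[keyname]]$src)
    }
    # members spanning an insertion column they do not share get '-'
    span <- p$span
    inside <- cols$ins > 0L & cols$ref_pos >= span[1] & cols$ref_pos < span[2]
    mat[i, inside & is.na(mat[i, ])] <- "-"
  }
  list(mat = mat, cols = cols, src = src,
       spans = lapply(projs, `[[`, "span"))
}

# Majority call over the member rows of one column.  NA (member does not
# cover the column) does not vote; the reference never votes.  Ties between
# bases resolve to the IUPAC ambiguity code (nucleotide) or 'X' (amino acid);
# a tie between a gap and a base resolves to the base.
.majority_call <- function(votes, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0) return("-")
  ct <- sort(table(toupper(votes)), decreasing = TRUE)
  top <- names(ct)[ct == max(ct)]
  if (length(top) == 1) return(top)
  bases <- setdiff(top, "-")
  if (length(bases) == 1) return(bases)
  if (length(bases) == 0) return("-")
  if (alphabet == "nt") iupac_code(bases) else "X"
}

#' Gap percentages in user-defined consensus regions
#'
#' Splits the alignment columns into consecutive regions by cumulative
#' fractions (boundaries rounded half-up) and reports the percentage of gap
#' (`-`) columns in each.  The default regions are the 5' 30%, the middle
#' 40%, and the 3' 30%.
#'
#' @param aligned_seq A single gapped sequence (a consensus), or a
#'   `consensus_record`.
#' @param fractions Region fractions, positive and summing to 1.
#' @return A named numeric vector of gap percentages, one per region.
#' @export
gap_stats <- function(aligned_seq, fractions = c(0.3, 0.4, 0.3)) {
  if (inherits(aligned_seq, "consensus_record")) {
    aligned_seq <- aligned_seq$aligned_seq
  }
  stopifnot(length(aligned_seq) == 1, nchar(aligned_seq) > 0)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    abort("region fractions must be positive and sum to 1")
  }
  cs <- chars(aligned_seq)
  L <- length(cs)
  bounds <- floor(L * cumsum(fractions) + 0.5)
  bounds[length(bounds)] <- L
  starts <- c(1L, head(bounds, -1) + 1L)
  pct <- map2_dbl(starts, bounds, function(s, e) {
    if (e < s) return(0)
    100 * mean(cs[s:e] == "-")
  })
  names(pct) <- paste0("region", seq_along(pct))
  pct
}

#' Back-translate an aligned amino-acid block to codon space
#'
#' Each residue column of an aligned peptide expands to the codon it was
#' translated from in its source nucleotide sequence; each gap expands to
#' `---`.  The 0-2 leading bases of a frame offset sit outside the aligned
#' block and are not included.  For negative frames the codons are taken from
#' the reverse complement of the source, so the returned block reads in the
#' translation's own orientation.
#'
#' @param aa_alignment Character vector of aligned amino-acid rows (equal
#'   lengths); the ungapped content of each row must equal the full
#'   frame-translation of its source.
#' @param sources Character vector of the original nucleotide sequences,
#'   parallel to `aa_alignment`.
#' @param frames Integer vector of reading frames in `c(-3:-1, 1:3)`.
#' @return Character vector of aligned nucleotide rows (each 3x the aa
#'   alignment length).
#' @export
back_translate <- function(aa_alignment, sources, frames) {
  stopifnot(length(aa_alignment) == length(sources),
            length(sources) == length(frames))
  out <- character(length(sources))
  for (i in seq_along(sources)) {
    row <- chars(aa_alignment[i])
    aa_plain <- paste(row[row != "-"], collapse = "")
    tr <- translate_frame(sources[i], frames[i])
    if (toupper(aa_plain) != toupper(tr)) {
      abort(paste0("row ", i, " is not the frame-", frames[i],
                   " translation of its source"))
    }
    s <- if (frames[i] < 0) revcomp(sources[i]) else sources[i]
    off <- abs(frames[i]) - 1L
    codons <- character(length(row))
    ai <- 0L
    for (c in seq_along(row)) {
      if (row[c] == "-") {
        codons[c] <- "---"
      } else {
        ai <- ai + 1L
        codons[c] <- substr(s, off + 3L * ai - 2L, off + 3L * ai)
      }
    }
    out[i] <- paste(codons, collapse = "")
  }
  out
}

# Reading frame that anchors a coding reference: the frame holding its
# longest ATG-to-stop ORF (frame +1 for a clean CDS), falling back to +1.
.best_ref_frame <- function(ref) {
  orf <- find_longest_orf(ref, min_transcript_len = 0L)
  if (is.null(orf)) 1L else orf$frame
}

#' Build a reference-anchored majority consensus
#'
#' A single member passes through verbatim (a "one-to-one" consensus), still
#' named after the reference.  Several members are oriented (nucleotide mode)
#' or translated in their best-hit frames (protein mode), projected onto the
#' reference by pairwise alignment, and majority-called column by column.
#' The reference only anchors: it never votes, and reference positions
#' covered by no member come out as `-`.  In protein mode the member
#' alignment is back-translated to codons before the (nucleotide) majority
#' call.
#'
#' @param members Sequence table of the assigned queries (>= 1 row).
#' @param reference One-row sequence table (or id + seq) of the anchoring
#'   database sequence.
#' @param mode `"nucleotide"` or `"protein_frame"`.
#' @param frames Named integer vector (by member id) of best-hit query
#'   frames; required in protein mode.
#' @param settings Alignment scoring for the anchoring ([search_settings()]);
#'   defaults fit the mode.
#' @param region_fractions Passed to [gap_stats()].
#' @return A `consensus_record`: list with `name`, `aligned_seq`,
#'   `members` (tibble of id and orientation/frame), `is_one_to_one`,
#'   `gap_pct`, `ref_len`, `discordant`.
#' @export
build_consensus <- function(members, reference,
                            mode = c("nucleotide", "protein_frame"),
                            frames = NULL,
                            settings = NULL,
                            region_fractions = c(0.3, 0.4, 0.3)) {
  mode <- match.arg(mode)
  assert_seq_tbl(members)
  if (nrow(members) == 0) abort("a consensus needs at least one member")
  if (is.data.frame(reference)) {
    ref_id <- reference$id[1]; ref_seq <- reference$seq[1]
  } else {
    ref_id <- names(reference)[1] %||% "reference"; ref_seq <- reference[[1]]
  }
  if (mode == "protein_frame") {
    if (is.null(frames) || !all(members$id %in% names(frames))) {
      abort("protein_frame mode needs a best-hit frame for every member")
    }
  }
  settings <- settings %||%
    if (mode == "nucleotide") search_settings("nucleotide")
    else search_settings("translated")

  if (nrow(members) == 1) {
    aligned <- members$seq[1]
    rec <- structure(list(
      name = ref_id, aligned_seq = aligned,
      members = tibble(id = members$id, orientation = "forward",
                       frame = NA_integer_),
      is_one_to_one = TRUE,
      gap_pct = gap_stats(aligned, region_fractions),
      ref_len = nchar(ref_seq), mode = mode, discordant = FALSE),
      class = "consensus_record")
    return(rec)
  }

  if (mode == "nucleotide") {
    oriented <- lapply(members$seq, best_orientation, ref = ref_seq,
                       settings = settings)
    mseqs <- setNames(map_chr(oriented, "oriented_seq"), members$id)
    proj <- .project_members(mseqs, ref_seq, .nt_matrix(settings),
                             settings$gap_open, settings$gap_extend)
    cons <- apply(proj$mat, 2, .majority_call, alphabet = "nt")
    aligned <- paste(cons, collapse = "")
    minfo <- tibble(id = members$id,
                    orientation = map_chr(oriented, "orientation"),
                    frame = NA_integer_)
  } else {
    ref_frame <- .best_ref_frame(ref_seq)
    ref_aa <- translate_frame(ref_seq, ref_frame)
    fr <- frames[members$id]
    maa <- setNames(
      map_chr(seq_len(nrow(members)),
              function(i) translate_frame(members$seq[i], fr[[i]])),
      members$id)
    proj <- .project_members(maa, ref_aa, .aa_matrix(settings$matrix_name),
                             settings$gap_open, settings$gap_extend)
    # expand each member row to codons, then majority-call per nt column
    nt_rows <- matrix(NA_character_,
                      nrow = nrow(proj$mat), ncol = 3L * ncol(proj$mat))
    for (i in seq_len(nrow(proj$mat))) {
      s <- if (fr[[i]] < 0) revcomp(members$seq[i]) else members$seq[i]
      off <- abs(fr[[i]]) - 1L
      for (j in seq_len(ncol(proj$mat))) {
        ch <- proj$mat[i, j]
        cod <- if (is.na(ch)) rep(NA_character_, 3)
          else if (ch == "-") rep("-", 3)
          else chars(substr(s, off + 3L * proj$src[i, j] - 2L,
                            off + 3L * proj$src[i, j]))
        nt_rows[i, (3L * j - 2L):(3L * j)] <- cod
      }
    }
    cons <- apply(nt_rows, 2, .majority_call, alphabet = "nt")
    # columns whose amino-acid call was an X-tie come out as NNN
    aligned <- paste(cons, collapse = "")
    minfo <- tibble(id = members$id, orientation = NA_character_,
                    frame = unname(unlist(fr)))
    proj$mat <- nt_rows
  }

  discordant <- .is_discordant(proj$mat)
  structure(list(
    name = ref_id, aligned_seq = aligned, members = minfo,
    is_one_to_one = FALSE,
    gap_pct = gap_stats(aligned, region_fractions),
    ref_len = nchar(ref_seq), mode = mode, discordant = discordant),
    class = "consensus_record")
}

# Paralog-joining heuristic: >= 2 members disagreeing at >= 10% of the
# columns they share.
.is_discordant <- function(mat, min_frac = 0.1) {
  n <- nrow(mat)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      if (sum(shared) == 0) next
      if (mean(toupper(mat[i, shared]) != toupper(mat[j, shared])) >= min_frac) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' @export
print.consensus_record <- function(x, ...) {
  cat("<consensus_record> ", x$name,
      if (x$is_one_to_one) " (one-to-one)" else
        paste0(" (", nrow(x$members), " members)"),
      "\n  length ", nchar(x$aligned_seq),
      ", gap% = ", paste(round(x$gap_pct, 1), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Reference-guided assembly of mitochondrial reads
#'
#' Places every member on the mitochondrial reference by its best local
#' alignment (testing both orientations), builds a per-position pileup of
#' base and gap (deletion) alleles, majority-calls a consensus (`-` where no
#' member covers a position), and reports per-feature coverage.  The pileup
#' is returned for downstream variant calling.
#'
#' @param members Sequence table of mtDNA-assigned reads.
#' @param reference One-row sequence table (or single string) of the
#'   mitochondrial genome.
#' @param features Optional feature tibble ([read_gff3_features()]) for the
#'   coverage report.
#' @param settings Nucleotide [search_settings()].
#' @return A list with `consensus` (reference-length string), `pileup`
#'   (tibble: `pos`, `allele`, `depth`), `coverage` (tibble per feature:
#'   `gene_name`, `feature_class`, `covered_frac`, `missing`), and `depth`
#'   (integer vector per reference position).
#' @export
reference_guided_assembly <- function(members, reference, features = NULL,
                                      settings = search_settings("nucleotide")) {
  assert_seq_tbl(members)
  if (is.data.frame(reference)) reference <- reference$seq[1]
  L <- nchar(reference)
  if (nrow(members) == 0) {
    pile <- tibble(pos = integer(), allele = character(), depth = integer())
    cons <- paste(rep("-", L), collapse = "")
    depth <- integer(L)
  } else {
    oriented <- map_chr(members$seq, function(s) {
      best_orientation(s, reference, settings)$oriented_seq
    })
    proj <- .project_members(setNames(oriented, members$id), reference,
                             .nt_matrix(settings),
                             settings$gap_open, settings$gap_extend)
    refcols <- which(proj$cols$ins == 0L)
    mat <- proj$mat[, refcols, drop = FALSE]
    depth <- apply(mat, 2, function(v) sum(!is.na(v)))
    cons <- paste(apply(mat, 2, .majority_call, alphabet = "nt"),
                  collapse = "")
    pile <- lapply(seq_len(ncol(mat)), function(j) {
      v <- mat[, j]; v <- v[!is.na(v)]
      if (length(v) == 0) return(NULL)
      ct <- table(toupper(v))
      tibble(pos = j, allele = names(ct), depth = as.integer(ct))
    })
    pile <- list_rbind(pile[!vapply(pile, is.null, logical(1))])
  }
  coverage <- NULL
  if (!is.null(features) && nrow(features) > 0) {
    coverage <- features |>
      mutate(covered_frac = map2_dbl(.data$start, .data$end, function(s, e) {
        mean(depth[s:e] > 0)
      })) |>
      mutate(missing = .data$covered_frac == 0) |>
      select("gene_name", "feature_class", "start", "end",
             "covered_frac", "missing")
  }
  list(consensus = cons, pileup = pile, coverage = coverage, depth = depth)
}
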
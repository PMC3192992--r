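#' Define one round of the homology-assignment cascade
#'
#' @param name Round name, one of `"mtDNA"`, `"ncRNA"`, `"coding"`,
#'   `"unigene"`, `"genomic"`, `"cross_species"`.
#' @param db Reference database as a sequence table ([seq_tbl()]), or a path
#'   to a FASTA file.
#' @param settings A [search_settings()]; defaults to the round's standard
#'   parameters (nucleotide word 11 for mtDNA/ncRNA, word 9 for
#'   unigene/genomic/cross-species, translated word 3 with BLOSUM45 for the
#'   coding round).
#' @param filter A [hit_filter()]; defaults to >= 50 bp and >= 50% identity
#'   for nucleotide rounds, >= 30 aa and >= 50% for the coding round.
#' @param species Optional species tag attached to assignments from this
#'   round's database.
#' @return A list with class `cascade_round`.
#' @export
cascade_round <- function(name, db, settings = NULL, filter = NULL,
                          species = NA_character_) {
  valid <- c("mtDNA", "ncRNA", "coding", "unigene", "genomic", "cross_species")
  if (!name %in% valid) {
    abort(paste0("round name must be one of: ", paste(valid, collapse = ", ")))
  }
  if (is.character(db) && length(db) == 1) db <- read_fasta(db)
  assert_seq_tbl(db)
  if (is.null(settings)) {
    settings <- switch(name,
      coding = search_settings("translated"),
      mtDNA = , ncRNA = search_settings("nucleotide"),
      search_settings("nucleotide", word_size = 9L))
  }
  if (is.null(filter)) {
    filter <- if (name == "coding") hit_filter(30L, 50, "aa")
              else hit_filter(50L, 50, "bp")
  }
  structure(list(name = name, db = db, settings = settings, filter = filter,
                 species = species),
            class = "cascade_round")
}

#' Standard round set for the cascade
#'
#' Builds the fixed-order round list: mtDNA and ncRNA first, then coding
#' (translated), Unigene-style EST clusters, and genomic sequence, each with
#' its standard settings and filters.
#'
#' @param mt_db,ncrna_db,coding_db,unigene_db,genomic_db Sequence tables (or
#'   FASTA paths); pass `NULL` to omit a round.
#' @return A list of [cascade_round()] objects in cascade order.
#' @export
cascade_rounds <- function(mt_db = NULL, ncrna_db = NULL, coding_db = NULL,
                           unigene_db = NULL, genomic_db = NULL) {
  dbs <- list(mtDNA = mt_db, ncRNA = ncrna_db, coding = coding_db,
              unigene = unigene_db, genomic = genomic_db)
  dbs <- dbs[!vapply(dbs, is.null, logical(1))]
  unname(imap(dbs, function(db, nm) cascade_round(nm, db)))
}

#' Select the best hit per query
#'
#' Resolution rule for a query hitting several database entries: smallest
#' e-value, then greatest alignment length, then highest percent identity;
#' remaining ties go to the first hit encountered in the (deterministic)
#' input order, so a given input always resolves identically.
#'
#' @param hits A hit tibble, non-empty; may contain several queries, in which
#'   case one best hit per query is returned.
#' @return A hit tibble with one row per query, in first-appearance query
#'   order.
#' @export
select_best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) {
    abort("select_best_hit() needs at least one hit")
  }
  hits$.ord <- seq_len(nrow(hits))
  out <- hits |>
    group_by(.data$query_id) |>
    arrange(.data$e_value, desc(.data$align_length),
            desc(.data$pct_identity), .data$.ord, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  out <- out[order(match(out$query_id, unique(hits$query_id))), ]
  select(out, -".ord")
}

.empty_assignments <- function() {
  tibble(query_id = character(), round = character(),
         subject_id = character(), reference_species = character(),
         e_value = numeric(), pct_identity = numeric(),
         align_length = integer(), frame = integer())
}

# Run one round: returns best assignments and surviving query ids.
.run_round <- function(seqs, rnd) {
  hits <- search_db(seqs, rnd$db, rnd$settings)
  hits <- filter_hits(hits, rnd$filter)
  if (nrow(hits) == 0) return(.empty_assignments())
  best <- select_best_hit(hits)
  tibble(query_id = best$query_id, round = rnd$name,
         subject_id = best$subject_id,
         reference_species = rnd$species,
         e_value = best$e_value, pct_identity = best$pct_identity,
         align_length = best$align_length, frame = best$frame)
}

#' Run the homology-assignment cascade
#'
#' Queries are searched round by round in the fixed order mtDNA, ncRNA,
#' coding, unigene, genomic.  The mtDNA and ncRNA searches form the first
#' pass: queries with a surviving mtDNA hit are assigned there (and are the
#' input set for reference-guided mitochondrial assembly); queries whose only
#' first-pass hit is ncRNA are recorded and removed from consensus building.
#' At every later round, queries with a surviving hit are assigned and
#' removed; the rest move on.  Queries never assigned anywhere are returned
#' as orphans.  Assignments and orphans always partition the input.
#'
#' @param seqs Query sequence table (contigs and singletons).
#' @param rounds A list of [cascade_round()] objects in cascade order (e.g.
#'   from [cascade_rounds()]).
#' @param contaminant_db Optional sequence table of contaminants; queries
#'   hitting it (nucleotide defaults) are removed before the first round and
#'   reported in the counts.
#' @return A list with class `cascade_result`: `assignments` (tibble:
#'   `query_id`, `round`, `subject_id`, `reference_species`, `e_value`,
#'   `pct_identity`, `align_length`, `frame`), `orphans` (sequence table),
#'   and `round_counts` (tibble: `round`, `n_in`, `n_assigned`).
#' @export
run_cascade <- function(seqs, rounds, contaminant_db = NULL) {
  assert_seq_tbl(seqs)
  nm <- vapply(rounds, function(r) r$name, character(1))
  if (anyDuplicated(nm)) abort("round names must be unique")
  order_ref <- c("mtDNA", "ncRNA", "coding", "unigene", "genomic",
                 "cross_species")
  if (is.unsorted(match(nm, order_ref))) {
    abort("rounds must be supplied in cascade order")
  }
  remaining <- seqs
  assignments <- list()
  counts <- list()
  if (!is.null(contaminant_db) && nrow(remaining) > 0) {
    scr <- .run_round(remaining, cascade_round("ncRNA", contaminant_db))
    scr$round <- "contaminant"
    counts[[length(counts) + 1]] <-
      tibble(round = "contaminant", n_in = nrow(remaining),
             n_assigned = nrow(scr))
    remaining <- remaining[!remaining$id %in% scr$query_id, ]
    if (nrow(scr) > 0) assignments[[length(assignments) + 1]] <- scr
  }
  for (rnd in rounds) {
    if (nrow(remaining) == 0) break
    asg <- .run_round(remaining, rnd)
    counts[[length(counts) + 1]] <-
      tibble(round = rnd$name, n_in = nrow(remaining),
             n_assigned = nrow(asg))
    if (nrow(asg) > 0) {
      assignments[[length(assignments) + 1]] <- asg
      remaining <- remaining[!remaining$id %in% asg$query_id, ]
    }
  }
  assignments <- if (length(assignments) > 0) list_rbind(assignments) else
    .empty_assignments()
  structure(list(assignments = assignments, orphans = remaining,
                 round_counts = list_rbind(counts)),
            class = "cascade_result")
}

#' Cross-species round: search orphans against other species' consensuses
#'
#' Each species' orphan sequences are searched against the pooled (ungapped)
#' consensus sequences of all *other* species; self-species consensuses are
#' excluded from the database.  Assignments carry the matched species tag.
#'
#' @param orphans_by_species Named list of sequence tables, one per species.
#' @param consensus_by_species Named list of sequence tables of ungapped
#'   consensus sequences, one per species.
#' @param settings,filter Search settings and filter; default to the
#'   cross-species standards (nucleotide, word 9; >= 50 bp, >= 50%).
#' @return An assignments tibble as in [run_cascade()], with
#'   `reference_species` naming the species whose consensus was matched.
#' @export
cross_species_round <- function(orphans_by_species, consensus_by_species,
                                settings = search_settings("nucleotide",
                                                           word_size = 9L),
                                filter = hit_filter(50L, 50, "bp")) {
  if (length(orphans_by_species) < 2 && length(consensus_by_species) < 2) {
    abort("cross-species comparison needs at least two species")
  }
  out <- list()
  for (sp in names(orphans_by_species)) {
    orphans <- orphans_by_species[[sp]]
    if (is.null(orphans) || nrow(orphans) == 0) next
    others <- consensus_by_species[setdiff(names(consensus_by_species), sp)]
    others <- others[vapply(others, function(x) nrow(x) > 0, logical(1))]
    if (length(others) == 0) next
    db <- list_rbind(imap(others, function(tbl, osp) {
      mutate(tbl, .species = osp)
    }))
    db_seq <- seq_tbl(db$id, gsub("-", "", db$seq, fixed = TRUE))
    asg <- .run_round(orphans,
                      cascade_round("cross_species", db_seq, settings, filter))
    if (nrow(asg) > 0) {
      asg$reference_species <- db$.species[match(asg$subject_id, db$id)]
      asg$query_species <- sp
      out[[length(out) + 1]] <- asg
    }
  }
  if (length(out) == 0) {
    return(tibble(query_id = character(), round = character(),
                  subject_id = character(), reference_species = character(),
                  e_value = numeric(), pct_identity = numeric(),
                  align_length = integer(), frame = integer(),
                  query_species = character()))
  }
  list_rbind(out)
}

#' Longest open reading frame of a species-specific transcript
#'
#' Applies only to transcripts longer than `min_transcript_len` (default
#' 1,000 bp, the gate used for species-specific sequences).  ORFs are
#' ATG-to-stop in all six reading frames; the longest deduced peptide wins,
#' ties resolved to the lowest frame (`+1,+2,+3,-1,-2,-3`) then the leftmost
#' start.
#'
#' @param seq A single nucleotide sequence.
#' @param min_transcript_len Length gate in bp (default 1000).
#' @return A one-row tibble with `peptide`, `frame`, `aa_length`, `nt_start`,
#'   `nt_end` (coordinates on the forward strand), or `NULL` when the gate is
#'   not met or no ORF exists.
#' @export
find_longest_orf <- function(seq, min_transcript_len = 1000L) {
  stopifnot(length(seq) == 1)
  n <- nchar(seq)
  if (n <= min_transcript_len) return(NULL)
  best <- NULL
  for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    aa <- translate_frame(seq, f)
    # ATG-initiated stretches ending at a stop
    m <- gregexpr("M[^*]*\\*", aa, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length") - 1L  # peptide length excl. stop
    for (k in seq_along(m)) {
      if (is.null(best) || lens[k] > best$aa_length) {
        a1 <- as.integer(m[k]); a2 <- a1 + lens[k]  # incl. stop codon
        ntc <- .aa_to_nt(a1, a2, f, n)
        best <- tibble(
          peptide = substr(aa, a1, a1 + lens[k] - 1L),
          frame = f, aa_length = lens[k],
          nt_start = ntc[1], nt_end = ntc[2])
      }
    }
  }
  best
}
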
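#' Microsatellite detection thresholds
#'
#' The MISA-convention minimum repeat counts: mononucleotide motifs must
#' repeat at least 10 times, di- to hexanucleotide motifs at least 5 times.
#' Two or more perfect repeats separated by less than `max_interruption`
#' bases (strictly) merge into one compound locus.
#'
#' @param min_repeats Named integer vector mapping motif length (`"1"`-`"6"`)
#'   to the minimum repeat count.
#' @param max_interruption Compound-merging spacer bound in bp (exclusive;
#'   default 50).
#' @param strict If `TRUE`, read the thresholds as strict ("more than")
#'   bounds, i.e. require `min_repeats + 1`.
#' @return A list with class `ssr_thresholds`.
#' @export
ssr_thresholds <- function(min_repeats = c(`1` = 10L, `2` = 5L, `3` = 5L,
                                           `4` = 5L, `5` = 5L, `6` = 5L),
                           max_interruption = 50L,
                           strict = FALSE) {
  if (!all(names(min_repeats) %in% as.character(1:6))) {
    abort("min_repeats must be named by motif lengths 1..6")
  }
  if (any(min_repeats < 2)) abort("min_repeats must be >= 2")
  structure(list(min_repeats = min_repeats,
                 max_interruption = as.integer(max_interruption),
                 strict = strict),
            class = "ssr_thresholds")
}

# TRUE when a motif is a tandem multiple of a shorter unit (e.g. "ATAT").
.is_primitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 &&
        strrep(substr(motif, 1, d), k %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Canonical microsatellite motif class
#'
#' The lexicographically minimal string over all rotations of the motif and
#' of its reverse complement, so that e.g. `GT`, `TG`, `AC` and `CA` all
#' report as class `AC`, and `ATT` as `AAT` -- the grouped classes used when
#' tabulating repeat types.
#'
#' @param motif Character vector of repeat units (length 1-6 each).
#' @return Character vector of canonical class strings.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    m <- toupper(m)
    k <- nchar(m)
    if (k < 1 || k > 6) abort("motif length must be 1..6")
    rots <- function(s) {
      vapply(seq_len(k), function(i) {
        paste0(substr(s, i, k), substr(s, 1, i - 1))
      }, character(1))
    }
    min(c(rots(m), rots(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Find perfect and compound microsatellites
#'
#' Maximal perfect tandem repeats of unit length 1-6 meeting the thresholds
#' are reported left to right; a repeat whose unit is itself periodic is
#' reported under its shortest unit.  Perfect loci separated by fewer than
#' `max_interruption` bases then merge into compound loci.
#'
#' @param seqs A sequence table ([seq_tbl()]) or a single sequence string.
#' @param thresholds An [ssr_thresholds()].
#' @return A tibble with one row per locus: `seq_id`, `kind` (`"perfect"` or
#'   `"compound"`), `motif` (the unit as found, or a compound label),
#'   `canonical_motif` (`NA` for compounds), `n_repeats`, `start`, `end`
#'   (1-based inclusive), and `components` (list-column of member perfect
#'   loci for compounds, `NULL` otherwise).
#' @export
find_ssrs <- function(seqs, thresholds = ssr_thresholds()) {
  if (is.character(seqs)) seqs <- seq_tbl("seq1", seqs)
  assert_seq_tbl(seqs)
  bump <- if (thresholds$strict) 1L else 0L
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    s <- toupper(seqs$seq[i])
    perfect <- list()
    for (k in 1:6) {
      minrep <- thresholds$min_repeats[[as.character(k)]] + bump
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, minrep - 1L)
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1) next
      len <- attr(m, "match.length")
      for (j in seq_along(m)) {
        unit <- substr(s, m[j], m[j] + k - 1L)
        if (!.is_primitive(unit)) next
        n_rep <- len[j] %/% k
        perfect[[length(perfect) + 1]] <- tibble(
          seq_id = seqs$id[i], kind = "perfect", motif = unit,
          canonical_motif = canonical_motif(unit),
          n_repeats = n_rep,
          start = as.integer(m[j]),
          end = as.integer(m[j]) + k * n_rep - 1L)
      }
    }
    if (length(perfect) == 0) return(NULL)
    loci <- arrange(list_rbind(perfect), .data$start, .data$end)
    # drop a locus fully contained in another (longer-unit echo)
    keep <- rep(TRUE, nrow(loci))
    for (a in seq_len(nrow(loci))) {
      for (b in seq_len(nrow(loci))) {
        if (a != b && keep[a] && keep[b] &&
            loci$start[b] <= loci$start[a] && loci$end[a] <= loci$end[b] &&
            (loci$end[b] - loci$start[b]) > (loci$end[a] - loci$start[a])) {
          keep[a] <- FALSE
        }
      }
    }
    loci <- loci[keep, ]
    # compound merging: spacer strictly below max_interruption
    grp <- cumsum(c(1L, as.integer(
      loci$start[-1] - loci$end[-nrow(loci)] - 1L >=
        thresholds$max_interruption)))
    loci |>
      mutate(.grp = grp) |>
      group_by(.data$.grp) |>
      group_map(function(g, key) {
        if (nrow(g) == 1) {
          g$components <- list(NULL)
          return(g)
        }
        tibble(seq_id = g$seq_id[1], kind = "compound",
               motif = paste0("(", g$motif, ")", g$n_repeats,
                              collapse = "-"),
               canonical_motif = NA_character_,
               n_repeats = sum(g$n_repeats),
               start = min(g$start), end = max(g$end),
               components = list(g))
      }) |>
      list_rbind()
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(tibble(seq_id = character(), kind = character(),
                  motif = character(), canonical_motif = character(),
                  n_repeats = integer(), start = integer(), end = integer(),
                  components = list()))
  }
  list_rbind(out)
}

#' Call SNP and indel sites from a pileup
#'
#' A pileup column is polymorphic when at least two alleles are observed.
#' The minor allele is the second most frequent; a site is high-confidence
#' when the minor-allele depth reaches `min_minor` (default 3, so a minimum
#' informative depth of 6) -- the rule separating genuine heterozygous sites
#' from sequencing error.  Columns with a gap allele are indels; an indel
#' adjacent to a homopolymer run of at least `homopolymer_min` identical
#' bases is flagged `in_homopolymer` (pyrosequencing-style error hotspots,
#' hence low-confidence regardless of depth).  Ties for the minor allele
#' keep the alphabetically first contenders and flag the site multi-allelic.
#'
#' @param pileup Tibble with columns `pos`, `allele` (`A/C/G/T/N/-`),
#'   `depth`, and optionally `seq_id`.
#' @param min_minor Minimum minor-allele depth for high confidence
#'   (default 3).
#' @param homopolymer_min Minimum adjacent identical-base run for the
#'   homopolymer flag (default 3).
#' @param context Optional reference/consensus sequence used to evaluate
#'   homopolymer context around indels.
#' @return A tibble with one row per polymorphic site: `seq_id` (if given),
#'   `pos`, `kind` (`"snp"`/`"indel"`), `major_allele`, `minor_allele`,
#'   `major_depth`, `minor_depth`, `total_depth`, `high_confidence`,
#'   `in_homopolymer`, `multi_allelic`.
#' @export
call_variants <- function(pileup, min_minor = 3L, homopolymer_min = 3L,
                          context = NULL) {
  if (is.null(pileup) || nrow(pileup) == 0) {
    abort("call_variants() needs a non-empty pileup")
  }
  if (!all(c("pos", "allele", "depth") %in% names(pileup))) {
    abort("pileup must have columns pos, allele, depth")
  }
  if (!"seq_id" %in% names(pileup)) pileup$seq_id <- "seq1"
  sites <- pileup |>
    group_by(.data$seq_id, .data$pos) |>
    group_map(function(g, key) {
      g <- g[g$depth > 0, ]
      if (nrow(g) < 2) return(NULL)
      g <- g[order(-g$depth, g$allele), ]
      multi <- nrow(g) > 2 && g$depth[3] == g$depth[2]
      major <- g$allele[1]; minor <- g$allele[2]
      is_indel <- major == "-" || minor == "-"
      in_homo <- FALSE
      if (is_indel && !is.null(context)) {
        in_homo <- .in_homopolymer(context, key$pos, homopolymer_min)
      }
      tibble(seq_id = key$seq_id, pos = key$pos,
             kind = if (is_indel) "indel" else "snp",
             major_allele = major, minor_allele = minor,
             major_depth = g$depth[1], minor_depth = g$depth[2],
             total_depth = sum(g$depth),
             high_confidence = g$depth[2] >= min_minor,
             in_homopolymer = in_homo,
             multi_allelic = multi)
    }) |>
    list_rbind()
  if (is.null(sites) || nrow(sites) == 0) {
    return(tibble(seq_id = character(), pos = integer(), kind = character(),
                  major_allele = character(), minor_allele = character(),
                  major_depth = integer(), minor_depth = integer(),
                  total_depth = integer(), high_confidence = logical(),
                  in_homopolymer = logical(), multi_allelic = logical()))
  }
  arrange(sites, .data$seq_id, .data$pos)
}

# Is position `pos` of `context` inside/adjacent to a run of >= min_run
# identical bases?
.in_homopolymer <- function(context, pos, min_run) {
  cs <- chars(toupper(context))
  n <- length(cs)
  if (pos < 1 || pos > n) return(FALSE)
  for (anchor in unique(c(max(1, pos - 1), min(n, pos), min(n, pos + 1)))) {
    b <- cs[anchor]
    if (is.na(b) || b == "-") next
    lo <- anchor; hi <- anchor
    while (lo > 1 && cs[lo - 1] == b) lo <- lo - 1
    while (hi < n && cs[hi + 1] == b) hi <- hi + 1
    if (hi - lo + 1 >= min_run) return(TRUE)
  }
  FALSE
}

#' Classify substitutions against an annotated reference
#'
#' Walks a pairwise alignment of a sample consensus and its reference,
#' classifies each substitution column as a transition (A<->G, C<->T) or
#' transversion, and, for columns inside a CDS feature, assigns the codon
#' position from the feature's frame and strand.  Columns containing a gap
#' or an ambiguous base are excluded.
#'
#' @param sample_aln,ref_aln Aligned sequences of equal length (gaps `-`);
#'   ungapped `ref_aln` must be the reference the features annotate.
#' @param features Optional feature tibble; `CDS` rows drive codon-position
#'   assignment.
#' @return A tibble with one row per substitution: `ref_pos`, `ref_base`,
#'   `sample_base`, `class` (`"transition"`/`"transversion"`), `codon_pos`
#'   (1-3 inside a CDS, `NA` outside), `gene_name`.
#' @export
classify_substitutions <- function(sample_aln, ref_aln, features = NULL) {
  sc <- chars(toupper(sample_aln)); rc <- chars(toupper(ref_aln))
  if (length(sc) != length(rc)) {
    abort("sample and reference alignments must have equal length")
  }
  cds <- if (!is.null(features)) {
    features[features$feature_class == "CDS", ]
  } else NULL
  rp <- 0L
  rows <- list()
  purine <- c("A", "G")
  for (c in seq_along(rc)) {
    if (rc[c] != "-") rp <- rp + 1L
    if (rc[c] == "-" || sc[c] == "-") next
    if (!rc[c] %in% c("A", "C", "G", "T") ||
        !sc[c] %in% c("A", "C", "G", "T")) next
    if (rc[c] == sc[c]) next
    cls <- if ((rc[c] %in% purine) == (sc[c] %in% purine)) {
      "transition"
    } else "transversion"
    codon_pos <- NA_integer_; gene <- NA_character_
    if (!is.null(cds) && nrow(cds) > 0) {
      hit <- which(cds$start <= rp & rp <= cds$end)
      if (length(hit) > 0) {
        h <- hit[1]
        codon_pos <- if (cds$strand[h] == "+") {
          (rp - cds$start[h]) %% 3L + 1L
        } else {
          (cds$end[h] - rp) %% 3L + 1L
        }
        gene <- cds$gene_name[h]
      }
    }
    rows[[length(rows) + 1]] <- tibble(
      ref_pos = rp, ref_base = rc[c], sample_base = sc[c], class = cls,
      codon_pos = codon_pos, gene_name = gene)
  }
  if (length(rows) == 0) {
    return(tibble(ref_pos = integer(), ref_base = character(),
                  sample_base = character(), class = character(),
                  codon_pos = integer(), gene_name = character()))
  }
  list_rbind(rows)
}
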
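#' Ortholog tables
#'
#' An ortholog table is a long tibble with columns `gene`, `taxon`, `seq`
#' (amino-acid sequence); a gene/taxon pair with no row (or an `NA` sequence)
#' is missing data.  This is the input to hybrid-taxon construction, paralog
#' filtering, per-gene alignment and supermatrix concatenation.
#'
#' @param gene,taxon Character vectors.
#' @param seq Character vector of amino-acid sequences (`NA` = missing).
#' @return A tibble with columns `gene`, `taxon`, `seq`.
#' @export
ortholog_table <- function(gene, taxon, seq) {
  out <- tibble(gene = as.character(gene), taxon = as.character(taxon),
                seq = as.character(seq))
  if (anyDuplicated(out[, c("gene", "taxon")])) {
    abort("one sequence per gene/taxon pair")
  }
  out[!is.na(out$seq), ]
}

#' Align the orthologs of every gene
#'
#' Builds one multiple alignment per gene with the built-in anchored
#' aligner: the longest present sequence anchors, the others are
#' pairwise-aligned to it globally and projected into common coordinates
#' (insertions relative to the anchor become anchor-gap columns).
#' Single-sequence genes pass through unaligned; absent taxa stay absent
#' (they are gap-padded only at concatenation).
#'
#' @param table An [ortholog_table()].
#' @param matrix_name Amino-acid scoring matrix (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (default 11/1).
#' @return A tibble with columns `gene`, `taxon`, `aligned_seq`; within a
#'   gene all rows have equal length.
#' @export
assemble_gene_alignments <- function(table, matrix_name = "BLOSUM62",
                                     gap_open = 11, gap_extend = 1) {
  stopifnot(all(c("gene", "taxon", "seq") %in% names(table)))
  submat <- .aa_matrix(matrix_name)
  table |>
    group_by(.data$gene) |>
    group_map(function(g, key) {
      if (nrow(g) == 1) {
        return(tibble(gene = key$gene, taxon = g$taxon,
                      aligned_seq = g$seq))
      }
      anchor_i <- which.max(nchar(g$seq))
      anchor <- g$seq[anchor_i]
      others <- g[-anchor_i, ]
      proj <- .project_members(setNames(others$seq, others$taxon), anchor,
                               submat, gap_open, gap_extend, type = "global")
      anchor_row <- ifelse(proj$cols$ins == 0L,
                           chars(anchor)[proj$cols$ref_pos], "-")
      rows <- unname(apply(proj$mat, 1, function(v) {
        v[is.na(v)] <- "-"
        paste(v, collapse = "")
      }))
      tibble(gene = key$gene,
             taxon = c(g$taxon[anchor_i], others$taxon),
             aligned_seq = c(paste(anchor_row, collapse = ""), rows))
    }) |>
    list_rbind() |>
    arrange(.data$gene, .data$taxon)
}

#' Hybrid-taxon specification
#'
#' A hybrid (chimeric) taxon fills its row of the supermatrix gene by gene
#' from a priority-ordered group of closely related species, reducing
#' missing data: for each gene the whole-gene sequence of the
#' highest-priority member that has one is used (e.g. the finch sequence,
#' falling back to chicken only where the finch sequence is unavailable).
#'
#' @param group_name Identifier of the new hybrid taxon.
#' @param priority Character vector of member taxa, highest priority first.
#' @return A list with class `hybrid_spec`.
#' @export
hybrid_spec <- function(group_name, priority) {
  if (length(priority) == 0) abort("priority must name at least one taxon")
  structure(list(group_name = group_name, priority = priority),
            class = "hybrid_spec")
}

#' Replace taxon groups with hybrid taxa
#'
#' @param table An [ortholog_table()].
#' @param specs A list of [hybrid_spec()]s; member taxa must be disjoint
#'   across specs.
#' @return A list with `table` (the new ortholog table, member taxa removed,
#'   hybrids added) and `provenance` (tibble: `hybrid`, `gene`,
#'   `source_taxon`).
#' @export
make_hybrids <- function(table, specs) {
  if (inherits(specs, "hybrid_spec")) specs <- list(specs)
  members <- unlist(lapply(specs, `[[`, "priority"))
  if (anyDuplicated(members)) {
    abort("hybrid groups must not share member taxa")
  }
  missing_taxa <- setdiff(members, unique(table$taxon))
  if (length(missing_taxa) > 0) {
    abort(paste0("hybrid member taxa not in table: ",
                 paste(missing_taxa, collapse = ", ")))
  }
  genes <- unique(table$gene)
  prov <- list(); rows <- list()
  for (sp in specs) {
    sub <- table[table$taxon %in% sp$priority, ]
    for (g in genes) {
      gsub <- sub[sub$gene == g, ]
      src <- sp$priority[sp$priority %in% gsub$taxon]
      if (length(src) == 0) next  # hybrid cell missing
      src <- src[1]
      rows[[length(rows) + 1]] <- tibble(
        gene = g, taxon = sp$group_name,
        seq = gsub$seq[gsub$taxon == src])
      prov[[length(prov) + 1]] <- tibble(
        hybrid = sp$group_name, gene = g, source_taxon = src)
    }
  }
  out <- table[!table$taxon %in% members, ]
  if (length(rows) > 0) out <- bind_rows(out, list_rbind(rows))
  list(table = arrange(out, .data$gene, .data$taxon),
       provenance = if (length(prov) > 0) list_rbind(prov) else
         tibble(hybrid = character(), gene = character(),
                source_taxon = character()))
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in lexicographic gene-id order; a taxon absent
#' from a gene receives an all-gap block for that partition.  Partition
#' ranges (1-based inclusive) tile the matrix.
#'
#' @param alignments Tibble with `gene`, `taxon`, `aligned_seq` (from
#'   [assemble_gene_alignments()]).
#' @param taxa Full taxon set for the matrix rows; defaults to all taxa seen.
#' @param provenance Optional hybrid provenance tibble to carry along.
#' @return A `supermatrix` object: list with `seqs` (named character vector,
#'   equal lengths), `partitions` (tibble: `gene`, `start`, `end`),
#'   `provenance`.
#' @export
concatenate_genes <- function(alignments, taxa = NULL, provenance = NULL) {
  stopifnot(all(c("gene", "taxon", "aligned_seq") %in% names(alignments)))
  if (nrow(alignments) == 0) abort("no gene alignments to concatenate")
  taxa <- taxa %||% sort(unique(alignments$taxon))
  genes <- sort(unique(alignments$gene))
  blocks <- matrix("", nrow = length(taxa), ncol = length(genes),
                   dimnames = list(taxa, genes))
  lens <- integer(length(genes))
  for (gi in seq_along(genes)) {
    g <- alignments[alignments$gene == genes[gi], ]
    L <- unique(nchar(g$aligned_seq))
    if (length(L) != 1) {
      abort(paste0("unequal aligned lengths within gene ", genes[gi]))
    }
    lens[gi] <- L
    blocks[, gi] <- strrep("-", L)
    blocks[g$taxon, gi] <- g$aligned_seq
  }
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1) + 1L)
  seqs <- apply(blocks, 1, paste, collapse = "")
  structure(list(seqs = seqs,
                 partitions = tibble(gene = genes, start = as.integer(starts),
                                     end = as.integer(ends)),
                 provenance = provenance),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$seqs), " taxa x ",
      nchar(x$seqs[1]), " columns, ", nrow(x$partitions), " partitions\n",
      sep = "")
  invisible(x)
}

# per-column gap score: fraction of non-gap residues (trimAl orientation)
.gap_scores <- function(m) {
  rows <- do.call(rbind, strsplit(unname(m$seqs), "", fixed = TRUE))
  colMeans(rows != "-")
}

#' Trim gapped columns from a supermatrix
#'
#' Two trimming modes: `remove_all_gapped` deletes every column containing
#' at least one gap; `max_drop` computes the per-column gap score (fraction
#' of non-gap residues), sorts the distinct scores in descending order,
#' finds the largest drop between consecutive scores, and deletes the
#' columns scoring strictly below the drop (ties in drop location resolve
#' toward retaining more columns).  Partitions are remapped; genes losing
#' every column are dropped from the partition table.
#'
#' @param m A `supermatrix`.
#' @param mode `"remove_all_gapped"` or `"max_drop"`.
#' @return The trimmed `supermatrix`, with attribute fields `trim_mode` and
#'   (for `max_drop`) `trim_threshold` recorded in the object.
#' @export
trim_columns <- function(m, mode = c("remove_all_gapped", "max_drop")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "supermatrix"))
  scores <- .gap_scores(m)
  threshold <- NA_real_
  if (mode == "remove_all_gapped") {
    keep <- scores == 1
  } else {
    d <- sort(unique(scores), decreasing = TRUE)
    if (length(d) == 1) {
      keep <- rep(TRUE, length(scores))
    } else {
      drops <- d[-length(d)] - d[-1]
      i_star <- max(which(drops == max(drops)))  # retain more columns on ties
      threshold <- d[i_star]
      keep <- scores >= threshold
    }
  }
  if (!any(keep)) abort("trimming removed every column")
  rows <- do.call(rbind, strsplit(unname(m$seqs), "", fixed = TRUE))
  new_seqs <- setNames(apply(rows[, keep, drop = FALSE], 1, paste,
                             collapse = ""), names(m$seqs))
  kept_per_gene <- map_int(seq_len(nrow(m$partitions)), function(i) {
    sum(keep[m$partitions$start[i]:m$partitions$end[i]])
  })
  parts <- m$partitions[kept_per_gene > 0, ]
  lens <- kept_per_gene[kept_per_gene > 0]
  ends <- cumsum(lens)
  parts$start <- as.integer(c(1L, head(ends, -1) + 1L))
  parts$end <- as.integer(ends)
  out <- structure(list(seqs = new_seqs, partitions = parts,
                        provenance = m$provenance),
                   class = "supermatrix")
  out$trim_mode <- mode
  out$trim_threshold <- threshold
  out
}

#' Keep only genes without known paralogs
#'
#' @param table An [ortholog_table()].
#' @param paralogs Tibble with columns `gene`, `taxon`, `has_paralog`
#'   (logical) covering every gene of `table` for every reference taxon.
#' @param reference_taxa Taxa whose paralog annotation is consulted;
#'   defaults to all taxa in `paralogs`.
#' @return The filtered ortholog table (possibly empty, with a warning).
#' @export
filter_paralog_free <- function(table, paralogs, reference_taxa = NULL) {
  stopifnot(all(c("gene", "taxon", "has_paralog") %in% names(paralogs)))
  reference_taxa <- reference_taxa %||% unique(paralogs$taxon)
  p <- paralogs[paralogs$taxon %in% reference_taxa, ]
  genes <- unique(table$gene)
  cover <- table(p$gene)[genes]
  if (anyNA(cover) || any(cover < length(reference_taxa))) {
    miss <- genes[is.na(cover) | cover < length(reference_taxa)]
    abort(paste0("paralog table does not cover gene(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  bad <- unique(p$gene[p$has_paralog])
  out <- table[!table$gene %in% bad, ]
  if (nrow(out) == 0) warn("no paralog-free genes remain")
  out
}

#' Export a supermatrix as relaxed PHYLIP with a partition file
#'
#' Relaxed PHYLIP: a `<n_taxa> <n_columns>` header, then one
#' `<full name><single space><row>` line per taxon.  The partition file
#' (written alongside unless `partitions_path = NA`) has one
#' `<gene> = <start>-<end>` line per gene, 1-based inclusive.
#'
#' @param m A `supermatrix`.
#' @param path Output path.
#' @param partitions_path Partition file path (default `<path>.partitions`;
#'   `NA` skips it).
#' @param missing_char Optionally remap `-` to another character (e.g. `?`).
#' @return `path`, invisibly.
#' @export
write_phylip <- function(m, path, partitions_path = paste0(path, ".partitions"),
                         missing_char = "-") {
  stopifnot(inherits(m, "supermatrix"))
  lens <- nchar(m$seqs)
  if (length(unique(lens)) != 1) {
    abort("all taxa must have the same aligned length")
  }
  seqs <- m$seqs
  if (missing_char != "-") {
    seqs <- gsub("-", missing_char, seqs, fixed = TRUE)
  }
  lines <- c(paste(length(seqs), lens[1]),
             paste(names(seqs), unname(seqs)))
  writeLines(lines, path)
  if (!is.na(partitions_path)) {
    writeLines(sprintf("%s = %d-%d", m$partitions$gene, m$partitions$start,
                       m$partitions$end), partitions_path)
  }
  invisible(path)
}

#' Read back a relaxed PHYLIP alignment
#'
#' @param path Path to a relaxed PHYLIP file written by [write_phylip()].
#' @return A sequence table ([seq_tbl()]).
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(lines[-1])]
  parts <- strsplit(body, " ", fixed = TRUE)
  out <- seq_tbl(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
  if (nrow(out) != header[1] || any(nchar(out$seq) != header[2])) {
    abort("PHYLIP body does not match its header")
  }
  out
}
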
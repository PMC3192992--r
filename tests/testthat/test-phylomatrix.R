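rand_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

test_that("gene alignments pass single sequences through and align the rest", {
  set.seed(60)
  base <- rand_aa(60)
  tb <- ortholog_table(
    gene = c("g1", "g1", "g1", "g2"),
    taxon = c("ta", "tb", "tc", "ta"),
    seq = c(base, base, base, rand_aa(25)))
  aln <- assemble_gene_alignments(tb)
  g1 <- aln[aln$gene == "g1", ]
  expect_equal(unique(nchar(g1$aligned_seq)), 60L)
  expect_false(any(grepl("-", g1$aligned_seq, fixed = TRUE)))
  expect_equal(nrow(aln[aln$gene == "g2", ]), 1L)
})

test_that("anchored alignment places an internal deletion as a gap", {
  set.seed(61)
  full <- rand_aa(50)
  short <- paste0(substr(full, 1, 20), substr(full, 31, 50))
  tb <- ortholog_table(c("g", "g"), c("long", "short"), c(full, short))
  aln <- assemble_gene_alignments(tb)
  srow <- aln$aligned_seq[aln$taxon == "short"]
  expect_equal(nchar(srow), 50L)
  expect_equal(sum(strsplit(srow, "")[[1]] == "-"), 10L)
})

test_that("hybrid cells follow priority and fall back to lower-priority members", {
  tb <- ortholog_table(
    gene = c("g1", "g1", "g2", "g3"),
    taxon = c("finch", "chicken", "chicken", "lizard"),
    seq = c("MFINCH", "MCHICK", "MCHICK2", "MLIZ"))
  hy <- make_hybrids(tb, hybrid_spec("birds", c("finch", "chicken")))
  btab <- hy$table[hy$table$taxon == "birds", ]
  expect_equal(btab$seq[btab$gene == "g1"], "MFINCH")
  expect_equal(btab$seq[btab$gene == "g2"], "MCHICK2")
  expect_false("g3" %in% btab$gene)  # missing in all members
  expect_false(any(c("finch", "chicken") %in% hy$table$taxon))
  # provenance names the taxon whose cell was copied, byte for byte
  for (i in seq_len(nrow(hy$provenance))) {
    pr <- hy$provenance[i, ]
    orig <- tb$seq[tb$gene == pr$gene & tb$taxon == pr$source_taxon]
    expect_equal(btab$seq[btab$gene == pr$gene], orig)
  }
  expect_error(
    make_hybrids(tb, list(hybrid_spec("h1", "finch"),
                          hybrid_spec("h2", c("finch", "lizard")))),
    "share")
})

test_that("concatenation gap-pads missing taxa and tiles partitions", {
  aln <- tibble::tibble(
    gene = c("g2", "g2", "g1", "g1", "g1"),
    taxon = c("ta", "tb", "ta", "tb", "tc"),
    aligned_seq = c("PQRST", "PQRSV", "MKL", "MKV", "MKI"))
  sm <- concatenate_genes(aln)
  # lexicographic gene order: g1 then g2
  expect_equal(sm$partitions$gene, c("g1", "g2"))
  expect_equal(sm$partitions$start, c(1L, 4L))
  expect_equal(sm$partitions$end, c(3L, 8L))
  expect_equal(unname(sm$seqs["tc"]), "MKI-----")
  expect_equal(unique(nchar(sm$seqs)), 8L)
  expect_error(concatenate_genes(aln[0, ]), "no gene alignments")
  ragged <- aln
  ragged$aligned_seq[1] <- "PQ"
  expect_error(concatenate_genes(ragged), "unequal")
})

test_that("remove_all_gapped leaves no gaps; gap-free matrices are unchanged", {
  aln <- tibble::tibble(gene = rep("g", 3), taxon = c("a", "b", "c"),
                        aligned_seq = c("MKLVP", "MK-VP", "MKLVP"))
  sm <- concatenate_genes(aln)
  tr <- trim_columns(sm, "remove_all_gapped")
  expect_false(any(grepl("-", tr$seqs, fixed = TRUE)))
  expect_equal(unique(nchar(tr$seqs)), 4L)

  clean <- concatenate_genes(tibble::tibble(
    gene = "g", taxon = c("a", "b"), aligned_seq = c("MKL", "MKV")))
  expect_equal(trim_columns(clean, "remove_all_gapped")$seqs, clean$seqs)
  expect_equal(trim_columns(clean, "max_drop")$seqs, clean$seqs)
})

test_that("max_drop cuts at the largest step of the sorted gap-score curve", {
  # 10 taxa; columns engineered to gap scores {1.0 x10, 0.9 x5, 0.2 x5}
  rows <- vapply(1:10, function(i) {
    paste(c(rep("A", 10),
            ifelse(rep(i, 5) == 1, "-", "C"),
            ifelse(rep(i, 5) <= 8, "-", "G")), collapse = "")
  }, character(1))
  sm <- concatenate_genes(tibble::tibble(gene = "g", taxon = paste0("t", 1:10),
                                         aligned_seq = rows))
  tr <- trim_columns(sm, "max_drop")
  expect_equal(unique(nchar(tr$seqs)), 15L)
  expect_equal(tr$trim_threshold, 0.9)
  # partitions remain a tiling of the trimmed matrix
  expect_equal(tr$partitions$start[1], 1L)
  expect_equal(tr$partitions$end[nrow(tr$partitions)], 15L)
})

test_that("trimming preserves column order and partition tiling", {
  set.seed(62)
  genes <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 3),
    taxon = rep(c("a", "b", "c"), 2),
    aligned_seq = c("MK-LV", "MKALV", "MKALV", "QR-", "QR-", "QRS"))
  sm <- concatenate_genes(genes)
  tr <- trim_columns(sm, "remove_all_gapped")
  # surviving columns keep their relative order
  expect_equal(unname(tr$seqs["b"]), "MKLVQR")
  parts <- tr$partitions
  expect_equal(parts$start[1], 1L)
  for (i in seq_len(nrow(parts) - 1)) {
    expect_equal(parts$start[i + 1], parts$end[i] + 1L)
  }
})

test_that("paralog filtering needs full coverage and drops flagged genes", {
  tb <- ortholog_table(c("g1", "g2"), c("x", "x"), c("MK", "ML"))
  par_tbl <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 2),
    taxon = rep(c("hs", "mm"), 2),
    has_paralog = c(FALSE, FALSE, TRUE, FALSE))
  out <- filter_paralog_free(tb, par_tbl, c("hs", "mm"))
  expect_equal(unique(out$gene), "g1")
  expect_error(filter_paralog_free(tb, par_tbl[par_tbl$gene == "g1", ],
                                   c("hs", "mm")),
               "does not cover")
  all_par <- par_tbl; all_par$has_paralog <- TRUE
  expect_warning(filter_paralog_free(tb, all_par, c("hs", "mm")),
                 "no paralog-free")
})

test_that("supermatrix tidiers report partitions and gap content", {
  aln <- tibble::tibble(gene = c("g1", "g1", "g2", "g2"),
                        taxon = c("a", "b", "a", "b"),
                        aligned_seq = c("MK", "M-", "LPQ", "LPQ"))
  sm <- concatenate_genes(aln)
  td <- tidy(sm)
  expect_equal(td$width, c(2L, 3L))
  g <- glance(sm)
  expect_equal(g$n_taxa, 2L)
  expect_equal(g$n_columns, 5L)
  expect_equal(g$n_complete_columns, 4L)
  expect_s3_class(autoplot(sm), "ggplot")
})
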
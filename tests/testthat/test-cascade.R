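mk_hit <- function(query_id = "q", subject_id = "s", e_value = 1e-10,
                   align_length = 100L, pct_identity = 90) {
  tibble::tibble(query_id = query_id, subject_id = subject_id,
                 e_value = e_value, align_length = align_length,
                 pct_identity = pct_identity)
}

test_that("best-hit selection applies e-value, length, identity, then input order", {
  h <- dplyr::bind_rows(
    mk_hit(subject_id = "weak", e_value = 1e-5),
    mk_hit(subject_id = "strong", e_value = 1e-20))
  expect_equal(select_best_hit(h)$subject_id, "strong")

  h2 <- dplyr::bind_rows(
    mk_hit(subject_id = "short", align_length = 80L),
    mk_hit(subject_id = "long", align_length = 100L))
  expect_equal(select_best_hit(h2)$subject_id, "long")

  h3 <- dplyr::bind_rows(
    mk_hit(subject_id = "lo", pct_identity = 85),
    mk_hit(subject_id = "hi", pct_identity = 95))
  expect_equal(select_best_hit(h3)$subject_id, "hi")

  h4 <- dplyr::bind_rows(mk_hit(subject_id = "first"),
                         mk_hit(subject_id = "second"))
  expect_equal(select_best_hit(h4)$subject_id, "first")

  expect_error(select_best_hit(h4[0, ]), "at least one hit")
})

test_that("a query hitting both mtDNA and coding is assigned at the mtDNA round", {
  mt <- sim_mt_genome(30)
  # the coding database contains a copy of a mitochondrial CDS
  cds_feat <- mt$features[mt$features$feature_class == "CDS", ][1, ]
  cds_seq <- substr(mt$genome$seq, cds_feat$start, cds_feat$end)
  coding <- seq_tbl(c("nuclear1", "mt_copy"),
                    c(txcascade:::.random_cds(600), cds_seq))
  frag <- seq_tbl("fr", substr(cds_seq, 10, 250))
  res <- run_cascade(frag, cascade_rounds(mt_db = mt$genome,
                                          coding_db = coding))
  expect_equal(res$assignments$round, "mtDNA")
  expect_equal(nrow(res$orphans), 0L)
})

test_that("unassignable queries come out as orphans and the partition holds", {
  set.seed(31)
  db <- seq_tbl("d1", random_dna(600))
  qs <- seq_tbl(c("hit", "miss"),
                c(substr(db$seq, 50, 300), strrep("ACGT", 60)))
  res <- run_cascade(qs, cascade_rounds(unigene_db = db))
  expect_equal(res$assignments$query_id, "hit")
  expect_equal(res$orphans$id, "miss")
  expect_setequal(c(res$assignments$query_id, res$orphans$id), qs$id)
  expect_length(intersect(res$assignments$query_id, res$orphans$id), 0)
})

test_that("rounds must be unique and in cascade order", {
  db <- seq_tbl("d", strrep("ACGTTGCA", 50))
  r_coding <- cascade_round("coding", db)
  r_mt <- cascade_round("mtDNA", db)
  expect_error(run_cascade(seq_tbl("q", "ACGT"), list(r_coding, r_mt)),
               "cascade order")
  expect_error(run_cascade(seq_tbl("q", "ACGT"), list(r_mt, r_mt)), "unique")
  expect_error(cascade_round("bogus", db), "round name")
})

test_that("cross-species round searches only the other species' consensuses", {
  set.seed(32)
  consA <- random_dna(500)
  orphA <- substr(consA, 30, 280)  # identical to species A's own consensus
  consB <- random_dna(500)
  orphB2 <- substr(consA, 100, 350)  # species B orphan matching species A
  res <- cross_species_round(
    orphans_by_species = list(A = seq_tbl("oa", orphA),
                              B = seq_tbl("ob", orphB2)),
    consensus_by_species = list(A = seq_tbl("consA", consA),
                                B = seq_tbl("consB", consB)))
  # A's orphan must not match A's own consensus
  expect_false("oa" %in% res$query_id)
  expect_true("ob" %in% res$query_id)
  expect_equal(res$reference_species[res$query_id == "ob"], "A")
})

test_that("longest-ORF finding respects the length gate and tie rules", {
  set.seed(33)
  # 1,200 bp with one long ORF
  orf <- txcascade:::.random_cds(903)   # 300 codons incl start/stop
  filler <- strrep("C", 150)
  seqlong <- paste0(filler, orf, strrep("C", 150))
  res <- find_longest_orf(seqlong, 1000L)
  expect_equal(res$aa_length, 300L)
  expect_equal(res$nt_start, 151L)
  expect_equal(translate_frame(substr(seqlong, res$nt_start, res$nt_end),
                               1L),
               paste0(res$peptide, "*"))

  # below the gate: nothing, regardless of content
  expect_null(find_longest_orf(substr(seqlong, 1, 900), 1000L))

  # two ORFs: the longest peptide over all frames wins (checked against an
  # independent codon-walk enumeration; incidental ORFs spanning the random
  # filler in other frames count too)
  orf_oracle <- function(s) {
    best <- 0L
    for (f in c(1:3, -(1:3))) {
      x <- if (f < 0) revcomp(s) else s
      off <- abs(f)
      cods <- substring(x, seq(off, nchar(x) - 2, by = 3),
                        seq(off + 2, nchar(x), by = 3))
      aa_open <- NA_integer_
      for (ci in seq_along(cods)) {
        if (is.na(aa_open) && cods[ci] == "ATG") aa_open <- ci
        if (!is.na(aa_open) && cods[ci] %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, ci - aa_open)
          aa_open <- NA_integer_
        }
      }
    }
    best
  }
  a <- txcascade:::.random_cds(153)   # 50 codons
  b <- txcascade:::.random_cds(243)   # 80 codons
  s2 <- paste0(strrep("C", 400), a, strrep("C", 200), b, strrep("C", 300))
  got <- find_longest_orf(s2, 1000L)
  expect_gte(got$aa_length, 80L)
  expect_equal(got$aa_length, orf_oracle(s2))
})

test_that("cascade tidiers summarise assignments", {
  set.seed(34)
  db <- seq_tbl("d1", random_dna(500))
  qs <- seq_tbl(c("a", "b"), c(substr(db$seq, 10, 260), strrep("GCAT", 50)))
  res <- run_cascade(qs, cascade_rounds(unigene_db = db))
  g <- glance(res)
  expect_equal(g$n_input, 2L)
  expect_equal(g$n_assigned, 1L)
  expect_equal(g$assignment_rate, 0.5)
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
})
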
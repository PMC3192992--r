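test_that("a single member passes through verbatim, named after the reference", {
  set.seed(40)
  ref <- seq_tbl("ENSREF1", random_dna(300))
  m <- seq_tbl("contig7", random_dna(120))
  cr <- build_consensus(m, ref)
  expect_true(cr$is_one_to_one)
  expect_equal(cr$aligned_seq, m$seq)
  expect_equal(cr$name, "ENSREF1")
})

test_that("majority voting calls the most frequent base; ties become IUPAC codes", {
  set.seed(41)
  ref <- random_dna(200)
  m <- substr(ref, 1, 200)
  # three members, one disagreeing at position 100
  m_var <- m
  substr(m_var, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                     substr(m, 100, 100))[1]
  cr <- build_consensus(seq_tbl(c("a", "b", "c"), c(m, m, m_var)),
                        seq_tbl("R", ref))
  expect_equal(cr$aligned_seq, m)

  # two members, 1-1 tie at a column -> ambiguity code
  m_a <- m; substr(m_a, 50, 50) <- "A"
  m_g <- m; substr(m_g, 50, 50) <- "G"
  cr2 <- build_consensus(seq_tbl(c("a", "b"), c(m_a, m_g)), seq_tbl("R", ref))
  expect_equal(substr(cr2$aligned_seq, 50, 50), "R")  # A/G
})

test_that("uncovered reference positions become gaps with correct region stats", {
  set.seed(42)
  ref <- random_dna(150)
  m1 <- substr(ref, 1, 50); m2 <- substr(ref, 101, 150)
  cr <- build_consensus(seq_tbl(c("m1", "m2"), c(m1, m2)), seq_tbl("R", ref))
  expect_equal(nchar(cr$aligned_seq), 150L)
  expect_equal(substr(cr$aligned_seq, 1, 50), m1)
  expect_equal(substr(cr$aligned_seq, 51, 100), strrep("-", 50))
  expect_equal(substr(cr$aligned_seq, 101, 150), m2)
  # regions 45/60/45: all 50 gap columns sit inside the middle region
  expect_equal(unname(cr$gap_pct), c(0, 100 * 50 / 60, 0), tolerance = 1e-9)
})

test_that("the reference anchors but never votes", {
  set.seed(43)
  ref <- random_dna(120)
  m <- substr(ref, 11, 110)
  members <- seq_tbl(c("a", "b"), c(m, m))
  cr1 <- build_consensus(members, seq_tbl("R", ref))
  # mutate reference residues (same length): member-covered consensus is unchanged
  ref2 <- ref
  for (p in c(30, 60, 90)) {
    substr(ref2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(ref2, p, p))[1]
  }
  cr2 <- build_consensus(members, seq_tbl("R", ref2))
  covered1 <- gsub("-", "", cr1$aligned_seq, fixed = TRUE)
  covered2 <- gsub("-", "", cr2$aligned_seq, fixed = TRUE)
  expect_equal(covered1, covered2)
})

test_that("members are auto-oriented before voting", {
  set.seed(44)
  ref <- random_dna(200)
  m1 <- substr(ref, 1, 120)
  m2 <- revcomp(substr(ref, 81, 200))
  cr <- build_consensus(seq_tbl(c("f", "r"), c(m1, m2)), seq_tbl("R", ref))
  expect_equal(cr$aligned_seq, ref)
  expect_equal(cr$members$orientation, c("forward", "reverse_complement"))
})

test_that("gap_stats splits columns by rounded cumulative fractions", {
  expect_equal(unname(gap_stats(paste0("---", "ACGTACG"))), c(100, 0, 0))
  expect_equal(unname(gap_stats(strrep("-", 10))), c(100, 100, 100))
  expect_equal(unname(gap_stats(strrep("A", 10))), c(0, 0, 0))
  # region column counts always sum to the alignment length
  set.seed(45)
  for (L in c(7, 10, 33, 100)) {
    s <- paste(sample(c("A", "-"), L, replace = TRUE), collapse = "")
    cs <- strsplit(s, "")[[1]]
    b <- floor(L * cumsum(c(0.3, 0.4, 0.3)) + 0.5); b[3] <- L
    manual <- c(100 * mean(cs[1:b[1]] == "-"),
                100 * mean(cs[(b[1] + 1):b[2]] == "-"),
                100 * mean(cs[(b[2] + 1):L] == "-"))
    expect_equal(unname(gap_stats(s)), manual)
  }
  expect_error(gap_stats("ACGT", fractions = c(0.5, 0.2)), "sum to 1")
})

test_that("back-translation expands residues to codons and gaps to ---", {
  expect_equal(back_translate("M-K", "ATGAAA", 1L), "ATG---AAA")
  # frame 2: the leading offset base stays outside the aligned block
  src <- paste0("G", "ATGAAATTTGGG")
  aa <- translate_frame(src, 2L)
  bt <- back_translate(aa, src, 2L)
  expect_equal(bt, "ATGAAATTTGGG")
  expect_equal(translate_frame(bt, 1L), aa)
  # integrity check: a row that is not the frame translation errors
  expect_error(back_translate("MKL", "ATGAAA", 1L), "not the frame")
})

test_that("protein-mode consensus recovers the coding sequence via codons", {
  set.seed(46)
  cds <- txcascade:::.random_cds(600)
  m1 <- substr(cds, 1, 360)
  m2 <- substr(cds, 241, 600)
  cr <- build_consensus(seq_tbl(c("m1", "m2"), c(m1, m2)),
                        seq_tbl("ref", cds), mode = "protein_frame",
                        frames = c(m1 = 1L, m2 = 1L))
  recovered <- gsub("-", "", cr$aligned_seq, fixed = TRUE)
  # the stop codon is never part of a translated alignment
  expect_equal(recovered, substr(cds, 1, nchar(cds) - 3))
  expect_error(build_consensus(seq_tbl(c("m1", "m2"), c(m1, m2)),
                               seq_tbl("ref", cds), mode = "protein_frame"),
               "frame")
})

test_that("reference-guided assembly recovers the genome and reports coverage", {
  mt <- sim_mt_genome(47)
  L <- nchar(mt$genome$seq)
  starts <- unique(c(seq(1, L - 199, by = 100), L - 199))
  tiles <- vapply(starts, function(s) substr(mt$genome$seq, s, s + 199), "")
  asm <- reference_guided_assembly(
    seq_tbl(paste0("t", seq_along(tiles)), tiles), mt$genome,
    features = mt$features)
  expect_equal(asm$consensus, mt$genome$seq)
  expect_true(all(asm$coverage$covered_frac == 1))
  expect_false(any(asm$coverage$missing))

  # a feature with no overlapping member is reported missing
  few <- seq_tbl("t1", substr(mt$genome$seq, 1, 400))
  asm2 <- reference_guided_assembly(few, mt$genome, features = mt$features)
  expect_true(any(asm2$coverage$missing))
  expect_true(all(asm2$coverage$covered_frac[asm2$coverage$missing] == 0))
})

test_that("a planted heterozygous column surfaces in the pileup at full depth", {
  mt <- sim_mt_genome(48)
  pv <- plant_variants(mt$genome$seq,
                       tibble::tibble(pos = c(700L, 700L),
                                      allele = c("A", "G"),
                                      depth = c(3L, 3L)))
  asm <- reference_guided_assembly(pv$reads, mt$genome)
  col <- asm$pileup[asm$pileup$pos == 700, ]
  expect_setequal(col$allele, c("A", "G"))
  expect_equal(sort(col$depth), c(3L, 3L))
})

test_that("consensus tidiers expose members and gap regions", {
  set.seed(49)
  ref <- seq_tbl("R", random_dna(200))
  m <- seq_tbl(c("a", "b"), c(substr(ref$seq, 1, 120), substr(ref$seq, 81, 200)))
  cr <- build_consensus(m, ref)
  expect_equal(nrow(tidy(cr)), 2L)
  g <- glance(cr)
  expect_equal(g$n_members, 2L)
  expect_false(g$is_one_to_one)
  expect_s3_class(autoplot(cr), "ggplot")
})
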
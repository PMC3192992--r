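test_that("perfect SSRs at and below thresholds are reported exactly", {
  set.seed(50)
  flank1 <- random_dna(40); flank2 <- random_dna(40)
  s <- paste0(flank1, strrep("AC", 12), flank2)
  loci <- find_ssrs(s)
  # flanks may or may not contribute; the planted locus must be exact
  planted <- loci[loci$motif == "AC", ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$n_repeats, 12L)
  expect_equal(planted$start, 41L)
  expect_equal(planted$end, 40L + 24L)

  expect_equal(nrow(find_ssrs(paste0(flank1, strrep("A", 8), flank2))), 0L)
  expect_equal(nrow(find_ssrs(paste0(flank1, strrep("AC", 4), flank2))), 0L)
  # at threshold: (A)10 and (AC)5 count
  expect_equal(find_ssrs(paste0(flank1, strrep("A", 10), flank2))$n_repeats, 10L)
  expect_equal(find_ssrs(paste0(flank1, strrep("GATC", 5), flank2))$motif, "GATC")
})

test_that("the strict 'more than' reading is selectable", {
  set.seed(51)
  f <- random_dna(30)
  s <- paste0(f, strrep("A", 10), f)
  expect_equal(nrow(find_ssrs(s, ssr_thresholds(strict = TRUE))), 0L)
  s11 <- paste0(f, strrep("A", 11), f)
  expect_equal(find_ssrs(s11, ssr_thresholds(strict = TRUE))$n_repeats, 11L)
})

test_that("a repeat of a periodic unit reports under the shortest unit", {
  set.seed(52)
  s <- paste0(random_dna(30), strrep("AT", 14), random_dna(30))
  loci <- find_ssrs(s)
  expect_equal(loci$motif, "AT")
  expect_equal(loci$n_repeats, 14L)
})

test_that("compound merging uses the strict 50 bp spacer boundary", {
  mk <- function(spacer) {
    paste0(SSR_FREE_FLANK_COMPOUND, strrep("AG", 6), spacer, strrep("CT", 7),
           SSR_FREE_FLANK_COMPOUND)
  }
  merged <- find_ssrs(mk(SSR_FREE_SPACER49))
  expect_equal(merged$kind, "compound")
  expect_equal(nrow(merged$components[[1]]), 2L)
  expect_equal(merged$n_repeats, 13L)
  expect_equal(merged$start, 61L)

  apart <- find_ssrs(mk(SSR_FREE_SPACER50))
  expect_equal(apart$kind, c("perfect", "perfect"))
  expect_equal(apart$motif, c("AG", "CT"))
  expect_equal(apart$start, c(61L, 61L + 12L + 50L))
})

test_that("canonical motifs are invariant under rotation and reverse complement", {
  expect_equal(canonical_motif(c("GT", "TG", "CA", "AC")),
               rep("AC", 4))
  expect_equal(canonical_motif("ATT"), "AAT")
  expect_equal(canonical_motif("CCT"), "AGG")
  expect_equal(canonical_motif("A"), "A")
  set.seed(53)
  for (i in 1:25) {
    k <- sample(1:6, 1)
    m <- random_dna(k)
    can <- canonical_motif(m)
    rot <- paste0(substr(m, k, k), substr(m, 1, k - 1))
    expect_equal(canonical_motif(rot), can)
    expect_equal(canonical_motif(revcomp(m)), can)
    expect_equal(canonical_motif(can), can)
  }
})

test_that("the minor-allele depth rule separates high-confidence calls", {
  pile <- tibble::tibble(
    pos = c(10L, 10L, 20L, 20L, 30L, 30L),
    allele = c("A", "G", "A", "G", "A", "-"),
    depth = c(3L, 3L, 10L, 2L, 4L, 3L))
  v <- call_variants(pile, min_minor = 3L, context = strrep("C", 50))
  expect_equal(v$kind, c("snp", "snp", "indel"))
  expect_equal(v$high_confidence, c(TRUE, FALSE, TRUE))
  expect_equal(v$minor_depth, c(3L, 2L, 3L))
  expect_error(call_variants(pile[0, ]), "non-empty")
})

test_that("indels in homopolymer context are flagged; snps are not", {
  ctx <- paste0(strrep("G", 10), "AAAA", strrep("C", 10))  # A-run at 11-14
  pile <- tibble::tibble(pos = c(12L, 12L, 20L, 20L),
                         allele = c("-", "A", "C", "T"),
                         depth = c(3L, 4L, 5L, 3L))
  v <- call_variants(pile, context = ctx)
  ind <- v[v$kind == "indel", ]
  expect_true(ind$in_homopolymer)
  expect_true(ind$high_confidence)
  expect_false(v$in_homopolymer[v$kind == "snp"])
})

test_that("minor-allele ties are kept in depth-then-alphabet order and flagged", {
  pile <- tibble::tibble(pos = rep(5L, 3), allele = c("T", "A", "G"),
                         depth = c(3L, 3L, 3L))
  v <- call_variants(pile)
  expect_equal(v$major_allele, "A")
  expect_equal(v$minor_allele, "G")
  expect_true(v$multi_allelic)
})

test_that("substitution classification separates ts/tv and codon positions", {
  feats <- tibble::tibble(seq_id = "r", gene_name = c("cds1", "cds2"),
                          start = c(10L, 40L), end = c(21L, 51L),
                          strand = c("+", "-"), feature_class = "CDS")
  ref <- strrep("ACGT", 15)   # 60 bp
  smp <- ref
  substr(smp, 13, 13) <- "G"  # ref A -> G : transition, + strand pos (13-10)%%3+1 = 1
  substr(smp, 15, 15) <- "A"  # ref G -> A : transition, pos 3
  substr(smp, 30, 30) <- "T"  # ref C -> T : transition, outside any CDS
  substr(smp, 45, 45) <- "T"  # ref A -> T : transversion, - strand pos (51-45)%%3+1 = 1
  res <- classify_substitutions(smp, ref, feats)
  expect_equal(nrow(res), 4L)
  expect_equal(sum(res$class == "transition"), 3L)
  expect_equal(sum(res$class == "transversion"), 1L)
  expect_equal(res$codon_pos[res$ref_pos == 13], 1L)
  expect_equal(res$codon_pos[res$ref_pos == 15], 3L)
  expect_true(is.na(res$codon_pos[res$ref_pos == 30]))
  expect_equal(res$codon_pos[res$ref_pos == 45], 1L)

  # gap columns are excluded from both counts
  smp_gap <- paste0(substr(smp, 1, 20), "-", substr(smp, 22, 60))
  res2 <- classify_substitutions(smp_gap, ref, feats)
  expect_false(21 %in% res2$ref_pos)
})

test_that("ts + tv equals the substitution column count on random pairs", {
  set.seed(54)
  ref <- random_dna(300)
  smp <- txcascade:::.add_errors(ref, 0.05)
  res <- classify_substitutions(smp, ref, NULL)
  manual <- sum(strsplit(ref, "")[[1]] != strsplit(smp, "")[[1]])
  expect_equal(nrow(res), manual)
  expect_equal(sum(res$class %in% c("transition", "transversion")), manual)
})
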
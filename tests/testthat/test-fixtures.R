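test_that("a fixed seed reproduces the corpus byte for byte", {
  cfg <- sim_config(seed = 70, n_genes = 5, depth = 3)
  a <- sim_reference_set(cfg); b <- sim_reference_set(cfg)
  expect_identical(a, b)
  fa <- sim_fragment_reads(a$truth, cfg); fb <- sim_fragment_reads(b$truth, cfg)
  expect_identical(fa, fb)
  expect_identical(sim_mt_genome(70), sim_mt_genome(70))
  # different seed, different corpus
  expect_false(identical(a$truth$seq,
                         sim_reference_set(sim_config(seed = 71,
                                                      n_genes = 5))$truth$seq))
})

test_that("zero divergence copies the truth; 5% divergence concentrates near 5%", {
  cfg0 <- sim_config(seed = 72, n_genes = 5, divergence = 0)
  rs0 <- sim_reference_set(cfg0)
  expect_equal(rs0$reference$seq, unname(rs0$truth$seq))

  cfg5 <- sim_config(seed = 73, n_genes = 100, gene_len = c(999, 1002),
                     divergence = 0.05)
  rs5 <- sim_reference_set(cfg5)
  expect_equal(mean(rs5$orthologs$observed_divergence), 0.05, tolerance = 0.04)
  expect_true(all(abs(rs5$orthologs$observed_divergence - 0.05) < 0.02 + 0.02))
})

test_that("diverged references stay free of in-frame stop codons", {
  cfg <- sim_config(seed = 74, n_genes = 10, divergence = 0.1)
  rs <- sim_reference_set(cfg)
  for (s in rs$reference$seq) {
    aa <- translate_frame(s, 1L)
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
})

test_that("error-free fragments are exact substrings of their gene", {
  cfg <- sim_config(seed = 75, n_genes = 5, depth = 4, error_rate = 0,
                    adaptor_rate = 0, polya_rate = 0)
  rs <- sim_reference_set(cfg)
  fr <- sim_fragment_reads(rs$truth, cfg)
  for (i in seq_len(nrow(fr$reads))) {
    info <- fr$truth[i, ]
    frag <- if (info$strand == "-") revcomp(fr$reads$seq[i]) else
      fr$reads$seq[i]
    expect_equal(frag, substr(rs$truth$seq[rs$truth$id == info$gene],
                              info$start, info$end))
  }
})

test_that("decoration rates are honoured at the extremes", {
  cfg <- sim_config(seed = 76, n_genes = 4, depth = 5, adaptor_rate = 1,
                    polya_rate = 0)
  fr <- sim_fragment_reads(sim_reference_set(cfg)$truth, cfg)
  expect_true(all(fr$truth$adaptor))
  expect_false(any(fr$truth$polya))
  cfg0 <- sim_config(seed = 76, n_genes = 4, depth = 5, adaptor_rate = 0)
  fr0 <- sim_fragment_reads(sim_reference_set(cfg0)$truth, cfg0)
  expect_false(any(fr0$truth$adaptor))
})

test_that("planted SSRs are found by the detector exactly where planted", {
  set.seed(77)
  base <- random_dna(400)
  pl <- plant_ssrs(base, tibble::tibble(motif = c("AC", "AAT"),
                                        n_repeats = c(12L, 6L),
                                        pos = c(50L, 200L)))
  loci <- find_ssrs(pl$seq)
  for (i in seq_len(nrow(pl$truth))) {
    row <- loci[loci$start == pl$truth$start[i], ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$end, pl$truth$end[i])
    expect_equal(row$n_repeats, pl$truth$n_repeats[i])
  }
  expect_error(plant_ssrs(base, tibble::tibble(motif = "AC", n_repeats = 12L,
                                               pos = 390L)),
               "past the sequence")
  expect_error(plant_ssrs(base, tibble::tibble(motif = c("AC", "AG"),
                                               n_repeats = c(10L, 10L),
                                               pos = c(50L, 60L))),
               "overlap")
})

test_that("planted variant reads realize the requested pileup depths exactly", {
  set.seed(78)
  ref <- random_dna(1000)
  cols <- tibble::tibble(pos = c(200L, 200L, 600L, 600L),
                         allele = c("A", "G", "C", "-"),
                         depth = c(4L, 3L, 5L, 3L))
  pv <- plant_variants(ref, cols)
  expect_equal(nrow(pv$reads), 15L)
  asm <- reference_guided_assembly(pv$reads, ref)
  for (p in unique(cols$pos)) {
    want <- cols[cols$pos == p, ]
    got <- asm$pileup[asm$pileup$pos == p, ]
    expect_setequal(got$allele, want$allele)
    expect_equal(got$depth[match(want$allele, got$allele)], want$depth)
  }
  expect_error(plant_variants(ref, tibble::tibble(pos = c(100L, 150L),
                                                  allele = c("A", "C"),
                                                  depth = c(3L, 3L))),
               "overlap")
})

test_that("the simulated mitochondrial genome matches its annotation", {
  mt <- sim_mt_genome(79)
  expect_true(all(mt$features$end <= nchar(mt$genome$seq)))
  cds <- mt$features[mt$features$feature_class == "CDS", ]
  for (i in seq_len(nrow(cds))) {
    s <- substr(mt$genome$seq, cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") s <- revcomp(s)
    aa <- translate_frame(s, 1L)
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
  expect_setequal(unique(mt$features$feature_class),
                  c("CDS", "tRNA", "rRNA", "control_region"))
})
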
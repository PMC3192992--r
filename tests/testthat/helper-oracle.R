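# Independent brute-force affine-gap local alignment oracle (Gotoh
# recurrences written directly in R, score only).  Deliberately separate
# from the package's compiled aligner so the two can be compared.
sw_affine_oracle <- function(q, s, match = 2, mismatch = -1,
                             gap_open = 5, gap_extend = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  FF <- matrix(-Inf, m + 1, n + 1)
  open1 <- gap_open + gap_extend
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(H[i, j - 1] - open1, E[i, j - 1] - gap_extend)
      FF[i, j] <- max(H[i - 1, j] - open1, FF[i - 1, j] - gap_extend)
      sub <- if (qc[i - 1] == sc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# SSR-free flanking/spacer sequences, frozen so that planted repeat loci
# have exact, boundary-safe coordinates.  Junction safety was enforced at
# generation time: no flank/spacer terminal base can extend an adjacent
# planted unit by rotation (e.g. a flank ending in T would turn
# "T|AACGT..." into a shifted TAACG run), and each constant was verified
# against every construct the tests build from it.
SSR_FREE_FLANK <-
  "CGTAGACACCCGGTGAGCCGGCAAGCTAGAGAACCTTAGGGTAGCAAGCTTCTTTAGCAG"
SSR_FREE_FLANK_COMPOUND <-
  "GACACGGACACTATGCGATAGTGATGATGGGAACGTAGCCGAAATATGCCCGTTCGAATC"
SSR_FREE_SPACER49 <- "CCAGAAGTTTCTTGACTAATCGCCGGCGAATAAATTGCCTCGAACAGTG"
SSR_FREE_SPACER50 <- "CTTGCACATACAGCATTTGCTCGCTACTCGGCTCTGATTCCCACTTCGCG"

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random coding sequence built independently of the package generator
random_cds_oracle <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste,
                      collapse = "")
  sense <- setdiff(all_codons, stops)
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), sample(stops, 1))
}
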
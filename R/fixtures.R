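# Synthetic-data generators.  Each generator seeds the RNG from its config,
# so a fixed seed yields byte-identical corpora; each emits a
# machine-readable truth table so closure tests (generate -> run pipeline ->
# compare to truth) need no external data.

.stop_codons <- c("TAA", "TAG", "TGA")
.sense_codons <- setdiff(names(Biostrings::GENETIC_CODE), .stop_codons)

#' Configuration for the synthetic corpus
#'
#' Defaults model a shallow pyrosequencing-style transcriptome survey: a
#' few-hundred-gene transcriptome sampled at low redundancy, reads of
#' 100-300 bp, ~5% divergence between the sequenced species and its
#' reference relatives, and library decorations (amplification adaptors,
#' polyA tails) on a configurable fraction of reads.
#'
#' @param seed Integer RNG seed; fixing it makes every generated corpus
#'   byte-identical.
#' @param n_genes Number of truth transcripts.
#' @param gene_len Length range (bp) of truth transcripts (rounded to whole
#'   codons).
#' @param divergence Per-base substitution fraction between truth and the
#'   derived reference species.
#' @param fragment_len Read-length range (bp).
#' @param depth Fragments generated per gene.
#' @param adaptor_rate Fraction of reads decorated with an adaptor.
#' @param internal_rate Of the decorated reads, fraction whose adaptor is
#'   internal (splitting the read) rather than terminal.
#' @param polya_rate Fraction of reads with a polyA tail.
#' @param error_rate Per-base substitution error in reads.
#' @param adaptors Adaptor sequences used for decoration.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, gene_len = c(600L, 1500L),
                       divergence = 0.05, fragment_len = c(100L, 300L),
                       depth = 5L, adaptor_rate = 0.3, internal_rate = 0.3,
                       polya_rate = 0.3, error_rate = 0.005,
                       adaptors = adaptor_spec()$adaptors) {
  rates <- c(divergence, adaptor_rate, internal_rate, polya_rate, error_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_len = as.integer(gene_len), divergence = divergence,
                 fragment_len = as.integer(fragment_len),
                 depth = as.integer(depth), adaptor_rate = adaptor_rate,
                 internal_rate = internal_rate, polya_rate = polya_rate,
                 error_rate = error_rate, adaptors = adaptors),
            class = "sim_config")
}

# Random coding sequence: ATG, sense codons, one stop.
.random_cds <- function(len_bp) {
  n_codons <- max(3L, len_bp %/% 3L)
  mid <- sample(.sense_codons, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(mid, collapse = ""), sample(.stop_codons, 1))
}

# Substitute bases at `rate`, never to the original base, resampling any
# substitution that would create an in-frame stop codon (frame +1).
.diverge_coding <- function(seq, rate) {
  cs <- chars(seq)
  n <- length(cs)
  hit <- which(runif(n) < rate)
  for (p in hit) {
    orig <- cs[p]
    repeat {
      cs[p] <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
      cod_i <- (p - 1L) %/% 3L
      codon <- paste(cs[(3L * cod_i + 1L):min(3L * cod_i + 3L, n)],
                     collapse = "")
      if (nchar(codon) < 3 || !(codon %in% .stop_codons) ||
          3L * cod_i + 3L == n) break
    }
  }
  paste(cs, collapse = "")
}

#' Generate truth transcripts and a diverged reference species
#'
#' Truth transcripts are random coding sequences (ATG ... stop); the
#' reference homolog of each is derived by per-base substitution at the
#' configured divergence, constrained never to introduce an in-frame stop
#' (as real coding orthologs are).  At divergence 0 the reference equals the
#' truth.
#'
#' @param cfg A [sim_config()].
#' @return A list: `truth` (sequence table, ids `g001`...), `reference`
#'   (sequence table, ids `ref_g001`...), `orthologs` (tibble: `gene`,
#'   `truth_id`, `ref_id`, `observed_divergence`).
#' @export
sim_reference_set <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  lens <- sample(seq(cfg$gene_len[1], cfg$gene_len[2]), cfg$n_genes,
                 replace = TRUE)
  truth_seq <- vapply(lens, .random_cds, character(1))
  ref_seq <- vapply(truth_seq, .diverge_coding, character(1),
                    rate = cfg$divergence, USE.NAMES = FALSE)
  obs_div <- map2_dbl(truth_seq, ref_seq, function(a, b) {
    mean(chars(a) != chars(b))
  })
  list(truth = seq_tbl(ids, truth_seq),
       reference = seq_tbl(paste0("ref_", ids), ref_seq),
       orthologs = tibble(gene = ids, truth_id = ids,
                          ref_id = paste0("ref_", ids),
                          observed_divergence = obs_div))
}

.add_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  cs <- chars(seq)
  hit <- which(runif(length(cs)) < rate)
  for (p in hit) {
    cs[p] <- sample(setdiff(c("A", "C", "G", "T"), cs[p]), 1)
  }
  paste(cs, collapse = "")
}

#' Fragment truth transcripts into decorated reads
#'
#' Draws `depth` fragments per gene with uniform start positions and
#' configured length range, applies per-base errors, random strand, and the
#' configured decoration rates: terminal or internal adaptors and polyA
#' tails.  Constant mid-30s qualities are attached so quality-aware stages
#' run.
#'
#' @param truth Truth transcripts (sequence table from
#'   [sim_reference_set()]).
#' @param cfg A [sim_config()].
#' @return A list: `reads` (sequence table with `qual`), `truth` (tibble:
#'   `read_id`, `gene`, `start`, `end`, `strand`, `clean_seq`, `adaptor`,
#'   `adaptor_internal`, `polya`).
#' @export
sim_fragment_reads <- function(truth, cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  reads <- list(); info <- list()
  r <- 0L
  for (i in seq_len(nrow(truth))) {
    L <- nchar(truth$seq[i])
    for (k in seq_len(cfg$depth)) {
      r <- r + 1L
      len <- min(L, sample(seq(cfg$fragment_len[1], cfg$fragment_len[2]), 1))
      start <- sample(seq_len(L - len + 1L), 1)
      frag <- substr(truth$seq[i], start, start + len - 1L)
      frag <- .add_errors(frag, cfg$error_rate)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") frag <- revcomp(frag)
      clean <- frag
      has_ad <- runif(1) < cfg$adaptor_rate
      internal <- FALSE
      if (has_ad) {
        ad <- sample(cfg$adaptors, 1)
        internal <- runif(1) < cfg$internal_rate
        if (internal && nchar(frag) >= 80) {
          at <- sample(seq(40L, nchar(frag) - 40L), 1)
          frag <- paste0(substr(frag, 1, at), ad,
                         substr(frag, at + 1L, nchar(frag)))
        } else {
          internal <- FALSE
          frag <- if (runif(1) < 0.5) paste0(ad, frag) else paste0(frag, ad)
        }
      }
      has_pa <- runif(1) < cfg$polya_rate
      if (has_pa) frag <- paste0(frag, strrep("A", sample(12:30, 1)))
      id <- sprintf("r%05d", r)
      reads[[r]] <- tibble(id = id, seq = frag,
                           qual = list(rep(35L, nchar(frag))))
      info[[r]] <- tibble(read_id = id, gene = truth$id[i],
                          start = start, end = start + len - 1L,
                          strand = strand, clean_seq = clean,
                          adaptor = has_ad, adaptor_internal = internal,
                          polya = has_pa)
    }
  }
  list(reads = list_rbind(reads), truth = list_rbind(info))
}

#' Plant perfect microsatellites into a sequence
#'
#' Each planted locus overwrites the sequence at `pos` with `n_repeats`
#' copies of `motif`.  Planted loci must fit inside the sequence and must
#' not overlap one another.
#'
#' @param seq A single nucleotide sequence.
#' @param plants Tibble with columns `motif`, `n_repeats`, `pos`.
#' @return A list: `seq` (the modified sequence), `truth` (tibble: `motif`,
#'   `n_repeats`, `start`, `end`).
#' @export
plant_ssrs <- function(seq, plants) {
  stopifnot(all(c("motif", "n_repeats", "pos") %in% names(plants)))
  plants <- arrange(plants, .data$pos)
  ends <- plants$pos + nchar(plants$motif) * plants$n_repeats - 1L
  if (any(ends > nchar(seq))) abort("planted locus extends past the sequence")
  if (nrow(plants) > 1 && any(plants$pos[-1] <= ends[-length(ends)])) {
    abort("planted loci overlap")
  }
  for (i in seq_len(nrow(plants))) {
    block <- strrep(toupper(plants$motif[i]), plants$n_repeats[i])
    substr(seq, plants$pos[i], ends[i]) <- block
  }
  list(seq = seq,
       truth = tibble(motif = toupper(plants$motif),
                      n_repeats = as.integer(plants$n_repeats),
                      start = as.integer(plants$pos), end = as.integer(ends)))
}

#' Plant variant columns realized by an exact read pileup
#'
#' For every requested column, reads spanning a window around the position
#' are emitted, carrying each requested allele at exactly its requested
#' depth (a `-` allele deletes the base).  Windows of different planted
#' columns must not overlap, so the pileup at each planted position
#' reproduces the requested allele depths exactly.
#'
#' @param ref_seq The sequence reads are drawn from.
#' @param columns Tibble with `pos`, `allele`, `depth` (several rows per
#'   position give several alleles).
#' @param flank Half-window size of the generated reads (default 50 bp).
#' @return A list: `reads` (sequence table), `truth` (the `columns` tibble).
#' @export
plant_variants <- function(ref_seq, columns, flank = 50L) {
  stopifnot(all(c("pos", "allele", "depth") %in% names(columns)))
  if (any(columns$depth < 1)) abort("allele depths must be >= 1")
  pos <- sort(unique(columns$pos))
  L <- nchar(ref_seq)
  if (any(pos < 1 | pos > L)) abort("planted position outside the sequence")
  win_lo <- pmax(1L, pos - flank); win_hi <- pmin(L, pos + flank)
  if (length(pos) > 1 && any(win_lo[-1] <= win_hi[-length(win_hi)])) {
    abort("planted variant windows overlap")
  }
  reads <- list()
  for (p in pos) {
    lo <- max(1L, p - flank); hi <- min(L, p + flank)
    window <- substr(ref_seq, lo, hi)
    at <- p - lo + 1L
    cols <- columns[columns$pos == p, ]
    for (i in seq_len(nrow(cols))) {
      base <- toupper(cols$allele[i])
      rs <- if (base == "-") {
        paste0(substr(window, 1, at - 1L),
               substr(window, at + 1L, nchar(window)))
      } else {
        s <- window; substr(s, at, at) <- base; s
      }
      for (k in seq_len(cols$depth[i])) {
        reads[[length(reads) + 1]] <- tibble(
          id = sprintf("v%d_%s_%d", p, if (base == "-") "del" else base, k),
          seq = rs)
      }
    }
  }
  list(reads = list_rbind(reads), truth = columns)
}

#' Simulate an annotated mitochondrial genome
#'
#' Builds a compact circular-genome-style sequence from consecutive
#' features -- protein-coding genes (ATG ... stop, one on the minus strand),
#' tRNAs, rRNAs and a control region -- separated by short spacers, plus the
#' matching feature table.
#'
#' @param seed RNG seed.
#' @param n_cds,n_trna,n_rrna Feature counts.
#' @return A list: `genome` (one-row sequence table, id `mt_genome`),
#'   `features` (tibble as from [read_gff3_features()]).
#' @export
sim_mt_genome <- function(seed = 1L, n_cds = 6L, n_trna = 5L, n_rrna = 2L) {
  set.seed(seed + 2L)
  parts <- list(); feats <- list()
  pos <- 1L
  add <- function(name, class, seq, strand = "+") {
    if (strand == "-") seq <- revcomp(seq)
    parts[[length(parts) + 1]] <<- seq
    feats[[length(feats) + 1]] <<- tibble(
      seq_id = "mt_genome", gene_name = name, start = pos,
      end = pos + nchar(seq) - 1L, strand = strand, feature_class = class)
    pos <<- pos + nchar(seq) + 10L
    parts[[length(parts) + 1]] <<- paste(
      sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
  }
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  for (i in seq_len(n_rrna)) add(paste0("rrn", i), "rRNA", rnd(450))
  for (i in seq_len(n_cds)) {
    add(paste0("mtCDS", i), "CDS", .random_cds(sample(seq(300, 900, 3), 1)),
        strand = if (i == n_cds) "-" else "+")
  }
  for (i in seq_len(n_trna)) add(paste0("trn", LETTERS[i]), "tRNA", rnd(70))
  add("CR", "control_region", rnd(400))
  genome <- paste(unlist(parts), collapse = "")
  list(genome = seq_tbl("mt_genome", genome), features = list_rbind(feats))
}
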
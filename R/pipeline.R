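#' Run the full annotation pipeline
#'
#' Executes the stages in their fixed order -- read cleaning, low-complexity
#' masking, the homology-assignment cascade, reference-guided mitochondrial
#' assembly with variant calling, consensus building for the nuclear rounds,
#' SSR screening of consensuses and orphans -- and writes every stage
#' artifact plus a run manifest into `out_dir`.  A rerun on identical inputs
#' is byte-identical (the manifest hash is the equality witness).
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `species` (name tag), `reads` (path to FASTA/FASTQ, or a sequence
#'   table), `dbs` (named list/paths: `mt`, `ncrna`, `coding`, `unigene`,
#'   `genomic`; any subset), optional `mt_features` (GFF3 path or feature
#'   tibble), optional `adaptors` (character vector), optional `min_minor`
#'   (variant rule, default 3), optional `seed` (recorded in the manifest).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results (`report`, `cascade`,
#'   `mt`, `consensus`, `ssrs`, `variants`) and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  known <- c("species", "reads", "dbs", "mt_features", "adaptors",
             "min_minor", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$reads)) abort("config$reads is required")
  dbs <- config$dbs %||% list()
  load_db <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) {
      if (!file.exists(x)) abort(paste0("database path not found: ", x))
      read_fasta(x)
    } else x
  }
  dbs <- lapply(dbs, load_db)  # config errors surface before any compute
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  reads <- config$reads
  if (is.character(reads)) {
    reads <- if (grepl("\\.f(ast)?q$", reads)) read_fastq(reads)
             else read_fasta(reads)
  }
  spec <- if (is.null(config$adaptors)) adaptor_spec()
          else adaptor_spec(adaptors = config$adaptors)

  pre <- preprocess_reads(reads, spec)
  clean <- pre$reads
  clean$seq <- mask_low_complexity(clean$seq)

  rounds <- cascade_rounds(mt_db = dbs$mt, ncrna_db = dbs$ncrna,
                           coding_db = dbs$coding, unigene_db = dbs$unigene,
                           genomic_db = dbs$genomic)
  if (length(rounds) == 0) abort("no cascade databases configured")
  casc <- run_cascade(clean, rounds)
  asg <- casc$assignments

  # mitochondrial branch: reference-guided assembly + variant calling
  mt_res <- NULL; variants <- NULL
  if (!is.null(dbs$mt)) {
    feats <- config$mt_features
    if (is.character(feats)) feats <- read_gff3_features(feats)
    mt_ids <- asg$query_id[asg$round == "mtDNA"]
    mt_res <- reference_guided_assembly(
      clean[clean$id %in% mt_ids, ], dbs$mt, features = feats)
    if (nrow(mt_res$pileup) > 0) {
      poly <- mt_res$pileup |>
        group_by(.data$pos) |> filter(n() > 1) |> ungroup()
      if (nrow(poly) > 0) {
        # context in reference coordinates (pileup positions are reference
        # positions)
        variants <- call_variants(poly,
                                  min_minor = config$min_minor %||% 3L,
                                  context = dbs$mt$seq[1])
      }
    }
  }

  # consensus building for the nuclear similarity rounds
  consensuses <- list()
  for (round_name in c("coding", "unigene")) {
    sub <- asg[asg$round == round_name, ]
    if (nrow(sub) == 0) next
    db <- if (round_name == "coding") dbs$coding else dbs$unigene
    for (sid in unique(sub$subject_id)) {
      members <- clean[clean$id %in% sub$query_id[sub$subject_id == sid], ]
      frames <- setNames(sub$frame[sub$subject_id == sid],
                         sub$query_id[sub$subject_id == sid])
      mode <- if (round_name == "coding") "protein_frame" else "nucleotide"
      consensuses[[sid]] <- build_consensus(
        members, db[db$id == sid, ], mode = mode,
        frames = if (mode == "protein_frame") frames else NULL)
    }
  }
  cons_tbl <- if (length(consensuses) > 0) {
    list_rbind(lapply(consensuses, glance))
  } else tibble()

  # marker screening on consensuses and orphans
  ssr_input <- bind_rows(
    if (length(consensuses) > 0) {
      tibble(id = map_chr(consensuses, "name"),
             seq = gsub("-", "", map_chr(consensuses, "aligned_seq"),
                        fixed = TRUE))
    } else NULL,
    casc$orphans[, c("id", "seq")])
  ssr_input <- ssr_input[nzchar(ssr_input$seq), ]
  ssr_input$id <- make.unique(ssr_input$id)
  ssrs <- find_ssrs(seq_tbl(ssr_input$id, toupper(ssr_input$seq)))

  # ---- write artifacts -----------------------------------------------------
  out <- function(...) file.path(out_dir, ...)
  readr::write_tsv(pre$report, out("preprocess_report.tsv"))
  readr::write_tsv(casc$round_counts, out("round_counts.tsv"))
  readr::write_tsv(asg, out("assignments.tsv"))
  write_fasta(casc$orphans[, c("id", "seq")], out("orphans.fasta"))
  if (length(consensuses) > 0) {
    write_fasta(seq_tbl(names(consensuses),
                        map_chr(consensuses, "aligned_seq")),
                out("consensus_aligned.fasta"))
    write_fasta(seq_tbl(names(consensuses),
                        gsub("-", "", map_chr(consensuses, "aligned_seq"),
                             fixed = TRUE)),
                out("consensus_ungapped.fasta"))
    readr::write_tsv(cons_tbl, out("consensus_stats.tsv"))
  }
  if (!is.null(mt_res)) {
    write_fasta(seq_tbl("mt_consensus", mt_res$consensus),
                out("mt_consensus.fasta"))
    if (!is.null(mt_res$coverage)) {
      readr::write_tsv(mt_res$coverage, out("mt_coverage.tsv"))
    }
    readr::write_tsv(mt_res$pileup, out("mt_pileup.tsv"))
  }
  if (!is.null(variants)) readr::write_tsv(variants, out("variants.tsv"))
  readr::write_tsv(select(ssrs, -"components"), out("ssrs.tsv"))

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  md5 <- tools::md5sum(file.path(out_dir, files))
  cfg_for_hash <- config[setdiff(names(config), "reads")]
  manifest <- list(
    package = "txcascade",
    version = as.character(utils::packageVersion("txcascade")),
    species = config$species %||% NA,
    seed = config$seed %||% NA,
    config_hash = .digest_string(
      jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, force = TRUE)),
    files = as.list(setNames(unname(md5), files)),
    manifest_hash = .digest_string(paste(files, unname(md5), collapse = ";")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(report = pre$report, cascade = casc, mt = mt_res,
                 consensus = consensuses, ssrs = ssrs, variants = variants,
                 manifest = manifest))
}

# md5 of a string via a temp file (tools::md5sum is file-based)
.digest_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(x), f)
  unname(tools::md5sum(f))
}
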
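# End-to-end orchestration with a single config, stage logging and a run
# manifest.

#' Default pipeline configuration
#'
#' Every threshold of the workflow is a named, documented key: length window
#' 18-30 nt, mature count floor 5, precursor MFE ceiling -18 kcal/mol, MFEI
#' floor 0.97, duplex energy-ratio floor 0.75, fold-change gate 2, alpha
#' 0.01.
#'
#' @return named list of defaults; override entries via [run_pipeline()]'s
#'   `config`.
#' @export
default_config <- function() {
  list(
    fastq = list(),           # library_id -> FASTQ path
    refs = list(),            # category -> FASTA path
    genome = NULL,            # FASTA path
    mature = NULL,            # known mature miRNA FASTA path
    transcripts = NULL,       # optional transcript FASTA for target scanning
    adapter3 = "TGGAATTCTCGGGTGCCAAGG",
    adapter5 = NULL,
    min_len = 18L, max_len = 30L, min_qual = 20L,
    max_mismatch_annot = 0L,
    conserved_max_mm = 2L, conserved_min_identity = 0.90,
    min_fc = 2, alpha = 0.01,
    novel_min_count = 5, mfe_max = -18, mfei_min = 0.97,
    energy_ratio_min = 0.75,
    seed = 1L,
    outdir = NULL)
}

#' Run the full pipeline
#'
#' Executes preprocess -> annotate -> conserved -> differential expression ->
#' novel prediction (-> target scanning when transcripts are given) and
#' writes stage outputs plus a plain-text manifest to `outdir`. All input
#' paths are checked before any stage runs; a rerun with the same config and
#' inputs reproduces identical outputs.
#'
#' @param config named list (see [default_config()]) or path to a YAML file
#'   with the same keys.
#' @param quiet suppress stage logging.
#' @return (invisibly) a list with all stage results and the `manifest` data
#'   frame of per-stage row counts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_config(), config)
  log_ <- function(...) if (!quiet) message(sprintf(...))

  paths <- c(unlist(cfg$fastq), unlist(cfg$refs), cfg$genome, cfg$mature,
             cfg$transcripts)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  if (length(cfg$fastq) != 2L || is.null(names(cfg$fastq))) {
    stop("config$fastq must name exactly two libraries")
  }
  if (is.null(cfg$outdir)) stop("config$outdir is required")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, fun) {
    r <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    r
  }

  # preprocess
  cleaned <- stage("preprocess", function() {
    lapply(cfg$fastq, function(p) {
      clean_reads(read_fastq(p), cfg$adapter3, cfg$adapter5,
                  cfg$min_len, cfg$max_len, cfg$min_qual)
    })
  })
  for (lib in names(cleaned)) {
    log_("preprocess[%s]: %d raw -> %d clean", lib,
         cleaned[[lib]]$stats$raw_reads, cleaned[[lib]]$stats$clean_reads)
  }
  tags <- collapse_tags(lapply(cleaned, `[[`, "sequences"))
  ld <- length_distribution(tags)
  genome <- stage("load_genome", function() read_fasta(cfg$genome, "genome"))
  gm <- stage("match_genome", function() match_genome(tags, genome))
  summaries <- do.call(rbind, lapply(names(cleaned), function(lib) {
    library_summary(lib, cleaned[[lib]]$stats,
                    unique_tags = sum(tags[[lib]] > 0),
                    genome_matched_reads = gm$matched_reads[[lib]])
  }))
  log_("collapse: %d unique tags; genome match %.2f%% / %.2f%%",
       nrow(tags), gm$percent[1L], gm$percent[2L])

  # annotate
  refsets <- stage("load_refs", function() {
    out <- list()
    for (cat in names(cfg$refs)) out[[cat]] <- read_fasta(cfg$refs[[cat]], cat)
    if (!is.null(cfg$mature) && is.null(out$known_mirna_mature)) {
      out$known_mirna_mature <- read_fasta(cfg$mature, "known_mirna_mature")
    }
    out
  })
  annot <- stage("annotate", function() {
    classify_tags(tags, refsets, cfg$max_mismatch_annot)
  })
  freqs <- class_frequencies(annot, tags)
  log_("annotate: %d/%d tags unannotated",
       sum(annot$category == "unannotated"), nrow(annot))

  # conserved + differential expression
  mature_set <- refsets$known_mirna_mature
  if (is.null(mature_set)) stop("a known_mirna_mature reference is required")
  # conserved identification runs on the tags left after higher-priority
  # annotation: the known-miRNA class plus the unannotated remainder
  mirna_tags <- tags[annot$category %in% c("known_miRNA", "unannotated"), ,
                     drop = FALSE]
  hits <- stage("conserved", function() {
    match_conserved(mirna_tags, mature_set, cfg$conserved_max_mm,
                    cfg$conserved_min_identity)
  })
  counts <- mirna_counts(hits, mirna_tags)
  families <- group_families(counts)
  totals <- vapply(cleaned, function(x) x$stats$clean_reads, numeric(1))
  de <- stage("diffexpr", function() {
    differential_expression(counts, totals, cfg$min_fc, cfg$alpha)
  })
  log_("conserved: %d miRNAs, %d families; %d differential",
       nrow(counts), nrow(families), sum(de$significant))

  # novel prediction on unannotated tags not already claimed as conserved,
  # per library, merged across libraries, then MFEI-filtered
  libs <- names(cfg$fastq)
  un <- tags[annot$category == "unannotated" &
               !(tags$sequence %in% hits$sequence), , drop = FALSE]
  novel <- stage("novel", function() {
    per_lib <- lapply(libs, function(lib) {
      cand <- predict_novel(un, genome, library = lib,
                            min_count = cfg$novel_min_count,
                            mfe_max = cfg$mfe_max)
      cand[cand$passed_all, , drop = FALSE]
    })
    names(per_lib) <- libs
    merged <- merge_libraries(per_lib[[1L]]$mature, per_lib[[2L]]$mature)
    all_cand <- unique(do.call(rbind, per_lib))
    final <- filter_mfei(all_cand[!duplicated(all_cand$mature), ,
                                  drop = FALSE], cfg$mfei_min)
    list(per_library = per_lib, merged = merged, final = final)
  })
  log_("novel: %d + %d candidates, union %d, %d past MFEI >= %.2f",
       novel$merged$n_a, novel$merged$n_b, novel$merged$union_count,
       nrow(novel$final), cfg$mfei_min)

  # optional target scanning for significant miRNAs
  target_hits <- NULL
  if (!is.null(cfg$transcripts)) {
    transcripts <- read_fasta(cfg$transcripts, "transcript")
    sig_ids <- de$mirna_id[de$significant]
    sig_set <- reference_set(
      mature_set$sequences[mature_set$ids %in% sig_ids],
      "known_mirna_mature")
    target_hits <- stage("targets", function() {
      scan_targets(sig_set, transcripts,
                   min_energy_ratio = cfg$energy_ratio_min)
    })
    log_("targets: %d passing sites", nrow(target_hits))
  }

  # outputs + manifest
  write_count_table(counts, file.path(cfg$outdir, "conserved_counts.tsv"))
  write.table(de, file.path(cfg$outdir, "diffexpr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(novel$final, file.path(cfg$outdir, "novel.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(summaries, file.path(cfg$outdir, "library_summaries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ld, file.path(cfg$outdir, "length_distribution.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(freqs, file.path(cfg$outdir, "class_frequencies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(target_hits)) {
    write.table(target_hits, file.path(cfg$outdir, "targets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfg_path <- file.path(cfg$outdir, "run_config.yaml")
  yaml::write_yaml(cfg[order(names(cfg))], cfg_path)
  manifest <- data.frame(
    stage = c("preprocess", "tags", "annotate", "conserved", "diffexpr",
              "novel", "targets"),
    rows = as.integer(c(
      sum(vapply(cleaned, function(x) x$stats$clean_reads, numeric(1))),
      nrow(tags), nrow(annot), nrow(counts), nrow(de), nrow(novel$final),
      if (is.null(target_hits)) NA_integer_ else nrow(target_hits))))
  manifest_lines <- c(
    sprintf("mirskin %s", as.character(utils::packageVersion("mirskin"))),
    sprintf("config_md5 %s", unname(tools::md5sum(cfg_path))),
    sprintf("%s %s", manifest$stage, manifest$rows))
  writeLines(manifest_lines, file.path(cfg$outdir, "manifest.txt"))

  invisible(list(tags = tags, summaries = summaries,
                 length_distribution = ld, annotations = annot,
                 class_frequencies = freqs, conserved = hits,
                 counts = counts, families = families, diffexpr = de,
                 novel = novel, targets = target_hits, manifest = manifest,
                 genome_match = gm, config = cfg))
}
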
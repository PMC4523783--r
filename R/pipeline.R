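#' Pipeline configuration
#'
#' Bundles the input paths and every threshold applied by the workflow. All
#' thresholds default to the study's published values: 18-30 nt clean-read
#' window, zero-mismatch genome mapping, two mismatches against known
#' matures, 20-copy genomic cap, -18 kcal/mol precursor MFE, 50-read
#' precursor support, 0.01 TPM zero substitution, 10-TPM low-expression
#' filter, |log2 FC| > 1 with p <= 0.001, and a 3.0 target-score cutoff.
#'
#' @param genome genome FASTA path.
#' @param reads named character vector of FASTQ paths; the first entry is the
#'   control library (fold-change denominator), the second the treatment.
#' @param known known-miRNA FASTA (matures `>name`, hairpins
#'   `>name-precursor`).
#' @param ncrna ncRNA FASTA with `category|id` headers, or NULL.
#' @param annotation GFF3 feature file, or NULL.
#' @param transcripts transcript FASTA for target scanning, or NULL.
#' @param out_dir output directory.
#' @param adapter_3p 3' adapter sequence.
#' @param seed integer seed.
#' @param backend folding backend ("auto", "viennarna", "nussinov").
#' @param qual_threshold,min_len,max_len,max_mm,max_copies read cleaning and
#'   matching thresholds.
#' @param criteria novel-precursor thresholds ([novel_criteria_thresholds()]).
#' @param fc_min,p_max,low_tpm DEM thresholds.
#' @param p_method p-value method ([pvalue_two_library()]).
#' @param target_max_score target-site score cutoff.
#' @export
pipeline_config <- function(genome, reads, known, ncrna = NULL,
                            annotation = NULL, transcripts = NULL,
                            out_dir = "coldmir_out",
                            adapter_3p = "TGGAATTCTCGGGTGCCAAGG", seed = 1,
                            backend = "auto", qual_threshold = 20,
                            min_len = 18L, max_len = 30L, max_mm = 2L,
                            max_copies = 20L,
                            criteria = novel_criteria_thresholds(),
                            fc_min = 1, p_max = 0.001, low_tpm = 10,
                            p_method = "audic-claverie",
                            target_max_score = 3.0) {
  stopifnot(length(reads) >= 2, !is.null(names(reads)))
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_backend <- function(backend) {
  switch(backend,
         auto = fold_backend_default(),
         viennarna = fold_backend_viennarna(),
         nussinov = fold_backend_nussinov(),
         stop("unknown backend: ", backend))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full discovery and differential-expression pipeline
#'
#' Stages run in fixed order: read cleaning and collapsing, genome mapping
#' and annotation triage, known-miRNA identification, novel-miRNA discovery,
#' differential expression, and (when transcripts are supplied) target
#' prediction for the DEMs. Every stage writes its table under
#' `config$out_dir`; a plain-text run log plus a machine-readable JSON
#' summary record the seed, every threshold applied and per-stage record
#' counts. Reruns with identical config and inputs are deterministic.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage results and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- character(0)
  logit <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logit("FAILED at stage ", name, ": ", conditionMessage(e))
      writeLines(log_lines, log_path)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  th <- config[c("adapter_3p", "qual_threshold", "min_len", "max_len",
                 "max_mm", "max_copies", "fc_min", "p_max", "low_tpm",
                 "p_method", "target_max_score", "backend", "seed")]
  logit("coldmiR run; seed=", config$seed)
  for (nm in names(th)) logit("threshold ", nm, " = ", th[[nm]])
  for (nm in names(config$criteria)) {
    logit("criteria ", nm, " = ", paste(config$criteria[[nm]], collapse = ","))
  }
  counts_log <- list()

  libs <- names(config$reads)
  genome <- stage("load_genome", {
    g <- Biostrings::readDNAStringSet(config$genome)
    names(g) <- sub("\\s.*$", "", names(g))
    setNames(as.character(g), names(g))
  })

  clean <- list(); summaries <- list()
  for (lib in libs) {
    cl <- stage(paste0("clean_", lib), {
      raw <- read_fastq(config$reads[[lib]])
      clean_reads(raw, config$adapter_3p, config$qual_threshold,
                  config$min_len, config$max_len)
    })
    clean[[lib]] <- cl$seq
    counts_log[[paste0("raw_reads_", lib)]] <- cl$n_raw
    counts_log[[paste0("clean_reads_", lib)]] <- cl$n_clean
    logit("library ", lib, ": ", cl$n_raw, " raw -> ", cl$n_clean,
          " clean (", paste(names(cl$tally), cl$tally, sep = "=",
                            collapse = ", "), ")")
    summaries[[lib]] <- cl
  }

  tag_table <- stage("collapse", collapse_tags(clean))
  counts_log$unique_tags <- nrow(tag_table)
  logit("collapsed to ", nrow(tag_table), " unique tags")
  write_tags(tag_table, file.path(config$out_dir, "tags"))
  sumtab <- do.call(rbind, lapply(libs, function(lib) {
    s <- library_summary(tag_table, lib, summaries[[lib]]$n_raw,
                         summaries[[lib]]$n_clean)
    data.frame(library = lib, raw_reads = s$raw_reads,
               clean_reads = s$clean_reads, unique_tags = s$unique_tags)
  }))
  write_tsv(sumtab, file.path(config$out_dir, "library_summary.tsv"))

  index <- stage("index", build_index(genome))
  hits <- stage("map", lookup_tags(index, tag_table$sequence))
  counts_log$mapped_tags <- length(unique(hits$tag))
  logit(counts_log$mapped_tags, " tags mapped to the genome (exact, both strands)")

  known_ref <- stage("load_known", {
    k <- Biostrings::readDNAStringSet(config$known)
    k <- setNames(as.character(k), sub("\\s.*$", "", names(k)))
    pre <- grepl("-precursor$", names(k))
    list(mature = k[!pre], precursor = k[pre])
  })
  ncrna <- if (!is.null(config$ncrna)) {
    nr <- Biostrings::readDNAStringSet(config$ncrna)
    setNames(as.character(nr), names(nr))
  } else character(0)
  annotation <- if (!is.null(config$annotation)) {
    gr <- rtracklayer::import(config$annotation)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               type = as.character(gr$type), stringsAsFactors = FALSE)
  } else NULL

  categories <- stage("classify", {
    classify_tags(tag_table, hits, ncrna, annotation, known_ref,
                  config$max_copies)
  })
  catsum <- category_summary(categories, tag_table)
  write_tsv(categories, file.path(config$out_dir, "categories.tsv"))
  write_tsv(catsum, file.path(config$out_dir, "category_summary.tsv"))
  counts_log$ncRNA_excluded_tags <-
    sum(catsum$unique_tags[catsum$category %in%
                           c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")])
  logit("category triage: ", counts_log$ncRNA_excluded_tags,
        " ncRNA tags excluded from miRNA analysis")

  cand <- categories$sequence[categories$category == "miRNA_candidate"]
  kh <- stage("known", {
    resolve_hits(match_known(cand, known_ref$mature, config$max_mm))
  })
  mature_counts <- per_mature_counts(kh, tag_table, annotated_only = TRUE)
  fam <- aggregate_families(kh, tag_table)
  variants <- list_variants(kh, tag_table)
  counts_log$known_matures <- nrow(mature_counts)
  logit(nrow(mature_counts), " known matures in ", nrow(fam), " families; ",
        nrow(variants), " isomiR variants listed (excluded from DEM)")
  write_tsv(mature_counts, file.path(config$out_dir, "known_mature_counts.tsv"))
  write_tsv(fam, file.path(config$out_dir, "family_counts.tsv"))
  write_tsv(variants, file.path(config$out_dir, "known_variants.tsv"))

  nv <- stage("novel", {
    identify_novel(tag_table, categories, hits, genome,
                   backend = resolve_backend(config$backend),
                   thresholds = config$criteria)
  })
  counts_log$novel_mirnas <- nrow(nv$novel)
  logit(nrow(nv$novel), " novel miRNAs accepted by the ten criteria")
  novel_out <- nv$novel
  novel_out$structure <- NULL
  write_tsv(novel_out, file.path(config$out_dir, "novel_mirnas.tsv"))
  if (nrow(nv$novel)) {
    writeLines(paste0(">", nv$novel$name, "\n", nv$novel$precursor_seq, "\n",
                      nv$novel$structure),
               file.path(config$out_dir, "novel_structures.txt"))
  }

  ctrl <- libs[1]; trt <- libs[2]
  totals <- setNames(vapply(libs, function(l) summaries[[l]]$n_clean,
                            numeric(1)), libs)
  dem_counts <- stage("dem_input", {
    km <- data.frame(name = mature_counts$mature_name,
                     count_NCT = mature_counts[[paste0("count_", ctrl)]],
                     count_CT = mature_counts[[paste0("count_", trt)]],
                     stringsAsFactors = FALSE)
    nvn <- data.frame(name = nv$novel$name,
                      count_NCT = if (nrow(nv$novel)) nv$novel[[paste0("count_", ctrl)]] else numeric(0),
                      count_CT = if (nrow(nv$novel)) nv$novel[[paste0("count_", trt)]] else numeric(0),
                      stringsAsFactors = FALSE)
    rbind(km, nvn)
  })
  dem <- stage("dem", {
    dem_table(dem_counts, totals[[ctrl]], totals[[trt]],
              method = config$p_method, fc_min = config$fc_min,
              p_max = config$p_max, low_tpm = config$low_tpm)
  })
  counts_log$dem_up <- sum(dem$class == "up")
  counts_log$dem_down <- sum(dem$class == "down")
  logit("DEM: ", counts_log$dem_up, " up, ", counts_log$dem_down, " down (",
        trt, " vs ", ctrl, ")")
  write_tsv(dem, file.path(config$out_dir, "dem.tsv"))

  targets <- NULL
  if (!is.null(config$transcripts)) {
    targets <- stage("targets", {
      tx <- Biostrings::readDNAStringSet(config$transcripts)
      tx_ann <- setNames(sub("^\\S+\\s*", "", names(tx)), sub("\\s.*$", "", names(tx)))
      tx <- setNames(as.character(tx), sub("\\s.*$", "", names(tx)))
      dems <- dem$name[dem$class %in% c("up", "down")]
      seqs <- c(setNames(known_ref$mature, names(known_ref$mature)),
                if (nrow(nv$novel)) setNames(to_dna(nv$novel$sequence), nv$novel$name))
      seqs <- seqs[names(seqs) %in% dems]
      ta <- scan_transcripts(seqs, tx, config$target_max_score)
      ta$annotation <- tx_ann[ta$transcript_id]
      ta
    })
    counts_log$target_sites <- nrow(targets)
    logit(nrow(targets), " predicted target sites for DEMs")
    write_tsv(targets, file.path(config$out_dir, "targets.tsv"))
  }

  writeLines(log_lines, log_path)
  summary <- list(seed = config$seed, thresholds = th,
                  criteria = config$criteria, records = counts_log)
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(tag_table = tag_table, categories = categories,
                 hits = hits, known = kh, mature_counts = mature_counts,
                 families = fam, variants = variants, novel = nv$novel,
                 dem = dem, targets = targets, summary = summary,
                 library_summaries = summaries))
}
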
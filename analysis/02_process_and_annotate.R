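#!/usr/bin/env Rscript
# Step 2 -- clean reads, collapse to tags, map, and triage by annotation.
#
# Reproduces the "clean reads" / "unique sRNAs" accounting: adapter trimming,
# N/quality/length filters, collapsing with per-library counts, exact-match
# genome mapping on both strands, and the category triage that excludes
# rRNA/tRNA/snRNA/snoRNA before any miRNA analysis.

library(coldmiR)

syn_dir <- "results/synthetic"
out <- "results/tags"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

adapter <- read_sim_params()$adapter_3p
clean <- list()
for (lib in c("NCT", "CT")) {
  raw <- read_fastq(file.path(syn_dir, paste0(lib, ".fq.gz")))
  cl <- clean_reads(raw, adapter)
  clean[[lib]] <- cl$seq
  message(lib, ": ", cl$n_raw, " raw -> ", cl$n_clean, " clean reads (",
          paste(names(cl$tally), cl$tally, sep = "=", collapse = ", "), ")")
}

tags <- collapse_tags(clean)
write_tags(tags, file.path(out, "tags"))
message("Collapsed to ", nrow(tags), " unique tags; length histogram modes: ",
        paste(head(library_summary(tags, "NCT")$length_histogram[
          order(-library_summary(tags, "NCT")$length_histogram$total_reads), "length"], 2),
          collapse = " and "), " nt")

genome <- Biostrings::readDNAStringSet(file.path(syn_dir, "genome.fa"))
genome <- setNames(as.character(genome), sub("\\s.*", "", names(genome)))
hits <- lookup_tags(build_index(genome), tags$sequence)
message(length(unique(hits$tag)), " tags map to the genome (exact, both strands)")

ncrna <- Biostrings::readDNAStringSet(file.path(syn_dir, "ncrna.fa"))
ncrna <- setNames(as.character(ncrna), names(ncrna))
known <- Biostrings::readDNAStringSet(file.path(syn_dir, "known_mirna.fa"))
known <- setNames(as.character(known), sub("\\s.*", "", names(known)))
known <- list(mature = known[!grepl("-precursor$", names(known))],
              precursor = known[grepl("-precursor$", names(known))])
ann_gr <- rtracklayer::import(file.path(syn_dir, "annotation.gff3"))
annotation <- data.frame(chrom = as.character(GenomicRanges::seqnames(ann_gr)),
                         start = GenomicRanges::start(ann_gr),
                         end = GenomicRanges::end(ann_gr),
                         strand = as.character(GenomicRanges::strand(ann_gr)),
                         type = as.character(ann_gr$type))

cats <- classify_tags(tags, hits, ncrna, annotation, known)
summ <- category_summary(cats, tags)
write.table(cats, file.path(out, "categories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summ, file.path(out, "category_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(hits, file.path(out, "genome_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Category triage (unique tags): ",
        paste(summ$category[summ$unique_tags > 0],
              summ$unique_tags[summ$unique_tags > 0],
              sep = "=", collapse = ", "))
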
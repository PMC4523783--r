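#!/usr/bin/env Rscript
# Step 3 -- identify known and novel miRNAs.
#
# Known: candidate tags matched against the mature reference with <= 2
# mismatches, aggregated per mature and per family; isomiR variants listed
# separately. Novel: unannotated tag clusters excised with 20-nt flanks,
# folded, and put through the ten-rule precursor check. Results are compared
# against the planted ground truth.

library(coldmiR)

syn_dir <- "results/synthetic"
out <- "results/mirnas"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tags <- read.table("results/tags/tags.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
cats <- read.table("results/tags/categories.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
hits <- read.table("results/tags/genome_hits.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
genome <- Biostrings::readDNAStringSet(file.path(syn_dir, "genome.fa"))
genome <- setNames(as.character(genome), sub("\\s.*", "", names(genome)))
known <- Biostrings::readDNAStringSet(file.path(syn_dir, "known_mirna.fa"))
known <- setNames(as.character(known), sub("\\s.*", "", names(known)))
mature_ref <- known[!grepl("-precursor$", names(known))]
truth <- read.table(file.path(syn_dir, "truth.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)

cand <- cats$sequence[cats$category == "miRNA_candidate"]
kh <- resolve_hits(match_known(cand, mature_ref))
mature_counts <- per_mature_counts(kh, tags)
fam <- aggregate_families(kh, tags)
variants <- list_variants(kh, tags)
write.table(mature_counts, file.path(out, "known_mature_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fam, file.path(out, "family_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(variants, file.path(out, "known_variants.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(nrow(mature_counts), " known matures in ", nrow(fam), " families; ",
        "largest family: ", fam$family[which.max(fam$n_members)], " (",
        max(fam$n_members), " members); ", nrow(variants), " isomiR variants")

nv <- identify_novel(tags, cats, hits, genome)
novel_out <- nv$novel
novel_out$structure <- NULL
write.table(novel_out, file.path(out, "novel_mirnas.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(nrow(nv$novel), " novel miRNAs accepted by the ten criteria, MFE ",
        if (nrow(nv$novel)) paste0(min(nv$novel$mfe), " to ", max(nv$novel$mfe),
                                   " kcal/mol") else "-")

planted <- to_dna(truth$mature_seq[truth$category == "novel_miRNA"])
hit_rate <- mean(planted %in% to_dna(nv$novel$sequence))
message("Planted novel loci recovered: ", round(100 * hit_rate), "% (",
        sum(planted %in% to_dna(nv$novel$sequence)), "/", length(planted), ")")
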
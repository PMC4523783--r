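#' Build an exact-match index over both strands of a genome
#'
#' @param genome named character vector or DNAStringSet of chromosomes.
#' @return object of class `genome_index`.
#' @export
build_index <- function(genome) {
  seqs <- setNames(as.character(genome), names(genome))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("duplicate or missing chromosome names")
  }
  structure(list(genome = Biostrings::DNAStringSet(seqs)), class = "genome_index")
}

#' Find all exact genomic occurrences of small-RNA tags
#'
#' Matching is exact (zero mismatches) on both strands; minus-strand hits are
#' reported in plus-strand genomic coordinates. Tags containing N yield no
#' hits.
#'
#' @param index a [build_index()] object.
#' @param tags character vector of tag sequences (DNA alphabet).
#' @return data.frame with columns tag, chrom, start, end, strand.
#' @export
lookup_tags <- function(index, tags) {
  tags <- to_dna(tags)
  ok <- !grepl("[^ACGT]", tags)
  res <- list()
  genome <- index$genome
  for (str in c("+", "-")) {
    qry <- if (str == "+") tags[ok] else revcomp(tags[ok])
    if (!length(qry)) next
    for (w in unique(nchar(qry))) {
      sel <- nchar(qry) == w
      pd <- Biostrings::PDict(qry[sel])
      for (ch in names(genome)) {
        m <- Biostrings::matchPDict(pd, genome[[ch]])
        n_hits <- S4Vectors::elementNROWS(m)
        if (!sum(n_hits)) next
        starts <- unlist(IRanges::start(m), use.names = FALSE)
        res[[length(res) + 1]] <- data.frame(
          tag = rep(tags[ok][sel], n_hits),
          chrom = ch, start = starts, end = starts + w - 1L, strand = str,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(res)) {
    return(data.frame(tag = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$tag, out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test whether each tag is an exact substring of any subject sequence
#'
#' The matching primitive behind ncRNA exclusion ("exact matches" to
#' reference non-coding RNA sets).
#'
#' @param tags character vector of tag sequences.
#' @param subjects character vector (or DNAStringSet) of reference sequences.
#' @return logical vector along `tags`.
#' @export
match_substring <- function(tags, subjects) {
  if (!length(subjects) || !length(tags)) return(logical(length(tags)))
  subjects <- to_dna(as.character(subjects))
  hit <- logical(length(tags))
  for (s in subjects) {
    todo <- which(!hit)
    if (!length(todo)) break
    hit[todo] <- vapply(tags[todo], function(t) grepl(t, s, fixed = TRUE),
                        logical(1), USE.NAMES = FALSE)
  }
  hit
}

CATEGORY_PRIORITY <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
                       "miRNA_candidate", "repeat", "exon_sense",
                       "exon_antisense", "intron_sense", "intron_antisense",
                       "unannotated")

#' Triage tags into annotation categories
#'
#' Each tag gets exactly one category, chosen by fixed priority:
#' rRNA > tRNA > snRNA > snoRNA > scRNA > miRNA candidate > repeat >
#' exon_sense > exon_antisense > intron_sense > intron_antisense >
#' unannotated. ncRNA matching is exact substring matching against the
#' category reference sets, and ncRNA categories preclude miRNA candidacy
#' (such tags are excluded from all downstream miRNA analyses). Tags with
#' more than `max_copies` genomic hits are flagged repeat-like and barred
#' from miRNA candidacy.
#'
#' @param tag_table collapsed tag table ([collapse_tags()]).
#' @param hits genome hits ([lookup_tags()]).
#' @param ncrna named character vector of ncRNA reference sequences; names
#'   are `category|id` with category in rRNA/tRNA/snRNA/snoRNA/scRNA/repeat.
#' @param annotation data.frame of features (chrom, start, end, strand, type)
#'   with types exon/intron/repeat, or NULL.
#' @param known optional list with `mature` and `precursor` named character
#'   vectors; tags matching a precursor as a substring, or a mature within
#'   two mismatches, are miRNA candidates.
#' @param max_copies genomic copy-number cap (default 20).
#' @return data.frame with columns sequence, category, n_hits.
#' @export
classify_tags <- function(tag_table, hits, ncrna = character(0),
                          annotation = NULL, known = NULL, max_copies = 20L) {
  tags <- tag_table$sequence
  n_hits <- integer(length(tags))
  ht <- table(hits$tag)
  n_hits[match(names(ht), tags)] <- as.integer(ht)
  cat_out <- rep(NA_character_, length(tags))

  nc_cat <- sub("\\|.*$", "", names(ncrna))
  for (cc in c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")) {
    open <- is.na(cat_out)
    if (!any(open)) break
    m <- match_substring(tags[open], ncrna[nc_cat == cc])
    cat_out[open][m] <- cc
  }

  if (!is.null(known)) {
    open <- which(is.na(cat_out))
    if (length(open)) {
      is_cand <- match_substring(tags[open], known$precursor)
      if (length(known$mature)) {
        rest <- open[!is_cand]
        if (length(rest)) {
          kh <- match_known(tags[rest], known$mature, max_mm = 2L)
          is_cand[!is_cand][tags[rest] %in% kh$tag] <- TRUE
        }
      }
      cat_out[open][is_cand] <- "miRNA_candidate"
    }
  }

  # repeat: reference repeat sets, annotated repeat features, or copy cap
  open <- which(is.na(cat_out))
  if (length(open)) {
    rep_hit <- match_substring(tags[open], ncrna[nc_cat == "repeat"])
    rep_hit <- rep_hit | n_hits[open] > max_copies
    cat_out[open][rep_hit] <- "repeat"
  }

  # genic categories from the feature annotation
  if (!is.null(annotation) && nrow(hits) > 0) {
    ann <- annotation[annotation$type %in% c("exon", "intron", "repeat"), , drop = FALSE]
    if (nrow(ann)) {
      hg <- GenomicRanges::GRanges(hits$chrom, IRanges::IRanges(hits$start, hits$end),
                                   strand = hits$strand)
      ag <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start, ann$end),
                                   strand = ann$strand)
      ov <- GenomicRanges::findOverlaps(hg, ag, ignore.strand = TRUE)
      if (length(ov)) {
        same <- as.character(GenomicRanges::strand(hg))[queryHits(ov)] ==
          as.character(GenomicRanges::strand(ag))[subjectHits(ov)]
        ftype <- ann$type[subjectHits(ov)]
        tag_of <- hits$tag[queryHits(ov)]
        lab <- ifelse(ftype == "repeat", "repeat",
                      paste0(ftype, ifelse(same, "_sense", "_antisense")))
        for (cc in c("repeat", "exon_sense", "exon_antisense",
                     "intron_sense", "intron_antisense")) {
          open <- is.na(cat_out)
          sel <- unique(tag_of[lab == cc])
          cat_out[open & tags %in% sel] <- cc
        }
      }
    }
  }
  cat_out[is.na(cat_out)] <- "unannotated"
  data.frame(sequence = tags, category = cat_out, n_hits = n_hits,
             stringsAsFactors = FALSE)
}

#' Category summary table
#'
#' @param categories output of [classify_tags()].
#' @param tag_table collapsed tag table (for read-count sums).
#' @return data.frame with unique-tag and total-read counts per category.
#' @export
category_summary <- function(categories, tag_table) {
  counts <- rowSums(as.matrix(tag_table[, grep("^count_", names(tag_table)),
                                        drop = FALSE]))
  cats <- factor(categories$category, levels = CATEGORY_PRIORITY)
  data.frame(
    category = levels(cats),
    unique_tags = as.integer(table(cats)),
    total_reads = as.numeric(tapply(counts, cats, sum, default = 0)),
    stringsAsFactors = FALSE
  )
}
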
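#' Thresholds of the ten-rule novel-miRNA precursor check
#'
#' Defaults are the published rule set for plant miRNA annotation from
#' replicate-free sequencing: (1) mature length 18-25 nt; (2) mature length on
#' the reference 20-23 nt; (3) at most 20 genomic copies; (4) precursor MFE at
#' most -18 kcal/mol; (5) at most 30 nt between miRNA and miRNA*; (6) at least
#' 16 base pairs in the miRNA/miRNA* duplex; (7) largest bulge at most 4;
#' (8) duplex asymmetry at most 4; (9) 20 nt precursor flanks; (10) at least
#' 50 reads on the precursor in at least one library.
#'
#' Criteria (1) and (2) are both length rules; the distinction between the
#' "miRNA sequence" and the "miRNA reference sequence" is ambiguous in the
#' source rule set, so both are checked as written (see the methods vignette).
#'
#' @param min_reads read-support threshold; the rule set states both "more
#'   than 50" and "less than 50 ... neglected", reconciled here as >= 50.
#' @export
novel_criteria_thresholds <- function(min_reads = 50) {
  list(
    mature_len = c(18L, 25L),
    ref_len = c(20L, 23L),
    max_copies = 20L,
    max_mfe = -18,
    max_space = 30L,
    min_paired = 16L,
    max_bulge = 4L,
    max_asym = 4L,
    flank = 20L,
    min_reads = min_reads
  )
}

#' Locate the miRNA* and compute duplex statistics from a folded precursor
#'
#' The star strand is the segment of the precursor pairing with the mature in
#' the dot-bracket structure, reported with the canonical 2-nt 3' overhang.
#' Duplex statistics are computed on the pairing core (the region actually
#' paired with the mature): `paired_bases` is the number of mature positions
#' paired into the star arm, `bulge_max` the longest run of consecutive
#' unpaired bases on either strand of the duplex, `asymmetry` the absolute
#' difference of unpaired counts between the two strands, and `spacing` the
#' number of nucleotides between the mature and star segments.
#'
#' @param structure dot-bracket string of the precursor.
#' @param mature_offset 1-based start of the mature within the precursor.
#' @param mature_len mature length (nt).
#' @return list with `ok`, `reason`, `arm` ("5p"/"3p"), `star_start`,
#'   `star_end`, and `stats` (paired_bases, bulge_max, asymmetry, spacing).
#' @export
find_duplex <- function(structure, mature_offset, mature_len) {
  n <- nchar(structure)
  m1 <- mature_offset
  m2 <- mature_offset + mature_len - 1L
  stopifnot(m1 >= 1, m2 <= n)
  pt <- pair_table(structure)
  m <- m1:m2
  partners <- pt[m]
  paired <- !is.na(partners)
  fail <- function(reason) list(ok = FALSE, reason = reason, arm = NA_character_,
                                star_start = NA_integer_, star_end = NA_integer_,
                                stats = list(paired_bases = sum(paired),
                                             bulge_max = NA_integer_,
                                             asymmetry = NA_integer_,
                                             spacing = NA_integer_))
  if (!any(paired)) return(fail("unpaired"))
  pp <- partners[paired]
  if (all(pp > m2)) {
    arm <- "5p"
  } else if (all(pp < m1)) {
    arm <- "3p"
  } else {
    return(fail("loop_spanning"))
  }
  lo <- min(pp); hi <- max(pp)
  core <- lo:hi
  paired_bases <- sum(paired)
  unpaired_m <- mature_len - paired_bases
  star_to_mature <- !is.na(pt[core]) & pt[core] >= m1 & pt[core] <= m2
  unpaired_s <- sum(!star_to_mature)
  run_max <- function(x) if (!any(x)) 0L else max(rle(x)$lengths[rle(x)$values])
  bulge_max <- max(run_max(!paired), run_max(!star_to_mature))
  asymmetry <- abs(unpaired_m - unpaired_s)
  spacing <- if (arm == "5p") lo - m2 - 1L else m1 - hi - 1L
  shift <- if (arm == "5p") 2L else -2L
  star_start <- max(1L, lo + shift)
  star_end <- min(n, hi + shift)
  list(ok = TRUE, reason = NA_character_, arm = arm,
       star_start = star_start, star_end = star_end,
       stats = list(paired_bases = paired_bases, bulge_max = bulge_max,
                    asymmetry = asymmetry, spacing = spacing))
}

#' Apply the ten novel-miRNA criteria to a hairpin candidate
#'
#' @param candidate list with fields `mature_seq`, `mfe`, `duplex_stats`
#'   (paired_bases, bulge_max, asymmetry, spacing; NAs if the duplex is
#'   undefined), `n_genomic_copies` and `flank`.
#' @param read_support named numeric vector of reads mapped to the precursor
#'   per library.
#' @param thresholds see [novel_criteria_thresholds()].
#' @return data.frame with one row per criterion (columns criterion, rule,
#'   measured, pass) and attribute `overall` (TRUE iff all pass).
#' @export
check_criteria <- function(candidate, read_support,
                           thresholds = novel_criteria_thresholds()) {
  th <- thresholds
  len <- nchar(candidate$mature_seq)
  ds <- candidate$duplex_stats
  meas <- c(len, len, candidate$n_genomic_copies, candidate$mfe,
            ds$spacing, ds$paired_bases, ds$bulge_max, ds$asymmetry,
            candidate$flank, max(read_support))
  pass <- c(
    len >= th$mature_len[1] && len <= th$mature_len[2],
    len >= th$ref_len[1] && len <= th$ref_len[2],
    candidate$n_genomic_copies <= th$max_copies,
    candidate$mfe <= th$max_mfe,
    !is.na(ds$spacing) && ds$spacing <= th$max_space,
    !is.na(ds$paired_bases) && ds$paired_bases >= th$min_paired,
    !is.na(ds$bulge_max) && ds$bulge_max <= th$max_bulge,
    !is.na(ds$asymmetry) && ds$asymmetry <= th$max_asym,
    candidate$flank == th$flank,
    max(read_support) >= th$min_reads
  )
  rep <- data.frame(
    criterion = 1:10,
    rule = c("mature length 18-25", "reference length 20-23",
             "genomic copies <= 20", "MFE <= -18 kcal/mol",
             "miRNA/miRNA* spacing <= 30", "duplex base pairs >= 16",
             "max bulge <= 4", "duplex asymmetry <= 4",
             "precursor flank = 20", "reads on precursor >= 50 in one library"),
    measured = as.numeric(meas),
    pass = pass,
    stringsAsFactors = FALSE
  )
  attr(rep, "overall") <- all(pass)
  rep
}

#' Cluster genome hits of candidate tags into putative loci
#'
#' Hits on the same chromosome and strand whose intervals lie within `gap`
#' nucleotides of each other are merged; each cluster carries the most
#' abundant member tag as its representative mature candidate.
#'
#' @param hits data.frame with columns tag, chrom, start, end, strand.
#' @param counts named numeric vector: total read count per tag sequence.
#' @param gap maximal merge distance (nt).
#' @return data.frame of clusters: chrom, start, end, strand, tag (the
#'   representative), tag_start, tag_end.
#' @export
cluster_hits <- function(hits, counts, gap = 10) {
  if (nrow(hits) == 0) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), tag = character(0),
                      tag_start = integer(0), tag_end = integer(0)))
  }
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start, hits$end),
                               strand = hits$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  members <- split(queryHits(ov), subjectHits(ov))
  rep_i <- vapply(members, function(m) m[which.max(counts[hits$tag[m]])],
                  integer(1))
  support <- vapply(members, function(m) {
    sum(counts[unique(hits$tag[m])])
  }, numeric(1))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red),
    end = GenomicRanges::end(red),
    strand = as.character(GenomicRanges::strand(red)),
    tag = hits$tag[rep_i],
    tag_start = hits$start[rep_i],
    tag_end = hits$end[rep_i],
    support = support,
    stringsAsFactors = FALSE
  )
}

#' Excise candidate precursor windows around a tag cluster
#'
#' For each cluster two windows are emitted, placing the representative tag as
#' the 5' arm (window extends downstream for loop and star) and as the 3' arm
#' (window extends upstream), each padded with `flank` nucleotides. Windows
#' exceeding chromosome bounds are clipped and flagged.
#'
#' @param clusters output of [cluster_hits()].
#' @param genome named character vector or DNAStringSet of chromosomes.
#' @param flank flank length (nt); criterion 9 checks this value.
#' @param max_space maximal loop spacing allowed between miRNA and miRNA*.
#' @return data.frame of windows with the precursor sequence (strand-adjusted,
#'   5'->3'), the mature offset within it, and the genomic location.
#' @export
excise_candidates <- function(clusters, genome, flank = 20, max_space = 30) {
  genome <- setNames(as.character(genome), names(genome))
  out <- vector("list", 2L * nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    chrom_seq <- genome[[cl$chrom]]
    clen <- nchar(chrom_seq)
    armlen <- cl$tag_end - cl$tag_start + 1L
    distal <- max_space + armlen + 4L + flank
    for (side in c("5p", "3p")) {
      if (side == "5p") {
        ws <- cl$start - flank; we <- cl$end + distal
      } else {
        ws <- cl$start - distal; we <- cl$end + flank
      }
      clipped <- ws < 1L || we > clen
      ws <- max(1L, ws); we <- min(clen, we)
      seq <- substr(chrom_seq, ws, we)
      if (cl$strand == "-") {
        seq <- revcomp(seq)
        mat_off <- we - cl$tag_end + 1L
      } else {
        mat_off <- cl$tag_start - ws + 1L
      }
      out[[2L * (i - 1L) + (side == "3p") + 1L]] <- data.frame(
        chrom = cl$chrom, start = ws, end = we, strand = cl$strand,
        arm_hint = side, precursor_seq = seq, mature_seq = cl$tag,
        mature_offset = mat_off, flank = flank, clipped = clipped,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Identify novel miRNAs from unannotated tags
#'
#' Runs the full discovery chain: select unannotated candidate tags within the
#' copy-number cap, cluster their genome hits, excise precursor windows, fold
#' them, locate the miRNA* duplex and apply the ten criteria. Overlapping
#' accepted windows on the same strand are merged, keeping the lowest-MFE
#' candidate.
#'
#' @param tag_table collapsed tag table (see [collapse_tags()]).
#' @param categories per-tag category assignment (see [classify_tags()]).
#' @param hits genome hits of the tags (see [lookup_tags()]).
#' @param genome named character vector / DNAStringSet of chromosomes.
#' @param backend folding backend.
#' @param thresholds criteria thresholds, see [novel_criteria_thresholds()].
#' @param libraries library-name columns of `tag_table` to report reads for.
#' @return list with `novel` (the accepted table: name, sequence, length,
#'   per-library reads, location, mfe) and `reports` (per-candidate criteria
#'   reports, including rejected candidates).
#' @export
identify_novel <- function(tag_table, categories, hits, genome,
                           backend = fold_backend_default(),
                           thresholds = novel_criteria_thresholds(),
                           libraries = NULL) {
  if (is.null(libraries)) {
    libraries <- grep("^count_", names(tag_table), value = TRUE)
  }
  counts_mat <- as.matrix(tag_table[, libraries, drop = FALSE])
  rownames(counts_mat) <- tag_table$sequence
  totals <- rowSums(counts_mat)

  copies <- table(hits$tag)
  cand_seqs <- categories$sequence[categories$category == "unannotated"]
  len <- nchar(cand_seqs)
  cand_seqs <- cand_seqs[len >= thresholds$mature_len[1] &
                         len <= thresholds$mature_len[2]]
  cand_seqs <- cand_seqs[cand_seqs %in% names(copies) &
                         copies[cand_seqs] <= thresholds$max_copies]
  cand_hits <- hits[hits$tag %in% cand_seqs, , drop = FALSE]
  clusters <- cluster_hits(cand_hits, totals)
  # neglect low-support loci before excision and folding: clusters whose tags
  # carry fewer than the criterion-10 read support in both libraries combined
  # cannot pass and are screened out up front
  if (!is.null(clusters) && nrow(clusters)) {
    clusters <- clusters[clusters$support >= thresholds$min_reads, , drop = FALSE]
  }
  empty <- data.frame(name = character(0), sequence = character(0),
                      length = integer(0), location = character(0),
                      mfe = numeric(0), stringsAsFactors = FALSE)
  if (is.null(clusters) || nrow(clusters) == 0) {
    return(list(novel = empty, reports = list()))
  }
  wins <- excise_candidates(clusters, genome, flank = thresholds$flank,
                            max_space = thresholds$max_space)
  folded <- fold_rna(wins$precursor_seq, backend)
  wins$structure <- folded$structure
  wins$mfe <- folded$mfe

  # read support per window: all tag hits falling inside, same strand
  all_gr <- GenomicRanges::GRanges(hits$chrom, IRanges::IRanges(hits$start, hits$end),
                                   strand = hits$strand)
  win_gr <- GenomicRanges::GRanges(wins$chrom, IRanges::IRanges(wins$start, wins$end),
                                   strand = wins$strand)
  ov <- GenomicRanges::findOverlaps(all_gr, win_gr, type = "within")
  win_members <- split(queryHits(ov), factor(subjectHits(ov),
                                             levels = seq_len(nrow(wins))))

  reports <- vector("list", nrow(wins))
  keep <- logical(nrow(wins))
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    dup <- find_duplex(w$structure, w$mature_offset, nchar(w$mature_seq))
    support_tags <- unique(hits$tag[win_members[[i]]])
    support <- colSums(counts_mat[support_tags, , drop = FALSE])
    cand <- list(mature_seq = w$mature_seq, mfe = w$mfe,
                 duplex_stats = dup$stats,
                 n_genomic_copies = as.integer(copies[w$mature_seq]),
                 flank = w$flank)
    rep_i <- check_criteria(cand, support, thresholds)
    reports[[i]] <- rep_i
    keep[i] <- dup$ok && attr(rep_i, "overall")
    wins$reads_str[i] <- paste(support, collapse = ",")
    for (lib in libraries) wins[[lib]][i] <- support[[lib]]
  }
  acc <- wins[keep, , drop = FALSE]
  if (nrow(acc) > 0) {
    # merge overlapping accepted windows (same strand), keep lowest MFE
    gr <- GenomicRanges::GRanges(acc$chrom, IRanges::IRanges(acc$start, acc$end),
                                 strand = acc$strand)
    red <- GenomicRanges::reduce(gr)
    ov2 <- GenomicRanges::findOverlaps(gr, red)
    pick <- vapply(seq_along(red), function(j) {
      members <- queryHits(ov2)[subjectHits(ov2) == j]
      members[which.min(acc$mfe[members])]
    }, integer(1))
    acc <- acc[pick, , drop = FALSE]
  }
  ord <- order(-rowSums(as.matrix(acc[, libraries, drop = FALSE])), acc$chrom, acc$start)
  acc <- acc[ord, , drop = FALSE]
  novel <- data.frame(
    name = if (nrow(acc)) paste0("novel_mir_", seq_len(nrow(acc))) else character(0),
    sequence = to_rna(acc$mature_seq),
    length = nchar(acc$mature_seq),
    stringsAsFactors = FALSE
  )
  for (lib in libraries) novel[[lib]] <- acc[[lib]]
  novel$location <- format_locus(acc$chrom, acc$start, acc$end, acc$strand)
  novel$mfe <- acc$mfe
  novel$precursor_seq <- acc$precursor_seq
  novel$structure <- acc$structure
  rownames(novel) <- NULL
  list(novel = novel, reports = reports)
}
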
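#' Parse the family from a mature miRNA name
#'
#' `vvi-miR156b` -> `miR156`; star strands (`vvi-miR3640*`) map to the same
#' family as their mature arm. Names without a `miR<digits>` core are
#' returned unchanged.
#'
#' @param name character vector of mature names.
#' @export
parse_family <- function(name) {
  m <- regexpr("miR[0-9]+", name)
  out <- name
  out[m > 0] <- regmatches(name, m)
  out
}

#' Match tags against a mature-miRNA reference with at most two mismatches
#'
#' The alignment model is ungapped: a tag is slid against each mature with an
#' end offset of at most `max_end_offset` nucleotides at either end (end
#' overhangs and truncations are not counted as mismatches but are capped),
#' and mismatches are counted over the aligned core (Hamming distance). For
#' each (tag, mature) pair the minimal mismatch count over admissible offsets
#' is reported; pairs above `max_mm` are dropped.
#'
#' @param tags character vector of tag sequences.
#' @param mature named character vector of reference mature sequences.
#' @param max_mm maximal mismatches (default 2).
#' @param max_end_offset maximal end overhang/truncation (default 2 nt).
#' @return data.frame with columns tag, mature_name, family, n_mismatches,
#'   is_annotated_mature.
#' @export
match_known <- function(tags, mature, max_mm = 2L, max_end_offset = 2L) {
  empty <- data.frame(tag = character(0), mature_name = character(0),
                      family = character(0), n_mismatches = integer(0),
                      is_annotated_mature = logical(0))
  if (!length(tags) || !length(mature)) return(empty)
  tags <- to_dna(tags)
  mature_dna <- to_dna(mature)
  res <- list()
  lens <- nchar(tags)
  for (mi in seq_along(mature_dna)) {
    mseq <- mature_dna[[mi]]
    lm <- nchar(mseq)
    best <- rep(Inf, length(tags))
    for (d in -max_end_offset:max_end_offset) {
      # tag position i aligns mature position i + d
      sel <- which(abs(lens + d - lm) <= max_end_offset)
      if (!length(sel)) next
      a <- max(1L, 1L + d)
      for (lt in unique(lens[sel])) {
        g <- sel[lens[sel] == lt]
        b <- min(lm, lt + d)
        if (b < a) next
        wid <- b - a + 1L
        tag_sub <- substr(tags[g], a - d, b - d)
        ref <- utf8ToInt(substr(mseq, a, b))
        mm <- colSums(matrix(utf8ToInt(paste(tag_sub, collapse = "")),
                             nrow = wid) != ref)
        best[g] <- pmin(best[g], mm)
      }
    }
    hit <- which(best <= max_mm)
    if (length(hit)) {
      res[[length(res) + 1]] <- data.frame(
        tag = tags[hit], mature_name = names(mature)[mi],
        n_mismatches = as.integer(best[hit]),
        is_annotated_mature = tags[hit] == mseq,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out$family <- parse_family(out$mature_name)
  out <- out[order(out$tag, out$n_mismatches, out$mature_name),
             c("tag", "mature_name", "family", "n_mismatches",
               "is_annotated_mature")]
  rownames(out) <- NULL
  out
}

#' Resolve multi-mature hits per tag
#'
#' Zero-mismatch hits outrank mismatched hits: only the minimal-mismatch hits
#' of each tag are kept. Remaining ties are kept as shared assignments
#' (`shared = TRUE`), mirroring fused row labels like `vvi-miR398b/c` in
#' published DEM tables.
#'
#' @param hits output of [match_known()].
#' @return the filtered hits with a `shared` column.
#' @export
resolve_hits <- function(hits) {
  if (!nrow(hits)) {
    hits$shared <- logical(0)
    return(hits)
  }
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$tag), function(i) {
    i[hits$n_mismatches[i] == min(hits$n_mismatches[i])]
  }), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  n_per_tag <- table(out$tag)
  out$shared <- as.integer(n_per_tag[out$tag]) > 1L
  rownames(out) <- NULL
  out
}

#' Per-mature read counts from resolved hits
#'
#' @param resolved output of [resolve_hits()].
#' @param tag_table collapsed tag table.
#' @param annotated_only if TRUE (default), only tags identical to the
#'   annotated mature sequence are counted (end/sequence variants -- isomiRs
#'   -- are listed separately and excluded), matching the convention that only
#'   the annotated mature is carried into differential expression.
#' @return data.frame mature_name, family, one `count_<library>` column per
#'   library, and `shared` (TRUE if any contributing tag was shared).
#' @export
per_mature_counts <- function(resolved, tag_table, annotated_only = TRUE) {
  libcols <- grep("^count_", names(tag_table), value = TRUE)
  h <- if (annotated_only) resolved[resolved$is_annotated_mature, , drop = FALSE]
       else resolved
  out <- data.frame(mature_name = unique(resolved$mature_name),
                    stringsAsFactors = FALSE)
  out$family <- parse_family(out$mature_name)
  idx <- match(h$tag, tag_table$sequence)
  for (lc in libcols) {
    s <- tapply(tag_table[[lc]][idx], h$mature_name, sum, default = 0)
    out[[lc]] <- as.numeric(s[out$mature_name])
    out[[lc]][is.na(out[[lc]])] <- 0
  }
  sh <- tapply(h$shared, h$mature_name, any)
  out$shared <- as.logical(sh[out$mature_name])
  out$shared[is.na(out$shared)] <- FALSE
  out[order(out$mature_name), , drop = FALSE]
}

#' Aggregate family-level read counts
#'
#' Family totals count each tag once per family (a tag shared between two
#' matures of the same family contributes its reads once), so the sum of
#' family totals never exceeds the total candidate-tag reads.
#'
#' @param resolved output of [resolve_hits()].
#' @param tag_table collapsed tag table.
#' @return data.frame family, n_members, one `reads_<library>` column per
#'   library.
#' @export
aggregate_families <- function(resolved, tag_table) {
  libcols <- grep("^count_", names(tag_table), value = TRUE)
  if (!nrow(resolved)) {
    out <- data.frame(family = character(0), n_members = integer(0))
    for (lc in libcols) out[[sub("^count_", "reads_", lc)]] <- numeric(0)
    return(out)
  }
  uu <- unique(resolved[, c("tag", "family")])
  idx <- match(uu$tag, tag_table$sequence)
  fams <- sort(unique(resolved$family))
  out <- data.frame(family = fams, stringsAsFactors = FALSE)
  memb <- tapply(resolved$mature_name, resolved$family,
                 function(x) length(unique(x)))
  out$n_members <- as.integer(memb[fams])
  for (lc in libcols) {
    s <- tapply(tag_table[[lc]][idx], uu$family, sum, default = 0)
    out[[sub("^count_", "reads_", lc)]] <- as.numeric(s[fams])
  }
  rownames(out) <- NULL
  out
}

#' List isomiR/sequence variants of known miRNAs
#'
#' Non-annotated variant tags (mismatch or end-shifted matches) with their
#' per-library counts.
#'
#' @param resolved output of [resolve_hits()].
#' @param tag_table collapsed tag table.
#' @return data.frame of variant tags with mature_name, n_mismatches and
#'   per-library counts.
#' @export
list_variants <- function(resolved, tag_table) {
  v <- resolved[!resolved$is_annotated_mature, , drop = FALSE]
  libcols <- grep("^count_", names(tag_table), value = TRUE)
  idx <- match(v$tag, tag_table$sequence)
  for (lc in libcols) v[[lc]] <- tag_table[[lc]][idx]
  rownames(v) <- NULL
  v
}
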
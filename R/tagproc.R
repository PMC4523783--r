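#' Read a FASTQ file into sequences and quality strings
#'
#' @param path FASTQ path (gzip allowed).
#' @return list with character vectors `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: ", path, " (", length(lines), " lines, truncated at record ",
         length(lines) %/% 4 + 1, ")")
  }
  heads <- lines[seq(1, length(lines), by = 4)]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad)) stop("malformed FASTQ record ", bad[1], ": missing @ header")
  list(seq = toupper(lines[seq(2, length(lines), by = 4)]),
       qual = lines[seq(4, length(lines), by = 4)])
}

# leftmost position where a prefix (>= min_match nt) of the adapter starts,
# allowing the adapter to run off the read end; 0 if none
find_adapter <- function(seqs, adapter, min_match = 6L) {
  seed <- substr(adapter, 1L, min_match)
  pos <- rep(0L, length(seqs))
  todo <- seq_along(seqs)
  offset <- rep(0L, length(seqs))
  rest <- seqs
  while (length(todo)) {
    p <- regexpr(seed, rest[todo], fixed = TRUE)
    found <- which(p > 0)
    if (!length(found)) break
    idx <- todo[found]
    abs_p <- offset[idx] + p[found]
    # verify the extension matches the adapter prefix
    ext <- substr(seqs[idx], abs_p, pmin(nchar(seqs[idx]), abs_p + nchar(adapter) - 1L))
    okay <- ext == substr(adapter, 1L, nchar(ext))
    pos[idx[okay]] <- abs_p[okay]
    # keep scanning past a false seed hit
    again <- idx[!okay]
    offset[again] <- abs_p[!okay]
    rest[again] <- substr(seqs[again], offset[again] + 1L, nchar(seqs[again]))
    todo <- again
  }
  pos
}

#' Clean raw small-RNA reads
#'
#' Trims the 3' adapter (leftmost exact match of at least 6 nt of its
#' prefix), then discards reads containing N, reads of mean Phred quality
#' below `qual_threshold`, and reads outside the 18-30 nt length window.
#' Untrimmed reads within the length window are kept (they may be full-length
#' inserts).
#'
#' @param reads list with `seq` and `qual` (see [read_fastq()]), or a
#'   `srna_library`.
#' @param adapter_3p 3' adapter sequence (non-empty).
#' @param qual_threshold minimal mean Phred score (default 20).
#' @param min_len,max_len retained insert length bounds.
#' @return list with clean `seq` and `qual`, a logical `kept` index into the
#'   input, and `tally`, a named vector partitioning removals by reason
#'   (adapter_trimmed counts trims, not discards).
#' @export
clean_reads <- function(reads, adapter_3p, qual_threshold = 20,
                        min_len = 18L, max_len = 30L) {
  stopifnot(nzchar(adapter_3p))
  seqs <- toupper(reads$seq)
  quals <- reads$qual
  adapter_3p <- to_dna(adapter_3p)

  pos <- find_adapter(seqs, adapter_3p)
  trimmed <- pos > 0L
  seqs[trimmed] <- substr(seqs[trimmed], 1L, pos[trimmed] - 1L)
  quals[trimmed] <- substr(quals[trimmed], 1L, pos[trimmed] - 1L)

  has_n <- grepl("N", seqs, fixed = TRUE)
  # mean Phred per read, vectorised over the concatenated quality string
  qlen <- nchar(quals)
  v <- utf8ToInt(paste(quals, collapse = "")) - 33L
  csum <- c(0, cumsum(v))
  ends <- cumsum(qlen)
  mq <- ifelse(qlen > 0, diff(csum[c(1L, ends + 1L)]) / qlen, 0)
  low_q <- !has_n & mq < qual_threshold
  len <- nchar(seqs)
  too_short <- !has_n & !low_q & len < min_len
  too_long <- !has_n & !low_q & len > max_len
  kept <- !(has_n | low_q | too_short | too_long)
  tally <- c(adapter_trimmed = sum(trimmed), contains_N = sum(has_n),
             low_quality = sum(low_q), too_short = sum(too_short),
             too_long = sum(too_long))
  list(seq = seqs[kept], qual = quals[kept], kept = kept, tally = tally,
       n_raw = length(reads$seq), n_clean = sum(kept))
}

#' Collapse clean reads into unique tags with per-library counts
#'
#' @param clean named list: library name -> character vector of clean read
#'   sequences.
#' @return data.frame with column `sequence` and one `count_<library>` column
#'   per library, ordered by total count (desc) then sequence; counts are
#'   conserved (column sums equal the clean-read counts).
#' @export
collapse_tags <- function(clean) {
  stopifnot(is.list(clean), !is.null(names(clean)))
  tabs <- lapply(clean, function(x) table(x))
  seqs <- sort(unique(unlist(lapply(tabs, names), use.names = FALSE)))
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (lib in names(tabs)) {
    cnt <- as.integer(tabs[[lib]][seqs])
    cnt[is.na(cnt)] <- 0L
    out[[paste0("count_", lib)]] <- cnt
  }
  if (nrow(out) > 0) {
    tot <- rowSums(as.matrix(out[, -1, drop = FALSE]))
    out <- out[base::order(-tot, out$sequence), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-library summary with tag-length histogram
#'
#' @param tag_table output of [collapse_tags()].
#' @param library library name (must match a `count_` column).
#' @param n_raw,n_clean optional raw/clean read counts from [clean_reads()].
#' @return list with `library_name`, `raw_reads`, `clean_reads`,
#'   `unique_tags` and `length_histogram` (length -> unique tags, total reads).
#' @export
library_summary <- function(tag_table, library, n_raw = NA, n_clean = NA) {
  col <- paste0("count_", library)
  stopifnot(col %in% names(tag_table))
  present <- tag_table[[col]] > 0
  len <- nchar(tag_table$sequence[present])
  cnt <- tag_table[[col]][present]
  hist <- data.frame(length = sort(unique(len)))
  hist$unique_tags <- vapply(hist$length, function(l) sum(len == l), numeric(1))
  hist$total_reads <- vapply(hist$length, function(l) sum(cnt[len == l]), numeric(1))
  list(library_name = library, raw_reads = n_raw,
       clean_reads = if (is.na(n_clean)) sum(cnt) else n_clean,
       unique_tags = sum(present), length_histogram = hist)
}

#' Write a collapsed tag table as FASTA (`>tag<serial>_x<count>`) and TSV
#'
#' @param tag_table output of [collapse_tags()].
#' @param prefix output path prefix; writes `<prefix>.fa` and `<prefix>.tsv`.
#' @export
write_tags <- function(tag_table, prefix) {
  counts <- rowSums(as.matrix(tag_table[, grep("^count_", names(tag_table)),
                                        drop = FALSE]))
  seqs <- setNames(tag_table$sequence,
                   paste0("tag", seq_len(nrow(tag_table)), "_x", counts))
  write_fasta(seqs, paste0(prefix, ".fa"))
  write.table(tag_table, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
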
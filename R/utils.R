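#' @import Biostrings
#' @import IRanges
#' @import GenomicRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
#' @importFrom stats rpois runif rbinom setNames cor.test
#' @importFrom utils write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Convert between DNA and RNA alphabets
#'
#' All sequences are handled internally in the DNA alphabet (T); miRNA-facing
#' outputs are reported in RNA (U), matching the convention of published
#' miRNA tables.
#'
#' @param x character vector of sequences.
#' @return character vector in the target alphabet, uppercase.
#' @export
to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname to_rna
#' @export
to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- to_dna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate random DNA sequences with a target GC fraction
#'
#' @param n number of sequences.
#' @param len length (recycled).
#' @param gc GC fraction in `[0, 1]`.
#' @return character vector of length `n`.
#' @export
random_seq <- function(n, len, gc = 0.5) {
  len <- rep_len(len, n)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(len, function(l) {
    paste(sample(DNA_BASES, l, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Format and parse genomic location strings
#'
#' Coordinates are 1-based, inclusive, strand-explicit, formatted
#' `chrom:start:end:strand` (e.g. `chr1:3865565:3865681:+`).
#'
#' @param chrom,start,end,strand location components.
#' @return `format_locus`: character vector; `parse_locus`: data.frame with
#'   columns chrom, start, end, strand.
#' @export
format_locus <- function(chrom, start, end, strand) {
  paste(chrom, start, end, strand, sep = ":")
}

#' @rdname format_locus
#' @param x character vector of location strings.
#' @export
parse_locus <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed location string: ", x[which(bad)[1]])
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.integer(vapply(parts, `[`, character(1), 2L)),
    end = as.integer(vapply(parts, `[`, character(1), 3L)),
    strand = vapply(parts, `[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
}

# Hamming distance between two equal-length sequences; Inf if lengths differ.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Inject k random substitutions into a sequence (never to the original base).
mutate_seq <- function(seq, k) {
  if (k == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(to_dna(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
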
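#' Score a miRNA/target-site duplex with plant-style complementarity penalties
#'
#' Penalty scheme for plant miRNA target prediction: match 0, G:U wobble 0.5,
#' mismatch 1, gap 2, with all penalties doubled at miRNA positions 2-13
#' (the seed-proximal and cleavage-competent core). The miRNA is given 5'->3';
#' the site is the target subsequence 5'->3' and is aligned antiparallel, so
#' miRNA position 1 pairs the last site position. Gaps (`-`) may appear in
#' either string of a pre-aligned duplex (at most one per site in scanning
#' practice).
#'
#' @param mirna miRNA sequence 5'->3' (RNA or DNA alphabet), possibly gapped.
#' @param site target site sequence 5'->3', possibly gapped; same aligned
#'   length as `mirna`.
#' @return list with `pair_states` (match/GU/mismatch/gap per aligned
#'   position, indexed from miRNA 5' position 1) and `score` (unrounded).
#' @export
score_site <- function(mirna, site) {
  m <- strsplit(to_dna(mirna), "")[[1]]
  s <- rev(strsplit(to_dna(site), "")[[1]])
  if (length(m) != length(s)) stop("mirna and site must have equal aligned length")
  if (any(!c(m, s) %in% c(DNA_BASES, "-"))) {
    stop("invalid character in duplex alignment")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  states <- character(length(m))
  score <- 0
  pos <- 0L
  for (i in seq_along(m)) {
    if (m[i] != "-") pos <- pos + 1L
    if (m[i] == "-" || s[i] == "-") {
      states[i] <- "gap"; pen <- 2
    } else if (comp[[m[i]]] == s[i]) {
      states[i] <- "match"; pen <- 0
    } else if ((m[i] == "G" && s[i] == "T") || (m[i] == "T" && s[i] == "G")) {
      states[i] <- "GU"; pen <- 0.5
    } else {
      states[i] <- "mismatch"; pen <- 1
    }
    if (pos >= 2 && pos <= 13) pen <- 2 * pen
    score <- score + pen
  }
  list(pair_states = states, score = score)
}

# penalty lookup used by the vectorised scanner (ungapped): rows = miRNA base,
# cols = target base; unknown characters score as mismatches
SITE_PENALTY <- local({
  p <- matrix(1, 5, 5, dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  p["A", "T"] <- p["T", "A"] <- p["C", "G"] <- p["G", "C"] <- 0
  p["G", "T"] <- p["T", "G"] <- 0.5
  p
})

#' Scan transcripts for miRNA target sites
#'
#' Exhaustive ungapped sliding-window scan of every transcript position; all
#' sites with penalty score at most `max_score` are reported. The expected
#' cleavage position is the transcript nucleotide paired to miRNA position 10
#' (between positions 10 and 11 of the guide). Multiple sites per transcript
#' are allowed.
#'
#' @param mirna named character vector of miRNA sequences (5'->3').
#' @param transcripts named character vector (or DNAStringSet) of transcript
#'   sequences.
#' @param max_score score cutoff (default 3.0).
#' @return data.frame with mirna_name, transcript_id, site_start, site_end
#'   (1-based transcript coordinates), score, expected_cleavage.
#' @export
scan_transcripts <- function(mirna, transcripts, max_score = 3.0) {
  transcripts <- setNames(to_dna(as.character(transcripts)), names(transcripts))
  if (is.null(names(transcripts))) stop("transcripts must be named")
  if (is.null(names(mirna))) names(mirna) <- paste0("mirna_", seq_along(mirna))
  res <- list()
  for (k in seq_along(mirna)) {
    mseq <- strsplit(to_dna(mirna[[k]]), "")[[1]]
    L <- length(mseq)
    mult <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
    mi <- match(mseq, rownames(SITE_PENALTY))
    if (anyNA(mi)) stop("invalid character in miRNA ", names(mirna)[k])
    for (tx in names(transcripts)) {
      tch <- strsplit(transcripts[[tx]], "")[[1]]
      n <- length(tch)
      if (n < L) next
      ti <- match(tch, rownames(SITE_PENALTY))
      ti[is.na(ti)] <- 5L
      nw <- n - L + 1L
      total <- numeric(nw)
      for (i in seq_len(L)) {
        # miRNA position i pairs transcript position (start + L - i)
        total <- total + SITE_PENALTY[cbind(mi[i], ti[(L - i + 1):(n - i + 1)])] * mult[i]
      }
      hit <- which(total <= max_score)
      if (length(hit)) {
        res[[length(res) + 1]] <- data.frame(
          mirna_name = names(mirna)[k], transcript_id = tx,
          site_start = hit, site_end = hit + L - 1L,
          score = total[hit], expected_cleavage = hit + L - 10L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(res)) {
    return(data.frame(mirna_name = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      score = numeric(0), expected_cleavage = integer(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise RACE clone 5' ends over a target site
#'
#' Cleavage positions from cloned 5'-RACE products are expressed relative to
#' the miRNA 5' end (the transcript position paired to miRNA position p maps
#' to offset p); fractions are reported over the total clone count, the way
#' cleavage-site diagrams annotate the fraction of clones terminating at each
#' position.
#'
#' @param site_start,site_end 1-based transcript coordinates of the aligned
#'   site.
#' @param clone_positions transcript positions of clone 5' ends.
#' @return list with `fraction_by_offset` (named numeric, offsets are
#'   miRNA-relative positions) and `modal_offset`.
#' @export
summarize_cleavage <- function(site_start, site_end, clone_positions) {
  if (!length(clone_positions)) stop("empty clone list")
  offsets <- site_end - clone_positions + 1L
  tab <- table(offsets)
  frac <- as.numeric(tab) / length(clone_positions)
  names(frac) <- names(tab)
  modal <- as.integer(names(frac)[which.max(frac)])
  list(fraction_by_offset = frac, modal_offset = modal)
}

#' Pearson correlation between miRNA and target expression series
#'
#' @param a,b numeric vectors on the same timepoint grid.
#' @return list with `r` and `p_value` (two-sided t-based).
#' @export
expression_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
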
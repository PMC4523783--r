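#' Transcripts-per-million normalisation with zero substitution
#'
#' `tpm = count / total_clean_reads * 1e6`; a zero count is substituted by
#' exactly 0.01 so that fold-changes against an undetected miRNA are defined
#' (library-exclusive miRNAs then show large finite fold-changes).
#'
#' @param count raw read count(s), >= 0.
#' @param total total clean reads of the library (> 0).
#' @return TPM value(s).
#' @export
tpm <- function(count, total) {
  if (any(total <= 0)) stop("total clean reads must be positive")
  if (any(count < 0)) stop("negative count")
  ifelse(count == 0, 0.01, count / total * 1e6)
}

#' Log2 fold-change between cold-treated and control libraries
#'
#' `log2(CT / NCT)`; both inputs must be positive (zero counts must already
#' have been substituted by [tpm()]).
#'
#' @param tpm_ct,tpm_nct TPM in the cold-treated and control library.
#' @export
fold_change <- function(tpm_ct, tpm_nct) {
  if (any(tpm_ct <= 0) || any(tpm_nct <= 0)) {
    stop("non-positive TPM: zero substitution was missed upstream")
  }
  log2(tpm_ct / tpm_nct)
}

#' Two-library exact p-value for tag counts
#'
#' Default method is the Audic-Claverie exact test for comparing a count x in
#' a library of N1 reads with a count y in a library of N2 reads:
#' with r = N2/N1, the conditional law of y given x is
#' p(y|x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1)),
#' i.e. y | x ~ NegBinomial(size = x+1, prob = N1/(N1+N2)). The two-sided
#' p-value doubles the smaller of the two directional enrichment tails --
#' observed-or-more-extreme y given x for enrichment in library 2, and
#' observed-or-more-extreme x given y for enrichment in library 1 -- capped
#' at 1. Evaluating each direction under its own conditioning makes the test
#' exactly symmetric under exchanging (x, N1) with (y, N2). Tails are
#' computed in log-space via the negative-binomial CDF, so extreme counts do
#' not overflow. The alternative method is a two-proportion normal (z) test
#' on x/N1 vs y/N2.
#'
#' @param x,y tag counts in the two libraries.
#' @param N1,N2 total reads of the two libraries.
#' @param method "audic-claverie" (default) or "two-proportion".
#' @return p-value(s) in `[0, 1]`, with attribute `method`.
#' @export
pvalue_two_library <- function(x, y, N1, N2,
                               method = c("audic-claverie", "two-proportion")) {
  method <- match.arg(method)
  stopifnot(all(x >= 0), all(y >= 0), all(x <= N1), all(y <= N2))
  if (method == "audic-claverie") {
    up_y <- stats::pnbinom(y - 1, size = x + 1, prob = N1 / (N1 + N2),
                           lower.tail = FALSE)
    up_x <- stats::pnbinom(x - 1, size = y + 1, prob = N2 / (N1 + N2),
                           lower.tail = FALSE)
    p <- pmin(1, 2 * pmin(up_y, up_x))
  } else {
    p1 <- x / N1; p2 <- y / N2
    pp <- (x + y) / (N1 + N2)
    se <- sqrt(pp * (1 - pp) * (1 / N1 + 1 / N2))
    z <- ifelse(se == 0, 0, (p2 - p1) / se)
    p <- 2 * stats::pnorm(-abs(z))
  }
  attr(p, "method") <- method
  p
}

#' Classify differential expression of one miRNA expression record
#'
#' Applies the study thresholds: records with TPM below `low_tpm` in both
#' libraries are neglected (`filtered_low`); otherwise `up` if the log2
#' fold-change exceeds `fc_min` with p <= `p_max`, `down` if it is below
#' `-fc_min` with p <= `p_max`, else `unchanged`. Classification uses
#' unrounded fold-changes.
#'
#' @param tpm_nct,tpm_ct TPM values (zero-substituted).
#' @param p p-value(s).
#' @param fc_min fold-change threshold (default 1, i.e. 2-fold).
#' @param p_max p-value threshold (default 0.001).
#' @param low_tpm low-expression filter (default 10 TPM).
#' @return character vector in {up, down, unchanged, filtered_low}.
#' @export
classify_dem <- function(tpm_nct, tpm_ct, p, fc_min = 1, p_max = 0.001,
                         low_tpm = 10) {
  fc <- fold_change(tpm_ct, tpm_nct)
  cls <- rep("unchanged", length(fc))
  cls[fc > fc_min & p <= p_max] <- "up"
  cls[fc < -fc_min & p <= p_max] <- "down"
  cls[tpm_nct < low_tpm & tpm_ct < low_tpm] <- "filtered_low"
  cls
}

#' Full differential-expression table from per-miRNA counts
#'
#' @param counts data.frame with columns `name`, `count_NCT`, `count_CT`.
#' @param total_nct,total_ct total clean reads per library.
#' @param method p-value method, see [pvalue_two_library()].
#' @param ... thresholds passed to [classify_dem()].
#' @return data.frame with TPM pair, log2 fold-change (2-decimal `fc_2dp`
#'   reporting column plus unrounded `fc`), p-value, BH-adjusted p (reported,
#'   unused for classification) and class.
#' @export
dem_table <- function(counts, total_nct, total_ct,
                      method = "audic-claverie", ...) {
  tn <- tpm(counts$count_NCT, total_nct)
  tc <- tpm(counts$count_CT, total_ct)
  p <- pvalue_two_library(counts$count_NCT, counts$count_CT, total_nct,
                          total_ct, method = method)
  fc <- fold_change(tc, tn)
  data.frame(
    name = counts$name,
    count_NCT = counts$count_NCT, count_CT = counts$count_CT,
    tpm_NCT = round(tn, 2), tpm_CT = round(tc, 2),
    fc = fc, fc_2dp = round(fc, 2),
    p_value = as.numeric(p),
    p_adj_BH = stats::p.adjust(as.numeric(p), method = "BH"),
    class = classify_dem(tn, tc, p, ...),
    stringsAsFactors = FALSE
  )
}

#' Expand fused miRNA row labels into member counts
#'
#' Published DEM tables fuse identical family members into one row:
#' `vvi-miR171a/i` (2 members), `vvi-miR398b/c` (2), `vvi-miR395a-m` (13).
#' Plain names, star strands and novel miRNAs count as one member.
#'
#' @param name character vector of row labels.
#' @return integer vector of member counts.
#' @export
expand_members <- function(name) {
  vapply(name, function(nm) {
    suffix <- sub(".*miR[0-9]+", "", nm)
    suffix <- sub("\\*$", "", suffix)
    if (grepl("^[a-z]-[a-z]$", suffix)) {
      letters_rng <- utf8ToInt(substr(suffix, 3, 3)) - utf8ToInt(substr(suffix, 1, 1)) + 1L
      return(as.integer(letters_rng))
    }
    if (grepl("/", suffix, fixed = TRUE)) {
      return(length(strsplit(suffix, "/", fixed = TRUE)[[1]]))
    }
    1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Classify a cold-stress expression time series into response groups
#'
#' Input series are relative expression values at 0, 2, 4, 8, 24 and 48 h of
#' cold exposure, normalised to 1 at 0 h. The four groups formalise the
#' qPCR validation patterns:
#' \describe{
#'   \item{II}{transient early rise: above control at 2 h, lower again by
#'     8 h, and on average repressed over the stress period.}
#'   \item{III}{early peak: maximum at 2-4 h above control, declining
#'     afterwards.}
#'   \item{IV}{late induction: repressed through 8 h but at least 2-fold
#'     induced at 48 h.}
#'   \item{I}{sustained early repression: minimum at 4 or 8 h and mean
#'     stress-period expression below control.}
#' }
#' Rules are tested in the order II, III, IV, I; a series matching none is
#' `unclassified` (e.g. a flat non-responsive control).
#'
#' @param values numeric vector of 6 relative expression values; the first
#'   must equal 1 (the 0 h reference).
#' @param timepoints hours, default `c(0, 2, 4, 8, 24, 48)`.
#' @return one of "I", "II", "III", "IV", "unclassified".
#' @export
classify_time_pattern <- function(values, timepoints = c(0, 2, 4, 8, 24, 48)) {
  stopifnot(length(values) == 6, length(timepoints) == 6, all(values > 0))
  if (abs(values[1] - 1) > 1e-8) stop("series must be normalised to 1 at 0 h")
  v <- values
  stress <- v[-1]
  stress_mean <- mean(stress)
  if (v[2] > 1 && v[4] < v[2] && stress_mean < 1) return("II")
  peak_at <- which.max(stress)  # index into 2,4,8,24,48 h
  if (peak_at %in% c(1, 2) && max(stress) > 1 && v[6] < max(stress) &&
      stress_mean > 1) return("III")
  if (v[4] == min(v[1:4]) && v[4] < 1 && v[6] >= 2) return("IV")
  min_at <- which.min(stress)
  if (min_at %in% c(2, 3) && stress_mean < 1) return("I")
  "unclassified"
}

#' Published grapevine cold-stress DEM reference table
#'
#' The differential-expression table reported by the grapevine cold-stress
#' sequencing study this workflow models: 29 rows of printed NCT/CT TPM
#' values (2 decimals), log2 fold-changes and p-values, with fused family
#' labels. Bundled as input data for reanalysis; `n_members` expands fused
#' labels.
#'
#' @return data.frame with columns name, tpm_NCT, tpm_CT, fc_printed,
#'   p_value, n_members.
#' @export
dem_table_published <- function() {
  path <- system.file("extdata", "dem_table_published.tsv", package = "coldmiR")
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tab$n_members <- expand_members(tab$name)
  tab
}
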
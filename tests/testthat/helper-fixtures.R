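# Shared fixtures, built once per test run. Everything is generated in code
# at test time; nothing is read from disk.
.fx <- new.env(parent = emptyenv())

fx_syn <- function() {
  if (is.null(.fx$syn)) {
    .fx$syn <- build_genome(
      synthetic_genome_spec(seed = 7, n_known_loci = 5, n_novel_loci = 3)
    )
  }
  .fx$syn
}

# simulated two-library experiment on the shared genome, plus the processed
# tag table, genome hits and category assignment
fx_sim <- function() {
  if (is.null(.fx$sim)) {
    syn <- fx_syn()
    p <- read_sim_params(total_reads = 30000, seed = 3)
    libs <- list(NCT = simulate_library(syn, p, "NCT"),
                 CT = simulate_library(syn, p, "CT"))
    clean <- lapply(libs, clean_reads, adapter_3p = p$adapter_3p)
    tags <- collapse_tags(lapply(clean, `[[`, "seq"))
    hits <- lookup_tags(build_index(syn$genome), tags$sequence)
    cats <- classify_tags(tags, hits, syn$ncrna, syn$annotation,
                          known = list(mature = syn$known_mature,
                                       precursor = syn$known_precursor))
    .fx$sim <- list(params = p, libs = libs, clean = clean, tags = tags,
                    hits = hits, cats = cats)
  }
  .fx$sim
}

# a noiseless simulation: no sequencing error, no isomiR offsets, no N or
# low-quality reads -- every miRNA read is the exact planted mature
fx_sim_clean <- function() {
  if (is.null(.fx$sim0)) {
    syn <- fx_syn()
    p <- read_sim_params(total_reads = 20000, seed = 5, error_rate = 0,
                         length_noise_prob = 0, n_base_fraction = 0,
                         low_quality_fraction = 0)
    .fx$sim0 <- list(params = p,
                     libs = list(NCT = simulate_library(syn, p, "NCT"),
                                 CT = simulate_library(syn, p, "CT")))
  }
  .fx$sim0
}

# a hairpin candidate that passes all ten criteria, for perturbation tests
fx_passing_candidate <- function() {
  list(mature_seq = strrep("A", 21), mfe = -45,
       duplex_stats = list(paired_bases = 19, bulge_max = 2, asymmetry = 1,
                           spacing = 12),
       n_genomic_copies = 1L, flank = 20L)
}

# independent direct-summation oracle for the two-library exact test:
# sums the conditional mass over the observed-or-more-extreme counts in each
# direction until the terms vanish
oracle_ac_pvalue <- function(x, y, N1, N2) {
  mass <- function(k, n, r) {
    exp(k * log(r) + lgamma(n + k + 1) - lgamma(n + 1) - lgamma(k + 1) -
          (n + k + 1) * log(1 + r))
  }
  tail_sum <- function(from, n, r) {
    acc <- 0; k <- from
    repeat {
      term <- mass(k, n, r)
      acc <- acc + term
      if ((k > from + 10 && term < acc * 1e-18) || k > from + 1e6) break
      k <- k + 1
    }
    acc
  }
  up_y <- tail_sum(y, x, N2 / N1)  # P(Y >= y | x)
  up_x <- tail_sum(x, y, N1 / N2)  # P(X >= x | y)
  min(1, 2 * min(up_y, up_x))
}

# independent per-window duplex recount from a pair table
oracle_duplex_stats <- function(structure, m1, m2) {
  ch <- strsplit(structure, "")[[1]]
  pt <- rep(NA_integer_, length(ch)); stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") { pt[i] <- stack[length(stack)]; pt[stack[length(stack)]] <- i
                        stack <- stack[-length(stack)] }
  }
  partners <- pt[m1:m2]; partners <- partners[!is.na(partners)]
  if (!length(partners) || (any(partners >= m1 & partners <= m2))) return(NULL)
  if (!(all(partners > m2) || all(partners < m1))) return(NULL)
  lo <- min(partners); hi <- max(partners)
  paired <- 0L; runs_m <- integer(0); run <- 0L
  for (i in m1:m2) {
    if (!is.na(pt[i]) && pt[i] >= lo && pt[i] <= hi) {
      paired <- paired + 1L
      if (run > 0) runs_m <- c(runs_m, run)
      run <- 0L
    } else run <- run + 1L
  }
  if (run > 0) runs_m <- c(runs_m, run)
  unp_s <- 0L; runs_s <- integer(0); run <- 0L
  for (i in lo:hi) {
    if (!is.na(pt[i]) && pt[i] >= m1 && pt[i] <= m2) {
      if (run > 0) runs_s <- c(runs_s, run); run <- 0L
    } else { unp_s <- unp_s + 1L; run <- run + 1L }
  }
  if (run > 0) runs_s <- c(runs_s, run)
  list(paired_bases = paired,
       bulge_max = max(c(0L, runs_m, runs_s)),
       asymmetry = abs((m2 - m1 + 1L - paired) - unp_s),
       spacing = if (all(pt[m1:m2] > m2, na.rm = TRUE)) lo - m2 - 1L else m1 - hi - 1L)
}

# brute-force ungapped known-miRNA matcher (per-character loops)
oracle_match_known <- function(tag, mature, max_mm = 2, max_off = 2) {
  best <- Inf
  lt <- nchar(tag); lm <- nchar(mature)
  for (d in -max_off:max_off) {
    if (abs(lt + d - lm) > max_off) next
    a <- max(1, 1 + d); b <- min(lm, lt + d)
    if (b < a) next
    mm <- 0
    for (i in a:b) {
      if (substr(tag, i - d, i - d) != substr(mature, i, i)) mm <- mm + 1
    }
    best <- min(best, mm)
  }
  best
}
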
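test_that("a spec without novel loci plants none, and packing overflow is named", {
  syn <- build_genome(synthetic_genome_spec(seed = 2, genome_length = 40000,
                                            n_known_loci = 2, n_novel_loci = 0,
                                            n_ncrna_loci = 4))
  expect_equal(sum(syn$truth$category == "novel_miRNA"), 0)
  expect_error(
    build_genome(synthetic_genome_spec(seed = 2, genome_length = 3000,
                                       n_known_loci = 10, n_novel_loci = 5,
                                       n_ncrna_loci = 10)),
    "infeasible packing.*chr")
})

test_that("the generator is byte-deterministic in its seed", {
  spec <- synthetic_genome_spec(seed = 13, genome_length = 50000,
                                n_known_loci = 2, n_novel_loci = 1,
                                n_ncrna_loci = 3)
  a <- build_genome(spec)
  b <- build_genome(spec)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  p <- read_sim_params(total_reads = 5000, seed = 21)
  expect_identical(simulate_library(a, p, "NCT"), simulate_library(b, p, "NCT"))
})

test_that("planted loci sit at their recorded coordinates on the recorded strand", {
  syn <- fx_syn()
  for (i in seq_len(nrow(syn$truth))) {
    tr <- syn$truth[i, ]
    gseq <- substr(syn$genome[[tr$chrom]], tr$start, tr$end)
    if (tr$strand == "-") gseq <- revcomp(gseq)
    expect_identical(gseq, tr$precursor_seq)
    if (!is.na(tr$mature_seq)) {
      expect_identical(substr(tr$precursor_seq, tr$mature_offset,
                              tr$mature_offset + nchar(tr$mature_seq) - 1L),
                       tr$mature_seq)
    }
  }
  # known matures appear verbatim in the emitted reference
  known <- syn$truth[syn$truth$category == "known_miRNA", ]
  expect_setequal(unname(syn$known_mature), known$mature_seq)
})

test_that("planted novel precursors pass the full ten-criteria check when re-excised", {
  syn <- fx_syn()
  backend <- fold_backend_default()
  novel <- syn$truth[syn$truth$category == "novel_miRNA", ]
  expect_gt(nrow(novel), 0)
  for (i in seq_len(nrow(novel))) {
    tr <- novel[i, ]
    mc_len <- nchar(tr$mature_seq)
    if (tr$strand == "+") {
      ms <- tr$start + tr$mature_offset - 1L
      me <- ms + mc_len - 1L
    } else {
      me <- tr$end - tr$mature_offset + 1L
      ms <- me - mc_len + 1L
    }
    cl <- data.frame(chrom = tr$chrom, start = ms, end = me, strand = tr$strand,
                     tag = tr$mature_seq, tag_start = ms, tag_end = me)
    wins <- excise_candidates(cl, syn$genome)
    folded <- fold_rna(wins$precursor_seq, backend)
    ok <- FALSE
    for (w in seq_len(nrow(wins))) {
      dup <- find_duplex(folded$structure[w], wins$mature_offset[w], mc_len)
      if (!dup$ok) next
      cand <- list(mature_seq = tr$mature_seq, mfe = folded$mfe[w],
                   duplex_stats = dup$stats, n_genomic_copies = 1L, flank = 20L)
      if (attr(check_criteria(cand, c(NCT = 100, CT = 100)), "overall")) ok <- TRUE
    }
    expect_true(ok, label = paste("planted locus", tr$name, "passes criteria"))
  }
})

test_that("zero-abundance loci are absent and noiseless reads are mature+adapter", {
  sim0 <- fx_sim_clean()
  syn <- fx_syn()
  truth <- syn$truth
  for (lib in c("NCT", "CT")) {
    l <- sim0$libs[[lib]]
    zero <- truth$name[truth$category %in% c("known_miRNA", "novel_miRNA") &
                       truth[[paste0("abundance_", lib)]] == 0]
    expect_false(any(l$origin %in% zero))
    mir <- l$origin %in% truth$name[!is.na(truth$mature_seq)]
    expected <- substr(
      paste0(truth$mature_seq[match(l$origin[mir], truth$name)],
             sim0$params$adapter_3p),
      1, sim0$params$read_length)
    expect_identical(l$seq[mir], expected)
  }
})

test_that("recovered counts are Poisson around the planted abundance", {
  spec <- synthetic_genome_spec(seed = 31, genome_length = 40000,
                                n_known_loci = 1, n_novel_loci = 0,
                                n_ncrna_loci = 2, dem_fraction = 0)
  syn <- build_genome(spec)
  syn$truth$abundance_NCT[1] <- 200
  counts <- vapply(1:10, function(s) {
    p <- read_sim_params(total_reads = 2000, seed = 100 + s, error_rate = 0,
                         length_noise_prob = 0)
    lib <- simulate_library(syn, p, "NCT")
    sum(lib$origin == syn$truth$name[1])
  }, numeric(1))
  se <- sqrt(200 / 10)
  expect_lt(abs(mean(counts) - 200), 3 * se)
})

test_that("noiseless collapsing recovers every planted mature with abundance >= 1", {
  sim0 <- fx_sim_clean()
  syn <- fx_syn()
  cl <- lapply(sim0$libs, clean_reads, adapter_3p = sim0$params$adapter_3p)
  tags <- collapse_tags(lapply(cl, `[[`, "seq"))
  for (lib in c("NCT", "CT")) {
    planted <- syn$truth[!is.na(syn$truth$mature_seq) &
                         syn$truth[[paste0("abundance_", lib)]] >= 1, ]
    drawn <- table(sim0$libs[[lib]]$origin)
    planted <- planted[planted$name %in% names(drawn), ]
    found <- tags[[paste0("count_", lib)]][match(planted$mature_seq, tags$sequence)]
    expect_true(all(!is.na(found) & found > 0),
                label = paste("all planted matures recovered in", lib))
  }
})

test_that("the synthetic bundle round-trips through its file formats", {
  syn <- build_genome(synthetic_genome_spec(seed = 2, genome_length = 40000,
                                            n_known_loci = 2, n_novel_loci = 0,
                                            n_ncrna_loci = 4))
  dir <- withr::local_tempdir()
  write_synthetic_data(syn, dir)
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(setNames(as.character(g), names(g)), syn$genome)
  tr <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tr), nrow(syn$truth))
  k <- Biostrings::readDNAStringSet(file.path(dir, "known_mirna.fa"))
  expect_true(all(names(syn$known_mature) %in% names(k)))
  p <- read_sim_params(total_reads = 2000, seed = 4)
  lib <- simulate_library(syn, p, "CT")
  fq <- file.path(dir, "ct.fq.gz")
  write_fastq(lib, fq)
  back <- read_fastq(fq)
  expect_identical(back$seq, lib$seq)
  expect_identical(back$qual, lib$qual)
})
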
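test_that("excised windows flank the tag cluster on both sides", {
  genome <- c(chr1 = random_seq(1, 400, 0.5))
  cl <- data.frame(chrom = "chr1", start = 100L, end = 120L, strand = "+",
                   tag = substr(genome[[1]], 100, 120),
                   tag_start = 100L, tag_end = 120L)
  wins <- excise_candidates(cl, genome, flank = 20)
  expect_equal(nrow(wins), 2)
  expect_true(all(wins$start <= 80 & wins$end >= 140))
  expect_false(any(wins$clipped))
  # chromosome-bound clipping is flagged
  cl2 <- transform(cl, start = 5L, end = 25L, tag_start = 5L, tag_end = 25L)
  wins2 <- excise_candidates(cl2, genome, flank = 20)
  expect_true(any(wins2$clipped))
  expect_true(all(wins2$start >= 1))
})

test_that("duplex statistics are exact on constructed hairpins", {
  mature <- "GCAGGCAGTTCGATCCAGGCA"  # 21 nt
  hp <- paste0(mature, strrep("A", 8), revcomp(mature))
  st <- paste0(strrep("(", 21), strrep(".", 8), strrep(")", 21))
  dup <- find_duplex(st, 1, 21)
  expect_true(dup$ok)
  expect_equal(dup$arm, "5p")
  expect_equal(dup$stats$paired_bases, 21)
  expect_equal(dup$stats$bulge_max, 0)
  expect_equal(dup$stats$asymmetry, 0)
  expect_equal(dup$stats$spacing, 8)
  # star interval carries the 2-nt 3' overhang convention
  expect_equal(dup$star_start, 32)

  # a mature spanning the terminal loop has no defined duplex
  loopy <- find_duplex(st, 15, 21)
  expect_false(loopy$ok)
  expect_equal(loopy$reason, "loop_spanning")

  # fully unpaired mature
  expect_equal(find_duplex(strrep(".", 60), 10, 21)$reason, "unpaired")
})

test_that("duplex stats equal a brute-force recount on random hairpins", {
  set.seed(11)
  backend <- fold_backend_default()
  n_checked <- 0
  for (i in 1:60) {
    mature <- random_seq(1, sample(19:23, 1), 0.5)
    star <- mutate_seq(revcomp(mature), sample(0:3, 1))
    hp <- paste0(random_seq(1, 12, .5), mature, random_seq(1, sample(6:20, 1), .5),
                 star, random_seq(1, 12, .5))
    f <- fold_rna(hp, backend)
    dup <- find_duplex(f$structure, 13, nchar(mature))
    if (!dup$ok) next
    oracle <- oracle_duplex_stats(f$structure, 13, 12 + nchar(mature))
    expect_equal(dup$stats, oracle)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 20)
})

test_that("each criterion trips on exactly its own perturbation", {
  cand <- fx_passing_candidate()
  support <- c(NCT = 120, CT = 80)
  base <- check_criteria(cand, support)
  expect_true(attr(base, "overall"))
  expect_true(all(base$pass))

  perturb <- list(
    list(field = "mfe", value = -17.5, criterion = 4),
    list(field = "paired_bases", value = 15, criterion = 6),
    list(field = "bulge_max", value = 5, criterion = 7),
    list(field = "asymmetry", value = 5, criterion = 8)
  )
  for (p in perturb) {
    c2 <- cand
    if (p$field == "mfe") c2$mfe <- p$value else c2$duplex_stats[[p$field]] <- p$value
    rep2 <- check_criteria(c2, support)
    expect_false(attr(rep2, "overall"))
    expect_equal(which(!rep2$pass), p$criterion,
                 label = paste("perturbing", p$field, "flips only criterion", p$criterion))
  }
  rep10 <- check_criteria(cand, c(NCT = 49, CT = 12))
  expect_equal(which(!rep10$pass), 10)
  # mature length rules: 24 nt passes the 18-25 rule but not the 20-23 rule
  c24 <- cand; c24$mature_seq <- strrep("A", 24)
  rep24 <- check_criteria(c24, support)
  expect_true(rep24$pass[1]); expect_false(rep24$pass[2])
})

test_that("read support below 50 in both libraries only ever revokes acceptance", {
  cand <- fx_passing_candidate()
  set.seed(3)
  for (i in 1:50) {
    c2 <- cand
    c2$mfe <- runif(1, -80, -10)
    c2$duplex_stats$paired_bases <- sample(10:21, 1)
    c2$duplex_stats$bulge_max <- sample(0:6, 1)
    high <- check_criteria(c2, c(NCT = sample(50:500, 1), CT = sample(50:500, 1)))
    low <- check_criteria(c2, c(NCT = sample(0:49, 1), CT = sample(0:49, 1)))
    # low support touches criterion 10 only, and can never grant acceptance
    expect_false(attr(low, "overall"))
    expect_identical(low$pass[1:9], high$pass[1:9])
    expect_false(low$pass[10])
  }
})

test_that("the criteria logic is independent of the folding backend", {
  # identical (structure, mfe) inputs must give identical reports
  st <- paste0(strrep("(", 20), strrep(".", 9), strrep(")", 20), ".")
  stub1 <- function(seqs) data.frame(structure = st, mfe = -33.3)
  stub2 <- function(seqs) data.frame(structure = st, mfe = -33.3)
  seqs <- random_seq(1, 50, .5)
  f1 <- fold_rna(seqs, stub1); f2 <- fold_rna(seqs, stub2)
  d1 <- find_duplex(f1$structure, 1, 20); d2 <- find_duplex(f2$structure, 1, 20)
  cand <- fx_passing_candidate()
  cand$duplex_stats <- d1$stats
  r1 <- check_criteria(cand, c(NCT = 60, CT = 0))
  cand$duplex_stats <- d2$stats
  r2 <- check_criteria(cand, c(NCT = 60, CT = 0))
  expect_identical(r1, r2)
})

test_that("tags above the copy cap yield no novel candidates", {
  tag <- "ACGTGATTCCAGGATCAACGT"
  genome <- c(chrA = paste(c(random_seq(1, 200, .5),
                             rep(paste0(tag, random_seq(1, 30, .5)), 25),
                             random_seq(1, 200, .5)), collapse = ""))
  tt <- collapse_tags(list(NCT = rep(tag, 80), CT = rep(tag, 10)))
  hits <- lookup_tags(build_index(genome), tt$sequence)
  cats <- data.frame(sequence = tag, category = "unannotated",
                     n_hits = nrow(hits))
  nv <- identify_novel(tt, cats, hits, genome)
  expect_equal(nrow(nv$novel), 0)
})

test_that("planted novel loci are recovered end-to-end and reported like a discovery table", {
  sim <- fx_sim()
  syn <- fx_syn()
  nv <- identify_novel(sim$tags, sim$cats, sim$hits, syn$genome)
  planted <- syn$truth[syn$truth$category == "novel_miRNA", ]
  expect_equal(nrow(nv$novel), nrow(planted))
  expect_setequal(to_dna(nv$novel$sequence), planted$mature_seq)
  # each reported locus contains its planted precursor
  loc <- parse_locus(nv$novel$location)
  for (i in seq_len(nrow(nv$novel))) {
    j <- match(to_dna(nv$novel$sequence[i]), planted$mature_seq)
    expect_equal(loc$chrom[i], planted$chrom[j])
    expect_lte(loc$start[i], planted$start[j] + 25)
    expect_gte(loc$end[i], planted$end[j] - 25)
    expect_equal(loc$strand[i], planted$strand[j])
  }
  expect_true(all(nv$novel$mfe <= -18))
  expect_true(all(nchar(nv$novel$sequence) >= 20 & nchar(nv$novel$sequence) <= 23))
})
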
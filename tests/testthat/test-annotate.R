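test_that("the exact-match index finds planted substrings on both strands", {
  syn <- fx_syn()
  idx <- build_index(syn$genome)
  q_plus <- substr(syn$genome[["chr1"]], 501, 521)
  hits <- lookup_tags(idx, q_plus)
  expect_true(any(hits$chrom == "chr1" & hits$start == 501 &
                  hits$end == 521 & hits$strand == "+"))
  q_minus <- revcomp(substr(syn$genome[["chr2"]], 1001, 1024))
  hits <- lookup_tags(idx, q_minus)
  expect_true(any(hits$chrom == "chr2" & hits$start == 1001 &
                  hits$strand == "-"))
  expect_equal(nrow(lookup_tags(idx, "ACGTNACGTNACGTNACGTN")), 0)
  expect_error(build_index(c(chr1 = "ACGT", chr1 = "ACGT")), "duplicate")
})

test_that("index lookups agree with a naive full-scan string search", {
  syn <- fx_syn()
  idx <- build_index(syn$genome)
  set.seed(42)
  n <- 300
  chrom <- sample(names(syn$genome), n, replace = TRUE)
  len <- sample(18:30, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(nchar(syn$genome[[chrom[i]]]) - len[i], 1)
  }, integer(1))
  tags <- substring(syn$genome[chrom], start, start + len - 1)
  tags[seq(1, n, by = 3)] <- revcomp(tags[seq(1, n, by = 3)])
  hits <- lookup_tags(idx, unique(tags))

  naive <- do.call(rbind, lapply(unique(tags), function(tg) {
    out <- NULL
    for (ch in names(syn$genome)) {
      for (str in c("+", "-")) {
        pat <- if (str == "+") tg else revcomp(tg)
        p <- gregexpr(pat, syn$genome[[ch]], fixed = TRUE)[[1]]
        p <- p[p > 0]
        if (length(p)) {
          out <- rbind(out, data.frame(tag = tg, chrom = ch, start = as.integer(p),
                                       end = as.integer(p) + nchar(tg) - 1L,
                                       strand = str))
        }
      }
    }
    out
  }))
  naive <- naive[order(naive$tag, naive$chrom, naive$start, naive$strand), ]
  rownames(naive) <- NULL
  expect_equal(hits, naive)
})

test_that("classification follows the fixed category priority", {
  syn <- fx_syn()
  rfrag <- substr(syn$ncrna[grep("^rRNA", names(syn$ncrna))][1], 10, 32)
  exon_tag <- substr(syn$genome[["chr1"]], 15, 35)  # planted exon feature
  tag_table <- collapse_tags(list(NCT = c(rfrag, exon_tag)))
  hits <- lookup_tags(build_index(syn$genome), tag_table$sequence)
  cats <- classify_tags(tag_table, hits, syn$ncrna, syn$annotation)
  expect_equal(cats$category[cats$sequence == rfrag], "rRNA")
  expect_equal(cats$category[cats$sequence == exon_tag], "exon_sense")
})

test_that("contaminant reads never leak into miRNA candidacy", {
  sim <- fx_sim()
  syn <- fx_syn()
  # contaminant-origin clean tags, identified through the generator ledger
  cont_tags <- unique(unlist(lapply(sim$libs, function(l) {
    cl <- clean_reads(l, sim$params$adapter_3p)
    cl$seq[l$origin[cl$kept] == "contaminant"]
  })))
  cls <- sim$cats$category[sim$cats$sequence %in% cont_tags]
  # error-free contaminant fragments are exact ncRNA substrings
  err_free <- cont_tags[match_substring(cont_tags, syn$ncrna)]
  cls0 <- sim$cats$category[sim$cats$sequence %in% err_free]
  expect_true(all(cls0 %in% c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")))
  expect_false(any(cls == "miRNA_candidate"))
})

test_that("categories partition the tag table and ignore reference order", {
  sim <- fx_sim()
  syn <- fx_syn()
  summ <- category_summary(sim$cats, sim$tags)
  expect_equal(sum(summ$unique_tags), nrow(sim$tags))
  expect_equal(sum(summ$total_reads),
               sum(sim$tags$count_NCT) + sum(sim$tags$count_CT))
  perm <- classify_tags(sim$tags, sim$hits, rev(syn$ncrna), syn$annotation,
                        known = list(mature = syn$known_mature,
                                     precursor = syn$known_precursor))
  expect_identical(perm$category, sim$cats$category)
})

test_that("tags above the genomic copy cap are flagged repeat-like", {
  tag <- "ACGTGATTCCAGGATCAACGT"
  genome <- c(chrA = paste(c(random_seq(1, 50, .5),
                             rep(c(tag, "TTTT"), 25)), collapse = ""))
  tt <- collapse_tags(list(NCT = tag))
  hits <- lookup_tags(build_index(genome), tag)
  expect_gt(nrow(hits), 20)
  cats <- classify_tags(tt, hits, character(0), NULL)
  expect_equal(cats$category, "repeat")
})
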
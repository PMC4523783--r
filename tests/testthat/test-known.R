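ref <- c("vvi-miR156a" = "TGACAGAAGAGAGTGAGCAC",
         "vvi-miR156b" = "TGACAGAAGAGAGTGAGCAT",
         "vvi-miR399a" = "TGCCAAAGGAGAGTTGCCCTG")

test_that("known matching honours the two-mismatch and end-offset rules", {
  hit <- match_known(ref[["vvi-miR156a"]], ref["vvi-miR156a"])
  expect_equal(hit$n_mismatches, 0)
  expect_true(hit$is_annotated_mature)
  expect_equal(hit$family, "miR156")

  three_mm <- "AGACAGAAGAGAGTGAGGGC"  # 3 substitutions vs miR156a
  expect_equal(nrow(match_known(three_mm, ref["vvi-miR156a"])), 0)

  # 2-nt 3' truncation: end offsets are capped but not counted as mismatches
  trunc <- substr(ref[["vvi-miR399a"]], 1, 19)
  hit <- match_known(trunc, ref["vvi-miR399a"])
  expect_equal(hit$n_mismatches, 0)
  expect_false(hit$is_annotated_mature)
  # a 3-nt truncation is out of reach
  expect_equal(nrow(match_known(substr(ref[["vvi-miR399a"]], 1, 18),
                                ref["vvi-miR399a"])), 0)
})

test_that("matching agrees with an exhaustive brute-force Hamming search", {
  syn <- fx_syn()
  set.seed(9)
  # random tags plus mutated copies of real matures to populate the 0-2 band
  tags <- unique(c(
    random_seq(150, sample(18:24, 150, replace = TRUE), 0.5),
    vapply(sample(syn$known_mature, 60, replace = TRUE),
           mutate_seq, character(1), k = 2),
    vapply(sample(syn$known_mature, 40, replace = TRUE),
           mutate_seq, character(1), k = 1)
  ))
  got <- match_known(tags, syn$known_mature)
  for (tg in tags) {
    for (mn in names(syn$known_mature)) {
      expected <- oracle_match_known(tg, syn$known_mature[[mn]])
      row <- got[got$tag == tg & got$mature_name == mn, ]
      if (expected <= 2) {
        expect_equal(nrow(row), 1)
        expect_equal(row$n_mismatches, expected)
      } else {
        expect_equal(nrow(row), 0)
      }
    }
  }
})

test_that("ties resolve to minimal mismatches with shared counting", {
  tag <- ref[["vvi-miR156a"]]
  hits <- match_known(tag, ref)
  # miR156a exact, miR156b at 1 mismatch
  expect_equal(sort(hits$mature_name), c("vvi-miR156a", "vvi-miR156b"))
  res <- resolve_hits(hits)
  expect_equal(res$mature_name, "vvi-miR156a")
  expect_false(res$shared)

  # equidistant tag (a and b differ only at position 20): shared assignment
  mid <- tag
  substr(mid, 20, 20) <- "G"
  res2 <- resolve_hits(match_known(mid, ref[1:2]))
  expect_equal(nrow(res2), 2)
  expect_true(all(res2$shared))
})

test_that("family aggregation sums members and counts shared tags once", {
  t1 <- ref[["vvi-miR156a"]]; t2 <- ref[["vvi-miR156b"]]
  tags <- collapse_tags(list(NCT = c(rep(t1, 10), rep(t2, 5))))
  res <- resolve_hits(match_known(tags$sequence, ref))
  fam <- aggregate_families(res, tags)
  expect_equal(fam$reads_NCT[fam$family == "miR156"], 15)
  expect_equal(fam$n_members[fam$family == "miR156"], 2)
  expect_lte(sum(fam$reads_NCT), sum(tags$count_NCT))

  empty <- aggregate_families(resolve_hits(match_known(character(0), ref)), tags)
  expect_equal(nrow(empty), 0)
})

test_that("noiseless family totals equal the planted abundances' draws", {
  sim0 <- fx_sim_clean()
  syn <- fx_syn()
  cl <- lapply(sim0$libs, clean_reads, adapter_3p = sim0$params$adapter_3p)
  tags <- collapse_tags(lapply(cl, `[[`, "seq"))
  res <- resolve_hits(match_known(tags$sequence, syn$known_mature))
  mc <- per_mature_counts(res, tags, annotated_only = TRUE)
  known <- syn$truth[syn$truth$category == "known_miRNA", ]
  drawn <- table(sim0$libs$NCT$origin)
  for (i in seq_len(nrow(known))) {
    nm <- known$name[i]
    expect_equal(mc$count_NCT[mc$mature_name == nm],
                 unname(as.numeric(drawn[nm])),
                 label = paste("annotated count of", nm))
  }
})

test_that("isomiR variants are listed but separated from annotated counts", {
  tag_var <- mutate_seq(ref[["vvi-miR399a"]], 1)
  tags <- collapse_tags(list(NCT = c(rep(ref[["vvi-miR399a"]], 4), rep(tag_var, 2))))
  res <- resolve_hits(match_known(tags$sequence, ref))
  mc <- per_mature_counts(res, tags, annotated_only = TRUE)
  expect_equal(mc$count_NCT[mc$mature_name == "vvi-miR399a"], 4)
  v <- list_variants(res, tags)
  expect_true(tag_var %in% v$tag)
  expect_equal(v$count_NCT[v$tag == tag_var], 2)
})
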
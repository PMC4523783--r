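test_that("duplex scoring follows the positional penalty table", {
  m <- "UGACAGAAGAGAGUGAGCAC"
  perfect <- score_site(m, revcomp(m))
  expect_equal(perfect$score, 0)
  expect_true(all(perfect$pair_states == "match"))

  # G:U wobble at miRNA position 15 (outside the doubled 2-13 core): 0.5
  m2 <- "ACGUACGUACGUACGUACGUA"  # 21 nt
  m4 <- m2; substr(m4, 15, 15) <- "G"
  site4 <- revcomp(m4); substr(site4, 21 - 15 + 1, 21 - 15 + 1) <- "T"
  s4 <- score_site(m4, site4)
  expect_equal(s4$pair_states[15], "GU")
  expect_equal(s4$score, 0.5)

  # single mismatch at position 5 (doubled region): 2.0
  m5 <- m2
  site5 <- revcomp(m5); substr(site5, 21 - 5 + 1, 21 - 5 + 1) <- "C"  # A vs C
  s5 <- score_site(m5, site5)
  expect_equal(s5$pair_states[5], "mismatch")
  expect_equal(s5$score, 2.0)

  # gap penalty, doubled inside the core
  m6 <- m2
  site6 <- revcomp(m6); substr(site6, 21 - 7 + 1, 21 - 7 + 1) <- "-"
  expect_equal(score_site(m6, site6)$score, 4.0)
  expect_error(score_site("ACXU", "ACGU"), "invalid character")
})

test_that("site scores are additive over the penalty table (4-mer enumeration)", {
  bases <- c("A", "C", "G", "T")
  penalty <- function(m, t, pos) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    p <- if (comp[[m]] == t) 0
         else if ((m == "G" && t == "T") || (m == "T" && t == "G")) 0.5
         else 1
    if (pos >= 2 && pos <= 13) 2 * p else p
  }
  set.seed(4)
  mers <- expand.grid(bases, bases, bases, bases, stringsAsFactors = FALSE)
  mirnas <- apply(mers, 1, paste, collapse = "")
  sites <- sample(mirnas, 40)
  for (m in sample(mirnas, 40)) {
    for (s in sites) {
      expected <- sum(vapply(1:4, function(i) {
        penalty(substr(m, i, i), substr(s, 4 - i + 1, 4 - i + 1), i)
      }, numeric(1)))
      expect_equal(score_site(m, s)$score, expected)
    }
  }
})

test_that("transcript scanning finds all sites at or below the cutoff", {
  m <- "UGACAGAAGAGAGUGAGCAC"
  set.seed(8)
  tx <- c(hit = paste0(random_seq(1, 40, .5), revcomp(m), random_seq(1, 30, .5)))
  res <- scan_transcripts(c(mir = m), tx, max_score = 3)
  exact <- res[res$score == 0, ]
  expect_equal(nrow(exact), 1)
  expect_equal(exact$site_start, 41)
  expect_equal(exact$site_end, 60)
  expect_equal(exact$expected_cleavage, exact$site_end - 9)

  # a planted single mismatch opposite miRNA position 18 scores 1.0
  site <- revcomp(m)
  pos <- nchar(m) - 18 + 1
  old <- substr(site, pos, pos)
  substr(site, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                    c(old, chartr("ACGU", "TGCA", substr(m, 18, 18))))[1]
  tx2 <- c(t2 = paste0(random_seq(1, 25, .5), site, random_seq(1, 25, .5)))
  res2 <- scan_transcripts(c(mir = m), tx2, max_score = 3)
  expect_true(any(res2$score == 1.0 & res2$site_start == 26))
})

test_that("scanning is complete against a brute-force window rescore", {
  set.seed(12)
  m <- random_seq(1, 21, 0.5)
  tx <- setNames(random_seq(3, 300, 0.5), paste0("tx", 1:3))
  got <- scan_transcripts(c(q = m), tx, max_score = 6)
  for (id in names(tx)) {
    n <- nchar(tx[[id]])
    for (s in seq_len(n - 21 + 1)) {
      sc <- score_site(m, substr(tx[[id]], s, s + 20))$score
      reported <- got$score[got$transcript_id == id & got$site_start == s]
      if (sc <= 6) {
        expect_equal(reported, sc)
      } else {
        expect_equal(length(reported), 0)
      }
    }
  }
})

test_that("cleavage summaries tally clone fractions by miRNA offset", {
  s <- summarize_cleavage(101, 121, rep(112, 8))
  expect_equal(unname(s$fraction_by_offset["10"]), 1.0)
  expect_equal(s$modal_offset, 10)

  s2 <- summarize_cleavage(101, 121, c(112, 112, 112, 111))
  expect_equal(unname(s2$fraction_by_offset[c("10", "11")]), c(0.75, 0.25))
  expect_equal(s2$modal_offset, 10)

  set.seed(5)
  clones <- sample(95:125, 40, replace = TRUE)
  s3 <- summarize_cleavage(101, 121, clones)
  expect_equal(sum(s3$fraction_by_offset), 1)
  tab <- table(121 - clones + 1)
  expect_equal(unname(s3$fraction_by_offset[names(tab)]),
               unname(as.numeric(tab) / 40))
  expect_error(summarize_cleavage(1, 21, integer(0)), "empty")
})

test_that("expression correlation is exact, affine-invariant and guarded", {
  t6 <- c(0, 2, 4, 8, 24, 48)
  a <- c(1, 0.8, 0.4, 0.5, 0.9, 1.3)
  expect_equal(expression_correlation(a, -a + 2)$r, -1)
  expect_equal(expression_correlation(a, a)$r, 1)
  set.seed(6)
  b <- runif(6)
  ref <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(expression_correlation(a, b)$r, ref, tolerance = 1e-12)
  expect_equal(expression_correlation(3 * a + 1, b)$r,
               expression_correlation(a, b)$r, tolerance = 1e-12)
  expect_error(expression_correlation(a, rep(1, 6)), "zero variance")
})
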
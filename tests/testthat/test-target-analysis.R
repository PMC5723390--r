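mir <- "TGACAGAAGAGAGTGAGCACA"  # 21 nt

perfect_site <- function(m = mir) rc(m)

# flip the site base opposite miRNA position k to a given target base
site_with <- function(pos, target_base, m = mir) {
  s <- strsplit(perfect_site(m), "")[[1]]
  # miRNA position k pairs site position (L - k + 1)
  s[nchar(m) - pos + 1] <- target_base
  paste(s, collapse = "")
}

test_that("target penalties follow the plant scoring conventions", {
  perfect <- target_score(mir, perfect_site())
  expect_equal(perfect$penalty, 0)
  expect_true(perfect$accepted)
  expect_equal(perfect$marks, strrep("|", 21))
  # G:U wobble at core position 2 costs 0.5 x 2
  gu_site <- site_with(2, "T")  # miRNA pos 2 is G, target T => G:U
  sc <- target_score(mir, gu_site)
  expect_equal(sc$penalty, 1.0)
  expect_equal(substr(sc$marks, 2, 2), "o")
  # mismatch at position 10: allen 2.0 accepted, schwab rejected
  mm10 <- site_with(10, "G")  # miRNA pos 10 is A; target G -> mismatch
  a <- target_score(mir, mm10, "allen")
  s <- target_score(mir, mm10, "schwab")
  expect_equal(a$penalty, 2.0)
  expect_true(a$accepted)
  expect_false(s$accepted)
  # non-core mismatch costs 1.0
  mm18 <- site_with(18, "A")  # miRNA pos 18 is C; target A -> mismatch
  expect_equal(target_score(mir, mm18)$penalty, 1.0)
  # length difference above 3 nt is an error
  expect_error(target_score(mir, substr(perfect_site(), 1, 15)),
               "more than 3")
})

test_that("adding imperfections never decreases the penalty", {
  set.seed(20)
  for (i in 1:25) {
    base_site <- perfect_site()
    k <- sample(21, 1)
    worse <- strsplit(base_site, "")[[1]]
    worse[k] <- sample(setdiff(c("A", "C", "G", "T"), worse[k]), 1)
    worse <- paste(worse, collapse = "")
    p0 <- target_score(mir, base_site)$penalty
    p1 <- target_score(mir, worse)$penalty
    expect_gte(p1, p0)
    # a second imperfection on top never helps either
    j <- sample(setdiff(1:21, k), 1)
    worst <- strsplit(worse, "")[[1]]
    worst[j] <- sample(setdiff(c("A", "C", "G", "T"), worst[j]), 1)
    expect_gte(target_score(mir, paste(worst, collapse = ""))$penalty, p1)
  }
})

test_that("transcriptome scanning equals exhaustive window scoring", {
  set.seed(21)
  transcripts <- tibble::tibble(
    id = sprintf("t%02d", 1:20),
    sequence = random_dna_str(20, 60))
  # plant one perfect site and one 2-mismatch site
  transcripts$sequence[3] <- paste0(substr(transcripts$sequence[3], 1, 20),
                                    perfect_site(),
                                    substr(transcripts$sequence[3], 41, 60))
  near <- strsplit(perfect_site(), "")[[1]]
  near[4] <- "A"; near[18] <- "C"
  transcripts$sequence[7] <- paste0(substr(transcripts$sequence[7], 1, 15),
                                    paste(near, collapse = ""),
                                    substr(transcripts$sequence[7], 37, 60))
  hits <- scan_targets(tibble::tibble(mirna_id = "m", sequence = mir),
                       transcripts)
  expect_true(any(hits$transcript_id == "t03" & hits$penalty == 0))
  # oracle: score every window of every transcript with target_score
  oracle <- list()
  for (ti in seq_len(nrow(transcripts))) {
    tseq <- transcripts$sequence[ti]
    n <- nchar(tseq)
    for (len in (21 - 3):(21 + 3)) {
      for (a in seq_len(n - len + 1)) {
        site <- substr(tseq, a, a + len - 1)
        sa <- target_score(mir, site, "allen")
        ss <- target_score(mir, site, "schwab")
        if (sa$accepted || ss$accepted) {
          oracle[[length(oracle) + 1]] <- data.frame(
            transcript_id = transcripts$id[ti], start = a,
            end = a + len - 1, penalty = sa$penalty)
        }
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  key <- function(d) sort(paste(d$transcript_id, d$start, d$end))
  expect_identical(key(hits), key(oracle))
  got <- hits[order(hits$transcript_id, hits$start, hits$end), ]
  ora <- oracle[order(oracle$transcript_id, oracle$start, oracle$end), ]
  expect_equal(got$penalty, ora$penalty, tolerance = 1e-9)
})

test_that("the pooled hits are the union of both rule sets", {
  tr <- tibble::tibble(id = "t1",
                       sequence = paste0(strrep("GTCA", 10),
                                         site_with(10, "G"),
                                         strrep("TGAC", 10)))
  hits <- scan_targets(tibble::tibble(mirna_id = "m", sequence = mir), tr)
  best <- hits[which.min(hits$penalty), ]
  expect_true(best$allen)
  expect_false(best$schwab)   # mismatch at position 10
  expect_true(all(hits$allen | hits$schwab))
})

test_that("DE filtering keeps exactly the listed transcripts", {
  pool <- tibble::tibble(
    mirna_id = "m", transcript_id = sprintf("t%d", 1:10),
    start = 1L, end = 21L, penalty = 0)
  de <- c("t2", "t4", "t6", "t8")
  kept <- filter_de_targets(pool, de)
  expect_setequal(kept$transcript_id, de)
  expect_equal(nrow(filter_de_targets(pool, character(0))), 0L)
  expect_equal(nrow(filter_de_targets(pool, pool$transcript_id)), 10L)
})

test_that("co-expression verdicts follow r and sign opposition", {
  s <- c(2, 1, 0.5, -1, 0.3)
  expect_equal(pair_inverse(s, -s)$verdict, "inverse")
  expect_equal(pair_inverse(s, s)$verdict, "positive")
  expect_equal(pair_inverse(s, -s)$r, -1)
  # anti-correlated but same sign at a responsive time is not inverse
  m <- c(2, 2, 2, 2, 0.1)
  t2 <- c(-2, -2, -2, -2, 4)
  v <- pair_inverse(m, t2, responsive_times = c(1, 3, 6, 12, 120))
  expect_equal(v$verdict, "uncorrelated")
  expect_equal(pair_inverse(rep(1, 5), s)$verdict, "uncorrelated")
})

test_that("ddCt relative expression matches hand arithmetic", {
  expect_equal(relative_expression(20, 18, 20, 18), 1)
  expect_equal(relative_expression(21, 18, 20, 18), 0.5)
  expect_equal(relative_expression(20, 18, 22, 18), 4)
})

test_that("cleavage positions convert to miRNA coordinates with mode", {
  # site [80, 100]: miRNA position 10 pairs transcript position 91
  cs <- cleavage_summary(rep(91L, 6), 80L, 100L)
  expect_equal(cs$mode_position, 10L)
  expect_equal(cs$mode_fraction, 1)
  cs2 <- cleavage_summary(c(91L, 91L, 91L, 90L), 80L, 100L)
  expect_equal(cs2$mode_position, 10L)
  expect_equal(cs2$mode_fraction, 0.75)
  expect_equal(sort(cs2$positions[[1]]), c(10L, 10L, 10L, 11L))
  expect_error(cleavage_summary(c(91L, 79L), 80L, 100L), "clone 2")
})
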
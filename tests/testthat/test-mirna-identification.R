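test_that("known-miRNA matching honours the mismatch and gap bounds", {
  ref <- tibble::tibble(id = c("mirA", "mirB"),
                        family = c("FAM1", "FAM2"),
                        sequence = c("TGACAGAAGAGAGTGAGCACA",
                                     "TTTGGATTGAAGGGAGCTCTA"))
  hit <- match_known("TGACAGAAGAGAGTGAGCACA", ref)
  expect_equal(hit$mirna_id, "mirA")
  expect_equal(hit$edits, 0L)
  # three substitutions exceed the bound (confirmed by the brute-force
  # oracle: the optimal alignment is the gapless 3-mismatch one)
  tag3 <- "TGACAGAAGAGAGTGAGCACA"
  substr(tag3, 5, 5) <- "T"; substr(tag3, 9, 9) <- "C"
  substr(tag3, 13, 13) <- "A"
  expect_false(bf_align(tag3, ref$sequence[1])$feasible)
  expect_equal(nrow(match_known(tag3, ref)), 0L)
  # two substitutions are accepted
  tag2 <- "TGACAGAAGAGAGTGAGCACA"
  substr(tag2, 1, 1) <- "C"; substr(tag2, 5, 5) <- "T"
  expect_equal(match_known(tag2, ref)$mismatches, 2L)
})

test_that("matching agrees with brute-force enumeration on toy pairs", {
  set.seed(42)
  n_agree <- 0L
  for (i in 1:200) {
    la <- sample(6:12, 1)
    tag <- random_dna_str(1, la)
    ref_seq <- if (runif(1) < 0.5) {
      # derive from the tag so near-misses are common
      ch <- strsplit(tag, "")[[1]]
      k <- sample(0:3, 1)
      if (k > 0) {
        pos <- sample(la, min(k, la))
        for (p in pos) ch[p] <- sample(c("A", "C", "G", "T"), 1)
      }
      drop <- sample(0:2, 1)
      if (drop > 0 && length(ch) - drop >= 4) {
        ch <- ch[-sample(length(ch), drop)]
      }
      paste(ch, collapse = "")
    } else random_dna_str(1, sample(6:12, 1))
    ref <- tibble::tibble(id = "r1", family = "F1", sequence = ref_seq)
    got <- match_known(tag, ref)
    oracle <- bf_align(tag, ref_seq)
    if (oracle$feasible) {
      expect_equal(nrow(got), 1L)
      expect_equal(got$edits, as.integer(oracle$edits))
    } else {
      expect_equal(nrow(got), 0L)
    }
    n_agree <- n_agree + 1L
  }
  expect_gte(n_agree, 190L)
})

test_that("assignment ties break to fewest edits then smallest id", {
  tag <- "TGACAGAAGAGAGTGAGCACA"
  one_off <- tag; substr(one_off, 3, 3) <- "T"
  ref <- tibble::tibble(id = c("mirZ", "mirA"),
                        family = c("F1", "F2"),
                        sequence = c(tag, one_off))
  expect_equal(match_known(tag, ref)$mirna_id, "mirZ")  # exact beats 1-edit
  ref2 <- tibble::tibble(id = c("mirZ", "mirA"),
                         family = c("F1", "F2"),
                         sequence = c(one_off, one_off))
  expect_equal(match_known(tag, ref2)$mirna_id, "mirA") # tie -> smaller id
})

test_that("the temporary database keeps the top expressed family member", {
  asg <- tibble::tibble(
    sequence = c("s1", "s2", "s3"),
    mirna_id = c("m1", "m2", "m3"),
    family = c("F1", "F1", "F2"),
    ref_sequence = c("AAAA", "CCCC", "GGGG"),
    edits = 0L, mismatches = 0L, gaps = 0L)
  tags <- tibble::tibble(
    sequence = c("s1", "s1", "s2", "s3"),
    library = c("G0", "W1", "G0", "G0"),
    count = c(10L, 15L, 10L, 7L))
  db <- build_temp_db(asg, tags)
  expect_equal(nrow(db), 2L)
  expect_equal(db$mirna_id[db$family == "F1"], "m1")   # 25 beats 10
  expect_equal(db$total_count[db$family == "F1"], 25L)
  # tie at equal totals -> lexicographically smaller id
  tags_tie <- dplyr::mutate(tags, count = c(5L, 5L, 10L, 7L))
  db_tie <- build_temp_db(asg, tags_tie)
  expect_equal(db_tie$mirna_id[db_tie$family == "F1"], "m1")
})

test_that("quantification sums tags gaplessly within two mismatches", {
  rep_seq <- "TGACAGAAGAGAGTGAGCACA"
  near <- rep_seq; substr(near, 2, 2) <- "A"
  db <- tibble::tibble(mirna_id = "m1", family = "F1", sequence = rep_seq)
  tags <- tibble::tibble(sequence = c(rep_seq, near),
                         library = "W1", count = c(3L, 4L))
  q <- quantify_known(tags, db)
  expect_equal(q$count[q$library == "W1"], 7L)
  # a tag within reach of two representatives counts once, best match
  far <- rep_seq; substr(far, 2, 2) <- "A"; substr(far, 4, 4) <- "A"
  db2 <- tibble::tibble(mirna_id = c("m1", "m2"), family = c("F1", "F2"),
                        sequence = c(rep_seq, near))
  q2 <- quantify_known(tibble::tibble(sequence = far, library = "W1",
                                      count = 5L), db2)
  expect_equal(q2$count[q2$mirna_id == "m2" & q2$library == "W1"], 5L)
  expect_equal(q2$count[q2$mirna_id == "m1" & q2$library == "W1"], 0L)
  # representatives with no matching tags keep a zero profile
  q3 <- quantify_known(tibble::tibble(sequence = strrep("TTTT", 5),
                                      library = "W1", count = 5L), db)
  expect_equal(nrow(q3), 1L)
  expect_equal(q3$count, 0L)
})

test_that("folding satisfies its basic thermodynamic contract", {
  for (backend in c("vienna", "stack")) {
    if (backend == "vienna" && !nzchar(Sys.which("RNAfold"))) next
    flat <- rna_fold(strrep("A", 60), backend = backend)
    expect_equal(flat$mfe, 0)
    expect_false(grepl("[()]", flat$structure))
    stem <- "GCGCTTGCATCCGGATACGTGCACG"
    hp <- paste0(stem, strrep("A", 8), rc(stem))
    f <- rna_fold(hp, backend = backend)
    expect_lt(f$mfe, -18)
    expect_gte(sum(strsplit(f$structure, "")[[1]] == "("), 20)
    expect_identical(rna_fold(hp, backend = backend),
                     rna_fold(hp, backend = backend))
  }
  expect_error(rna_fold("ACGTNACGT"), "non-ACGU")
})

test_that("each hairpin criterion rejects with its own reason code", {
  ok <- valid_hairpin_stats()
  expect_true(check_hairpin_criteria(ok)$accepted)
  cases <- list(
    list(field = "mature_len", value = 19L, reason = "mature_length"),
    list(field = "copy_number", value = 21L, reason = "copy_number"),
    list(field = "mfe", value = -17.5, reason = "mfe"),
    list(field = "arm_space", value = 301L, reason = "arm_space"),
    list(field = "duplex_pairs", value = 15L, reason = "duplex_pairs"),
    list(field = "duplex_bulge_max", value = 5L, reason = "duplex_bulge"),
    list(field = "duplex_asymmetry", value = 5L,
         reason = "duplex_asymmetry"),
    list(field = "flank_5p", value = 0L, reason = "flank"))
  for (cs in cases) {
    st <- ok
    st[[cs$field]] <- cs$value
    res <- check_hairpin_criteria(st)
    expect_false(res$accepted)
    expect_equal(res$reason, cs$reason)
  }
  # boundary values themselves are accepted
  at_bound <- ok
  at_bound$mfe <- -18
  at_bound$arm_space <- 300L
  at_bound$duplex_pairs <- 16L
  at_bound$duplex_bulge_max <- 4L
  at_bound$duplex_asymmetry <- 4L
  expect_true(check_hairpin_criteria(at_bound)$accepted)
})

test_that("novel calling rejects tags without hairpin support", {
  set.seed(9)
  tr <- tibble::tibble(id = "t1", sequence = random_dna_str(1, 400))
  inside <- substr(tr$sequence, 100, 120)
  out <- call_novel(inside, tr)
  expect_false(out$accepted)
  expect_true(out$reason %in% c("duplex_pairs", "mfe", "duplex_bulge",
                                "duplex_asymmetry", "arm_space"))
  # unmapped tag
  miss <- call_novel(random_dna_str(1, 21), tr)
  expect_false(miss$accepted)
  expect_equal(miss$reason, "unmapped")
  # empty transcriptome is an error
  expect_error(call_novel(inside, tr[0, ]), "non-empty")
})

test_that("no tag is both ncRNA-annotated and miRNA-assigned", {
  seqs <- c("TGACAGAAGAGAGTGAGCACA", "GGGATTGAGTGCACTCAGGAT")
  tags <- tibble::tibble(sequence = seqs, library = "G0", count = 10L)
  ncrna <- tibble::tibble(id = "r1", class = "rRNA",
                          sequence = paste0("AAAA", seqs[1], "TTTT"))
  ann <- annotate_ncrna(tags, ncrna)
  ref <- tibble::tibble(id = "m1", family = "F1", sequence = seqs[1])
  asg <- match_known(ann, ref)
  expect_false(seqs[1] %in% asg$sequence)
})
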
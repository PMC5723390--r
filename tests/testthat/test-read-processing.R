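fq_lines <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  as.vector(rbind(sprintf("@r%d", seq_along(seqs)), seqs,
                  rep("+", length(seqs)), quals))
}

test_that("cleaning enforces the 18-30 nt window and quality floor", {
  seqs <- c(strrep("A", 17), strrep("C", 18), strrep("G", 30),
            strrep("T", 31))
  out <- clean_reads(tibble::tibble(sequence = seqs))
  expect_equal(out$reads$sequence, seqs[2:3])
  expect_equal(out$stats$raw_reads, 4L)
  expect_equal(out$stats$clean_reads, 2L)
  # low-quality read removed
  rt <- tibble::tibble(sequence = rep(strrep("A", 20), 2),
                       quality = c(strrep("I", 20), strrep("#", 20)))
  out2 <- clean_reads(rt, quality_floor = 20)
  expect_equal(nrow(out2$reads), 1L)
  expect_equal(out2$stats$removed_quality, 1L)
})

test_that("a mixed fixture keeps exactly the hand-counted survivors", {
  set.seed(1)
  good <- random_dna_str(7, 21)
  short <- random_dna_str(3, 15)
  out <- clean_reads(tibble::tibble(sequence = c(short[1], good[1:3],
                                                 short[2:3], good[4:7])))
  expect_equal(out$stats$clean_reads, 7L)
  expect_setequal(out$reads$sequence, good)
})

test_that("cleaning an empty library returns zero counts", {
  out <- clean_reads(tibble::tibble(sequence = character(0)))
  expect_equal(nrow(out$reads), 0L)
  expect_equal(out$stats$clean_reads, 0L)
})

test_that("cleaning is idempotent on already-clean reads", {
  set.seed(2)
  reads <- tibble::tibble(sequence = random_dna_str(20, 24),
                          quality = strrep("I", 24))
  once <- clean_reads(reads)
  twice <- clean_reads(once$reads)
  expect_identical(once$reads, twice$reads)
  expect_equal(twice$stats$clean_reads, twice$stats$raw_reads)
})

test_that("3' adapters are trimmed before length filtering", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  core <- strrep("ACGT", 6)
  out <- clean_reads(tibble::tibble(sequence = paste0(core, adapter)),
                     adapter = adapter)
  expect_equal(out$reads$sequence, core)
  expect_equal(out$stats$adapter_trimmed, 1L)
})

test_that("malformed FASTQ records fail with their record index", {
  path <- withr::local_tempfile(fileext = ".fastq")
  lines <- fq_lines(c(strrep("A", 20), strrep("C", 20)))
  lines[5] <- "not_a_header"
  writeLines(lines, path)
  expect_error(read_fastq_tbl(path), "record 2")
  writeLines(lines[1:6], path)
  expect_error(read_fastq_tbl(path), "record 2")
  # quality/sequence length mismatch
  lines2 <- fq_lines(strrep("A", 20))
  lines2[4] <- "III"
  writeLines(lines2, path)
  expect_error(read_fastq_tbl(path), "record 1")
})

test_that("FASTQ round trip preserves reads", {
  path <- withr::local_tempfile(fileext = ".fastq")
  seqs <- c(strrep("ACGTT", 4), strrep("GGCAT", 5))
  writeLines(fq_lines(seqs), path)
  tbl <- read_fastq_tbl(path, library = "G0")
  expect_equal(tbl$sequence, seqs)
  expect_equal(unique(tbl$library), "G0")
})

test_that("tag collapsing counts unique sequences and conserves reads", {
  reads <- tibble::tibble(
    sequence = c("ACGTACGTACGTACGTAA", "ACGTACGTACGTACGTAA",
                 "TTTTACGTACGTACGTAC"),
    library = "W1")
  tags <- collapse_tags(reads)
  expect_equal(nrow(tags), 2L)
  expect_equal(tags$count[tags$sequence == "ACGTACGTACGTACGTAA"], 2L)
  # same sequence in two libraries stays one tag with two count entries
  reads2 <- dplyr::bind_rows(reads,
                             dplyr::mutate(reads[1, ], library = "D1"))
  tags2 <- collapse_tags(reads2)
  expect_equal(dplyr::n_distinct(tags2$sequence), 2L)
  expect_equal(nrow(tags2), 3L)
  # conservation over a random fixture
  set.seed(3)
  rnd <- tibble::tibble(
    sequence = sample(random_dna_str(30, 20), 500, replace = TRUE),
    library = sample(library_names(), 500, replace = TRUE))
  tg <- collapse_tags(rnd)
  per_lib_in <- table(rnd$library)
  per_lib_out <- tapply(tg$count, tg$library, sum)
  expect_equal(as.numeric(per_lib_out[names(per_lib_in)]),
               as.numeric(per_lib_in))
})

test_that("the count floor keeps tags reaching 5 reads in any library", {
  tags <- tibble::tibble(
    sequence = rep(c("A1", "A2", "A3"), each = 2),
    library = rep(c("G0", "W1"), 3),
    count = c(4L, 4L, 5L, 0L, 1L, 1L))
  kept <- min_count_filter(tags, threshold = 5)
  expect_setequal(unique(kept$sequence), "A2")
  # boundary: exactly 5 in one library is retained
  expect_true("A2" %in% kept$sequence)
  # threshold 1 keeps every tag with a nonzero count
  expect_equal(min_count_filter(tags, threshold = 1), tags)
  # stricter per-library reading zeroes sub-threshold entries
  strict <- min_count_filter(tags, threshold = 5, per_library = TRUE)
  expect_equal(nrow(strict), 1L)
  expect_equal(strict$library, "G0")
})

test_that("ncRNA annotation matches substrings with fixed precedence", {
  rref <- paste0(strrep("GATTACA", 10), "TGACAGAAGAGAGTGAGCACA",
                 strrep("CCGGA", 4))
  tag_in_r <- substr(rref, 71, 91)
  ncrna <- tibble::tibble(
    id = c("r1", "t1"), class = c("rRNA", "tRNA"),
    sequence = c(rref, paste0("AAAA", tag_in_r, "GGGG")))
  tags <- tibble::tibble(sequence = c(tag_in_r, strrep("ATGC", 6)),
                         library = "G0", count = 10L)
  ann <- annotate_ncrna(tags, ncrna)
  # matches both references: rRNA wins by precedence
  expect_equal(ann$annotation[ann$sequence == tag_in_r], "rRNA")
  expect_equal(ann$annotation[ann$sequence != tag_in_r], "unannotated")
  # no references: everything unannotated
  ann0 <- annotate_ncrna(tags, NULL)
  expect_true(all(ann0$annotation == "unannotated"))
  # reference without a valid class label is an error
  bad <- tibble::tibble(id = "x", class = "lncRNA", sequence = rref)
  expect_error(annotate_ncrna(tags, bad), "class")
})

test_that("library statistics partition clean reads exactly", {
  set.seed(4)
  tags <- tibble::tibble(
    sequence = random_dna_str(40, 21),
    library = sample(c("G0", "W1", "D1"), 40, replace = TRUE),
    count = sample(1:50, 40, replace = TRUE),
    annotation = sample(c("rRNA", "unannotated", "known_miRNA"), 40,
                        replace = TRUE))
  st <- library_stats(tags)
  by_class <- tapply(st$classes$reads, st$classes$library, sum)
  expect_equal(as.numeric(by_class[st$totals$library]),
               st$totals$clean_reads)
  by_len <- tapply(st$lengths$reads, st$lengths$library, sum)
  expect_equal(as.numeric(by_len[st$totals$library]),
               st$totals$clean_reads)
})
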
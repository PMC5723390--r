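#' Read a FASTQ file into a tibble
#'
#' Parses a (optionally gzipped) Sanger-encoded FASTQ file. Each record is
#' validated (marker lines, matching sequence/quality lengths) and a
#' malformed record raises an error naming its 1-based record index.
#'
#' @param path Path to a FASTQ file (`.gz` allowed).
#' @param library Optional library label attached to every read.
#' @return A tibble with columns `sequence`, `quality` (Sanger string) and,
#'   when `library` is given, `library`.
#' @export
read_fastq_tbl <- function(path, library = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("malformed FASTQ record %d in %s: truncated file",
                  length(lines) %/% 4L + 1L, path))
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    out <- tibble(sequence = character(0), quality = character(0))
    if (!is.null(library)) out$library <- character(0)
    return(out)
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ record %d in %s", bad[1], path))
  }
  out <- tibble(sequence = toupper(seqs), quality = qual)
  if (!is.null(library)) out$library <- library
  out
}

mean_phred <- function(quality) {
  vapply(quality, function(q) {
    if (!nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Clean raw small RNA reads
#'
#' Applies the standard small RNA cleaning pipeline to one library: 3'
#' adapter removal (first exact occurrence of the adapter string), length
#' filtering to the gel-selected small RNA range, and removal of
#' low-quality reads (mean Phred below `quality_floor`).
#'
#' @param reads A tibble with columns `sequence` and optionally `quality`,
#'   as returned by [read_fastq_tbl()], or a path to a FASTQ file.
#' @param min_len,max_len Retained read length range in nt (defaults 18-30,
#'   the gel size-selection window).
#' @param quality_floor Minimum mean Phred score; reads without a quality
#'   string are kept.
#' @param adapter Optional 3' adapter sequence to trim before filtering.
#' @param library Library label recorded in the statistics.
#' @return A list with `reads` (tibble of retained `sequence`s, plus
#'   `quality`/`library` when present) and `stats` (one-row tibble:
#'   `library`, `raw_reads`, `clean_reads`, `adapter_trimmed`,
#'   `removed_length`, `removed_quality`).
#' @export
clean_reads <- function(reads, min_len = 18L, max_len = 30L,
                        quality_floor = 20, adapter = NULL,
                        library = NA_character_) {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_fastq_tbl(reads,
                            library = if (!is.na(library)) library)
  }
  assert_that(is.data.frame(reads) && "sequence" %in% names(reads),
              "`reads` must be a tibble with a `sequence` column")
  reads <- as_tibble(reads)
  if ("library" %in% names(reads) && is.na(library) && nrow(reads)) {
    library <- reads$library[[1]]
  }
  raw_n <- nrow(reads)
  has_q <- "quality" %in% names(reads)
  n_trim <- 0L
  if (!is.null(adapter) && nzchar(adapter) && raw_n) {
    pos <- regexpr(adapter, reads$sequence, fixed = TRUE)
    hit <- pos > 0L
    n_trim <- sum(hit)
    reads$sequence[hit] <- substr(reads$sequence[hit], 1L, pos[hit] - 1L)
    if (has_q) {
      reads$quality[hit] <- substr(reads$quality[hit], 1L, pos[hit] - 1L)
    }
  }
  len <- nchar(reads$sequence)
  keep_len <- len >= min_len & len <= max_len
  n_len <- sum(!keep_len)
  reads <- reads[keep_len, , drop = FALSE]
  n_qual <- 0L
  if (has_q && nrow(reads)) {
    mq <- mean_phred(reads$quality)
    keep_q <- is.na(mq) | mq >= quality_floor
    n_qual <- sum(!keep_q)
    reads <- reads[keep_q, , drop = FALSE]
  }
  stats <- tibble(library = library, raw_reads = raw_n,
                  clean_reads = nrow(reads), adapter_trimmed = n_trim,
                  removed_length = n_len, removed_quality = n_qual)
  list(reads = reads, stats = stats)
}

#' Collapse cleaned reads into unique sequence tags
#'
#' Collapses reads to one row per unique sequence and library with its
#' read count, the atomic unit the rest of the pipeline works on. Counts
#' are conserved: per library they sum to the number of input reads.
#'
#' @param reads A tibble with columns `sequence` and `library`.
#' @return A tidy tag table: tibble with columns `sequence`, `library`,
#'   `count`, sorted by sequence.
#' @export
collapse_tags <- function(reads) {
  assert_that(all(c("sequence", "library") %in% names(reads)),
              "`reads` must have `sequence` and `library` columns")
  reads |>
    count(.data$sequence, .data$library, name = "count") |>
    arrange(.data$sequence, .data$library)
}

#' Remove tags below the expression noise floor
#'
#' Drops tags whose counts never reach `threshold` reads. Under the
#' default (global) reading a tag is retained iff its count is at least
#' `threshold` in at least one library, so a tag expressed strongly at a
#' single time point survives; `per_library = TRUE` applies the stricter
#' reading that zeroes counts below the threshold in each library
#' separately and drops tags left with no counts.
#'
#' @param tags Tidy tag table (`sequence`, `library`, `count`).
#' @param threshold Minimum per-library count (default 5 reads).
#' @param per_library Apply the threshold within each library separately.
#' @return Filtered tag table.
#' @export
min_count_filter <- function(tags, threshold = 5L, per_library = FALSE) {
  if (per_library) {
    tags <- filter(tags, .data$count >= threshold)
  } else {
    # max over libraries >= threshold <=> some row reaches the threshold
    keep <- unique(tags$sequence[tags$count >= threshold])
    tags <- filter(tags, .data$sequence %in% keep)
  }
  tags
}

NCRNA_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

#' Annotate tags matching structural non-coding RNA
#'
#' Flags tags that are exact substrings of a reference rRNA, tRNA, snRNA
#' or snoRNA sequence; such tags are excluded from miRNA calling
#' downstream. When a tag matches references of several classes, the fixed
#' precedence rRNA > tRNA > snRNA > snoRNA applies. Matching is exact
#' full-tag substring search, a reproducible stand-in for database
#' alignment.
#'
#' @param tags Tidy tag table (`sequence`, `library`, `count`).
#' @param ncrna_ref Tibble with columns `id`, `class` (one of rRNA, tRNA,
#'   snRNA, snoRNA) and `sequence`, e.g. from [read_fasta_tbl()] on a
#'   FASTA with `class=` header tags. A reference with a missing or
#'   unknown class is an error.
#' @return The tag table with an `annotation` column (`"rRNA"`, `"tRNA"`,
#'   `"snRNA"`, `"snoRNA"` or `"unannotated"`).
#' @export
annotate_ncrna <- function(tags, ncrna_ref) {
  seqs <- unique(tags$sequence)
  ann <- rep("unannotated", length(seqs))
  if (!is.null(ncrna_ref) && nrow(ncrna_ref) > 0) {
    assert_that(all(c("id", "class", "sequence") %in% names(ncrna_ref)),
                "`ncrna_ref` must have `id`, `class`, `sequence` columns")
    if (any(is.na(ncrna_ref$class)) ||
        !all(ncrna_ref$class %in% NCRNA_CLASSES)) {
      abort(paste0("ncRNA reference without a valid class label; classes ",
                   "must be one of: ", paste(NCRNA_CLASSES, collapse = ", ")))
    }
    for (cls in NCRNA_CLASSES) {
      refs <- ncrna_ref$sequence[ncrna_ref$class == cls]
      if (!length(refs)) next
      blob <- paste(toupper(refs), collapse = "NNNN")
      todo <- which(ann == "unannotated")
      hit <- vapply(seqs[todo], function(s) grepl(s, blob, fixed = TRUE),
                    logical(1), USE.NAMES = FALSE)
      ann[todo[hit]] <- cls
    }
  }
  left_join(tags, tibble(sequence = seqs, annotation = ann), by = "sequence")
}

#' Per-library composition statistics of an annotated tag table
#'
#' Summarises, per library, clean read totals and the partition of reads
#' by annotation class (the per-library audit table of a small RNA run),
#' together with the read length histogram.
#'
#' @param tags Tag table with `sequence`, `library`, `count` and
#'   optionally `annotation`.
#' @return A list with `classes` (tibble: `library`, `annotation`,
#'   `reads`), `totals` (tibble: `library`, `clean_reads`) and `lengths`
#'   (tibble: `library`, `length`, `reads`).
#' @export
library_stats <- function(tags) {
  if (!"annotation" %in% names(tags)) tags$annotation <- "unannotated"
  classes <- tags |>
    group_by(.data$library, .data$annotation) |>
    summarise(reads = sum(.data$count), .groups = "drop")
  totals <- tags |>
    group_by(.data$library) |>
    summarise(clean_reads = sum(.data$count), .groups = "drop")
  lengths <- tags |>
    mutate(length = nchar(.data$sequence)) |>
    group_by(.data$library, .data$length) |>
    summarise(reads = sum(.data$count), .groups = "drop")
  list(classes = classes, totals = totals, lengths = lengths)
}
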
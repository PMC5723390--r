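encode_seq <- function(x) {
  m <- match(strsplit(to_dna(x), "")[[1]], DNA_BASES) - 1L
  if (anyNA(m)) abort(paste0("non-ACGT/U character in sequence: ", x))
  m
}

#' Assign tags to known mature miRNAs
#'
#' Aligns each unannotated tag against a mature miRNA reference and
#' assigns it to the reference entry it matches within at most
#' `max_mismatch` substitutions and `max_gap` gap columns (counting every
#' indel column of a global alignment, terminal ones included). When
#' several references are in reach the tie is broken deterministically:
#' fewest total edits (substitutions + gap columns), then lexicographic
#' reference id.
#'
#' @param tags Tag table (`sequence`, ...) or character vector of tag
#'   sequences; tags already annotated as non-coding RNA are skipped.
#' @param mature_ref Tibble with columns `id`, `family`, `sequence`
#'   (mature miRNA reference, e.g. [read_fasta_tbl()] on a miRBase-style
#'   FASTA carrying `family=` header tags).
#' @param max_mismatch Maximum substitutions (default 2).
#' @param max_gap Maximum gap columns (default 3).
#' @return Tibble of assignments: `sequence`, `mirna_id`, `family`,
#'   `ref_sequence`, `edits`, `mismatches`, `gaps`. Unassigned tags are
#'   absent.
#' @export
match_known <- function(tags, mature_ref, max_mismatch = 2L, max_gap = 3L) {
  seqs <- if (is.character(tags)) unique(tags) else {
    t2 <- tags
    if ("annotation" %in% names(t2)) {
      t2 <- filter(t2, .data$annotation %in% c("unannotated", "candidate"))
    }
    unique(t2$sequence)
  }
  assert_that(is.data.frame(mature_ref) && nrow(mature_ref) > 0,
              "`mature_ref` must be a non-empty data frame")
  ref <- arrange(as_tibble(mature_ref), .data$id)
  ref$sequence <- to_dna(ref$sequence)
  ref_enc <- lapply(ref$sequence, encode_seq)
  ref_len <- nchar(ref$sequence)
  out <- vector("list", length(seqs))
  for (si in seq_along(seqs)) {
    s <- to_dna(seqs[si])
    # fast path: exact sequence match
    ex <- which(ref$sequence == s)
    if (length(ex)) {
      k <- ex[1]
      out[[si]] <- tibble(sequence = seqs[si], mirna_id = ref$id[k],
                          family = ref$family[k], ref_sequence = ref$sequence[k],
                          edits = 0L, mismatches = 0L, gaps = 0L)
      next
    }
    enc <- encode_seq(s)
    cand <- which(abs(ref_len - length(enc)) <= max_gap)
    best <- NULL
    for (k in cand) {
      r <- align_bounded_cpp(enc, ref_enc[[k]], max_mismatch, max_gap)
      if (r[1] < 0) next
      if (is.null(best) || r[1] < best$edits) {
        best <- list(k = k, edits = r[1], mm = r[2], gap = r[3])
      }
    }
    if (!is.null(best)) {
      k <- best$k
      out[[si]] <- tibble(sequence = seqs[si], mirna_id = ref$id[k],
                          family = ref$family[k], ref_sequence = ref$sequence[k],
                          edits = as.integer(best$edits),
                          mismatches = as.integer(best$mm),
                          gaps = as.integer(best$gap))
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(tibble(sequence = character(0), mirna_id = character(0),
                  family = character(0), ref_sequence = character(0),
                  edits = integer(0), mismatches = integer(0),
                  gaps = integer(0)))
  }
  list_rbind(out)
}

#' Build the temporary one-per-family miRNA database
#'
#' Collapses the mature reference to its expressed representatives: for
#' each miRNA family the member with the highest total expression (summed
#' assigned tag counts over all libraries) is selected; ties break to the
#' lexicographically smaller id. Families with no expressed member are
#' absent.
#'
#' @param assignments Output of [match_known()].
#' @param tags Tag table with `sequence`, `library`, `count`.
#' @return Tibble `mirna_id`, `family`, `sequence` (the representative's
#'   mature sequence), `total_count`.
#' @export
build_temp_db <- function(assignments, tags) {
  totals <- tags |>
    group_by(.data$sequence) |>
    summarise(total = sum(.data$count), .groups = "drop")
  assignments |>
    left_join(totals, by = "sequence") |>
    mutate(total = ifelse(is.na(.data$total), 0L, .data$total)) |>
    group_by(.data$mirna_id, .data$family, .data$ref_sequence) |>
    summarise(total_count = sum(.data$total), .groups = "drop") |>
    filter(.data$total_count > 0) |>
    group_by(.data$family) |>
    arrange(dplyr::desc(.data$total_count), .data$mirna_id,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(mirna_id = "mirna_id", family = "family",
           sequence = "ref_sequence", total_count = "total_count") |>
    arrange(.data$mirna_id)
}

# best gapless mismatch count of tag vs reference over all offsets of the
# shorter sequence inside the longer; NA when above `max_mm`.
gapless_mismatches <- function(tag_chars, ref_chars, max_mm) {
  a <- tag_chars; b <- ref_chars
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  la <- length(a); lb <- length(b)
  best <- NA_integer_
  for (off in 0:(lb - la)) {
    mm <- sum(a != b[(off + 1):(off + la)])
    if (is.na(best) || mm < best) best <- mm
  }
  if (!is.na(best) && best <= max_mm) best else NA_integer_
}

#' Quantify known miRNAs against the temporary database
#'
#' Per-library counts of each family representative are obtained by
#' summing the counts of all tags that align to it gaplessly within
#' `max_mismatch` substitutions (the shorter sequence slid along the
#' longer, mismatches counted in the overlap). A tag contributes to at
#' most one representative: the one with fewest mismatches, ties broken
#' by lexicographic id. Representatives with no matching tag keep a
#' zero profile.
#'
#' @param tags Tag table (`sequence`, `library`, `count`).
#' @param temp_db Output of [build_temp_db()], or any tibble with
#'   `mirna_id`, `family`, `sequence`.
#' @param max_mismatch Maximum substitutions (default 2); no gaps are
#'   allowed at this stage.
#' @return Tibble `mirna_id`, `family`, `sequence`, `library`, `count`
#'   with a row for every representative x library combination.
#' @export
quantify_known <- function(tags, temp_db, max_mismatch = 2L) {
  db <- arrange(as_tibble(temp_db), .data$mirna_id)
  db$sequence <- to_dna(db$sequence)
  seqs <- unique(tags$sequence)
  tag_chars <- lapply(to_dna(seqs), function(s) strsplit(s, "")[[1]])
  db_chars <- lapply(db$sequence, function(s) strsplit(s, "")[[1]])
  assign_to <- rep(NA_integer_, length(seqs))
  for (si in seq_along(seqs)) {
    best_mm <- NA_integer_
    for (k in seq_len(nrow(db))) {
      mm <- gapless_mismatches(tag_chars[[si]], db_chars[[k]], max_mismatch)
      if (!is.na(mm) && (is.na(best_mm) || mm < best_mm)) {
        best_mm <- mm
        assign_to[si] <- k
      }
    }
  }
  libs <- unique(tags$library)
  asg <- tibble(sequence = seqs, k = assign_to) |> filter(!is.na(.data$k))
  counted <- tags |>
    dplyr::inner_join(asg, by = "sequence") |>
    group_by(.data$k, .data$library) |>
    summarise(count = sum(.data$count), .groups = "drop")
  grid <- tidyr::expand_grid(k = seq_len(nrow(db)), library = libs)
  grid |>
    left_join(counted, by = c("k", "library")) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
           mirna_id = db$mirna_id[.data$k],
           family = db$family[.data$k],
           sequence = db$sequence[.data$k]) |>
    select("mirna_id", "family", "sequence", "library", "count") |>
    arrange(.data$mirna_id, .data$library)
}
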
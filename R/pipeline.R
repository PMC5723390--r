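#' Default pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its standard
#' value: read length window 18-30 nt, mean Phred floor 20, 5-count
#' noise floor, known-miRNA matching within 2 mismatches and 3 gaps,
#' gapless 2-mismatch quantification, the eight hairpin criteria
#' ([hairpin_criteria()]), |log2FC| >= 1 with p < 0.05 calling, RPM < 1
#' exclusion with 0.01 zero revision, r > 0.9 consistency, and target
#' penalty cutoff 4.0. Unknown option names are rejected.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `submir_options`.
#' @export
pipeline_options <- function(...) {
  defaults <- list(
    min_len = 18L, max_len = 30L, quality_floor = 20, adapter = NULL,
    min_count = 5L, min_count_per_library = FALSE,
    max_mismatch = 2L, max_gap = 3L, quant_max_mismatch = 2L,
    criteria = hairpin_criteria(),
    lfc_min = 1, p_max = 0.05, min_rpm = 1, zero_value = 0.01,
    r_min = 0.9, pair_r_min = 0.5,
    target_weights = target_weights(),
    fold_backend = "auto")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  assert_that(length(unknown) == 0,
              paste("unknown pipeline options:",
                    paste(unknown, collapse = ", ")))
  defaults[names(over)] <- over
  structure(defaults, class = "submir_options")
}

#' Run the full small RNA analysis pipeline
#'
#' Executes every stage on a tag table (e.g. from [simulate_libraries()]
#' or from cleaned, collapsed FASTQ input): count-floor filtering, ncRNA
#' annotation, known-miRNA matching, family collapsing and
#' quantification, novel miRNA calling, expression profiling with
#' responsiveness calls, target scanning for responsive miRNAs, DE
#' filtering against the mRNA matrix and inverse co-expression pairing.
#' A failing stage aborts with the stage name.
#'
#' @param tags Tag table (`sequence`, `library`, `count`).
#' @param mature_ref Known mature miRNA reference (`id`, `family`,
#'   `sequence`).
#' @param transcripts Transcriptome tibble (`id`, `sequence`).
#' @param ncrna_ref Optional ncRNA reference (`id`, `class`, `sequence`).
#' @param mrna_expr Optional transcript x library expression tibble
#'   (`transcript_id` + the 11 library columns) for DE filtering and
#'   pairing.
#' @param options Thresholds from [pipeline_options()].
#' @return A list of class `submir_report`: `tags` (annotated),
#'   `stats` (per-library class/length tables), `known` (assignments),
#'   `temp_db`, `counts` (known + novel per-library counts), `novel`
#'   (candidate table), `profiles` (`submir_profiles`), `hits`,
#'   `de_hits`, `pairs`, and `summary` (named list of the report
#'   tables).
#' @export
run_pipeline <- function(tags, mature_ref, transcripts, ncrna_ref = NULL,
                         mrna_expr = NULL, options = pipeline_options()) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  opt <- options
  # clean-read totals (the RPM denominators) are taken before the count
  # floor: the floor removes noise tags from analysis, not from the
  # library size
  clean_totals <- tags |>
    group_by(.data$library) |>
    summarise(clean_reads = sum(.data$count), .groups = "drop")
  tags <- stage("min_count", {
    min_count_filter(tags, threshold = opt$min_count,
                     per_library = opt$min_count_per_library)
  })
  tags <- stage("annotate_ncrna", {
    if (!is.null(ncrna_ref)) annotate_ncrna(tags, ncrna_ref)
    else mutate(tags, annotation = "unannotated")
  })
  known <- stage("match_known", {
    match_known(tags, mature_ref, max_mismatch = opt$max_mismatch,
                max_gap = opt$max_gap)
  })
  tags <- tags |>
    mutate(annotation = ifelse(
      .data$annotation == "unannotated" &
        .data$sequence %in% known$sequence,
      "known_miRNA", .data$annotation))
  temp_db <- stage("build_temp_db", build_temp_db(known, tags))
  known_counts <- stage("quantify_known", {
    quantify_known(filter(tags, .data$annotation == "known_miRNA"),
                   temp_db, max_mismatch = opt$quant_max_mismatch)
  })
  candidates <- tags |>
    filter(.data$annotation == "unannotated",
           nchar(.data$sequence) >= opt$criteria$mature_len[1],
           nchar(.data$sequence) <= opt$criteria$mature_len[2])
  novel <- stage("call_novel", {
    call_novel(candidates, transcripts, criteria = opt$criteria,
               backend = opt$fold_backend)
  })
  novel_acc <- filter(novel, .data$accepted)
  tags <- tags |>
    mutate(annotation = ifelse(
      .data$annotation == "unannotated" &
        .data$sequence %in% novel_acc$sequence,
      "candidate", .data$annotation))
  novel_counts <- candidates |>
    filter(.data$sequence %in% novel_acc$sequence) |>
    mutate(mirna_id = paste0("novel_tag_",
                             match(.data$sequence,
                                   sort(unique(.data$sequence))))) |>
    select("mirna_id", sequence2 = "sequence", "library", "count") |>
    rename(sequence = "sequence2") |>
    mutate(family = NA_character_) |>
    select("mirna_id", "family", "sequence", "library", "count")
  counts <- bind_rows(
    mutate(known_counts, origin = "known"),
    mutate(novel_counts, origin = "novel"))
  stats <- stage("library_stats", library_stats(tags))
  totals <- setNames(clean_totals$clean_reads, clean_totals$library)
  for (l in LIBRARY_NAMES) if (!l %in% names(totals)) totals[l] <- 1
  profiles <- stage("profile_expression", {
    profile_expression(counts, totals, lfc_min = opt$lfc_min,
                       p_max = opt$p_max, min_rpm = opt$min_rpm,
                       zero_value = opt$zero_value, r_min = opt$r_min)
  })
  calls <- profiles$calls |>
    left_join(distinct(counts, .data$mirna_id, .data$origin,
                       .data$sequence),
              by = "mirna_id")
  responsive <- filter(calls, .data$responsive)
  hits <- stage("scan_targets", {
    if (nrow(responsive)) {
      scan_targets(select(responsive, "mirna_id", "sequence"),
                   transcripts, weights = opt$target_weights)
    } else NULL
  })
  de_hits <- NULL
  pairs <- NULL
  if (!is.null(mrna_expr) && !is.null(hits) && nrow(hits)) {
    mrna_fc <- stage("mrna_fold_change", {
      list_rbind(lapply(seq_along(TIME_POINTS), function(i) {
        w <- paste0("W", TIME_POINTS[i]); d <- paste0("D", TIME_POINTS[i])
        tibble(transcript_id = mrna_expr$transcript_id,
               time = TIME_POINTS[i],
               log2fc = fold_change(mrna_expr[[w]], mrna_expr[[d]],
                                    min_rpm = opt$min_rpm,
                                    zero_value = opt$zero_value))
      }))
    })
    de_genes <- mrna_fc |>
      group_by(.data$transcript_id) |>
      summarise(de = any(!is.na(.data$log2fc) &
                           abs(.data$log2fc) >= opt$lfc_min),
                .groups = "drop") |>
      filter(.data$de) |>
      pull("transcript_id")
    de_hits <- stage("filter_de_targets", filter_de_targets(hits, de_genes))
    pairs <- stage("pair_inverse", {
      mir_fc <- profiles$fc |> filter(.data$comparison == "W_vs_D")
      best <- de_hits |>
        group_by(.data$mirna_id, .data$transcript_id) |>
        arrange(.data$penalty, .by_group = TRUE) |>
        dplyr::slice(1) |>
        ungroup()
      list_rbind(lapply(seq_len(nrow(best)), function(i) {
        mid <- best$mirna_id[i]; tid <- best$transcript_id[i]
        mf <- mir_fc |> filter(.data$mirna_id == mid) |>
          arrange(match(.data$time, TIME_POINTS)) |> pull("log2fc")
        tf <- mrna_fc |> filter(.data$transcript_id == tid) |>
          arrange(match(.data$time, TIME_POINTS)) |> pull("log2fc")
        qt <- mir_fc |>
          filter(.data$mirna_id == mid, !is.na(.data$log2fc),
                 abs(.data$log2fc) >= opt$lfc_min) |>
          pull("time")
        pv <- pair_inverse(mf, tf, responsive_times = qt,
                           r_min = opt$pair_r_min)
        tibble(mirna_id = mid, transcript_id = tid,
               penalty = best$penalty[i], r = pv$r, verdict = pv$verdict)
      }))
    })
  }
  summary <- list(
    library_classes = stats$classes,
    known_families = if (nrow(known)) {
      summarize_partition(
        known |> distinct(.data$mirna_id, .data$family) |>
          count(.data$family, name = "members") |>
          mutate(class = ifelse(.data$members == 1L, "single_member",
                                "multi_member")),
        class_col = "class")
    } else NULL,
    occupancy = summarize_partition(profiles$calls),
    timing = summarize_partition(
      filter(profiles$calls, .data$responsive), class_col = "timing"),
    n_known = dplyr::n_distinct(known_counts$mirna_id),
    n_novel = dplyr::n_distinct(novel_counts$mirna_id),
    n_responsive = sum(profiles$calls$responsive, na.rm = TRUE),
    n_de_targets = if (!is.null(de_hits)) {
      dplyr::n_distinct(de_hits$transcript_id)
    } else NA_integer_,
    pair_verdicts = if (!is.null(pairs)) count(pairs, .data$verdict)
                    else NULL)
  structure(list(tags = tags, stats = stats, known = known,
                 temp_db = temp_db, counts = counts, novel = novel,
                 profiles = profiles, hits = hits, de_hits = de_hits,
                 pairs = pairs, summary = summary, options = opt),
            class = "submir_report")
}

#' @export
print.submir_report <- function(x, ...) {
  s <- x$summary
  cat("<submir_report>\n")
  cat("  known miRNAs quantified:", s$n_known, "\n")
  cat("  novel miRNAs accepted:  ", s$n_novel, "\n")
  cat("  responsive:             ", s$n_responsive, "\n")
  if (!is.null(s$timing) && nrow(s$timing)) {
    cat("  timing:",
        paste(s$timing$class, s$timing$n, sep = "=", collapse = ", "),
        "\n")
  }
  if (!is.na(s$n_de_targets)) {
    cat("  DE target transcripts:  ", s$n_de_targets, "\n")
  }
  invisible(x)
}

#' Length histogram plot of a tag table
#'
#' @param tags Tag table (`sequence`, `library`, `count`).
#' @return A ggplot bar chart of total reads per read length.
#' @export
plot_length_distribution <- function(tags) {
  dat <- tags |>
    mutate(length = nchar(.data$sequence)) |>
    group_by(.data$length) |>
    summarise(reads = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$length, y = .data$reads)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::labs(x = "read length (nt)", y = "reads") +
    ggplot2::theme_minimal(base_size = 10)
}
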
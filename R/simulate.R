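DYNAMICS_CLASSES <- c("constant", "upland_specific", "pond_specific",
                      "early_up", "early_down", "late", "varied",
                      "consistent")

#' Configuration of the synthetic small RNA experiment
#'
#' Describes a simulated eleven-library wet/dry time-course experiment
#' with planted ground truth: known and novel miRNAs assigned to
#' expression dynamics classes, non-coding RNA contamination, degradation
#' background, and miRNA:target couplings. The defaults emulate the study
#' design the pipeline targets: one control library, five upland and five
#' pond libraries at 1, 3, 6, 12 and 120 h, a read length distribution
#' peaking at 24 nt then 21 nt, and 4-fold expression effects.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_known_mirnas,n_novel_mirnas Number of planted known/novel
#'   miRNAs (default 40 + 20).
#' @param n_transcripts Transcriptome size (default 200); the first
#'   `n_novel_mirnas` transcripts host the planted precursors.
#' @param library_names The 11 library labels (fixed design).
#' @param depth_per_library Reads per library (default 1e6).
#' @param dispersion Negative binomial dispersion: per-library counts are
#'   drawn with variance `mu * (1 + dispersion)`, i.e. the relative
#'   excess over Poisson sampling noise, the regime of technical
#'   variation around a pooled library (default 0.1).
#' @param effect_fold Fold-change magnitude of responsive dynamics
#'   classes (default 4, safely above the 2-fold calling threshold).
#' @param ncrna_fraction Expected fraction of reads from rRNA/tRNA/
#'   snRNA/snoRNA contamination, in `[0, 1)` (default 0.15).
#' @param mirna_fraction Expected fraction of reads from planted miRNAs
#'   (default 0.35); the remainder is mRNA degradation background.
#' @param dynamics_assignment Optional named character vector mapping
#'   miRNA ids to dynamics classes; by default classes are assigned
#'   round-robin over `constant`, `upland_specific`, `pond_specific`,
#'   `early_up`, `early_down`, `late`, `varied`, `consistent`.
#' @param baseline_rpm_range Range the per-miRNA baseline expression
#'   (RPM) is drawn from, log-normally (default 50-2000).
#' @param n_degradation_windows Size of the transcriptome-fragment
#'   window pool (default: twice the library depth).
#' @param degradation_fragment_share Fraction of the degradation reads
#'   drawn from recurrent transcriptome fragments (default 0.55); the
#'   rest is a diverse background of effectively unique reads. The
#'   fragment pool mean is kept well below the 5-count noise floor so
#'   that, as in real libraries, only a bounded number of recurrent
#'   fragments survive it.
#' @param mrna_noise Log-normal sd of multiplicative noise on the mRNA
#'   expression matrix (default 0.05; 0 gives exactly anti-correlated
#'   coupled targets).
#' @param low_quality_fraction Fraction of simulated reads written with a
#'   low-quality string to exercise cleaning (default 0).
#' @param adapter Optional 3' adapter appended to written reads to
#'   exercise trimming (default none).
#' @return A validated list of class `submir_config`.
#' @export
simulation_config <- function(seed = 42L, n_known_mirnas = 40L,
                              n_novel_mirnas = 20L, n_transcripts = 200L,
                              library_names = LIBRARY_NAMES,
                              depth_per_library = 1e6,
                              dispersion = 0.1, effect_fold = 4,
                              ncrna_fraction = 0.15, mirna_fraction = 0.35,
                              dynamics_assignment = NULL,
                              baseline_rpm_range = c(50, 2000),
                              n_degradation_windows = NULL,
                              degradation_fragment_share = 0.55,
                              mrna_noise = 0.05,
                              low_quality_fraction = 0, adapter = NULL) {
  assert_that(length(library_names) == 11L,
              "exactly 11 library names are required")
  assert_that(ncrna_fraction >= 0 && ncrna_fraction < 1,
              "`ncrna_fraction` must be in [0, 1)")
  assert_that(mirna_fraction > 0 && mirna_fraction < 1 &&
                ncrna_fraction + mirna_fraction < 1,
              "`mirna_fraction` + `ncrna_fraction` must be below 1")
  assert_that(low_quality_fraction >= 0 && low_quality_fraction < 1,
              "`low_quality_fraction` must be in [0, 1)")
  assert_that(depth_per_library > 0, "`depth_per_library` must be positive")
  assert_that(dispersion >= 0, "`dispersion` must be non-negative")
  assert_that(degradation_fragment_share >= 0 &&
                degradation_fragment_share <= 1,
              "`degradation_fragment_share` must be in [0, 1]")
  assert_that(effect_fold > 1, "`effect_fold` must exceed 1")
  assert_that(n_transcripts >= n_novel_mirnas + n_known_mirnas,
              "`n_transcripts` must accommodate precursors and targets")
  if (!is.null(dynamics_assignment)) {
    assert_that(all(dynamics_assignment %in% DYNAMICS_CLASSES),
                paste("dynamics classes must be among:",
                      paste(DYNAMICS_CLASSES, collapse = ", ")))
  }
  structure(list(
    seed = as.integer(seed), n_known_mirnas = as.integer(n_known_mirnas),
    n_novel_mirnas = as.integer(n_novel_mirnas),
    n_transcripts = as.integer(n_transcripts),
    library_names = library_names,
    depth_per_library = depth_per_library, dispersion = dispersion,
    effect_fold = effect_fold, ncrna_fraction = ncrna_fraction,
    mirna_fraction = mirna_fraction,
    dynamics_assignment = dynamics_assignment,
    baseline_rpm_range = baseline_rpm_range,
    n_degradation_windows = as.integer(
      n_degradation_windows %||% (2 * depth_per_library)),
    degradation_fragment_share = degradation_fragment_share,
    mrna_noise = mrna_noise,
    low_quality_fraction = low_quality_fraction, adapter = adapter),
    class = "submir_config")
}

# read length distribution of the non-miRNA background (18-30 nt),
# shaped so the aggregate library histogram peaks at 24 nt, then 21 nt
BACKGROUND_LENGTH_WEIGHTS <- setNames(
  c(0.035, 0.035, 0.04, 0.16, 0.05, 0.05, 0.34, 0.08, 0.07, 0.06, 0.05,
    0.02, 0.01),
  18:30)
MIRNA_LENGTH_WEIGHTS <- setNames(c(0.05, 0.45, 0.05, 0.05, 0.40), 20:24)

#' Construct a precursor hairpin around a mature miRNA
#'
#' Builds a stem-loop precursor (5' flank, mature arm, loop, star arm =
#' reverse complement of the mature with up to `imperfections` planted
#' mismatches, 3' flank) and verifies by folding that it satisfies all
#' hairpin acceptance criteria ([check_hairpin_criteria()]); random
#' flanks/loops are retried a bounded number of times and failure to
#' satisfy the criteria is an error.
#'
#' @param mature Mature miRNA sequence, 20-24 nt (shorter or longer is an
#'   error).
#' @param seed Integer seed; the same mature + seed give the identical
#'   precursor.
#' @param loop_len Loop length in nt (default 8).
#' @param flank_len Flank length on each side (default 20, the criterion
#'   value).
#' @param imperfections Number of mismatches planted into the star arm
#'   (default 0; at most 2).
#' @param criteria Acceptance thresholds ([hairpin_criteria()]).
#' @param backend Folding backend ([rna_fold()]).
#' @param max_tries Retry budget (default 25).
#' @return A list: `precursor` (DNA string), `mature_start`,
#'   `mature_end`, `star_start`, `star_end` (1-based), `structure`,
#'   `mfe`.
#' @export
make_hairpin <- function(mature, seed, loop_len = 8L, flank_len = 20L,
                         imperfections = 0L, criteria = hairpin_criteria(),
                         backend = "auto", max_tries = 25L) {
  mature <- to_dna(mature)
  mlen <- nchar(mature)
  if (mlen < criteria$mature_len[1] || mlen > criteria$mature_len[2]) {
    abort(sprintf("mature length %d outside [%d, %d] nt", mlen,
                  criteria$mature_len[1], criteria$mature_len[2]))
  }
  assert_that(imperfections <= 2, "at most 2 star imperfections")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      star <- revcomp(mature)
      if (imperfections > 0) {
        pos <- sample(2:(mlen - 1), imperfections)
        sc <- strsplit(star, "")[[1]]
        for (p in pos) sc[p] <- sample(setdiff(DNA_BASES, sc[p]), 1)
        star <- paste(sc, collapse = "")
      }
      loop <- paste(sample(c("A", "T"), loop_len, replace = TRUE),
                    collapse = "")
      # +4 nt margin so the criterion flank is still intact beyond the
      # 2 nt 3' overhang the star arm is assigned during evaluation
      f5 <- random_dna(1, flank_len + 4L)
      f3 <- random_dna(1, flank_len + 4L)
      precursor <- paste0(f5, mature, loop, star, f3)
      ms <- flank_len + 5L
      me <- flank_len + 4L + mlen
      an <- analyze_hairpin_locus(precursor, ms, me, criteria = criteria,
                                  backend = backend)
      st <- an$stats
      st$copy_number <- 1L
      chk <- check_hairpin_criteria(st, criteria)
      if (chk$accepted) {
        return(list(precursor = precursor, mature_start = ms,
                    mature_end = me,
                    star_start = me + loop_len + 1L,
                    star_end = me + loop_len + nchar(star),
                    structure = an$structure, mfe = st$mfe))
      }
    }
    abort(sprintf(
      "could not construct a criteria-satisfying hairpin for %s in %d tries",
      mature, max_tries))
  })
}

simulate_references <- function(config) {
  with_seed(config$seed, {
    nk <- config$n_known_mirnas
    nn <- config$n_novel_mirnas
    lens_k <- as.integer(sample(names(MIRNA_LENGTH_WEIGHTS), nk,
                                replace = TRUE,
                                prob = MIRNA_LENGTH_WEIGHTS))
    lens_n <- as.integer(sample(names(MIRNA_LENGTH_WEIGHTS), nn,
                                replace = TRUE,
                                prob = MIRNA_LENGTH_WEIGHTS))
    known_seq <- vapply(lens_k, function(l) random_dna(1, l), character(1))
    novel_seq <- vapply(lens_n, function(l) random_dna(1, l), character(1))
    # family structure: about 70% singleton families
    n_fam <- max(1L, ceiling(nk * 0.7))
    fam_of <- sort(c(seq_len(n_fam),
                     sample(seq_len(n_fam), nk - n_fam, replace = TRUE)))
    known <- tibble(
      id = sprintf("sim-miR%03d", seq_len(nk)),
      family = sprintf("MIRSIM%03d", fam_of),
      sequence = known_seq, origin = "known")
    novel <- tibble(
      id = sprintf("novel_mir_%02d", seq_len(nn)),
      family = NA_character_, sequence = novel_seq, origin = "novel")
    # transcriptome: random transcripts; the first nn host the planted
    # precursors of the novel miRNAs
    t_len <- sample(350:650, config$n_transcripts, replace = TRUE)
    t_seq <- vapply(t_len, function(l) random_dna(1, l), character(1))
    hairpins <- vector("list", nn)
    for (i in seq_len(nn)) {
      hp <- make_hairpin(novel_seq[i], seed = config$seed + i,
                         backend = "auto")
      ins <- sample(50:150, 1)
      t_seq[i] <- paste0(substr(t_seq[i], 1, ins), hp$precursor,
                         substr(t_seq[i], ins + 1, nchar(t_seq[i])))
      hairpins[[i]] <- tibble(
        mirna_id = novel$id[i], transcript_id = sprintf("contig%04d", i),
        precursor = hp$precursor,
        mature_start = ins + hp$mature_start,
        mature_end = ins + hp$mature_end, mfe = hp$mfe)
    }
    transcripts <- tibble(id = sprintf("contig%04d",
                                       seq_len(config$n_transcripts)),
                          sequence = t_seq)
    # one inverse-coupled target per responsive miRNA (and a positive
    # control pair per 'constant' novel miRNA is not planted); target
    # sites are exact reverse complements inserted into dedicated
    # transcripts after the precursor hosts
    all_mirnas <- bind_rows(known, novel)
    dyn <- config$dynamics_assignment
    if (is.null(dyn)) {
      # dynamics are assigned per family unit (members of a known family
      # share their class, so the family representative the
      # quantification stage reports has a well-defined planted truth)
      units <- c(unique(known$family), novel$id)
      unit_class <- setNames(rep(DYNAMICS_CLASSES, length.out =
                                   length(units)), units)
      dyn <- setNames(
        unit_class[ifelse(all_mirnas$origin == "known",
                          all_mirnas$family, all_mirnas$id)],
        all_mirnas$id)
    }
    all_mirnas$dynamics <- unname(dyn[all_mirnas$id])
    responsive_classes <- c("early_up", "early_down", "late", "varied",
                            "pond_specific", "upland_specific")
    tgt_mirnas <- all_mirnas$id[all_mirnas$dynamics %in%
                                  c("early_up", "early_down", "late",
                                    "varied")]
    tgt_slots <- nn + seq_along(tgt_mirnas)
    target_map <- tibble(
      mirna_id = tgt_mirnas,
      transcript_id = transcripts$id[tgt_slots],
      inverse = TRUE)
    site <- integer(0)
    tm_rows <- list()
    for (i in seq_along(tgt_mirnas)) {
      mseq <- all_mirnas$sequence[all_mirnas$id == tgt_mirnas[i]]
      ti <- tgt_slots[i]
      ins <- sample(80:200, 1)
      site_seq <- revcomp(mseq)
      old <- transcripts$sequence[ti]
      transcripts$sequence[ti] <- paste0(substr(old, 1, ins), site_seq,
                                         substr(old, ins + 1, nchar(old)))
      tm_rows[[i]] <- tibble(site_start = ins + 1L,
                             site_end = ins + nchar(site_seq))
    }
    target_map <- bind_cols(target_map, list_rbind(tm_rows))
    # ncRNA references
    ncrna <- bind_rows(
      tibble(id = sprintf("rRNA_%d", 1:3), class = "rRNA",
             sequence = random_dna(3, 150)),
      tibble(id = sprintf("tRNA_%d", 1:4), class = "tRNA",
             sequence = random_dna(4, 76)),
      tibble(id = sprintf("snRNA_%d", 1:3), class = "snRNA",
             sequence = random_dna(3, 140)),
      tibble(id = sprintf("snoRNA_%d", 1:3), class = "snoRNA",
             sequence = random_dna(3, 100)))
    list(mirnas = all_mirnas, transcripts = transcripts,
         hairpins = list_rbind(hairpins), ncrna = ncrna,
         target_map = target_map,
         responsive_classes = responsive_classes)
  })
}

# per-library mean multiplier of each dynamics class (relative to the
# miRNA's baseline); columns follow LIBRARY_NAMES
class_multipliers <- function(effect_fold) {
  f <- effect_fold
  m <- matrix(1, nrow = length(DYNAMICS_CLASSES), ncol = 11,
              dimnames = list(DYNAMICS_CLASSES, LIBRARY_NAMES))
  m["upland_specific", c("G0", pond_libraries())] <- 0
  m["pond_specific", c("G0", upland_libraries())] <- 0
  m["early_up", paste0("W", EARLY_TIMES)] <- f
  m["early_down", paste0("W", EARLY_TIMES)] <- 1 / f
  m["late", "W120"] <- f
  m["varied", "W1"] <- f
  m["varied", "W120"] <- 1 / f
  # consistent: same non-constant response in both treatments
  m["consistent", upland_libraries()] <- c(f, 1, 1, 1, f)
  m["consistent", pond_libraries()] <- c(f, 1, 1, 1, f)
  m
}

true_timing <- function(dynamics) {
  dplyr::case_when(
    dynamics %in% c("early_up", "early_down") ~ "early",
    dynamics == "late" ~ "late",
    dynamics %in% c("varied", "pond_specific", "upland_specific") ~ "varied",
    TRUE ~ "none")
}

rnb <- function(n, mu, dispersion) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    if (dispersion > 0) {
      out[pos] <- rnbinom(sum(pos), mu = mu[pos],
                          size = mu[pos] / dispersion)
    } else {
      out[pos] <- stats::rpois(sum(pos), mu[pos])
    }
  }
  out
}

#' Simulate the eleven small RNA libraries with planted ground truth
#'
#' Generates the collapsed tag table (and optionally FASTQ files) of the
#' simulated experiment: planted known and novel miRNA reads whose
#' per-library means follow the assigned dynamics class times negative
#' binomial noise, non-coding RNA contamination drawn from windows of the
#' simulated rRNA/tRNA/snRNA/snoRNA references, and an mRNA degradation
#' background filling each library to exactly `depth_per_library` reads.
#' The aggregate read length histogram peaks at 24 nt with a secondary
#' mode at 21 nt.
#'
#' @param config A [simulation_config()].
#' @param fastq_dir Optional directory; when given, one
#'   `<library>.fastq` file per library is written
#'   (see [write_simulated_fastq()]).
#' @return A list of class `submir_sim`: `tags` (tibble `sequence`,
#'   `library`, `count`, `source`, `mirna_id`), `truth` (per-miRNA truth
#'   table with dynamics, expected responsiveness/timing and targets),
#'   `references` (mirnas, transcripts, hairpins, ncrna, target_map),
#'   `library_totals` (named vector, all equal to the depth) and
#'   `config`.
#' @export
simulate_libraries <- function(config, fastq_dir = NULL) {
  refs <- simulate_references(config)
  libs <- config$library_names
  depth <- config$depth_per_library
  mult <- class_multipliers(config$effect_fold)
  sim <- with_seed(config$seed + 1000L, {
    mir <- refs$mirnas
    n_mir <- nrow(mir)
    base_rpm <- exp(rnorm(n_mir, mean = log(300), sd = 0.8))
    base_rpm <- pmin(pmax(base_rpm, config$baseline_rpm_range[1]),
                     config$baseline_rpm_range[2])
    # rescale so miRNA reads take about mirna_fraction of each library
    scale <- config$mirna_fraction * 1e6 / sum(base_rpm)
    base_rpm <- base_rpm * scale
    mu_mat <- outer(base_rpm, rep(1, length(libs))) *
      mult[mir$dynamics, libs, drop = FALSE] * depth / 1e6
    mir_counts <- list_rbind(lapply(seq_along(libs), function(li) {
      tibble(sequence = mir$sequence, library = libs[li],
             count = rnb(n_mir, mu_mat[, li], config$dispersion),
             source = "mirna", mirna_id = mir$id)
    }))
    # ncRNA contamination: a few fixed windows per reference
    nc_windows <- list_rbind(lapply(seq_len(nrow(refs$ncrna)), function(i) {
      ref <- refs$ncrna[i, ]
      n_win <- 4L
      wl <- as.integer(sample(names(BACKGROUND_LENGTH_WEIGHTS), n_win,
                              replace = TRUE,
                              prob = BACKGROUND_LENGTH_WEIGHTS))
      st <- vapply(wl, function(l) {
        sample.int(nchar(ref$sequence) - l + 1L, 1L)
      }, integer(1))
      tibble(sequence = substr(rep(ref$sequence, n_win), st, st + wl - 1L),
             source = ref$class, weight = exp(rnorm(n_win, sd = 0.8)))
    }))
    nc_mu <- config$ncrna_fraction * depth * nc_windows$weight /
      sum(nc_windows$weight)
    nc_counts <- list_rbind(lapply(libs, function(l) {
      tibble(sequence = nc_windows$sequence, library = l,
             count = rnb(nrow(nc_windows), nc_mu, config$dispersion),
             source = nc_windows$source, mirna_id = NA_character_)
    }))
    # Degradation background fills each library to exactly `depth`.
    # Two components mirror real libraries: recurrent mRNA fragments
    # (a uniform pool of transcriptome windows kept at low mean so only
    # a bounded number pass the count floor) and a diverse unassigned
    # background of effectively unique reads that never reaches it.
    n_deg <- config$n_degradation_windows
    t_idx <- sample.int(nrow(refs$transcripts), n_deg, replace = TRUE)
    dl <- as.integer(sample(names(BACKGROUND_LENGTH_WEIGHTS), n_deg,
                            replace = TRUE,
                            prob = BACKGROUND_LENGTH_WEIGHTS))
    t_seqs <- refs$transcripts$sequence[t_idx]
    max_st <- nchar(t_seqs) - dl + 1L
    st <- floor(runif(n_deg) * max_st) + 1L
    deg_pool <- unique(substr(t_seqs, st, st + dl - 1L))
    remaining <- vapply(libs, function(l) {
      used <- sum(mir_counts$count[mir_counts$library == l]) +
        sum(nc_counts$count[nc_counts$library == l])
      r <- depth - used
      assert_that(r >= 0, paste0(
        "library ", l, " overflows its depth; lower mirna_fraction/",
        "ncrna_fraction"))
      r
    }, numeric(1))
    # keep the fragment pool mean well below the count floor
    n_frag <- pmin(round(remaining * config$degradation_fragment_share),
                   floor(length(deg_pool) / 4))
    deg_counts <- list_rbind(lapply(seq_along(libs), function(li) {
      cnt <- as.integer(rmultinom(1, n_frag[li],
                                  rep(1, length(deg_pool))))
      tibble(sequence = deg_pool, library = libs[li], count = cnt,
             source = "degradation", mirna_id = NA_character_) |>
        filter(.data$count > 0)
    }))
    # diverse background: windows of a long random sequence taken at
    # distinct positions, so reads are (near-)unique singletons
    n_bg <- as.integer(remaining - n_frag)
    mother_len <- as.integer(min(max(8 * sum(n_bg), 1e6), 6e7))
    mother <- paste(sample(DNA_BASES, mother_len, replace = TRUE),
                    collapse = "")
    bg_pos <- sample.int(mother_len - 31L, sum(n_bg))
    bg_len <- as.integer(sample(names(BACKGROUND_LENGTH_WEIGHTS),
                                sum(n_bg), replace = TRUE,
                                prob = BACKGROUND_LENGTH_WEIGHTS))
    bg_counts <- tibble(
      sequence = substring(mother, bg_pos, bg_pos + bg_len - 1L),
      library = rep(libs, times = n_bg),
      count = 1L, source = "degradation", mirna_id = NA_character_)
    bind_rows(mir_counts, nc_counts, deg_counts, bg_counts) |>
      filter(.data$count > 0) |>
      arrange(.data$sequence, .data$library)
  })
  truth <- refs$mirnas |>
    mutate(timing = true_timing(.data$dynamics),
           responsive = .data$dynamics %in% refs$responsive_classes) |>
    left_join(refs$target_map |>
                group_by(.data$mirna_id) |>
                summarise(targets = list(.data$transcript_id),
                          .groups = "drop"),
              by = c(id = "mirna_id"))
  out <- structure(list(
    tags = sim, truth = truth,
    references = refs[c("mirnas", "transcripts", "hairpins", "ncrna",
                        "target_map")],
    library_totals = setNames(
      vapply(libs, function(l) sum(sim$count[sim$library == l]),
             numeric(1)), libs),
    config = config), class = "submir_sim")
  if (!is.null(fastq_dir)) write_simulated_fastq(out, fastq_dir)
  out
}

#' @export
print.submir_sim <- function(x, ...) {
  cat("<submir_sim> ", nrow(x$truth), " planted miRNAs, ",
      length(x$library_totals), " libraries, depth ",
      format(x$config$depth_per_library, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Write the simulated libraries as FASTQ files
#'
#' Expands the tag table of a simulation into per-library FASTQ files
#' (Sanger qualities), shuffling read order deterministically. A
#' configured `low_quality_fraction` of reads receives a low quality
#' string and a configured `adapter` is appended to every read, so the
#' cleaning stage has something to do.
#'
#' @param sim A `submir_sim` object from [simulate_libraries()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_simulated_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  paths <- character(0)
  with_seed(cfg$seed + 2000L, {
    for (l in cfg$library_names) {
      tl <- sim$tags[sim$tags$library == l, ]
      seqs <- rep(tl$sequence, tl$count)
      if (length(seqs)) seqs <- sample(seqs)
      if (!is.null(cfg$adapter)) seqs <- paste0(seqs, cfg$adapter)
      qual <- strrep("I", nchar(seqs))
      if (cfg$low_quality_fraction > 0 && length(seqs)) {
        lo <- runif(length(seqs)) < cfg$low_quality_fraction
        qual[lo] <- strrep("#", nchar(seqs[lo]))
      }
      path <- file.path(dir, paste0(l, ".fastq"))
      ids <- sprintf("@%s_read%07d", l, seq_along(seqs))
      writeLines(as.vector(rbind(ids, seqs, rep("+", length(seqs)), qual)),
                 path)
      paths <- c(paths, path)
    }
  })
  invisible(paths)
}

#' Simulate the transcript expression matrix of the mRNA side
#'
#' Builds a transcript x library expression matrix whose inverse-coupled
#' target transcripts move opposite to their miRNA: at each time point
#' the target's pond-vs-upland log2 fold-change is the negative of the
#' miRNA's planted fold-change (Pearson r of the two series is exactly -1
#' before noise), while uncoupled transcripts get independent random
#' series.
#'
#' @param config A [simulation_config()].
#' @param sim The matching `submir_sim` (for the planted target map).
#' @return Tibble `transcript_id` plus one expression column per library.
#' @export
simulate_mrna_profiles <- function(config, sim) {
  refs <- sim$references
  mult <- class_multipliers(config$effect_fold)
  with_seed(config$seed + 3000L, {
    n_t <- nrow(refs$transcripts)
    libs <- config$library_names
    base <- exp(rnorm(n_t, log(100), 0.6))
    expr <- matrix(rep(base, length(libs)), nrow = n_t,
                   dimnames = list(refs$transcripts$id, libs))
    # uncoupled transcripts: independent mild wander
    expr <- expr * 2^matrix(rnorm(n_t * length(libs), 0, 0.25),
                            nrow = n_t)
    dyn <- setNames(refs$mirnas$dynamics, refs$mirnas$id)
    for (i in seq_len(nrow(refs$target_map))) {
      mid <- refs$target_map$mirna_id[i]
      tid <- refs$target_map$transcript_id[i]
      fc <- log2(mult[dyn[mid], pond_libraries()] /
                   mult[dyn[mid], upland_libraries()])
      b <- base[match(tid, refs$transcripts$id)]
      expr[tid, upland_libraries()] <- b
      expr[tid, pond_libraries()] <- b * 2^(-fc)
      expr[tid, "G0"] <- b
    }
    if (config$mrna_noise > 0) {
      expr <- expr * exp(matrix(rnorm(length(expr), 0, config$mrna_noise),
                                nrow = n_t))
    }
    as_tibble(expr, rownames = "transcript_id")
  })
}

#' Simulate a qPCR Ct table for validation pairs
#'
#' Emits threshold-cycle values for each planted miRNA:target pair and
#' time point, with a constant reference gene (UBC-like, Ct 18) and
#' target Ct values encoding the planted pond-vs-upland fold changes, so
#' [relative_expression()] recovers them.
#'
#' @param sim A `submir_sim` object.
#' @return Tibble `mirna_id`, `transcript_id`, `time`,
#'   `ct_target_treated`, `ct_ref_treated`, `ct_target_control`,
#'   `ct_ref_control`, `expected_fold`.
#' @export
simulate_ct_table <- function(sim) {
  refs <- sim$references
  mult <- class_multipliers(sim$config$effect_fold)
  dyn <- setNames(refs$mirnas$dynamics, refs$mirnas$id)
  list_rbind(lapply(seq_len(nrow(refs$target_map)), function(i) {
    mid <- refs$target_map$mirna_id[i]
    fc <- log2(mult[dyn[mid], pond_libraries()] /
                 mult[dyn[mid], upland_libraries()])
    mrna_fc <- -fc
    tibble(mirna_id = mid,
           transcript_id = refs$target_map$transcript_id[i],
           time = TIME_POINTS,
           ct_target_treated = 22 - mrna_fc, ct_ref_treated = 18,
           ct_target_control = 22, ct_ref_control = 18,
           expected_fold = 2^mrna_fc)
  }))
}

#' Simulate 5' RACE clone positions for planted target sites
#'
#' Places clone 5' ends opposite the canonical slicing register: a
#' `mode_fraction` of clones at miRNA position 10 (between positions 10
#' and 11) and the rest at position 11.
#'
#' @param sim A `submir_sim` object.
#' @param n_clones Clones per validated pair (default 10).
#' @param mode_fraction Fraction at the canonical position (default 0.8).
#' @return Tibble `mirna_id`, `transcript_id`, `site_start`, `site_end`,
#'   `clone_position` (transcript coordinates).
#' @export
simulate_race_clones <- function(sim, n_clones = 10L, mode_fraction = 0.8) {
  refs <- sim$references
  list_rbind(lapply(seq_len(nrow(refs$target_map)), function(i) {
    tm <- refs$target_map[i, ]
    n_mode <- round(n_clones * mode_fraction)
    pos <- c(rep(tm$site_end - 9L, n_mode),
             rep(tm$site_end - 10L, n_clones - n_mode))
    tibble(mirna_id = tm$mirna_id, transcript_id = tm$transcript_id,
           site_start = tm$site_start, site_end = tm$site_end,
           clone_position = pos)
  }))
}
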
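#' Hairpin acceptance criteria for novel miRNA calling
#'
#' The eight structural thresholds a candidate precursor must satisfy to
#' be called a novel miRNA: mature length within `mature_len` nt; at most
#' `max_copy` loci on the reference; precursor minimum free energy at most
#' `mfe_max` kcal/mol; at most `max_space` nt between the mature and star
#' arms; at least `min_duplex_pairs` base pairs in the miRNA/miRNA*
#' duplex; largest duplex bulge at most `max_bulge` nt; duplex asymmetry
#' at most `max_asymmetry` nt; and `flank` nt of precursor sequence on
#' both sides of the duplex.
#'
#' @param mature_len Length range of the mature sequence (nt).
#' @param max_copy Maximum copy number on the reference.
#' @param mfe_max Maximum (i.e. least negative) precursor free energy,
#'   kcal/mol.
#' @param max_space Maximum distance between mature and star arms, nt.
#' @param min_duplex_pairs Minimum mature/star base pairs.
#' @param max_bulge Maximum bulge (longest unpaired run on either duplex
#'   strand), nt.
#' @param max_asymmetry Maximum duplex asymmetry (absolute difference of
#'   unpaired nt between the two strands), nt.
#' @param flank Required flanking sequence on each side of the duplex, nt.
#' @return A named list of thresholds.
#' @export
hairpin_criteria <- function(mature_len = c(20L, 24L), max_copy = 20L,
                             mfe_max = -18, max_space = 300L,
                             min_duplex_pairs = 16L, max_bulge = 4L,
                             max_asymmetry = 4L, flank = 20L) {
  list(mature_len = mature_len, max_copy = max_copy, mfe_max = mfe_max,
       max_space = max_space, min_duplex_pairs = min_duplex_pairs,
       max_bulge = max_bulge, max_asymmetry = max_asymmetry, flank = flank)
}

#' Evaluate a hairpin candidate against the acceptance criteria
#'
#' Checks the structural statistics of a candidate precursor against each
#' criterion in a fixed order (mature length, copy number, free energy,
#' arm spacing, duplex pairs, bulge, asymmetry, flanks) and reports the
#' verdict with the first violated criterion as the reason code. A
#' missing (`NA`) statistic is treated as not evaluated and skipped: a
#' candidate without any identifiable duplex has no defined precursor
#' free energy and fails on `duplex_pairs`.
#'
#' @param stats A one-row data frame or named list with elements
#'   `mature_len`, `copy_number`, `mfe`, `arm_space`, `duplex_pairs`,
#'   `duplex_bulge_max`, `duplex_asymmetry`, `flank_5p`, `flank_3p`.
#' @param criteria Thresholds from [hairpin_criteria()].
#' @return A list with `accepted` (logical) and `reason` (`NA` when
#'   accepted, otherwise one of `"mature_length"`, `"copy_number"`,
#'   `"mfe"`, `"arm_space"`, `"duplex_pairs"`, `"duplex_bulge"`,
#'   `"duplex_asymmetry"`, `"flank"`).
#' @export
check_hairpin_criteria <- function(stats, criteria = hairpin_criteria()) {
  s <- as.list(stats)
  bad <- function(x, test) !is.null(x) && !is.na(x) && test(x)
  reason <- NA_character_
  if (bad(s$mature_len, function(x) x < criteria$mature_len[1] ||
                                     x > criteria$mature_len[2])) {
    reason <- "mature_length"
  } else if (bad(s$copy_number, function(x) x > criteria$max_copy)) {
    reason <- "copy_number"
  } else if (bad(s$mfe, function(x) x > criteria$mfe_max)) {
    reason <- "mfe"
  } else if (bad(s$arm_space, function(x) x > criteria$max_space)) {
    reason <- "arm_space"
  } else if (is.na(s$duplex_pairs %||% NA) ||
             s$duplex_pairs < criteria$min_duplex_pairs) {
    reason <- "duplex_pairs"
  } else if (bad(s$duplex_bulge_max, function(x) x > criteria$max_bulge)) {
    reason <- "duplex_bulge"
  } else if (bad(s$duplex_asymmetry,
                 function(x) x > criteria$max_asymmetry)) {
    reason <- "duplex_asymmetry"
  } else if (bad(s$flank_5p, function(x) x < criteria$flank) ||
             bad(s$flank_3p, function(x) x < criteria$flank)) {
    reason <- "flank"
  }
  list(accepted = is.na(reason), reason = reason)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact occurrences of each tag on a set of transcripts, via a single
# concatenated subject (separator outside the DNA alphabet). Returns a
# list (per tag) of tibbles (ti, start).
locate_tags <- function(seqs, tseqs) {
  sep <- "\x01"
  blob <- paste(tseqs, collapse = sep)
  offsets <- cumsum(c(0L, nchar(tseqs[-length(tseqs)]) + 1L))
  lapply(seqs, function(s) {
    m <- gregexpr(s, blob, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    ti <- findInterval(m, offsets + 1L)
    tibble(ti = ti, start = as.integer(m) - offsets[ti])
  })
}

# Duplex statistics of a mature arm [ms, me] within a folded sequence
# (partner vector from parse_dotbracket). Returns NULL when the mature
# arm has no partner arm on one side of a stem-loop.
duplex_stats <- function(partner, ms, me) {
  idx <- ms:me
  p <- partner[idx]
  outside <- p != 0L & (p < ms | p > me)
  if (!any(outside)) return(NULL)
  po <- p[outside]
  right <- sum(po > me) >= sum(po < ms)
  po <- if (right) po[po > me] else po[po < ms]
  if (!length(po)) return(NULL)
  star_lo <- min(po); star_hi <- max(po)
  paired <- p != 0L & p >= star_lo & p <= star_hi
  duplex_pairs <- sum(paired)
  unp_mature <- length(idx) - duplex_pairs
  star_span <- star_lo:star_hi
  star_paired <- partner[star_span] != 0L & partner[star_span] >= ms &
    partner[star_span] <= me
  unp_star <- length(star_span) - sum(star_paired)
  longest_run <- function(x) {
    if (!length(x) || !any(x)) return(0L)
    r <- rle(x)
    max(r$lengths[r$values])
  }
  bulge <- max(longest_run(!paired), longest_run(!star_paired))
  arm_space <- if (right) star_lo - me - 1L else ms - star_hi - 1L
  list(duplex_pairs = duplex_pairs, duplex_bulge_max = bulge,
       duplex_asymmetry = abs(unp_mature - unp_star),
       arm_space = max(arm_space, 0L),
       star_lo = star_lo, star_hi = star_hi, star_right = right)
}

# Complementarity prescan: find star-arm candidates for a mature locus
# without folding. Regions of the transcript within `max_space` of the
# mature are scanned (banded DP, no core doubling) for near-reverse
# complements of the mature; a duplex of >= min_duplex_pairs base pairs
# cannot exist without such a match, so tags with no hit are rejected
# cheaply. Returns a tibble of candidate spans in transcript coordinates
# sorted by penalty then distance.
find_star_candidates <- function(transcript_seq, ms, me,
                                 criteria = hairpin_criteria(),
                                 max_candidates = 2L) {
  n <- nchar(transcript_seq)
  L <- me - ms + 1L
  reach <- criteria$max_space + L + criteria$flank + 6L
  lo <- max(1L, ms - reach)
  hi <- min(n, me + reach)
  region <- substr(transcript_seq, lo, hi)
  rn <- nchar(region)
  menc <- encode_seq(substr(transcript_seq, ms, me))
  renc <- encode_seq(revcomp(region))
  cutoff <- 2 * (L - criteria$min_duplex_pairs) + 4
  win <- scan_windows_cpp(menc, renc, 0.5, 1, 2, -1L, -1L, cutoff, 4L)
  if (!nrow(win)) return(NULL)
  # rc coords -> transcript coords
  st <- lo + (rn - win$end)
  en <- lo + (rn - win$start)
  keep <- en < ms | st > me          # star must not overlap the mature
  dist <- ifelse(en < ms, ms - en, st - me)
  keep <- keep & dist - 1L <= criteria$max_space
  if (!any(keep)) return(NULL)
  out <- tibble(star_lo = st[keep], star_hi = en[keep],
                penalty = win$penalty[keep], dist = dist[keep])
  out <- arrange(out, .data$penalty, .data$dist, .data$star_lo)
  head(out, max_candidates)
}

# Excise the precursor around a mature/star duplex (with the 2 nt 3'
# overhang of the star) plus `flank` margins; folding happens in the
# caller so precursors can be batched.
evaluate_precursor <- function(transcript_seq, ms, me, star_lo, star_hi,
                               criteria) {
  n <- nchar(transcript_seq)
  if (star_lo > me) star_hi <- min(n, star_hi + 2L)
  else star_hi <- min(ms - 1L, star_hi + 2L)
  duplex_lo <- min(ms, star_lo)
  duplex_hi <- max(me, star_hi)
  pre_lo <- duplex_lo - criteria$flank
  pre_hi <- duplex_hi + criteria$flank
  flank_5p <- duplex_lo - max(1L, pre_lo)
  flank_3p <- min(n, pre_hi) - duplex_hi
  pre_lo <- max(1L, pre_lo); pre_hi <- min(n, pre_hi)
  precursor <- substr(transcript_seq, pre_lo, pre_hi)
  list(precursor = precursor, pre_lo = pre_lo, pre_hi = pre_hi,
       flank_5p = flank_5p, flank_3p = flank_3p)
}

precursor_stats <- function(job, structure, mfe, criteria) {
  p2 <- parse_dotbracket(structure)
  ms2 <- job$ms - job$pre_lo + 1L
  me2 <- job$me - job$pre_lo + 1L
  ds <- duplex_stats(p2, ms2, me2)
  if (is.null(ds)) {
    ds <- list(duplex_pairs = 0L, duplex_bulge_max = NA_integer_,
               duplex_asymmetry = NA_integer_, arm_space = NA_integer_,
               star_lo = NA_integer_, star_hi = NA_integer_)
  }
  tibble(mature_len = job$me - job$ms + 1L, mfe = mfe,
         arm_space = as.integer(ds$arm_space),
         duplex_pairs = as.integer(ds$duplex_pairs),
         duplex_bulge_max = as.integer(ds$duplex_bulge_max),
         duplex_asymmetry = as.integer(ds$duplex_asymmetry),
         flank_5p = job$flank_5p, flank_3p = job$flank_3p,
         star_start = if (is.na(ds$star_lo[1])) NA_integer_
                      else job$pre_lo + ds$star_lo - 1L,
         star_end = if (is.na(ds$star_hi[1])) NA_integer_
                    else job$pre_lo + ds$star_hi - 1L)
}

# Single-locus hairpin analysis: prescan for the star arm, excise and
# fold the precursor, return statistics. Used by make_hairpin and as the
# unbatched reference path of call_novel.
analyze_hairpin_locus <- function(transcript_seq, mature_start, mature_end,
                                  criteria = hairpin_criteria(),
                                  backend = "auto") {
  transcript_seq <- to_dna(transcript_seq)
  cand <- find_star_candidates(transcript_seq, mature_start, mature_end,
                               criteria)
  mlen <- mature_end - mature_start + 1L
  if (is.null(cand)) {
    return(list(stats = tibble(
      mature_len = mlen, mfe = NA_real_, arm_space = NA_integer_,
      duplex_pairs = 0L, duplex_bulge_max = NA_integer_,
      duplex_asymmetry = NA_integer_, flank_5p = criteria$flank,
      flank_3p = criteria$flank, star_start = NA_integer_,
      star_end = NA_integer_),
      precursor = NA_character_, structure = NA_character_))
  }
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    job <- evaluate_precursor(transcript_seq, mature_start, mature_end,
                              cand$star_lo[k], cand$star_hi[k], criteria)
    job$ms <- mature_start; job$me <- mature_end
    f <- rna_fold(job$precursor, backend = backend)
    st <- precursor_stats(job, f$structure[1], f$mfe[1], criteria)
    res <- list(stats = st, precursor = job$precursor,
                structure = f$structure[1],
                precursor_start = job$pre_lo, precursor_end = job$pre_hi)
    if (is.null(best)) best <- res
    chk <- check_hairpin_criteria(c(st, copy_number = 1L), criteria)
    if (chk$accepted) return(res)
  }
  best
}

#' Call novel miRNAs from hairpin structure on a transcriptome
#'
#' For each candidate tag (a cleaned, unannotated, unassigned sequence of
#' mature length), locates its exact occurrences on the transcriptome,
#' finds star-arm candidates by a fast complementarity prescan (a duplex
#' of 16+ base pairs requires a near-reverse-complement of the mature
#' within the allowed arm spacing), excises the implied precursor with
#' flanking margins, folds it and evaluates the eight hairpin criteria
#' ([check_hairpin_criteria()]). Precursors are folded in batches. A tag
#' is accepted at its first passing locus/star combination; otherwise the
#' first combination's failure reason is reported.
#'
#' @param tags Tag table or character vector of candidate sequences.
#' @param transcripts Tibble with `id`, `sequence` (the transcriptome);
#'   must be non-empty.
#' @param criteria Thresholds from [hairpin_criteria()].
#' @param backend Folding backend passed to [rna_fold()].
#' @param max_loci Maximum loci examined per tag.
#' @return Tibble with one row per candidate tag: `sequence`, `accepted`,
#'   `reason`, `transcript_id`, `locus_start`, `locus_end`, `copy_number`,
#'   `precursor`, `structure`, `mfe`, `precursor_len`, duplex statistics
#'   and star coordinates.
#' @export
call_novel <- function(tags, transcripts, criteria = hairpin_criteria(),
                       backend = "auto", max_loci = 3L) {
  assert_that(is.data.frame(transcripts) && nrow(transcripts) > 0,
              "`transcripts` must be a non-empty tibble (id, sequence)")
  seqs <- if (is.character(tags)) unique(tags) else unique(tags$sequence)
  seqs <- sort(to_dna(seqs))
  tseqs <- to_dna(transcripts$sequence)
  loci_all <- locate_tags(seqs, tseqs)
  base_row <- function(s) {
    tibble(sequence = s, accepted = FALSE, reason = NA_character_,
           transcript_id = NA_character_, locus_start = NA_integer_,
           locus_end = NA_integer_, copy_number = 0L,
           precursor = NA_character_, structure = NA_character_,
           mfe = NA_real_, precursor_len = NA_integer_,
           mature_len = nchar(s), arm_space = NA_integer_,
           duplex_pairs = NA_integer_, duplex_bulge_max = NA_integer_,
           duplex_asymmetry = NA_integer_, star_start = NA_integer_,
           star_end = NA_integer_)
  }
  results <- setNames(vector("list", length(seqs)), seqs)
  queues <- setNames(vector("list", length(seqs)), seqs)
  copies <- setNames(integer(length(seqs)), seqs)
  for (si in seq_along(seqs)) {
    s <- seqs[si]
    row <- base_row(s)
    mlen <- nchar(s)
    if (mlen < criteria$mature_len[1] || mlen > criteria$mature_len[2]) {
      row$reason <- "mature_length"
      results[[s]] <- row
      next
    }
    loci <- loci_all[[si]]
    copy_number <- if (is.null(loci)) 0L else nrow(loci)
    copies[[s]] <- copy_number
    row$copy_number <- copy_number
    if (copy_number == 0L) {
      row$reason <- "unmapped"
      results[[s]] <- row
      next
    }
    if (copy_number > criteria$max_copy) {
      row$reason <- "copy_number"
      results[[s]] <- row
      next
    }
    # build the evaluation queue: loci in order, star candidates per
    # locus by prescan rank
    queue <- list()
    for (li in seq_len(min(nrow(loci), max_loci))) {
      ti <- loci$ti[li]
      st <- loci$start[li]
      cand <- find_star_candidates(tseqs[ti], st, st + mlen - 1L,
                                   criteria)
      if (is.null(cand)) next
      for (k in seq_len(nrow(cand))) {
        queue[[length(queue) + 1L]] <- list(
          ti = ti, ms = st, me = st + mlen - 1L,
          star_lo = cand$star_lo[k], star_hi = cand$star_hi[k])
      }
    }
    if (!length(queue)) {
      # no complementarity anywhere in reach: no duplex can exist
      row$reason <- "duplex_pairs"
      row$transcript_id <- transcripts$id[loci$ti[1]]
      row$locus_start <- loci$start[1]
      row$locus_end <- row$locus_start + mlen - 1L
      row$duplex_pairs <- 0L
      results[[s]] <- row
      next
    }
    queues[[s]] <- utils::head(queue, 3L)
  }
  pending <- names(queues)[!vapply(queues, is.null, logical(1))]
  round <- 0L
  while (length(pending) && round < 4L) {
    round <- round + 1L
    jobs <- list()
    for (s in pending) {
      q <- queues[[s]]
      entry <- q[[1]]
      queues[[s]] <- q[-1]
      job <- evaluate_precursor(tseqs[entry$ti], entry$ms, entry$me,
                                entry$star_lo, entry$star_hi, criteria)
      job$ms <- entry$ms; job$me <- entry$me; job$ti <- entry$ti
      job$sequence <- s
      jobs[[length(jobs) + 1L]] <- job
    }
    folded <- rna_fold(vapply(jobs, `[[`, character(1), "precursor"),
                       backend = backend)
    for (ji in seq_along(jobs)) {
      job <- jobs[[ji]]
      s <- job$sequence
      st <- precursor_stats(job, folded$structure[ji], folded$mfe[ji],
                            criteria)
      chk <- check_hairpin_criteria(c(st, copy_number = copies[[s]]),
                                    criteria)
      row <- base_row(s)
      row$accepted <- chk$accepted
      row$reason <- chk$reason
      row$copy_number <- copies[[s]]
      row$transcript_id <- transcripts$id[job$ti]
      row$locus_start <- job$ms
      row$locus_end <- job$me
      row$precursor <- job$precursor
      row$structure <- folded$structure[ji]
      row$mfe <- st$mfe
      row$precursor_len <- nchar(job$precursor)
      row$arm_space <- st$arm_space
      row$duplex_pairs <- st$duplex_pairs
      row$duplex_bulge_max <- st$duplex_bulge_max
      row$duplex_asymmetry <- st$duplex_asymmetry
      row$star_start <- st$star_start
      row$star_end <- st$star_end
      # keep the first evaluated combination unless a later one passes
      if (is.null(results[[s]]) || chk$accepted) results[[s]] <- row
      if (chk$accepted) queues[[s]] <- list()
    }
    pending <- Filter(function(s) {
      length(queues[[s]]) > 0 && !isTRUE(results[[s]]$accepted)
    }, pending)
  }
  list_rbind(unname(results[seqs]))
}
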
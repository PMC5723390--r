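target_weights <- function(p_gu = 0.5, p_mm = 1, p_gap = 2,
                           core = c(2L, 13L), cutoff = 4) {
  list(p_gu = p_gu, p_mm = p_mm, p_gap = p_gap, core = core, cutoff = cutoff)
}

core_mult <- function(i, core) ifelse(i >= core[1] & i <= core[2], 2, 1)

# column kind of miRNA base vs reverse-complemented site base:
# 0 match, 1 G:U wobble, 2 mismatch (bases as A/C/G/T characters)
column_kind <- function(m, r) {
  ifelse(m == r, 0L,
         ifelse((m == "G" & r == "A") | (m == "T" & r == "C"), 1L, 2L))
}

#' Score a miRNA target site by plant complementarity penalties
#'
#' Aligns a miRNA (5' to 3') against the reverse complement of a
#' candidate target site and scores each column: Watson-Crick match 0,
#' G:U wobble `p_gu` (0.5), mismatch `p_mm` (1.0), indel `p_gap` (2.0),
#' with every penalty doubled at miRNA core positions 2-13 (counted from
#' the miRNA 5' end). The minimal-penalty alignment is found by dynamic
#' programming. Under the `allen` rule set a site is accepted when the
#' penalty is at most `cutoff` (4.0); the `schwab` rule set additionally
#' rejects any site with a mismatch at miRNA positions 10 or 11 (the
#' cleavage-spanning positions).
#'
#' @param mirna miRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param site Target site as it appears on the transcript, 5' to 3'.
#'   Its length must be within 3 nt of the miRNA length.
#' @param rule_set `"allen"` or `"schwab"`.
#' @param weights Penalty scheme from `target_weights()` (exposed via the
#'   `...` defaults: `p_gu`, `p_mm`, `p_gap`, core 2-13, cutoff 4).
#' @return A list: `penalty`, `accepted`, `mirna_aln` (5'->3'),
#'   `site_aln` (3'->5', so columns base-pair), `marks` (`|` match, `o`
#'   G:U, `x` mismatch, space at gaps).
#' @examples
#' target_score("TGACAGAAGAGAGTGAGCACA",
#'              as.character(Biostrings::reverseComplement(
#'                Biostrings::DNAString("TGACAGAAGAGAGTGAGCACA"))))
#' @export
target_score <- function(mirna, site, rule_set = c("allen", "schwab"),
                         weights = target_weights()) {
  rule_set <- match.arg(rule_set)
  m <- strsplit(to_dna(mirna), "")[[1]]
  L <- length(m)
  if (abs(nchar(site) - L) > 3L) {
    abort("site length differs from miRNA length by more than 3 nt")
  }
  r <- strsplit(revcomp(to_dna(site)), "")[[1]]
  S <- length(r)
  w <- weights
  mult <- function(i) core_mult(i, w$core)
  sub_cost <- function(i, j) {
    k <- column_kind(m[i], r[j])
    c(0, w$p_gu, w$p_mm)[k + 1] * mult(i)
  }
  INF <- 1e9
  D <- matrix(INF, L + 1L, S + 1L)
  D[1, 1] <- 0
  for (j in seq_len(S)) D[1, j + 1] <- D[1, j] + w$p_gap * mult(1)
  for (i in seq_len(L)) {
    gap_m <- w$p_gap * mult(i)                       # consume miRNA only
    gap_s <- w$p_gap * if (i < L) mult(i + 1) else 1 # consume site only
    D[i + 1, 1] <- D[i, 1] + gap_m
    for (j in seq_len(S)) {
      D[i + 1, j + 1] <- min(D[i, j] + sub_cost(i, j),
                             D[i, j + 1] + gap_m,
                             D[i + 1, j] + gap_s)
    }
  }
  # traceback
  i <- L; j <- S
  cols <- list()
  while (i > 0 || j > 0) {
    gap_m <- if (i > 0) w$p_gap * mult(i) else INF
    gap_s <- w$p_gap * if (i <= 0) mult(1) else if (i < L) mult(i + 1) else 1
    if (i > 0 && j > 0 &&
        isTRUE(all.equal(D[i + 1, j + 1], D[i, j] + sub_cost(i, j)))) {
      k <- column_kind(m[i], r[j])
      cols[[length(cols) + 1]] <- list(m = m[i], s = r[j],
                                       mark = c("|", "o", "x")[k + 1],
                                       pos = i, kind = k)
      i <- i - 1; j <- j - 1
    } else if (i > 0 &&
               isTRUE(all.equal(D[i + 1, j + 1], D[i, j + 1] + gap_m))) {
      cols[[length(cols) + 1]] <- list(m = m[i], s = "-", mark = " ",
                                       pos = i, kind = 3L)
      i <- i - 1
    } else {
      cols[[length(cols) + 1]] <- list(m = "-", s = r[j], mark = " ",
                                       pos = NA_integer_, kind = 3L)
      j <- j - 1
    }
  }
  cols <- rev(cols)
  penalty <- D[L + 1, S + 1]
  mm_pos <- vapply(cols, function(cc) {
    if (cc$kind == 2L) as.numeric(cc$pos) else NA_real_
  }, numeric(1))
  accepted <- penalty <= w$cutoff
  if (rule_set == "schwab" && any(mm_pos %in% c(10L, 11L), na.rm = TRUE)) {
    accepted <- FALSE
  }
  site_aln <- vapply(cols, `[[`, character(1), "s")
  list(penalty = penalty, accepted = accepted,
       mirna_aln = paste(vapply(cols, `[[`, character(1), "m"),
                         collapse = ""),
       # complement back so the shown target strand reads 3'->5'
       site_aln = paste(chartr("ACGT-", "TGCA-", site_aln), collapse = ""),
       marks = paste(vapply(cols, `[[`, character(1), "mark"),
                     collapse = ""))
}

#' Scan a transcriptome for miRNA target sites
#'
#' Scores every transcript window whose length is within 3 nt of the
#' miRNA length ([target_score()] semantics, evaluated with a banded
#' dynamic program in C++) and retains windows accepted by either rule
#' set; the pooled hits are the union of the `allen` and `schwab`
#' acceptances, deduplicated by (miRNA, transcript, site).
#'
#' @param mirnas Tibble (`mirna_id`, `sequence`) or named character
#'   vector of mature miRNA sequences.
#' @param transcripts Tibble (`id`, `sequence`); must be non-empty.
#' @param weights Penalty scheme (see [target_score()]).
#' @return Tibble of hits: `mirna_id`, `transcript_id`, `start`, `end`
#'   (1-based on the transcript), `penalty`, `allen`, `schwab`,
#'   `mirna_aln`, `site_aln`, `marks`.
#' @export
scan_targets <- function(mirnas, transcripts, weights = target_weights()) {
  assert_that(is.data.frame(transcripts) && nrow(transcripts) > 0,
              "`transcripts` must be a non-empty tibble (id, sequence)")
  if (!is.data.frame(mirnas)) {
    mirnas <- tibble(mirna_id = names(mirnas), sequence = unname(mirnas))
  }
  band <- max(3L, as.integer(floor(weights$cutoff / weights$p_gap)))
  hits <- list()
  tseqs <- to_dna(transcripts$sequence)
  rencs <- lapply(revcomp(tseqs), encode_seq)
  for (mi in seq_len(nrow(mirnas))) {
    mseq <- to_dna(mirnas$sequence[mi])
    menc <- encode_seq(mseq)
    for (ti in seq_len(nrow(transcripts))) {
      tseq <- tseqs[ti]
      n <- nchar(tseq)
      renc <- rencs[[ti]]
      win <- scan_windows_cpp(menc, renc, weights$p_gu, weights$p_mm,
                              weights$p_gap, weights$core[1],
                              weights$core[2], weights$cutoff, band)
      if (!nrow(win)) next
      win <- win[abs((win$end - win$start + 1L) - length(menc)) <= 3L, ,
                 drop = FALSE]
      for (k in seq_len(nrow(win))) {
        # rc coordinates -> transcript coordinates
        t_start <- n - win$end[k] + 1L
        t_end <- n - win$start[k] + 1L
        site <- substr(tseq, t_start, t_end)
        sc_a <- target_score(mseq, site, "allen", weights)
        sc_s <- target_score(mseq, site, "schwab", weights)
        if (!sc_a$accepted && !sc_s$accepted) next
        hits[[length(hits) + 1]] <- tibble(
          mirna_id = mirnas$mirna_id[mi],
          transcript_id = transcripts$id[ti],
          start = t_start, end = t_end,
          penalty = sc_a$penalty, allen = sc_a$accepted,
          schwab = sc_s$accepted, mirna_aln = sc_a$mirna_aln,
          site_aln = sc_a$site_aln, marks = sc_a$marks)
      }
    }
  }
  if (!length(hits)) {
    return(tibble(mirna_id = character(0), transcript_id = character(0),
                  start = integer(0), end = integer(0), penalty = numeric(0),
                  allen = logical(0), schwab = logical(0),
                  mirna_aln = character(0), site_aln = character(0),
                  marks = character(0)))
  }
  list_rbind(hits) |>
    distinct(.data$mirna_id, .data$transcript_id, .data$start, .data$end,
             .keep_all = TRUE) |>
    arrange(.data$mirna_id, .data$transcript_id, .data$start)
}

#' Keep target hits on differentially expressed transcripts
#'
#' @param hits Hit table from [scan_targets()].
#' @param de_genes Character vector of differentially expressed
#'   transcript ids.
#' @return The hits whose transcript is in `de_genes`.
#' @export
filter_de_targets <- function(hits, de_genes) {
  filter(hits, .data$transcript_id %in% de_genes)
}

#' Classify the co-expression of a miRNA and a candidate target
#'
#' Correlates the five-point pond-vs-upland log2 fold-change series of a
#' miRNA and a transcript. The pair is `inverse` when Pearson r is at
#' most `-r_min` and the two fold-changes have opposite signs at every
#' time point where the miRNA response qualifies; `positive` when r is at
#' least `r_min`; otherwise `uncorrelated`. Zero-variance series are
#' `uncorrelated`.
#'
#' @param mirna_fc,mrna_fc Numeric log2 fold-change series over the five
#'   time points (1, 3, 6, 12, 120 h).
#' @param responsive_times Time points where the miRNA is called
#'   responsive (subset of 1, 3, 6, 12, 120); sign opposition is enforced
#'   there. Default: all time points.
#' @param r_min Correlation magnitude threshold (default 0.5).
#' @return Tibble `r`, `verdict`.
#' @export
pair_inverse <- function(mirna_fc, mrna_fc, responsive_times = TIME_POINTS,
                         r_min = 0.5) {
  assert_that(length(mirna_fc) == length(TIME_POINTS) &&
                length(mrna_fc) == length(TIME_POINTS),
              "fold-change series must cover the five time points")
  if (anyNA(mirna_fc) || anyNA(mrna_fc) ||
      stats::sd(mirna_fc) == 0 || stats::sd(mrna_fc) == 0) {
    return(tibble(r = NA_real_, verdict = "uncorrelated"))
  }
  r <- stats::cor(mirna_fc, mrna_fc)
  idx <- match(intersect(responsive_times, TIME_POINTS), TIME_POINTS)
  opposite <- all(sign(mirna_fc[idx]) * sign(mrna_fc[idx]) < 0)
  verdict <- if (r <= -r_min && opposite) "inverse"
             else if (r >= r_min) "positive"
             else "uncorrelated"
  tibble(r = r, verdict = verdict)
}

#' Relative expression by the double-delta Ct method
#'
#' Computes `2^-ddCt` with
#' `ddCt = (Ct_target_treated - Ct_ref_treated) -
#' (Ct_target_control - Ct_ref_control)`, the standard relative qPCR
#' quantification against a reference gene and a control condition.
#'
#' @param ct_target_treated,ct_ref_treated Ct of the gene of interest and
#'   of the reference gene in the treated sample.
#' @param ct_target_control,ct_ref_control The same in the control
#'   sample.
#' @return Fold ratio(s), treated relative to control.
#' @examples
#' relative_expression(20, 18, 22, 18) # 4
#' @export
relative_expression <- function(ct_target_treated, ct_ref_treated,
                                ct_target_control, ct_ref_control) {
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Summarise 5' RACE cleavage positions over a target site
#'
#' Converts the 5' ends of RACE clones (transcript coordinates) into
#' miRNA coordinates, counting from the miRNA 5' end; a cleavage at the
#' phosphate between miRNA positions 10 and 11 is reported as position 10
#' (the canonical slicing register). Reports the modal position and the
#' fraction of clones supporting it.
#'
#' @param clone_positions 1-based transcript positions of clone 5' ends;
#'   a clone outside the site is an error naming the clone.
#' @param site_start,site_end Target site interval on the transcript (the
#'   miRNA 5' end pairs opposite `site_end`).
#' @return Tibble `mode_position`, `mode_fraction`, `n_clones`, plus a
#'   `positions` list column of per-clone miRNA coordinates.
#' @export
cleavage_summary <- function(clone_positions, site_start, site_end) {
  bad <- which(clone_positions < site_start | clone_positions > site_end)
  if (length(bad)) {
    abort(sprintf(
      "clone %d (position %d) lies outside the target site [%d, %d]",
      bad[1], clone_positions[bad[1]], site_start, site_end))
  }
  mir_pos <- site_end - clone_positions + 1L
  tab <- sort(table(mir_pos), decreasing = TRUE)
  mode_pos <- as.integer(names(tab)[1])
  tibble(mode_position = mode_pos,
         mode_fraction = unname(tab[1]) / length(mir_pos),
         n_clones = length(mir_pos),
         positions = list(as.integer(mir_pos)))
}
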
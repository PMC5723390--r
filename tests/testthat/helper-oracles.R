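# Independent oracles used to cross-check the package implementations.

# Branch-and-bound enumeration of all global alignments of a vs b.
# Finds the minimal total edits (substitutions + gap columns) and
# whether some edit-optimal alignment keeps substitutions <= max_mm and
# gap columns <= max_gap. Returns list(edits, feasible).
bf_align <- function(a, b, max_mm = 2L, max_gap = 3L) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  la <- length(ac); lb <- length(bc)
  # start from the naive left-anchored alignment as an upper bound
  ov <- min(la, lb)
  best <- sum(ac[seq_len(ov)] != bc[seq_len(ov)]) + abs(la - lb)
  feasible <- FALSE
  rec <- function(i, j, mm, gg) {
    # remaining edits can never undercut the remaining length difference
    if (mm + gg + abs((la - i) - (lb - j)) > best) return(invisible())
    if (i > la && j > lb) {
      tot <- mm + gg
      ok <- mm <= max_mm && gg <= max_gap
      if (tot < best) {
        best <<- tot
        feasible <<- ok
      } else if (tot == best && ok) {
        feasible <<- TRUE
      }
      return(invisible())
    }
    if (i <= la && j <= lb) {
      rec(i + 1L, j + 1L, mm + (ac[i] != bc[j]), gg)
    }
    if (i <= la) rec(i + 1L, j, mm, gg + 1L)
    if (j <= lb) rec(i, j + 1L, mm, gg + 1L)
  }
  rec(1L, 1L, 0L, 0L)
  list(edits = best, feasible = feasible)
}

# Direct term-by-term summation of the count-comparison posterior
# (flat-prior Poisson rate): p(k | x) for library totals n1, n2, via the
# multiplicative recurrence, then the two-sided tail; symmetrised by
# exchange like the implementation.
oracle_ac_directed <- function(x, n1, y, n2) {
  r <- n2 / n1
  q <- r / (1 + r)
  p0 <- (1 / (1 + r))^(x + 1)
  terms <- numeric(y + 1)
  terms[1] <- p0
  if (y > 0) {
    for (k in 0:(y - 1)) {
      terms[k + 2] <- terms[k + 1] * (x + k + 1) / (k + 1) * q
    }
  }
  tail_le <- sum(terms)
  tail_ge <- 1 - (tail_le - terms[y + 1])
  min(1, 2 * min(tail_le, tail_ge))
}

oracle_ac <- function(x, n1, y, n2) {
  (oracle_ac_directed(x, n1, y, n2) + oracle_ac_directed(y, n2, x, n1)) / 2
}

# Closed-form Pearson correlation + two-sided t-test p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, p = p)
}

random_dna_str <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Expected pond-vs-upland log2 fold-change series (times 1,3,6,12,120 h)
# of each planted dynamics class, from the class definitions.
planted_fc <- function(dynamics, effect_fold) {
  lf <- log2(effect_fold)
  switch(dynamics,
         early_up = c(lf, lf, lf, lf, 0),
         early_down = c(-lf, -lf, -lf, -lf, 0),
         late = c(0, 0, 0, 0, lf),
         varied = c(lf, 0, 0, 0, -lf),
         c(0, 0, 0, 0, 0))
}

# A small mature sequence whose planted hairpin folds cleanly.
fixture_mature <- function() "TGACAGAAGAGAGTGAGCACA"

# Statistics row of a hairpin candidate that satisfies every criterion;
# boundary tests perturb one field at a time.
valid_hairpin_stats <- function() {
  list(mature_len = 21L, copy_number = 1L, mfe = -45.2, arm_space = 8L,
       duplex_pairs = 21L, duplex_bulge_max = 0L, duplex_asymmetry = 0L,
       flank_5p = 20L, flank_3p = 20L)
}
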
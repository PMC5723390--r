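#' @importFrom rlang .data abort
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols distinct across n rename pull count first
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_dbl map_int map2 pmap imap list_rbind
#' @importFrom stats rnbinom rnorm runif setNames cor pt quantile rmultinom
#' @importFrom utils head tail write.table read.delim
NULL

# The 11-library wet/dry design: untreated control, five upland (drained)
# and five pond (submerged) sampling points at 1, 3, 6, 12 and 120 h.
LIBRARY_NAMES <- c("G0", "D1", "D3", "D6", "D12", "D120",
                   "W1", "W3", "W6", "W12", "W120")
TIME_POINTS <- c(1L, 3L, 6L, 12L, 120L)
EARLY_TIMES <- c(1L, 3L, 6L, 12L)

#' Library labels of the wet/dry time-course design
#'
#' Returns the ordered labels of the eleven small RNA libraries: the
#' untreated control `G0`, the upland (drained) series `D1..D120` and the
#' pond (submerged) series `W1..W120`, sampled at 1, 3, 6, 12 and 120 h.
#'
#' @return Character vector of length 11.
#' @export
library_names <- function() LIBRARY_NAMES

upland_libraries <- function() paste0("D", TIME_POINTS)
pond_libraries <- function() paste0("W", TIME_POINTS)

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Seeded evaluation that restores the caller's RNG state afterwards, so
# generator calls are reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Read a FASTA file into a tibble
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that splits the
#' description line into the record id (first word) and any `key=value`
#' annotations (e.g. `family=MIR156`, `class=rRNA`).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence` and one column per
#'   `key=value` tag found in the headers.
#' @export
read_fasta_tbl <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  out <- tibble(id = id, sequence = as.character(ss))
  kv <- regmatches(hdr, gregexpr("\\b(\\w+)=(\\S+)", hdr))
  keys <- unique(unlist(lapply(kv, function(x) sub("=.*$", "", x))))
  for (k in keys) {
    out[[k]] <- vapply(kv, function(x) {
      hit <- grep(paste0("^", k, "="), x, value = TRUE)
      if (length(hit)) sub("^[^=]+=", "", hit[[1]]) else NA_character_
    }, character(1))
  }
  out
}

write_fasta <- function(tbl, path, annotations = NULL) {
  hdr <- tbl$id
  if (!is.null(annotations)) {
    for (k in annotations) {
      hdr <- paste0(hdr, " ", k, "=", tbl[[k]])
    }
  }
  lines <- as.vector(rbind(paste0(">", hdr), tbl$sequence))
  writeLines(lines, path)
  invisible(path)
}

write_tsv_plain <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       check.names = FALSE))
}
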
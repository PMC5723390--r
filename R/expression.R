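#' Reads-per-million normalisation
#'
#' Scales a read count by the clean-read total of its library:
#' `rpm = count / total * 1e6`.
#'
#' @param count Read count(s).
#' @param library_total Clean-read total(s) of the corresponding library;
#'   must be positive.
#' @return Numeric RPM values.
#' @examples
#' rpm_normalize(5, 1e6) # 5
#' @export
rpm_normalize <- function(count, library_total) {
  assert_that(all(library_total > 0), "`library_total` must be positive")
  count / library_total * 1e6
}

#' Log2 fold-change with low-expression exclusion and zero revision
#'
#' Computes `log2(rpm_a / rpm_b)` under the time-course comparison rules:
#' when both RPM values are below `min_rpm` the comparison is excluded
#' (returned as `NA`, the low-expression exclusion); otherwise any zero
#' value (an unobserved miRNA) is revised to `zero_value` before taking
#' the ratio. Exclusion is checked before revision, so a zero paired with
#' a low value is excluded rather than revised.
#'
#' @param rpm_a,rpm_b RPM values (numerator and denominator). Vectorised.
#' @param min_rpm Exclusion floor: excluded when both values are below it
#'   (default 1 RPM).
#' @param zero_value Replacement for zero RPM (default 0.01).
#' @return Numeric log2 ratios; `NA` marks excluded comparisons.
#' @examples
#' fold_change(4, 0)     # log2(4 / 0.01) ~ 8.64
#' fold_change(0.8, 0.9) # NA (both below 1)
#' @export
fold_change <- function(rpm_a, rpm_b, min_rpm = 1, zero_value = 0.01) {
  excluded <- rpm_a < min_rpm & rpm_b < min_rpm
  a <- ifelse(rpm_a == 0, zero_value, rpm_a)
  b <- ifelse(rpm_b == 0, zero_value, rpm_b)
  ifelse(excluded, NA_real_, log2(a / b))
}

# Directed Audic-Claverie two-sided p: posterior tail of observing y reads
# in a library of total n2 given x reads in a library of total n1.
ac_directed <- function(x, n1, y, n2) {
  logr <- log(n2) - log(n1)
  lognorm <- log1p(n2 / n1)
  logp <- function(k) k * logr + lchoose(x + k, k) - (x + k + 1) * lognorm
  tail_le <- sum(exp(logp(0:y)))
  tail_ge <- 1 - if (y == 0) 0 else sum(exp(logp(0:(y - 1))))
  min(1, 2 * min(tail_le, tail_ge))
}

#' Exact significance of a count difference between two libraries
#'
#' Audic-Claverie style exact test for differential representation of a
#' tag between two sequencing libraries without replicates: the posterior
#' distribution of the second count given the first (under a flat prior
#' on the underlying Poisson rate) gives a two-sided tail probability.
#' Because the directed posterior tail is not exactly symmetric under
#' exchanging the two libraries, the reported p-value is the mean of the
#' two directed two-sided tails, which is symmetric by construction.
#'
#' @param count_a,count_b Read counts in the two libraries. Vectorised.
#' @param total_a,total_b Clean-read totals of the two libraries.
#' @return p-values in `[0, 1]`.
#' @examples
#' count_significance(0, 1e6, 0, 1e6)  # 1
#' @export
count_significance <- function(count_a, total_a, count_b, total_b) {
  mapply(function(x, n1, y, n2) {
    (ac_directed(x, n1, y, n2) + ac_directed(y, n2, x, n1)) / 2
  }, count_a, total_a, count_b, total_b)
}

OCCUPANCY_LEVELS <- c("all_libraries", "shared_other", "control_specific",
                      "pond_specific", "upland_specific", "not_expressed")

#' Classify each miRNA by the treatment groups it is detected in
#'
#' A miRNA is "expressed" in a library when its count is positive; the
#' occupancy class records which of the three treatment groups (control
#' `G0`, upland `D*`, pond `W*`) detect it: all three (`all_libraries`),
#' exactly one (`control_specific`, `pond_specific`, `upland_specific`)
#' or any other combination of two groups (`shared_other`).
#'
#' @param counts Tidy count table (`mirna_id`, `library`, `count`).
#' @return Tibble `mirna_id`, `occupancy_class`.
#' @export
classify_occupancy <- function(counts) {
  grp <- counts |>
    mutate(group = dplyr::case_when(
      .data$library == "G0" ~ "control",
      startsWith(.data$library, "D") ~ "upland",
      startsWith(.data$library, "W") ~ "pond")) |>
    group_by(.data$mirna_id, .data$group) |>
    summarise(expressed = any(.data$count > 0), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "expressed",
                       values_fill = FALSE)
  for (g in c("control", "upland", "pond")) {
    if (!g %in% names(grp)) grp[[g]] <- FALSE
  }
  grp |>
    mutate(occupancy_class = dplyr::case_when(
      .data$control & .data$upland & .data$pond ~ "all_libraries",
      .data$control & !.data$upland & !.data$pond ~ "control_specific",
      !.data$control & !.data$upland & .data$pond ~ "pond_specific",
      !.data$control & .data$upland & !.data$pond ~ "upland_specific",
      !.data$control & !.data$upland & !.data$pond ~ "not_expressed",
      TRUE ~ "shared_other")) |>
    select("mirna_id", "occupancy_class") |>
    arrange(.data$mirna_id)
}

#' Summarise a partition with percentages
#'
#' Turns class counts into the count-and-percentage rows of the summary
#' tables (percentage = count / group total x 100, reported to one
#' decimal).
#'
#' @param x Either a tibble with a class column (named by `class_col`) and
#'   one row per item, or a named integer vector of class counts.
#' @param class_col Column holding the class label when `x` is a tibble.
#' @param total Group total used as the percentage denominator; defaults
#'   to the sum of the class counts (pass it explicitly when some items
#'   fall outside the listed classes).
#' @return Tibble `class`, `n`, `pct` (one decimal).
#' @examples
#' summarize_partition(c(single_member = 52, multi_member = 24))
#' @export
summarize_partition <- function(x, class_col = "occupancy_class",
                                total = NULL) {
  if (is.data.frame(x)) {
    tab <- x |> count(.data[[class_col]], name = "n") |>
      rename(class = dplyr::all_of(class_col))
  } else {
    tab <- tibble(class = names(x), n = as.integer(x))
  }
  denom <- total %||% sum(tab$n)
  tab |> mutate(pct = round(.data$n / denom * 100, 1))
}

#' Consistency of a miRNA's upland and pond response series
#'
#' Pearson correlation between the five-point log2 fold-change series of
#' the upland and pond treatments (each vs the untreated control), with a
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#' The expression pattern is called consistent when `r > r_min` and
#' `p < p_max`. A series with zero variance (or containing excluded
#' values) has undefined correlation and is never consistent.
#'
#' @param series_d,series_w Log2 fold-change series of the upland and pond
#'   treatments over the five time points; `NA` marks exclusions.
#' @param r_min,p_max Consistency thresholds (defaults r > 0.9, p < 0.05).
#' @return Tibble `r`, `p`, `consistent`.
#' @export
consistency <- function(series_d, series_w, r_min = 0.9, p_max = 0.05) {
  ok <- !anyNA(series_d) && !anyNA(series_w) &&
    stats::sd(series_d) > 0 && stats::sd(series_w) > 0
  if (!ok) return(tibble(r = NA_real_, p = NA_real_, consistent = FALSE))
  ct <- stats::cor.test(series_d, series_w, method = "pearson")
  r <- unname(ct$estimate)
  p <- ct$p.value
  tibble(r = r, p = p, consistent = r > r_min & p < p_max)
}

#' Call submergence-responsive miRNAs and their timing class
#'
#' A miRNA is submergence-responsive when, at one or more time points, the
#' magnitude of its pond-vs-upland log2 fold-change reaches `lfc_min`
#' with significance `p < p_max`. miRNAs expressed only in the
#' upland-treated samples are exempted from the p-value requirement (but
#' still need the fold-change). The timing class is `early` when every
#' qualifying time point is within 1-12 h, `late` when all are at 120 h,
#' and `varied` otherwise; non-responsive miRNAs have timing `none`.
#'
#' @param fc_wd Tibble with columns `mirna_id`, `time` (hours), `log2fc`
#'   (`NA` = excluded) and `pvalue` for the pond-vs-upland comparison.
#' @param occupancy Optional tibble `mirna_id`, `occupancy_class` used for
#'   the upland-only exemption.
#' @param lfc_min Fold-change magnitude threshold (default 1, i.e.
#'   2-fold).
#' @param p_max Significance threshold (default 0.05).
#' @return Tibble `mirna_id`, `responsive`, `timing`, `n_qualifying`.
#' @export
call_responsive <- function(fc_wd, occupancy = NULL, lfc_min = 1,
                            p_max = 0.05) {
  x <- as_tibble(fc_wd)
  if (!is.null(occupancy)) {
    x <- left_join(x, occupancy, by = "mirna_id")
  } else {
    x$occupancy_class <- NA_character_
  }
  x |>
    mutate(exempt = !is.na(.data$occupancy_class) &
             .data$occupancy_class == "upland_specific",
           qualifies = !is.na(.data$log2fc) &
             abs(.data$log2fc) >= lfc_min &
             (.data$exempt | .data$pvalue < p_max)) |>
    group_by(.data$mirna_id) |>
    summarise(
      responsive = any(.data$qualifies),
      n_qualifying = sum(.data$qualifies),
      timing = {
        qt <- .data$time[.data$qualifies]
        if (!length(qt)) "none"
        else if (all(qt %in% EARLY_TIMES)) "early"
        else if (all(qt == 120L)) "late"
        else "varied"
      },
      .groups = "drop") |>
    arrange(.data$mirna_id)
}

#' Full expression profiling of a miRNA count table
#'
#' Runs the whole expression stage: RPM normalisation, per-time-point
#' log2 fold-changes of each treatment series against the control and of
#' pond against upland (with low-expression exclusion and zero revision,
#' see [fold_change()]), exact count significance
#' ([count_significance()]), occupancy classification, upland/pond
#' consistency and the submergence-responsive call with timing.
#'
#' @param counts Tidy count table (`mirna_id`, `library`, `count`) over
#'   the 11 libraries ([library_names()]).
#' @param library_totals Named numeric vector (or tibble `library`,
#'   `total`) of clean-read totals per library.
#' @param lfc_min,p_max,min_rpm,zero_value,r_min Thresholds; see
#'   [call_responsive()], [fold_change()] and [consistency()].
#' @return An object of class `submir_profiles`: a list with `rpm` (wide
#'   tibble), `fc` (long tibble of all comparisons with `log2fc`,
#'   `pvalue`), `calls` (per-miRNA occupancy, consistency, responsive,
#'   timing) and `library_totals`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
profile_expression <- function(counts, library_totals, lfc_min = 1,
                               p_max = 0.05, min_rpm = 1, zero_value = 0.01,
                               r_min = 0.9) {
  if (is.data.frame(library_totals)) {
    library_totals <- setNames(library_totals$total, library_totals$library)
  }
  libs <- LIBRARY_NAMES
  assert_that(all(libs %in% names(library_totals)),
              "`library_totals` must cover all 11 libraries")
  counts <- counts |>
    filter(.data$library %in% libs) |>
    group_by(.data$mirna_id, .data$library) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(rpm = rpm_normalize(.data$count,
                               unname(library_totals[.data$library])))
  wide <- function(col) {
    counts |>
      select("mirna_id", "library", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "library",
                         values_from = dplyr::all_of(col),
                         values_fill = 0) |>
      (\(d) { for (l in libs) if (!l %in% names(d)) d[[l]] <- 0; d })() |>
      select("mirna_id", dplyr::all_of(libs)) |>
      arrange(.data$mirna_id)
  }
  rpm_w <- wide("rpm")
  cnt_w <- wide("count")
  comparisons <- list(
    list(name = "D_vs_G0", a = upland_libraries(), b = rep("G0", 5)),
    list(name = "W_vs_G0", a = pond_libraries(), b = rep("G0", 5)),
    list(name = "W_vs_D", a = pond_libraries(), b = upland_libraries()))
  fc <- list_rbind(lapply(comparisons, function(cmp) {
    list_rbind(lapply(seq_along(TIME_POINTS), function(i) {
      la <- cmp$a[i]; lb <- cmp$b[i]
      tibble(mirna_id = rpm_w$mirna_id, comparison = cmp$name,
             time = TIME_POINTS[i],
             log2fc = fold_change(rpm_w[[la]], rpm_w[[lb]],
                                  min_rpm = min_rpm,
                                  zero_value = zero_value),
             pvalue = count_significance(cnt_w[[la]], library_totals[[la]],
                                         cnt_w[[lb]], library_totals[[lb]]))
    }))
  }))
  occupancy <- classify_occupancy(counts)
  cons <- fc |>
    filter(.data$comparison != "W_vs_D") |>
    select("mirna_id", "comparison", "time", "log2fc") |>
    tidyr::pivot_wider(names_from = "comparison", values_from = "log2fc") |>
    group_by(.data$mirna_id) |>
    summarise(res = list(consistency(.data$D_vs_G0, .data$W_vs_G0,
                                     r_min = r_min, p_max = p_max)),
              .groups = "drop") |>
    tidyr::unnest("res")
  resp <- call_responsive(filter(fc, .data$comparison == "W_vs_D"),
                          occupancy, lfc_min = lfc_min, p_max = p_max)
  calls <- occupancy |>
    left_join(cons, by = "mirna_id") |>
    left_join(resp, by = "mirna_id")
  structure(list(rpm = rpm_w, fc = fc, calls = calls,
                 library_totals = library_totals),
            class = "submir_profiles")
}

#' @export
print.submir_profiles <- function(x, ...) {
  cat("<submir_profiles> ", nrow(x$rpm), " miRNAs x ",
      length(LIBRARY_NAMES), " libraries\n", sep = "")
  cat("  responsive:", sum(x$calls$responsive, na.rm = TRUE), "of",
      nrow(x$calls), "\n")
  tm <- table(x$calls$timing[x$calls$responsive])
  if (length(tm)) {
    cat("  timing:", paste(names(tm), tm, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fold-change table of an expression profile
#'
#' @param x A `submir_profiles` object.
#' @param ... Unused.
#' @return Long tibble `mirna_id`, `comparison`, `time`, `log2fc`,
#'   `pvalue` with per-miRNA calls joined on.
#' @export
tidy.submir_profiles <- function(x, ...) {
  left_join(x$fc, x$calls, by = "mirna_id")
}

#' One-row summary of an expression profile
#'
#' @param x A `submir_profiles` object.
#' @param ... Unused.
#' @return One-row tibble: miRNA totals, responsive counts by timing,
#'   consistent count.
#' @export
glance.submir_profiles <- function(x, ...) {
  calls <- x$calls
  tibble(
    n_mirna = nrow(calls),
    n_responsive = sum(calls$responsive, na.rm = TRUE),
    n_early = sum(calls$timing == "early", na.rm = TRUE),
    n_late = sum(calls$timing == "late", na.rm = TRUE),
    n_varied = sum(calls$timing == "varied", na.rm = TRUE),
    n_consistent = sum(calls$consistent, na.rm = TRUE))
}

#' Heatmap of pond-vs-upland fold changes
#'
#' @param object A `submir_profiles` object.
#' @param comparison Which comparison to draw (default `"W_vs_D"`).
#' @param ... Unused.
#' @return A ggplot object: miRNA x time tile heatmap of log2 fold-change.
#' @export
autoplot.submir_profiles <- function(object, comparison = "W_vs_D", ...) {
  dat <- object$fc |>
    filter(.data$comparison == !!comparison) |>
    mutate(time = factor(.data$time, levels = TIME_POINTS))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$mirna_id,
                                    fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey95",
                                  high = "#b2182b", na.value = "grey80") +
    ggplot2::labs(x = "time (h)", y = NULL, fill = "log2 FC",
                  title = paste("log2 fold-change,", comparison)) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
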
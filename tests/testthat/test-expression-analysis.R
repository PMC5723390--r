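test_that("RPM normalisation follows its definition", {
  expect_equal(rpm_normalize(5, 1e6), 5)
  expect_equal(rpm_normalize(0, 1e6), 0)
  # counting every clean read once makes library RPM sum to one million
  set.seed(10)
  counts <- sample(1:100, 50, replace = TRUE)
  expect_equal(sum(rpm_normalize(counts, sum(counts))), 1e6)
  expect_error(rpm_normalize(5, 0), "positive")
})

test_that("fold-change applies exclusion before zero revision", {
  expect_true(is.na(fold_change(0.8, 0.9)))     # both below 1 RPM
  expect_equal(fold_change(4, 0), log2(4 / 0.01))
  expect_equal(fold_change(4, 0), 8.6438, tolerance = 1e-4)
  expect_equal(fold_change(2, 2), 0)
  # a zero paired with a sub-floor value is excluded, not revised
  expect_true(is.na(fold_change(0, 0.5)))
})

test_that("fold-change is antisymmetric away from its special cases", {
  set.seed(11)
  a <- runif(1000, 0, 50)
  b <- runif(1000, 0, 50)
  fab <- fold_change(a, b)
  fba <- fold_change(b, a)
  ok <- !is.na(fab)
  expect_identical(is.na(fab), is.na(fba))
  expect_equal(fab[ok], -fba[ok])
  # exclusion is monotone under scaling both values below the floor
  a2 <- runif(200, 0, 0.99); b2 <- runif(200, 0, 0.99)
  expect_true(all(is.na(fold_change(a2, b2))))
})

test_that("the exact count test matches direct summation", {
  expect_equal(count_significance(0, 1e6, 0, 1e6), 1)
  expect_gt(count_significance(50, 1e6, 50, 1e6), 0.95)
  grid <- expand.grid(x = c(0, 1, 5, 20, 100, 500),
                      y = c(0, 3, 10, 60, 250),
                      n1 = c(1e6, 2e6), n2 = c(1e6, 5e5))
  p_impl <- count_significance(grid$x, grid$n1, grid$y, grid$n2)
  p_oracle <- mapply(oracle_ac, grid$x, grid$n1, grid$y, grid$n2)
  expect_lt(max(abs(p_impl - p_oracle)), 1e-9)
  # symmetric under exchanging the two libraries
  p_swap <- count_significance(grid$y, grid$n2, grid$x, grid$n1)
  expect_equal(p_impl, p_swap, tolerance = 1e-12)
  # a strong difference is significant
  expect_lt(count_significance(100, 1e6, 10, 1e6), 1e-10)
})

test_that("occupancy classes partition the printed example exactly", {
  # the five-way split of 81 novel miRNAs across treatment groups
  counts <- c(all_libraries = 12, shared_other = 16,
              control_specific = 5, pond_specific = 21,
              upland_specific = 24)
  s <- summarize_partition(counts, total = 81)
  expect_equal(sum(s$n), 78)  # three novels fall outside the five classes
  got <- setNames(s$pct, s$class)
  expect_equal(unname(got[names(counts)]), c(14.8, 19.8, 6.2, 25.9, 29.6))
  # single-member families: 52 of 76
  fam <- summarize_partition(c(single_member = 52, multi_member = 24))
  expect_equal(fam$pct[fam$class == "single_member"], 68.4)
  # known miRNAs seen in all three groups: 113 of 220
  known <- summarize_partition(c(all_groups = 113, elsewhere = 107))
  expect_equal(known$pct[known$class == "all_groups"], 51.4)
})

test_that("occupancy classification reads group detection from counts", {
  libs <- library_names()
  mk <- function(id, on) {
    tibble::tibble(mirna_id = id, library = libs,
                   count = ifelse(libs %in% on, 10L, 0L))
  }
  counts <- dplyr::bind_rows(
    mk("all", libs), mk("ctrl", "G0"), mk("pond", c("W1", "W120")),
    mk("up", c("D3")), mk("pw", c("W1", "D1")))
  oc <- classify_occupancy(counts)
  got <- setNames(oc$occupancy_class, oc$mirna_id)
  expect_equal(unname(got[c("all", "ctrl", "pond", "up", "pw")]),
               c("all_libraries", "control_specific", "pond_specific",
                 "upland_specific", "shared_other"))
  # one class only: percentages still sum to 100
  s <- summarize_partition(oc[oc$occupancy_class == "pond_specific", ])
  expect_equal(sum(s$pct), 100)
})

test_that("consistency combines Pearson r with the t-test verdict", {
  x <- c(1.2, -0.5, 0.3, 2.0, 1.1)
  same <- consistency(x, x)
  expect_equal(same$r, 1)
  expect_true(same$consistent)
  opp <- consistency(x, -x)
  expect_equal(opp$r, -1)
  expect_false(opp$consistent)
  # matches the closed-form oracle on a noisy pair
  set.seed(12)
  y <- x + rnorm(5, sd = 0.2)
  got <- consistency(x, y)
  ora <- oracle_pearson(x, y)
  expect_equal(got$r, ora$r, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)
  expect_equal(got$consistent, ora$r > 0.9 && ora$p < 0.05)
  # zero-variance series are never consistent
  flat <- consistency(rep(1, 5), x)
  expect_true(is.na(flat$r))
  expect_false(flat$consistent)
})

test_that("responsiveness needs one qualifying time point and maps timing", {
  fc <- function(id, lfc, p = rep(1e-6, 5)) {
    tibble::tibble(mirna_id = id, time = c(1L, 3L, 6L, 12L, 120L),
                   log2fc = lfc, pvalue = p)
  }
  calls <- call_responsive(dplyr::bind_rows(
    fc("quiet", rep(0.5, 5)),
    fc("early", c(2, 2, 0, 0, 0)),
    fc("late", c(0, 0, 0, 0, -2)),
    fc("varied", c(2, 0, 0, 0, 2)),
    fc("ns", c(2, 2, 2, 2, 2), p = rep(0.5, 5))))
  got <- setNames(calls$timing, calls$mirna_id)
  expect_equal(unname(got[c("quiet", "early", "late", "varied", "ns")]),
               c("none", "early", "late", "varied", "none"))
  expect_equal(calls$responsive, calls$timing != "none")
  # upland-only miRNAs are exempt from the p-value requirement
  occ <- tibble::tibble(mirna_id = "ns",
                        occupancy_class = "upland_specific")
  ex <- call_responsive(fc("ns", c(2, 2, 2, 2, 2), p = rep(0.5, 5)), occ)
  expect_true(ex$responsive)
  # timing classes partition the responsive set
  expect_equal(sum(calls$timing != "none"), sum(calls$responsive))
})

test_that("profiles expose tidy, glance and autoplot interfaces", {
  libs <- library_names()
  set.seed(13)
  counts <- tidyr::expand_grid(mirna_id = c("m1", "m2", "m3"),
                               library = libs) |>
    dplyr::mutate(count = sample(50:500, 33, replace = TRUE))
  totals <- setNames(rep(1e5, 11), libs)
  prof <- profile_expression(counts, totals)
  expect_s3_class(prof, "submir_profiles")
  td <- tidy(prof)
  expect_true(all(c("mirna_id", "comparison", "time", "log2fc",
                    "pvalue", "occupancy_class", "timing") %in% names(td)))
  expect_equal(nrow(td), 3 * 3 * 5)
  gl <- glance(prof)
  expect_equal(gl$n_mirna, 3L)
  expect_equal(gl$n_early + gl$n_late + gl$n_varied, gl$n_responsive)
  p <- ggplot2::autoplot(prof)
  expect_s3_class(p, "ggplot")
})
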
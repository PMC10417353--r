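# Independent truth-table oracle for the per-visit decision tree, coded as a
# flat condition table rather than the sequential tree in the package.
oracle_score <- function(pf, pe, dsrt, prev_worsened,
                         rec_f = 100, rec_e = 40, wor_e = 20, wor_f = 50,
                         window = 90, band = 10) {
  recurrence <- abs(pf) >= rec_f || pe >= rec_e
  worsened <- pe >= wor_e || pf >= wor_f
  mixed <- (pf <= -band && pe >= band) || (pe <= -band && pf >= band)
  improved <- pf <= -band && pe <= -band
  code <- if (recurrence) "4"
  else if (worsened && prev_worsened) "3c"
  else if (worsened && !is.na(dsrt) && dsrt <= window) "3a"
  else if (worsened) "3b"
  else if (mixed) "3b"
  else if (improved) "1"
  else "2"
  code
}

# Build a two- or three-visit series realizing given percent changes.
# Base volumes 10 cc (FLAIR) and 5 / 6.25 cc (ENH) make the printed cutoff
# percentages exactly representable.
series_for <- function(pf, pe, dsrt = 200, prev_worsened = FALSE) {
  if (!prev_worsened) {
    visit_series(date_days = c(0, 100),
                 flair_cc = c(10, 10 * (1 + pf / 100)),
                 enh_cc = c(5, 5 * (1 + pe / 100)),
                 days_since_rt = c(NA, dsrt))
  } else {
    # middle visit worsens (enh +25%) without reaching recurrence
    visit_series(date_days = c(0, 50, 100),
                 flair_cc = c(10, 10, 10 * (1 + pf / 100)),
                 enh_cc = c(5, 6.25, 6.25 * (1 + pe / 100)),
                 days_since_rt = c(NA, 40, dsrt))
  }
}

last_code <- function(vs, params = cutoff_params()) {
  res <- classify_series(vs, params)
  format_score(res[[length(res)]])
}

test_that("percent change handles measurable, new and resolved lesions", {
  pc <- percent_change(10, 17)
  expect_equal(pc$pct, 70)                    # the +70% visit
  expect_identical(pc$flag, "none")
  expect_equal(percent_change(5, 5)$pct, 0)
  expect_identical(percent_change(0, 0.5)$flag, "new_lesion")
  expect_identical(percent_change(0.5, 0.01)$flag, "resolved")
  expect_equal(percent_change(0.05, 0.09)$pct, 0)  # both sub-measurable
  expect_error(percent_change(-1, 2), "non-negative")
})

test_that("the five-visit worked sequence scores 0, 3a, 3c, 3b, 4", {
  vs <- visit_series(
    date_days = c(30, 120, 180, 240, 300),
    flair_cc = c(10, 12.6, 12.6 * 1.37, 12.6 * 1.37 * 0.70,
                 12.6 * 1.37 * 0.70),
    enh_cc = c(4, 5.0, 5.0 * 1.27, 5.0 * 1.27 * 1.12,
               5.0 * 1.27 * 1.12 * 1.70),
    days_since_rt = c(NA, 30, 90, 150, 210))
  res <- classify_series(vs)
  expect_identical(vapply(res, format_score, ""),
                   c("0", "3a", "3c", "3b", "4"))
  # the rationale names the fired rules
  expect_identical(res[[1]]$rationale, "baseline")
  expect_true("consecutive_worsening" %in% res[[3]]$rationale)
  expect_true("mixed_findings" %in% res[[4]]$rationale)
  expect_true("recurrence_enh_increase" %in% res[[5]]$rationale)
})

test_that("cutoff boundaries are inclusive exactly at the printed values", {
  # FLAIR +100% recurrence, inclusive; just below falls to worsened (>= 50%)
  expect_identical(last_code(series_for(100, 0)), "4")
  expect_identical(last_code(series_for(100 - 1e-6, 0)), "3b")
  # "changed by 100%" is read literally: a full -100% shrink also triggers
  # recurrence in the default mode, but not in increase-only mode
  expect_identical(last_code(series_for(-100, 0)), "4")
  inc_only <- cutoff_params(flair_recurrence_increase_only = TRUE)
  expect_identical(last_code(series_for(-100, 0), inc_only), "2")
  # ENH +40% recurrence, inclusive
  expect_identical(last_code(series_for(0, 40)), "4")
  expect_identical(last_code(series_for(0, 40 - 1e-6)), "3b")
  # ENH +20% worsened, inclusive; sub-letter from the post-RT window
  expect_identical(last_code(series_for(0, 20, dsrt = 200)), "3b")
  expect_identical(last_code(series_for(0, 20, dsrt = 30)), "3a")
  expect_identical(last_code(series_for(0, 20 - 1e-6)), "2")
  # FLAIR +50% worsened, inclusive
  expect_identical(last_code(series_for(50, 0, dsrt = 30)), "3a")
  # stability band
  expect_identical(last_code(series_for(-5, 5)), "2")
  expect_identical(last_code(series_for(-15, -15)), "1")
  expect_identical(last_code(series_for(-30, 12)), "3b")
})

test_that("the decision tree agrees with the flat truth-table oracle", {
  # changes keep both volumes measurable so no new/resolved flags fire; the
  # oracle is fed the percent changes actually realized by the volume pairs
  # (the construction volume * (1 + pct/100) is not exact in floating point)
  realized <- function(base, p) (base * (1 + p / 100) - base) / base * 100
  grid <- c(-95, -50, -30, -10, -5, 0, 5, 10, 15, 19.9, 20, 25,
            39.9, 40, 49.9, 50, 99.9, 100, 150)
  for (prev in c(FALSE, TRUE)) for (dsrt in c(30, 200)) {
    for (pf in grid) for (pe in grid) {
      if (prev && (abs(pf) >= 100 || pe >= 40)) {
        # rule precedence for recurrence ignores the worsened chain and is
        # covered by the prev = FALSE sweep
        next
      }
      fbase <- 10
      ebase <- if (prev) 6.25 else 5
      expect_identical(
        last_code(series_for(pf, pe, dsrt, prev_worsened = prev)),
        oracle_score(realized(fbase, pf), realized(ebase, pe), dsrt, prev),
        label = sprintf("pf=%g pe=%g dsrt=%d prev=%d", pf, pe, dsrt, prev))
    }
  }
})

test_that("scores are monotone in the worsening region and 3c needs a chain", {
  # in the region where both changes are above the improvement band,
  # increasing either percent change never lowers the major category
  major_of <- function(pf, pe) {
    res <- classify_series(series_for(pf, pe, dsrt = 200))
    res[[2]]$major
  }
  pts <- c(-9, 0, 10, 19, 20, 39, 40, 60, 99, 100, 130)
  for (pf in pts) {
    majors <- vapply(pts, function(pe) major_of(pf, pe), integer(1))
    expect_true(all(diff(majors) >= 0), label = paste("pe sweep at pf", pf))
  }
  for (pe in pts) {
    majors <- vapply(pts, function(pf) major_of(pf, pe), integer(1))
    expect_true(all(diff(majors) >= 0), label = paste("pf sweep at pe", pe))
  }
  # a 3c can never be the first worsened visit of a series
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(3:6, 1)
    fl <- 10 * cumprod(c(1, runif(n - 1, 0.5, 1.8)))
    en <- 5 * cumprod(c(1, runif(n - 1, 0.5, 1.8)))
    vs <- visit_series(seq(0, by = 60, length.out = n), fl, en,
                       days_since_rt = c(NA, seq(30, by = 60,
                                                 length.out = n - 1)))
    res <- classify_series(vs)
    codes <- vapply(res, format_score, "")
    first_worse <- which(vapply(res, function(r) r$worsened_flag, TRUE))[1]
    if (!is.na(first_worse)) expect_false(codes[first_worse] == "3c")
  }
})

test_that("new and resolved lesions route to the right branches", {
  # lesion appearing from nothing -> recurrence
  vs_new <- visit_series(c(0, 60), flair_cc = c(10, 10), enh_cc = c(0, 1),
                         days_since_rt = c(NA, 120))
  expect_identical(last_code(vs_new), "4")
  # both lesions resolving -> improved
  vs_gone <- visit_series(c(0, 60), flair_cc = c(10, 0.01),
                          enh_cc = c(5, 0.0), days_since_rt = c(NA, 120))
  expect_identical(last_code(vs_gone), "1")
  # worsened visit with unknown RT date falls through to 3b with a warning
  vs_na <- visit_series(c(0, 60), flair_cc = c(10, 10), enh_cc = c(5, 6.2))
  expect_warning(res <- classify_series(vs_na), "days_since_rt")
  expect_identical(format_score(res[[2]]), "3b")
  # invalid construction
  expect_error(visit_series(c(10, 5), c(1, 1), c(1, 1)), "increasing")
  expect_error(visit_series(c(0, 10), c(-1, 1), c(1, 1)), "non-negative")
})
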
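test_that("de-medianing centers each segment at zero and is idempotent", {
  prof <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 2),
    segment = rep(1:2, 3),
    median = c(0.4, 1, 0.5, 1, 0.6, 1)
  )
  dd <- demedian(prof)
  expect_equal(dd$segment_medians$m, c(0.5, 1))
  expect_equal(sort(dd$demedianed$dm[dd$demedianed$segment == 1]), c(-0.1, 0, 0.1))
  expect_equal(dd$demedianed$dm[dd$demedianed$segment == 2], rep(0, 3))

  again <- demedian(dplyr::transmute(
    dd$demedianed, subject_id = subject_id, segment = segment, median = dm
  ))
  expect_equal(again$demedianed$dm, dd$demedianed$dm)

  expect_error(
    demedian(prof[prof$subject_id == "a", ]),
    "at least 2"
  )
})

test_that("mean-absolute-deviation outlier removal matches the direct formula", {
  v <- c(-0.1, 0, 0.1, 10)
  # median 0.05; MAD = (0.15 + 0.05 + 0.05 + 9.95)/4 = 2.55; 3 MAD = 7.65
  ro <- remove_outliers(c(v, rep(0, 6)))
  expect_equal(ro$removed, 10)
  expect_equal(ro$n_removed, 1L)
  expect_equal(length(ro$kept) + ro$n_removed, 10L)

  expect_warning(ro0 <- remove_outliers(rep(3, 12)), "constant")
  expect_equal(ro0$n_removed, 0L)
  expect_error(remove_outliers(1:5), "at least 10")
})

test_that("a standard-normal pooled sample loses about 1.7% to the 3-MAD filter", {
  set.seed(99)
  fracs <- replicate(60, {
    ro <- remove_outliers(rnorm(480))
    ro$n_removed / 480
  })
  expect_equal(mean(fracs), 0.0167, tolerance = 0.25)
})

test_that("the normative halfwidth is 1.96 sigma of the kept pooled values", {
  set.seed(5)
  prof <- gaussian_hc_profiles(n_subj = 700, K = 15, sigma = 1, base = rep(0, 15))
  # with an enormous factor nothing is trimmed: kept values are N(0,1)
  m_raw <- build_normative(prof, factor = 1e6)
  expect_equal(glance(m_raw)$halfwidth, 1.96, tolerance = 0.05 / 1.96)
  expect_equal(glance(m_raw)$n_outliers_removed, 0L)

  # translation equivariance
  prof2 <- dplyr::mutate(prof, median = median + 7)
  m2 <- build_normative(prof2, factor = 1e6)
  expect_equal(glance(m2)$halfwidth, glance(m_raw)$halfwidth)
  expect_equal(tidy(m2)$lo, tidy(m_raw)$lo + 7, tolerance = 1e-12)
})

test_that("degenerate constant controls give a point interval that flags any deviation", {
  prof <- gaussian_hc_profiles(n_subj = 4, K = 3, sigma = 0, base = rep(0.5, 3))
  m <- suppressWarnings(build_normative(prof))
  expect_equal(tidy(m)$lo, tidy(m)$hi)
  pat <- tibble::tibble(
    subject_id = "p", hemisphere = "L", parameter = "MD",
    segment = 1:3, median = c(0.5, 0.51, 0.49)
  )
  fl <- classify_segments(pat, m)
  expect_equal(fl$flag, c("normal", "high", "low"))
})

test_that("classification uses strict inequalities and flags known lesions exactly", {
  set.seed(7)
  prof <- gaussian_hc_profiles(n_subj = 32, K = 15, sigma = 0.02)
  model <- build_normative(prof)
  iv <- tidy(model)

  # boundary value is normal
  pat <- tibble::tibble(
    subject_id = "p", hemisphere = "L", parameter = "MD",
    segment = 1:15, median = iv$hi
  )
  expect_true(all(classify_segments(pat, model)$flag == "normal"))

  # +5 sigma lesion on 10 known segments flags exactly those, as "high"
  sigma <- glance(model)$sigma
  lesioned <- c(1, 2, 3, 4, 5, 8, 10, 12, 14, 15)
  pat2 <- tibble::tibble(
    subject_id = "p2", hemisphere = "L", parameter = "MD",
    segment = 1:15,
    median = iv$m + ifelse(1:15 %in% lesioned, 5 * sigma, 0)
  )
  fl2 <- classify_segments(pat2, model)
  expect_equal(which(fl2$flag == "high"), lesioned)
  expect_true(all(fl2$flag[-lesioned] == "normal"))

  # missing segment stays unclassified
  pat3 <- pat2
  pat3$median[4] <- NA
  expect_true(is.na(classify_segments(pat3, model)$flag[4]))

  # parameter not covered by the model
  pat4 <- dplyr::mutate(pat2, parameter = "FA")
  expect_error(classify_segments(pat4, model), "does not cover")
})

test_that("raising a value can only move its flag toward 'high'", {
  set.seed(8)
  prof <- gaussian_hc_profiles(n_subj = 20, K = 15)
  model <- build_normative(prof)
  pat <- dplyr::filter(prof, subject_id == "hc001") |>
    dplyr::mutate(subject_id = "p")
  f0 <- classify_segments(pat, model)$flag
  f1 <- classify_segments(dplyr::mutate(pat, median = median + 0.01), model)$flag
  rank_of <- c(low = 1, normal = 2, high = 3)
  expect_true(all(rank_of[f1] >= rank_of[f0]))
})

test_that("subject summaries count directional abnormalities and medians", {
  flagged <- tidyr::crossing(
    subject_id = "p", hemisphere = "L",
    parameter = c("FA", "MD", "AD", "RD"), segment = 1:15
  ) |>
    dplyr::mutate(
      median = as.numeric(segment),
      lo = 0, hi = 100,
      flag = dplyr::case_when(
        parameter == "FA" & segment <= 3 ~ "low",
        parameter == "MD" & segment <= 5 ~ "high",
        parameter == "AD" & segment == 1 ~ "high", # wrong direction for AD
        TRUE ~ "normal"
      )
    )
  summ <- summarize_subjects(flagged)
  expect_equal(
    summ$n_abnormal[match(c("FA", "MD", "AD", "RD"), summ$parameter)],
    c(3L, 5L, 0L, 0L)
  )
  expect_equal(
    summ$n_abnormal_two_sided[summ$parameter == "AD"], 1L
  )
  expect_true(all(summ$median_across_segments == 8))

  wide <- subject_metrics(summ)
  expect_equal(wide$FA_dec_segments, 3)
  expect_equal(wide$MD_inc_segments, 5)
  expect_equal(wide$median_RD, 8)
})

test_that("HC coverage of the normative interval is near the nominal 95%", {
  # the interval estimates the 2.5th-97.5th percentiles of the
  # outlier-cleaned control distribution, so nominal 95% coverage holds
  # for the values surviving the MAD filter; including the trimmed
  # ~1.7% tail mass, raw coverage sits near 93%
  set.seed(12)
  cover <- sapply(1:25, function(i) {
    prof <- gaussian_hc_profiles(n_subj = 32, K = 15, sigma = 0.02)
    model <- build_normative(prof)
    fl <- classify_segments(prof, model)
    dd <- demedian(prof)$demedianed
    keep <- abs(dd$dm - median(dd$dm)) <=
      3 * mean(abs(dd$dm - median(dd$dm)))
    c(kept = mean(fl$flag[keep] == "normal"), raw = mean(fl$flag == "normal"))
  })
  expect_gt(mean(cover["kept", ]), 0.93)
  expect_lt(mean(cover["kept", ]), 0.97)
  expect_gt(mean(cover["raw", ]), 0.90)
})
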
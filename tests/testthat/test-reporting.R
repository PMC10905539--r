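test_that("cohort quartiles follow linear order-statistic interpolation", {
  df <- data.frame(setting = "a", c_max = c(1, 2, 3, 4), D_final_s = c(1, 2, 3, 4))
  s <- summarize_cohort(df)
  r <- s[s$metric == "c_max", ]
  expect_equal(r$q1, 1.75)
  expect_equal(r$median, 2.5)
  expect_equal(r$q3, 3.25)
  expect_equal(r$mean, 2.5)
  expect_equal(r$n, 4)
  # two values: median = mean = midpoint
  s2 <- summarize_cohort(data.frame(setting = "a", c_max = c(0, 1), D_final_s = c(0, 1)))
  expect_equal(s2$median[1], 0.5); expect_equal(s2$mean[1], 0.5)
  # all equal: quartiles collapse onto the mean
  s3 <- summarize_cohort(data.frame(setting = "a", c_max = rep(2, 5), D_final_s = rep(2, 5)))
  expect_true(all(unlist(s3[1, c("q1", "median", "q3", "mean")]) == 2))
  expect_warning(summarize_cohort(data.frame(setting = "a", c_max = NA_real_,
                                             D_final_s = NA_real_)), "omitted")
})

test_that("percent change and ratio reproduce the published comparisons", {
  p <- percent_change(0.40, 0.63)
  expect_equal(p$ratio, 1.575)
  expect_equal(p$percent, 57.5)
  expect_equal(p$percent_rounded, 58)   # half away from zero
  p2 <- percent_change(0.61, 0.40)
  expect_equal(p2$percent, -34.42623, tolerance = 1e-6)
  expect_equal(percent_change(2, 2)$percent, 0)
  expect_equal(percent_change(2, 2)$ratio, 1)
  expect_true(is.na(percent_change(0, 1)$percent))
  # ratio = 1 + percent/100 identity
  for (pair in list(c(0.4, 0.63), c(0.61, 0.40), c(15, 48.8))) {
    pc <- percent_change(pair[1], pair[2])
    expect_equal(pc$ratio, 1 + pc$percent / 100, tolerance = 1e-12)
  }
})

test_that("fraction tables partition each case", {
  cl <- data.frame(case = "b",
                   occlusivity = c("nonocclusive", "semiocclusive", "fully_occlusive", "fully_occlusive"),
                   contact = c("contact", "contact", "no_contact", "diffusion_range"))
  ft <- fraction_tables(cl)
  expect_equal(unname(unlist(ft$contact[1, c("contact", "diffusion_range", "no_contact")])),
               c(0.5, 0.25, 0.25))
  expect_equal(sum(unlist(ft$occlusivity[1, -1])), 1)
  expect_equal(sum(unlist(ft$contact[1, -1])), 1)
  sf <- data.frame(case = "b", order = c(5, 5, 6, 6), occlusive = c(TRUE, TRUE, TRUE, FALSE))
  ft2 <- fraction_tables(cl, sf)
  expect_equal(ft2$per_order_occlusive$occlusive_fraction,
               c(1, 0.5))
})

test_that("setting comparisons expose means, medians and ratios coherently", {
  df <- rbind(data.frame(setting = "nb", c_max = c(0.3, 0.5), D_final_s = c(10, 20)),
              data.frame(setting = "b", c_max = c(0.6, 0.66), D_final_s = c(40, 56)))
  cmp <- compare_settings(df, reference = "nb", treatment = "b")
  r <- cmp[cmp$metric == "c_max", ]
  expect_equal(r$mean_ratio, 0.63 / 0.40)
  expect_equal(r$mean_percent, 57.5)
  expect_equal(r$median_ratio, 1 + r$median_percent / 100, tolerance = 1e-12)
  # unpaired cohorts are refused unless explicitly allowed
  dfp <- df
  dfp$seed <- 1
  dfp$truth_id <- c(1, 2, 1, 3)
  expect_error(compare_settings(dfp, "nb", "b"), "not paired")
  expect_s3_class(compare_settings(dfp, "nb", "b", allow_unpaired = TRUE),
                  "data.frame")
})
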
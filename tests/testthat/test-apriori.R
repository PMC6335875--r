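# cohort builder for screening power checks
screen_cohort <- function(..., seed = 21L) {
  generate_cohort(small_config(...,
                               n_subjects = 12, n_features = 60,
                               n_trend = 10, n_circadian = 10,
                               n_condition = 10, n_mixed = 5,
                               flag_rate = 0, seed = seed))
}

test_that("trend test detects real slopes and is exact when noiseless", {
  ch <- screen_cohort(trend_slope = 0.05, noise_sd = 0.1, trait_sd = 0.5)
  tf <- ch$truth[ch$truth$class == "trend", ]
  sc <- screen_features(ch$expression, ch$metadata)
  got <- sc[match(tf$feature_id, sc$feature_id), ]
  # significant in both conditions with concordant (true) sign
  expect_true(all(got$p_s < 0.05 & got$p_i < 0.05))
  expect_true(all(sign(got$slope_s) == sign(tf$a_g)))
  expect_true(all(sign(got$slope_i) == sign(tf$a_g)))

  # noiseless pure trend: slope recovered exactly, p numerically tiny
  ch0 <- generate_cohort(synthetic_config(n_subjects = 6, n_features = 10,
                                          n_trend = 10, n_circadian = 0,
                                          n_condition = 0, n_mixed = 0,
                                          trend_slope = 0.05, trait_sd = 0,
                                          noise_sd = 0, flag_rate = 0,
                                          seed = 1L))
  tt <- trend_test(ch0$expression[1, ], ch0$metadata)
  expect_equal(unname(tt$slope["sufficient"]),
               ch0$truth$a_g[1], tolerance = 1e-10)
  expect_lt(max(tt$p), 1e-12)
})

test_that("null features reject near the nominal screening level", {
  ch <- generate_cohort(synthetic_config(n_subjects = 12,
                                         n_features = 1000,
                                         n_trend = 0, n_circadian = 0,
                                         n_condition = 0, n_mixed = 0,
                                         trait_sd = 1, noise_sd = 0.4,
                                         flag_rate = 0, seed = 31L))
  sc <- screen_features(ch$expression, ch$metadata)
  for (p in list(sc$p_s, sc$p_circ, sc$p_cond)) {
    rate <- mean(p < 0.05)
    expect_gt(rate, 0.02)
    expect_lt(rate, 0.09)
  }
})

test_that("cosinor recovers amplitude and detects circadian features", {
  ch <- screen_cohort(circadian_amplitude = 0.5, noise_sd = 0.1,
                      trait_sd = 0.5)
  cf <- ch$truth[ch$truth$class == "circadian", ]
  sc <- screen_features(ch$expression, ch$metadata)
  got <- sc[match(cf$feature_id, sc$feature_id), ]
  expect_true(all(got$p_circ < 0.05))
  expect_true(all(abs(got$amplitude - 0.5) < 0.1))  # within 20%

  # noiseless pure cosine: amplitude exact
  ch0 <- generate_cohort(synthetic_config(n_subjects = 6, n_features = 5,
                                          n_trend = 0, n_circadian = 5,
                                          n_condition = 0, n_mixed = 0,
                                          circadian_amplitude = 0.7,
                                          trait_sd = 0, noise_sd = 0,
                                          flag_rate = 0, seed = 2L))
  ct <- circadian_test(ch0$expression[1, ], ch0$metadata)
  expect_equal(ct$amplitude, 0.7, tolerance = 1e-9)
})

test_that("paired condition test is powered despite trait variance", {
  ch <- generate_cohort(synthetic_config(n_subjects = 18, n_features = 40,
                                         n_trend = 0, n_circadian = 0,
                                         n_condition = 20, n_mixed = 0,
                                         condition_effect = 0.6,
                                         trait_sd = 1, noise_sd = 0.3,
                                         flag_rate = 0, seed = 41L))
  cf <- ch$truth[ch$truth$class == "condition", ]
  sc <- screen_features(ch$expression, ch$metadata)
  got <- sc[match(cf$feature_id, sc$feature_id), ]
  expect_gt(mean(got$p_cond < 0.05), 0.9)   # power > 0.9
  expect_true(all(sign(got$shift) == sign(cf$delta_g)))

  # zero effect, zero noise -> shift exactly 0
  ch0 <- generate_cohort(synthetic_config(n_subjects = 6, n_features = 5,
                                          n_trend = 0, n_circadian = 0,
                                          n_condition = 0, n_mixed = 0,
                                          trait_sd = 0.5, noise_sd = 0,
                                          flag_rate = 0, seed = 3L))
  ct <- condition_test(ch0$expression[1, ], ch0$metadata)
  expect_equal(ct$shift, 0, tolerance = 1e-12)
})

test_that("a-priori sets recover their feature classes and stay disjoint", {
  ch <- generate_cohort(synthetic_config(n_subjects = 18, n_features = 200,
                                         n_trend = 50, n_circadian = 50,
                                         n_condition = 50, n_mixed = 10,
                                         trend_slope = 0.05,
                                         circadian_amplitude = 0.5,
                                         condition_effect = 0.6,
                                         trait_sd = 1, noise_sd = 0.3,
                                         flag_rate = 0, seed = 51L))
  sc <- screen_features(ch$expression, ch$metadata)
  hrs <- select_a_priori(sc, "hours_awake")
  suf <- select_a_priori(sc, "sleep_sufficiency")
  expect_length(intersect(hrs, suf), 0L)
  cls <- ch$truth$class[match(hrs, ch$truth$feature_id)]
  trend_ids <- ch$truth$feature_id[ch$truth$class == "trend"]
  # recall of the trend class
  expect_gte(sum(trend_ids %in% hrs) / length(trend_ids), 0.8)
  # condition features leak in at most at the false-positive level
  n_cond_leaked <- sum(cls == "condition")
  expect_lte(n_cond_leaked, ceiling(0.05 * 50) + 2)
  # sleep-sufficiency set is dominated by condition features
  cls_s <- ch$truth$class[match(suf, ch$truth$feature_id)]
  cond_ids <- ch$truth$feature_id[ch$truth$class == "condition"]
  expect_gte(sum(cond_ids %in% suf) / length(cond_ids), 0.8)
  # mixed trend+condition features are excluded from both sets
  mixed_ids <- ch$truth$feature_id[ch$truth$class == "mixed"]
  expect_length(intersect(mixed_ids, c(hrs, suf)), 0L)
})

test_that("lowering alpha_screen weakly shrinks the positive criteria", {
  # the conjunction with negated exclusion criteria is not monotone in
  # alpha (negations grow as alpha falls), but each positive criterion is
  ch <- screen_cohort()
  sc <- screen_features(ch$expression, ch$metadata)
  alphas <- c(0.1, 0.05, 0.01, 0.001)
  n_trend <- vapply(alphas, function(a)
    sum(sc$p_s < a & sc$p_i < a & sign(sc$slope_s) == sign(sc$slope_i)),
    numeric(1))
  n_cond <- vapply(alphas, function(a) sum(sc$p_cond < a), numeric(1))
  expect_true(all(diff(n_trend) <= 0))
  expect_true(all(diff(n_cond) <= 0))
})

test_that("an all-null cohort yields only small false-positive sets", {
  ch <- generate_cohort(synthetic_config(n_subjects = 12, n_features = 300,
                                         n_trend = 0, n_circadian = 0,
                                         n_condition = 0, n_mixed = 0,
                                         trait_sd = 1, noise_sd = 0.4,
                                         flag_rate = 0, seed = 61L))
  sc <- screen_features(ch$expression, ch$metadata)
  hrs <- suppressMessages(select_a_priori(sc, "hours_awake"))
  suf <- suppressMessages(select_a_priori(sc, "sleep_sufficiency"))
  # hours-awake needs joint trend significance in both conditions with
  # concordant sign: expected mass ~ alpha^2 / 2
  expect_lte(length(hrs), 4)
  # sleep-sufficiency mass ~ alpha * (1 - alpha) * (1 - 2 alpha) ~ 0.043
  expect_lte(length(suf), qbinom(0.999, 300, 0.05))
})

test_that("degenerate designs are rejected", {
  ch <- generate_cohort(small_config())
  md <- ch$metadata
  md$hours_awake <- 20
  expect_error(screen_features(ch$expression, md), "constant|degenerate")
  md2 <- ch$metadata
  md2$clock_time <- 3
  expect_error(screen_features(ch$expression, md2), "half a cycle")
})
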
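cohort36 <- function(seed = 2L, flag_rate = 0)
  generate_cohort(synthetic_config(n_subjects = 36, n_features = 50,
                                   n_trend = 5, n_circadian = 5,
                                   n_condition = 5, n_mixed = 0,
                                   flag_rate = flag_rate, seed = seed))

test_that("UPUS split is subject-disjoint and sex-balanced", {
  ch <- cohort36()
  sp <- split_upus(ch$metadata, seed = 4L)
  expect_length(sp$train_subjects, 18L)
  expect_length(sp$validation_subjects, 18L)
  expect_length(intersect(sp$train_subjects, sp$validation_subjects), 0L)
  expect_length(intersect(sp$train_sample_ids, sp$validation_sample_ids), 0L)
  sex <- unique(ch$metadata[, c("subject_id", "sex")])
  males_train <- sum(sex$sex[sex$subject_id %in% sp$train_subjects] == "M")
  expect_equal(males_train, 9L)
  # all of a subject's samples follow the subject
  s <- sp$train_subjects[1]
  expect_true(all(ch$metadata$sample_id[ch$metadata$subject_id == s] %in%
                    sp$train_sample_ids))
  # reproducible under the same seed, different under another
  expect_identical(split_upus(ch$metadata, seed = 4L)$train_subjects,
                   sp$train_subjects)
  expect_false(identical(split_upus(ch$metadata, seed = 5L)$train_subjects,
                         sp$train_subjects))
})

test_that("UPUS warns and keeps a singleton stratum in training", {
  ch <- cohort36()
  md <- ch$metadata
  md$sex[md$subject_id == "sub01"] <- "X"
  expect_warning(sp <- split_upus(md, seed = 1L), "single subject")
  expect_true("sub01" %in% sp$train_subjects)
})

test_that("OPUS split crosses conditions with balance", {
  ch <- cohort36()
  sp <- split_opus(ch$metadata, seed = 9L)
  # every subject on both sides
  expect_setequal(sp$train_subjects, sp$validation_subjects)
  expect_length(intersect(sp$train_sample_ids, sp$validation_sample_ids), 0L)
  md <- ch$metadata
  tr <- md[md$sample_id %in% sp$train_sample_ids, ]
  blocks <- unique(tr[, c("subject_id", "condition")])
  expect_equal(nrow(blocks), 36L)         # one condition block per subject
  n_suff <- sum(blocks$condition == "sufficient")
  expect_lte(abs(n_suff - 18L), 1L)
  # a subject's other condition is in validation
  va <- md[md$sample_id %in% sp$validation_sample_ids, ]
  s <- blocks$subject_id[1]
  expect_false(blocks$condition[1] ==
                 unique(va$condition[va$subject_id == s]))
})

test_that("OPUS excludes subjects lacking one condition", {
  ch <- generate_cohort(small_config())
  md <- ch$metadata[!(ch$metadata$subject_id == "sub02" &
                        ch$metadata$condition == "insufficient"), ]
  expect_warning(sp <- split_opus(md, seed = 1L), "sub02")
  expect_false("sub02" %in% sp$train_subjects)
})

test_that("acute_loss assembly counts and classes", {
  ch <- cohort36()
  lab <- assemble_variable(ch$expression, ch$metadata, "acute_loss",
                           "between")
  # 36 subjects x 2 conditions at samples #1 and #9
  expect_equal(nrow(lab$x), 144L)
  expect_equal(unname(table(lab$target)["positive"]), 72L)
  # per UPUS side: 18 subjects -> 72 units, 36 per class
  sp <- split_upus(ch$metadata, seed = 1L)
  tr <- subset_samples(ch$expression, ch$metadata, sp$train_sample_ids)
  lab_tr <- assemble_variable(tr$expression, tr$metadata, "acute_loss",
                              "between")
  expect_equal(nrow(lab_tr$x), 72L)
  expect_equal(as.integer(table(lab_tr$target)), c(36L, 36L))
  # within mode: (#2-#1) negative vs (#10-#1) positive
  labw <- assemble_variable(ch$expression, ch$metadata, "acute_loss",
                            "within")
  expect_equal(nrow(labw$x), 144L)
  expect_equal(as.integer(table(labw$target)), c(72L, 72L))
})

test_that("gt24 thresholds at 24 hours awake", {
  ch <- generate_cohort(small_config())
  lab <- assemble_variable(ch$expression, ch$metadata, "gt24", "between")
  md <- ch$metadata[match(lab$ids, ch$metadata$sample_id), ]
  expect_identical(lab$target == "positive", md$hours_awake > 24)
  # 22.5 hr -> negative; 25.5 hr -> positive
  expect_equal(as.character(lab$target[md$hours_awake == 22.5][1]),
               "negative")
  expect_equal(as.character(lab$target[md$hours_awake == 25.5][1]),
               "positive")
})

test_that("chronic insufficiency uses #1 with fallback #2", {
  ch <- cohort36()
  lab <- assemble_variable(ch$expression, ch$metadata,
                           "chronic_insufficiency")
  expect_equal(nrow(lab$x), 72L)  # one sample per (subject, condition)
  md <- ch$metadata[match(lab$ids, ch$metadata$sample_id), ]
  expect_true(all(md$sample_index == 1L))
  expect_identical(lab$target == "positive", md$condition == "insufficient")
  # remove one subject's #1 in one condition: falls back to #2
  drop_id <- ch$metadata$sample_id[ch$metadata$subject_id == "sub03" &
                                     ch$metadata$condition == "sufficient" &
                                     ch$metadata$sample_index == 1L]
  keep <- setdiff(colnames(ch$expression), drop_id)
  lab2 <- assemble_variable(ch$expression[, keep],
                            ch$metadata[ch$metadata$sample_id %in% keep, ],
                            "chronic_insufficiency")
  md2 <- ch$metadata[match(lab2$ids, ch$metadata$sample_id), ]
  got <- md2[md2$subject_id == "sub03" & md2$condition == "sufficient", ]
  expect_equal(got$sample_index, 2L)
  # the #9 variant
  lab9 <- assemble_variable(ch$expression, ch$metadata,
                            "chronic_insufficiency", sample_index = 9)
  md9 <- ch$metadata[match(lab9$ids, ch$metadata$sample_id), ]
  expect_true(all(md9$sample_index == 9L))
})

test_that("sleep_change pairs visits and labels sleep decrease positive", {
  ch <- cohort36()
  lab <- assemble_variable(ch$expression, ch$metadata, "sleep_change")
  expect_equal(nrow(lab$x), 36L)   # one differential unit per subject
  first <- unique(ch$metadata[ch$metadata$visit == 1,
                              c("subject_id", "condition")])
  # positive = sufficient week first (sleep decreased at visit 2)
  pos <- lab$ids[lab$target == "positive"]
  expect_setequal(pos, first$subject_id[first$condition == "sufficient"])
  # the differential value is visit1 - visit2 at sample index 2
  s <- lab$ids[1]
  md <- ch$metadata
  v1 <- md$sample_id[md$subject_id == s & md$visit == 1 &
                       md$sample_index == 2L]
  v2 <- md$sample_id[md$subject_id == s & md$visit == 2 &
                       md$sample_index == 2L]
  expect_equal(unname(lab$x[s, ]),
               unname(ch$expression[, v1] - ch$expression[, v2]))
})

test_that("train/validation labeled sets stay disjoint for every variable", {
  ch <- cohort36()
  for (scheme in c("UPUS", "OPUS")) {
    sp <- if (scheme == "UPUS") split_upus(ch$metadata, seed = 3L)
          else split_opus(ch$metadata, seed = 3L)
    tr <- subset_samples(ch$expression, ch$metadata, sp$train_sample_ids)
    va <- subset_samples(ch$expression, ch$metadata,
                         sp$validation_sample_ids)
    for (v in c("time_awake", "acute_loss", "chronic_insufficiency")) {
      lt <- assemble_variable(tr$expression, tr$metadata, v)
      lv <- assemble_variable(va$expression, va$metadata, v)
      expect_length(intersect(lt$ids, lv$ids), 0L)
      if (scheme == "UPUS")
        expect_length(intersect(lt$subjects, lv$subjects), 0L)
      if (is.factor(lt$target))
        expect_lte(abs(diff(table(lt$target))), 1L)
    }
  }
})
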
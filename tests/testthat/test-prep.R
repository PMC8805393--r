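test_that("inclusion filters count each exclusion on the toy cohort", {
  flt <- apply_inclusion_filters(toy_cohort())
  rep <- flt$report
  expect_equal(rep$n_input_patients, 5)
  expect_equal(rep$n_excluded_polypharmacy, 1)      # patient B
  expect_equal(rep$n_excluded_single_observation, 1) # patient C
  expect_equal(rep$n_visits_truncated_2y, 1)         # D's 2.5-year visit
  expect_equal(rep$n_excluded_age_range, 0)
  expect_equal(rep$n_output_patients, 3)
  expect_setequal(unique(flt$cohort$patient_id), c("A", "D", "E"))
  # E (pre-prescription only) is retained: the 2-year cap is post-initiation
  expect_equal(sum(flt$cohort$patient_id == "E"), 2)
  # D lost exactly its late visit
  expect_equal(max(flt$cohort$time[flt$cohort$patient_id == "D"]), 1.0)
})

test_that("filters are idempotent and error on empty output", {
  once <- apply_inclusion_filters(toy_cohort())
  twice <- apply_inclusion_filters(once$cohort)
  expect_equal(twice$cohort, once$cohort)
  expect_equal(twice$report$n_excluded_polypharmacy, 0)
  expect_equal(twice$report$n_visits_truncated_2y, 0)

  solo <- toy_cohort()
  solo <- solo[solo$patient_id == "C", ]
  expect_error(apply_inclusion_filters(solo), "no patients retained")
})

test_that("age window exclusions are applied and counted", {
  coh <- toy_cohort()
  coh$age[coh$patient_id == "A"] <- 105
  rep <- apply_inclusion_filters(coh)$report
  expect_equal(rep$n_excluded_age_range, 1)
  expect_equal(rep$n_output_patients, 2)
})

test_that("visit encoding has the documented 20-dimensional layout", {
  v <- list(age = 81, duration = 0.5, score = 22, drug = "donepezil")
  p <- list(sex = "F", ethnicity = "white", marital_status = "not_available")
  enc <- encode_visit(v, p)
  expect_length(enc, 20)
  expect_identical(names(enc), encoded_feature_names())
  # not_available is a category of its own, not an imputation
  expect_equal(unname(enc["marital_not_available"]), 1)
  expect_equal(sum(enc[grep("^marital_", names(enc))]), 1)
  expect_equal(unname(enc["score"]), 22 / 30)
  expect_equal(unname(enc["age"]), 81)
  # determinism
  expect_identical(enc, encode_visit(v, p))
  # unscaled mode
  expect_equal(unname(encode_visit(v, p, scale_norm = FALSE)["score"]), 22)
})

test_that("encoding errors name the offending field", {
  v <- list(age = 81, duration = 0.5, score = 22, drug = "aspirin")
  p <- list(sex = "F", ethnicity = "white", marital_status = "married")
  expect_error(encode_visit(v, p), "drug")
  p$ethnicity <- "martian"
  v$drug <- "donepezil"
  expect_error(encode_visit(v, p), "ethnicity")
})

test_that("encode/decode is a bijection over every categorical level", {
  lv <- nntoc:::encoding_levels()
  for (sx in lv$sex) for (eth in lv$ethnicity) {
    for (mar in lv$marital_status) for (dr in lv$drug) {
      v <- list(age = 77.5, duration = 0.3, score = 13, drug = dr)
      p <- list(sex = sx, ethnicity = eth, marital_status = mar)
      dec <- decode_visit(encode_visit(v, p))
      expect_identical(dec$sex, sx)
      expect_identical(dec$ethnicity, eth)
      expect_identical(dec$marital_status, mar)
      expect_identical(dec$drug, dr)
      expect_equal(dec$score, 13)
    }
  }
})

test_that("short histories are left-zero-padded with the next visit as target", {
  coh <- toy_cohort()
  coh <- coh[coh$patient_id == "E", ]  # 2 visits
  sq <- build_sequences(coh, window_length = 4, mode = "random", seed = 1)
  expect_length(sq, 1)
  s <- sq[[1]]
  expect_equal(s$n_real_steps, 1)
  expect_true(all(s$steps[1:3, ] == 0))
  expect_gt(sum(abs(s$steps[4, ])), 0)
  expect_equal(s$target_score, 25)   # E's second visit
  # a 2-step window on a 3-visit patient has both steps real
  coh3 <- toy_cohort()
  coh3 <- coh3[coh3$patient_id == "A", ]
  s2 <- build_sequences(coh3, window_length = 2, mode = "random", seed = 1)[[1]]
  expect_equal(s2$n_real_steps, 2)
  expect_equal(sum(rowSums(abs(s2$steps)) == 0), 0)
})

test_that("window draws are contiguous, reproducible, and padding-consistent", {
  sim <- small_sim(n = 80, seed = 21)
  flt <- apply_inclusion_filters(sim$cohort)
  a <- build_sequences(flt$cohort, 4, mode = "random", seed = 7)
  b <- build_sequences(flt$cohort, 4, mode = "random", seed = 7)
  expect_identical(a, b)
  for (s in a) {
    zero_rows <- sum(rowSums(abs(s$steps)) == 0)
    expect_equal(zero_rows, nrow(s$steps) - s$n_real_steps)
    # real steps are time-ordered consecutive visits: durations of steps
    # 2..k are strictly positive
    real <- s$steps[rowSums(abs(s$steps)) > 0, , drop = FALSE]
    if (nrow(real) > 1) {
      expect_true(all(real[-1, "duration"] > 0))
    }
  }
  # draws > 1 multiplies the windows per patient
  d3 <- build_sequences(flt$cohort, 4, mode = "random", seed = 7, draws = 3)
  expect_length(d3, 3 * length(a))
})

test_that("initiation windows end at the first prescribed visit", {
  sim <- small_sim(n = 60, seed = 22)
  flt <- apply_inclusion_filters(sim$cohort)
  sq <- build_sequences(flt$cohort, 4, mode = "initiation")
  for (s in sq) {
    real <- s$steps[rowSums(abs(s$steps)) > 0, , drop = FALSE]
    on_drug <- real[, paste0("drug_", dementia_drugs())]
    if (s$n_real_steps > 0) {
      # exactly the last real step carries the prescription
      last <- real[nrow(real), paste0("drug_", dementia_drugs())]
      expect_equal(sum(last), 1)
      if (nrow(real) > 1) {
        expect_true(all(real[-nrow(real), "drug_none"] == 1))
      }
    }
  }
})

test_that("patient split reproduces the 2015/1343 arithmetic", {
  ids <- sprintf("P%04d", 1:3358)
  sp <- split_train_validation(ids, fraction = 0.60, seed = 3)
  expect_length(sp$train, 2015)
  expect_length(sp$validation, 1343)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_identical(sp, split_train_validation(ids, 0.60, seed = 3))
  expect_false(identical(sp, split_train_validation(ids, 0.60, seed = 4)))
  expect_error(split_train_validation("P1", 0.5), "at least 2")
  expect_error(split_train_validation(ids, 1.2), "fraction")
})
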
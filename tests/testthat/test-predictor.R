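test_that("model_spec enforces the two-layer recurrent core", {
  expect_error(model_spec(recurrent_layers = 1), "fixed at 2")
  expect_silent(model_spec(kind = "ridge", recurrent_layers = 1))
  expect_error(model_spec(learning_rate = 0), "learning_rate")
})

test_that("ridge recovers an exact linear target as the penalty vanishes", {
  set.seed(13)
  n <- 60
  sqs <- lapply(seq_len(n), function(i) {
    s <- make_sequence(n_real = 4, id = sprintf("L%02d", i),
                       fill = runif(1))
    s$steps[, "age"] <- runif(4, 60, 100)
    s$steps[, "duration"] <- runif(4, 0, 1)
    s
  })
  # target := linear function of the flattened (trainer-scaled) features,
  # re-expressed on the score scale; anchor-residualisation keeps linearity
  st <- nntoc:::stack_sequences(sqs)
  Xf <- nntoc:::flatten_X(st$X)
  w <- rnorm(ncol(Xf), sd = 0.005)
  y01 <- 0.5 + as.numeric(Xf %*% w)  # stays inside (0, 1): no clamping
  for (i in seq_len(n)) sqs[[i]]$target_score <- 30 * y01[i]
  m <- train_baseline("ridge", sqs, model_spec(kind = "ridge",
                                               l2_penalty = 1e-12))
  preds <- predict_score(m, sqs)
  expect_lt(mean(abs(preds - 30 * y01)), 1e-6)
})

test_that("oversampling balances target-drug counts by exact duplication", {
  counts <- c(donepezil = 10, galantamine = 3, rivastigmine = 2,
              memantine = 5)
  sqs <- unlist(lapply(names(counts), function(d) {
    lapply(seq_len(counts[[d]]), function(i) {
      make_sequence(target_drug = d, id = paste0(d, i))
    })
  }), recursive = FALSE)
  over <- oversample_minority(sqs, seed = 4)
  tab <- table(vapply(over, `[[`, character(1), "target_drug"))
  expect_true(all(tab == 10))
  # originals all retained, duplicates exact copies
  ids <- vapply(over, `[[`, character(1), "patient_id")
  orig_ids <- vapply(sqs, `[[`, character(1), "patient_id")
  expect_true(all(orig_ids %in% ids))
  extra <- ids[duplicated(ids)]
  expect_true(all(extra %in% orig_ids))  # multiset superset of originals
  for (i in which(duplicated(ids))) {
    expect_identical(over[[i]], over[[match(ids[i], ids)]])
  }
  # already balanced input is returned unchanged
  bal <- sqs[1:8]
  for (i in 1:8) bal[[i]]$target_drug <- dementia_drugs()[(i - 1) %% 4 + 1]
  expect_identical(oversample_minority(bal, seed = 1), bal)
})

test_that("a single-point grid is selected trivially", {
  sim <- small_sim(n = 40, seed = 81)
  flt <- apply_inclusion_filters(sim$cohort)
  sq <- build_sequences(flt$cohort, 4, mode = "random", seed = 1)
  gs <- grid_search("ridge", list(l2_penalty = 0.01), sq[1:20], sq[21:38])
  expect_equal(gs$best_spec$l2_penalty, 0.01)
  expect_equal(nrow(gs$results), 1)
})

test_that("multitask training matches single-task on an MMSE-only cohort", {
  sim <- small_sim(n = 70, seed = 82)
  flt <- apply_inclusion_filters(sim$cohort)
  sq <- build_sequences(flt$cohort, 4, mode = "random", seed = 2)
  spec <- model_spec(epochs = 40)
  single <- train_score_model(sq, spec, seed = 6)
  multi <- train_multitask(sq, spec, seed = 6)
  expect_true(multi$multitask)
  # same data, same masking-selected head: losses agree to training noise
  expect_equal(tail(multi$loss_trace, 1), tail(single$loss_trace, 1),
               tolerance = 0.35)
  mae_s <- prediction_mae(single, sq)
  mae_m <- prediction_mae(multi, sq)
  expect_lt(abs(mae_s - mae_m), 0.75)
})

test_that("multitask handles mixed scales and rejects unlabelled input", {
  sim_mmse <- small_sim(n = 40, seed = 83)
  sim_moca <- simulate_cohort(cohort_config(n_patients = 40,
                                            scale_kind = "MoCA",
                                            baseline_score_mean = 17.9,
                                            seed = 84))
  sq <- c(
    build_sequences(apply_inclusion_filters(sim_mmse$cohort)$cohort, 4,
                    mode = "random", seed = 1),
    build_sequences(apply_inclusion_filters(sim_moca$cohort)$cohort, 4,
                    mode = "random", seed = 1)
  )
  m <- train_multitask(sq, model_spec(epochs = 20), seed = 3)
  mae <- prediction_mae(m, sq)
  expect_true(is.finite(mae))
  bad <- sq
  bad[[1]]$scale_kind <- "SMMSE"
  expect_error(train_multitask(bad, model_spec(epochs = 2)),
               "labelled scale")
})

test_that("forest and cnn baselines beat the constant predictor when learnable", {
  cfg <- cohort_config(n_patients = 150, noise_sd = 0, round_scores = FALSE,
                       plateau_years = 0, n_pretreatment_range = c(0, 0),
                       seed = 85)
  sim <- simulate_cohort(cfg)
  flt <- apply_inclusion_filters(sim$cohort)
  sp <- split_train_validation(flt$cohort, 0.6, seed = 86)
  tr <- build_sequences(flt$cohort[flt$cohort$patient_id %in% sp$train, ],
                        4, mode = "random", seed = 1)
  va <- build_sequences(flt$cohort[flt$cohort$patient_id %in% sp$validation, ],
                        4, mode = "random", seed = 2)
  y_tr <- vapply(tr, `[[`, numeric(1), "target_score")
  y_va <- vapply(va, `[[`, numeric(1), "target_score")
  const_mae <- mean(abs(y_va - mean(y_tr)))
  forest <- train_baseline("random_forest", tr,
                           model_spec(kind = "random_forest", n_trees = 100))
  cnn <- train_baseline("cnn1d", tr, model_spec(kind = "cnn1d", epochs = 60))
  expect_lte(prediction_mae(forest, va), const_mae)
  expect_lte(prediction_mae(cnn, va), const_mae)
  expect_true(is.finite(prediction_mae(forest, va)))
})

test_that("drug-blind ablation makes predictions drug-invariant", {
  sim <- small_sim(n = 40, seed = 87)
  flt <- apply_inclusion_filters(sim$cohort)
  sq <- build_sequences(flt$cohort, 4, mode = "random", seed = 1)
  m <- train_score_model(sq, model_spec(epochs = 10, drug_blind = TRUE),
                         seed = 4)
  preds <- sapply(dementia_drugs(), function(d) predict_score(m, sq, d))
  expect_true(all(abs(preds - preds[, 1]) < 1e-12))
})
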
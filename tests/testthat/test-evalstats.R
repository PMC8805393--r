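# independent textbook-formula implementations used as oracles
oracle_welch <- function(m1, s1, n1, m2, s2, n2) {
  t <- (m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)
  df <- (s1^2 / n1 + s2^2 / n2)^2 /
    ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  c(t = t, df = df)
}
oracle_chi2 <- function(a, b, c, d, yates) {
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  adj <- if (yates) pmin(abs(o - e), 0.5) else 0
  sum((abs(o - e) - adj)^2 / e)
}

test_that("welch_t matches published group comparisons at printed precision", {
  age <- welch_t(81.12, 7.01, 222, 82.05, 6.73, 1550)
  expect_equal(round(age$t, 2), -1.86)
  expect_equal(round(age$df, 2), 282.50)
  mmse <- welch_t(20.84, 4.89, 222, 21.06, 5.20, 1550)
  expect_equal(round(mmse$t, 2), -0.62)
  expect_equal(round(mmse$df, 2), 297.27)
})

test_that("welch_t agrees with independent implementations to 1e-10", {
  set.seed(4)
  for (i in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    n1 <- sample(2:500, 1); n2 <- sample(2:500, 1)
    w <- welch_t(m1, s1, n1, m2, s2, n2)
    o <- oracle_welch(m1, s1, n1, m2, s2, n2)
    expect_lt(abs(w$t - o["t"]), 1e-10)
    expect_lt(abs(w$df - o["df"]), 1e-10)
  }
  # against stats::t.test on raw data carrying exactly these moments
  standardise <- function(n) {
    z <- seq_len(n)
    as.numeric(scale(z))
  }
  x <- 5 + 2 * standardise(41)
  y <- 4 + 3 * standardise(67)
  ref <- stats::t.test(x, y)
  w <- welch_t(mean(x), stats::sd(x), 41, mean(y), stats::sd(y), 67)
  expect_lt(abs(w$t - unname(ref$statistic)), 1e-10)
  expect_lt(abs(w$df - unname(ref$parameter)), 1e-10)
  expect_lt(abs(w$p - ref$p.value), 1e-10)
})

test_that("welch_t handles identical and degenerate inputs", {
  w <- welch_t(5, 1, 10, 5, 1, 10)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  expect_error(welch_t(5, 0, 10, 4, 1, 10), "positive SDs")
  expect_error(welch_t(5, 1, 1, 4, 1, 10), "n >= 2")
})

test_that("chi_square_2x2 reproduces published table statistics", {
  # counts reconstructed from the published group percentages
  marital <- chi_square_2x2(76, 146, 648, 902)
  expect_equal(round(marital$chi2, 2), 4.30)
  ethnicity <- chi_square_2x2(180, 42, 1267, 283)
  expect_equal(round(ethnicity$chi2, 2), 0.02)
  # perfectly proportional table, uncorrected: exactly zero
  prop <- chi_square_2x2(10, 10, 100, 100, continuity = FALSE)
  expect_equal(prop$chi2, 0)
})

test_that("chi_square_2x2 agrees with the textbook formula to 1e-10", {
  set.seed(8)
  for (i in 1:20) {
    cells <- sample(1:80, 4, replace = TRUE)
    for (yates in c(TRUE, FALSE)) {
      got <- chi_square_2x2(cells[1], cells[2], cells[3], cells[4],
                            continuity = yates)
      expect_lt(abs(got$chi2 - oracle_chi2(cells[1], cells[2], cells[3],
                                           cells[4], yates)), 1e-10)
    }
  }
  expect_error(chi_square_2x2(0, 0, 3, 4), "margins")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(chi_square_2x2(1.5, 2, 3, 4), "non-negative")
})

test_that("trajectory declines use the initiation visit as reference", {
  mk <- function(id, times, scores, drug) {
    data.frame(patient_id = id, visit = seq_along(times), time = times,
               age = 80, sex = "F", ethnicity = "white",
               marital_status = "married", scale_kind = "MMSE",
               score = scores, drug = drug, duration = c(0, diff(times)),
               stringsAsFactors = FALSE)
  }
  # sign convention: 24 -> 20 is a decline of +4
  coh <- rbind(mk("a", c(0, 1.5), c(24, 22), "donepezil"),
               mk("b", c(0, 1.6), c(25, 21), "donepezil"),
               mk("c", c(0, 1.5), c(20, 20), "memantine"))
  ts <- trajectory_summary(coh, list(g1 = c("a", "b"), g2 = "c"),
                           bin_width = 1, horizon = 2)
  row <- ts[ts$group == "g1" & ts$bin == 2, ]
  expect_equal(row$n, 2)
  expect_equal(row$mean_decline, 3)        # declines 2 and 4
  expect_equal(row$sd, sqrt(2))
  expect_equal(row$se, 1)
  # constant-score patient: decline 0
  expect_equal(ts$mean_decline[ts$group == "g2" & ts$bin == 2], 0)
  # bin 0 is the index visit: decline 0 by construction
  expect_true(all(ts$mean_decline[ts$bin == 0] == 0))
  # empty bin recorded as missing, not zero
  empty <- ts[ts$group == "g1" & ts$bin == 1, ]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_decline))
})

test_that("constant-score cohorts yield all-zero trajectories", {
  cfg <- cohort_config(n_patients = 20, noise_sd = 0, round_scores = FALSE,
                       base_decline_rate_mean = 1, base_decline_rate_sd = 0,
                       n_pretreatment_range = c(0, 0), plateau_years = 0,
                       drug_effect_matrix_spec = function(p, h)
                         matrix(1, nrow(p), 4),
                       seed = 3)
  sim <- simulate_cohort(cfg)
  ids <- sim$truth$patient_id
  ts <- trajectory_summary(sim$cohort,
                           list(g1 = ids[1:10], g2 = ids[11:20]))
  expect_true(all(ts$mean_decline[!is.na(ts$mean_decline)] == 0))
})

test_that("recovery_rate scores matches against planted truth", {
  truth <- data.frame(patient_id = sprintf("P%02d", 1:10),
                      best_drug = rep(dementia_drugs(), length.out = 10))
  recs <- data.frame(patient_id = truth$patient_id, nntoc = truth$best_drug)
  perfect <- recovery_rate(recs, truth)
  expect_equal(perfect$rate, 1.0)

  recs2 <- recs
  recs2$nntoc[c(2, 4, 6, 8)] <- c("donepezil", "donepezil", "memantine",
                                  "rivastigmine")
  # rows 2,4,6,8 originally galantamine/memantine/galantamine/memantine
  hand_rate <- mean(recs2$nntoc == truth$best_drug)
  got <- recovery_rate(recs2, truth)
  expect_equal(got$rate, hand_rate)
  expect_equal(got$rate, 0.6)
  expect_equal(got$p,
               stats::binom.test(6, 10, 0.25)$p.value)

  bad <- recs
  bad$patient_id[1] <- "ZZZ"
  expect_error(recovery_rate(bad, truth), "missing from truth")
})

test_that("permutation importance is exactly zero for a constant predictor", {
  sim <- small_sim(n = 60, seed = 51)
  sim$cohort$sex <- "F"   # constant across all patients
  flt <- apply_inclusion_filters(sim$cohort)
  sq <- build_sequences(flt$cohort, 4, mode = "random", seed = 1)
  # identical padding patterns so the shuffle is an exact identity
  sq <- Filter(function(s) s$n_real_steps == 4, sq)
  m <- train_baseline("ridge", sq, model_spec(kind = "ridge"))
  imp <- permutation_importance(m, sq, predictor = "sex", repeats = 3,
                                seed = 2)
  expect_equal(imp$pct_increase, 0)
  expect_error(permutation_importance(m, sq, predictor = "shoe_size"),
               "unknown predictor")
})
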
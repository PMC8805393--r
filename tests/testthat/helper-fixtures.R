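# in-code fixtures shared across test files

# minimal hand-built visit table; patient layout:
#   A: 3 visits on donepezil (compliant)
#   B: two distinct drugs (polypharmacy)
#   C: a single visit
#   D: 4 visits, the last 2.5 years after initiation (gets truncated)
#   E: 2 visits, both pre-prescription
toy_cohort <- function() {
  mk <- function(id, times, drugs, scores) {
    data.frame(patient_id = id, visit = seq_along(times), time = times,
               age = 75 + times, sex = "F", ethnicity = "white",
               marital_status = "married", scale_kind = "MMSE",
               score = scores, drug = drugs,
               duration = c(0, diff(times)), stringsAsFactors = FALSE)
  }
  rbind(
    mk("A", c(0, 0.5, 1.2), rep("donepezil", 3), c(24, 23, 22)),
    mk("B", c(0, 0.6, 1.0), c("donepezil", "memantine", "memantine"),
       c(20, 19, 18)),
    mk("C", 0, "rivastigmine", 21),
    mk("D", c(0, 0.5, 1.0, 2.5), rep("galantamine", 4), c(25, 24, 23, 20)),
    mk("E", c(0, 0.7), c("none", "none"), c(26, 25))
  )
}

# small deterministic simulated cohort for pipeline-level tests
small_sim <- function(n = 120, seed = 42, ...) {
  simulate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}

# a valid encoded_sequence built directly (bypassing the cohort), with
# controllable step features
make_sequence <- function(window = 4, n_real = 2, target_score = 20,
                          target_drug = "donepezil", scale_kind = "MMSE",
                          id = "X1", fill = NULL) {
  nms <- c(encoded_feature_names(), nntoc:::target_block_names())
  steps <- matrix(0, window, length(nms), dimnames = list(NULL, nms))
  for (j in seq_len(n_real)) {
    r <- window - n_real + j
    steps[r, "sex_F"] <- 1
    steps[r, "ethnicity_white"] <- 1
    steps[r, "marital_married"] <- 1
    steps[r, "drug_donepezil"] <- 1
    steps[r, "age"] <- 80
    steps[r, "duration"] <- if (j == 1) 0 else 0.5
    steps[r, "score"] <- if (is.null(fill)) 20 / 30 else fill
  }
  steps[window, paste0("target_drug_", target_drug)] <- 1
  steps[window, "target_duration"] <- 0.5
  structure(list(patient_id = id, steps = steps,
                 target_score = target_score, target_drug = target_drug,
                 n_real_steps = n_real, scale_kind = scale_kind),
            class = "encoded_sequence")
}
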
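#' Apply the cohort inclusion/exclusion filters
#'
#' Reproduces the sample-preparation rules for the longitudinal analysis:
#' patients outside the 59-102 age window are excluded; patients taking more
#' than one distinct anti-dementia drug (polypharmacy) are excluded; visits
#' more than 2 years after the initial prescription are truncated; patients
#' left with fewer than 2 observations are excluded (no follow-up to define
#' an outcome). Patients with no prescription at all are retained — the
#' 2-year cap only applies post-initiation.
#'
#' @param cohort Visit data.frame as produced by [simulate_cohort()] (columns
#'   `patient_id`, `time`, `age`, `score`, `drug`, ...). `drug` uses `"none"`
#'   (or `NA`) for unprescribed visits.
#' @param cap_years Follow-up cap after first prescription, years (default 2).
#' @param age_window Permitted age window (default `c(59, 102)`).
#' @return List with class `filtered_cohort`:
#'   \describe{
#'     \item{cohort}{the retained visit table}
#'     \item{report}{a `filter_report`: `n_input_patients`,
#'       `n_excluded_age_range`, `n_excluded_polypharmacy`,
#'       `n_excluded_single_observation`, `n_visits_truncated_2y`,
#'       `n_output_patients`}
#'   }
#' @examples
#' sim <- simulate_cohort(cohort_config(n_patients = 30, seed = 2))
#' flt <- apply_inclusion_filters(sim$cohort)
#' flt$report
#' @export
apply_inclusion_filters <- function(cohort, cap_years = 2,
                                    age_window = c(59, 102)) {
  stopifnot(is.data.frame(cohort),
            all(c("patient_id", "time", "age", "drug") %in% names(cohort)))
  cohort <- cohort[order(cohort$patient_id, cohort$time), , drop = FALSE]
  drug <- as.character(cohort$drug)
  drug[is.na(drug)] <- "none"
  cohort$drug <- drug

  ids <- unique(cohort$patient_id)
  n_input <- length(ids)

  by_id <- split(seq_len(nrow(cohort)), cohort$patient_id)
  by_id <- by_id[ids]  # preserve first-appearance order

  n_age <- 0L; n_poly <- 0L; n_single <- 0L; n_trunc <- 0L
  keep_rows <- integer(0)
  for (id in ids) {
    rows <- by_id[[id]]
    sub <- cohort[rows, , drop = FALSE]
    if (any(sub$age < age_window[1] | sub$age > age_window[2])) {
      n_age <- n_age + 1L
      next
    }
    on_drug <- sub$drug != "none"
    if (length(unique(sub$drug[on_drug])) > 1L) {
      n_poly <- n_poly + 1L
      next
    }
    if (any(on_drug)) {
      t0 <- min(sub$time[on_drug])
      drop <- sub$time > t0 + cap_years
      n_trunc <- n_trunc + sum(drop)
      rows <- rows[!drop]
    }
    if (length(rows) < 2L) {
      n_single <- n_single + 1L
      next
    }
    keep_rows <- c(keep_rows, rows)
  }

  out <- cohort[sort(keep_rows), , drop = FALSE]
  rownames(out) <- NULL
  n_output <- length(unique(out$patient_id))
  if (n_output == 0L) {
    stop("no patients retained after inclusion filters", call. = FALSE)
  }
  report <- structure(
    list(n_input_patients = n_input,
         n_excluded_age_range = n_age,
         n_excluded_polypharmacy = n_poly,
         n_excluded_single_observation = n_single,
         n_visits_truncated_2y = n_trunc,
         n_output_patients = n_output),
    class = "filter_report"
  )
  stopifnot(n_output == n_input - n_age - n_poly - n_single)
  structure(list(cohort = out, report = report), class = "filtered_cohort")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (f in names(x)) cat(sprintf("  %-30s %d\n", f, x[[f]]))
  invisible(x)
}

# categorical level sets of the visit encoding, in fixed one-hot order
encoding_levels <- function() {
  list(
    sex = c("M", "F"),
    ethnicity = c("white", "Asian", "black", "other", "not_available"),
    marital_status = c("married", "separated", "single", "widowed",
                       "not_available"),
    drug = c(dementia_drugs(), "none")
  )
}

#' Feature names of the encoded visit vector
#'
#' @param missing_indicator Include the score-missingness indicator column.
#' @return Character vector of feature names, in encoding order: one-hot
#'   blocks for sex (2), ethnicity (5), marital status (5), drug (5, incl.
#'   `none`), then continuous `age`, `duration`, `score`
#'   (+ `score_missing` when enabled). Length 20 by default.
#' @export
encoded_feature_names <- function(missing_indicator = FALSE) {
  lv <- encoding_levels()
  nm <- c(paste0("sex_", lv$sex),
          paste0("ethnicity_", lv$ethnicity),
          paste0("marital_", lv$marital_status),
          paste0("drug_", lv$drug),
          "age", "duration", "score")
  if (missing_indicator) nm <- c(nm, "score_missing")
  nm
}

# names of the target block appended to the last real step of a sequence
target_block_names <- function() {
  c(paste0("target_drug_", dementia_drugs()), "target_duration")
}

#' Encode one visit as a numeric feature vector
#'
#' One-hot blocks for sex, ethnicity, marital status and drug — the
#' `not_available` level is a category of its own; nothing is imputed — plus
#' continuous age (years), duration since the previous visit (years) and the
#' cognitive score (min-max scaled to \[0, 1\] over the 0-30 range when
#' `scale_norm` is on).
#'
#' @param visit One visit: a list or one-row data.frame with `age`,
#'   `duration`, `score`, `drug` (and optionally the demographic fields).
#' @param patient Patient demographics: list/one-row data.frame with `sex`,
#'   `ethnicity`, `marital_status`; may be the visit row itself.
#' @param scale_norm Divide the score by 30 (default `TRUE`).
#' @param missing_indicator Add a `score_missing` column; a missing score is
#'   then zero-filled and flagged instead of raising an error.
#' @return Named numeric vector (length 20 under the default level sets).
#' @examples
#' v <- list(age = 81, duration = 0.5, score = 22, drug = "donepezil")
#' p <- list(sex = "F", ethnicity = "white", marital_status = "not_available")
#' encode_visit(v, p)
#' @export
encode_visit <- function(visit, patient = visit, scale_norm = TRUE,
                         missing_indicator = FALSE) {
  lv <- encoding_levels()
  one_hot <- function(value, field) {
    value <- as.character(value)
    levels <- lv[[field]]
    if (is.na(value) && field == "drug") value <- "none"
    if (!value %in% levels) {
      stop(sprintf("unknown level '%s' for field '%s'", value, field),
           call. = FALSE)
    }
    as.numeric(levels == value)
  }
  score <- as.numeric(visit$score)
  miss <- is.na(score)
  if (miss && !missing_indicator) {
    stop("missing score with missing_indicator = FALSE", call. = FALSE)
  }
  score_val <- if (miss) 0 else if (scale_norm) score / 30 else score
  out <- c(one_hot(patient$sex, "sex"),
           one_hot(patient$ethnicity, "ethnicity"),
           one_hot(patient$marital_status, "marital_status"),
           one_hot(visit$drug, "drug"),
           as.numeric(visit$age),
           as.numeric(visit$duration),
           score_val)
  if (missing_indicator) out <- c(out, as.numeric(miss))
  names(out) <- encoded_feature_names(missing_indicator)
  out
}

#' Decode an encoded visit vector
#'
#' Inverse of [encode_visit()] on the categorical blocks (and continuous
#' fields). Used to assert the encoding is a bijection on the level sets.
#'
#' @param vec Named numeric vector from [encode_visit()].
#' @param scale_norm Whether the score was min-max scaled.
#' @return List with `sex`, `ethnicity`, `marital_status`, `drug`, `age`,
#'   `duration`, `score`.
#' @export
decode_visit <- function(vec, scale_norm = TRUE) {
  lv <- encoding_levels()
  pick <- function(prefix, levels) {
    block <- vec[paste0(prefix, levels)]
    levels[which(block == 1)]
  }
  miss <- "score_missing" %in% names(vec) && vec[["score_missing"]] == 1
  score <- if (miss) NA_real_ else if (scale_norm) {
    vec[["score"]] * 30
  } else {
    vec[["score"]]
  }
  list(sex = pick("sex_", lv$sex),
       ethnicity = pick("ethnicity_", lv$ethnicity),
       marital_status = pick("marital_", lv$marital_status),
       drug = pick("drug_", lv$drug),
       age = vec[["age"]],
       duration = vec[["duration"]],
       score = score)
}

#' Build fixed-length, left-zero-padded training/evaluation sequences
#'
#' For every eligible patient (at least 2 visits) emits one window of
#' `window_length` consecutive visits plus a prediction target: the score at
#' the visit immediately following the window, with that visit's drug as the
#' target drug. Patients with fewer than `window_length` usable visits are
#' left-zero-padded, e.g. a 2-visit patient under window 4 yields
#' `[0, 0, 0, encode(visit1)]` with visit 2 as target. The target visit's
#' drug (one-hot over the four canonical drugs) and the duration from the
#' window's last visit to the target are appended to the last real step;
#' counterfactual prediction later substitutes this block.
#'
#' @param cohort Filtered visit table ([apply_inclusion_filters()]).
#' @param window_length Steps per sequence (4 for MMSE mode, 2 for MoCA).
#' @param mode Window placement: `"random"` — a uniformly random contiguous
#'   run (the training draw); `"initiation"` — the window ends at the first
#'   prescribed visit (the main evaluation); `"random_visit"` — the window
#'   ends at a uniformly random visit.
#' @param seed Integer seed for the random draws (ignored for
#'   `"initiation"`).
#' @param draws Number of independent window draws per patient (`"random"`
#'   mode only). Values above 1 emulate re-drawing a fresh window each
#'   training epoch; 1 is the strict one-window-per-patient reading.
#' @param scale_norm,missing_indicator Passed to [encode_visit()].
#' @return List of `encoded_sequence` objects, each with `patient_id`,
#'   `steps` (matrix `window_length` x 25: 20 visit features + 5 appended
#'   target features), `target_score` (raw points), `target_drug`,
#'   `n_real_steps`, `scale_kind`. Patients without a usable target visit in
#'   `"initiation"` mode are skipped.
#' @export
build_sequences <- function(cohort, window_length = 4,
                            mode = c("random", "initiation", "random_visit"),
                            seed = NULL, draws = 1, scale_norm = TRUE,
                            missing_indicator = FALSE) {
  mode <- match.arg(mode)
  stopifnot(window_length >= 1, draws >= 1)
  if (mode != "random") draws <- 1
  cohort <- cohort[order(cohort$patient_id, cohort$time), , drop = FALSE]
  by_id <- split(cohort, cohort$patient_id)
  with_seed(seed, {
    out <- lapply(by_id, function(sub) {
      n <- nrow(sub)
      if (n < 2L) {
        stop(sprintf("patient %s has fewer than 2 visits", sub$patient_id[1]),
             call. = FALSE)
      }
      # choose the window's last input visit e; target is visit e + 1
      lapply(seq_len(draws), function(k) {
        e <- switch(mode,
          random = {
            if (n - 1L <= window_length) n - 1L
            else window_length + sample.int(n - 1L - window_length + 1L, 1) - 1L
          },
          initiation = {
            on_drug <- which(sub$drug != "none")
            if (!length(on_drug) || on_drug[1] >= n) return(NULL)
            on_drug[1]
          },
          random_visit = sample.int(n - 1L, 1)
        )
        if (is.null(e)) return(NULL)
        s <- max(1L, e - window_length + 1L)
        build_sequence(sub, s:e, target_index = e + 1L,
                       window_length = window_length, scale_norm = scale_norm,
                       missing_indicator = missing_indicator)
      })
    })
  })
  out <- unlist(out, recursive = FALSE, use.names = FALSE)
  out[!vapply(out, is.null, logical(1))]
}

# assemble one encoded_sequence from visit rows `idx` and a target row
build_sequence <- function(sub, idx, target_index, window_length,
                           scale_norm = TRUE, missing_indicator = FALSE) {
  d_visit <- length(encoded_feature_names(missing_indicator))
  d_total <- d_visit + 5L
  steps <- matrix(0, window_length, d_total)
  colnames(steps) <- c(encoded_feature_names(missing_indicator),
                       target_block_names())
  n_real <- length(idx)
  offset <- window_length - n_real
  for (j in seq_along(idx)) {
    steps[offset + j, seq_len(d_visit)] <-
      encode_visit(sub[idx[j], ], sub[idx[j], ], scale_norm = scale_norm,
                   missing_indicator = missing_indicator)
  }
  tgt <- sub[target_index, ]
  tgt_drug <- as.character(tgt$drug)
  drug_hot <- as.numeric(dementia_drugs() == tgt_drug)  # all-zero if "none"
  steps[window_length, d_visit + 1:4] <- drug_hot
  steps[window_length, d_total] <- tgt$time - sub$time[idx[n_real]]
  structure(
    list(patient_id = sub$patient_id[1],
         steps = steps,
         target_score = as.numeric(tgt$score),
         target_drug = tgt_drug,
         n_real_steps = n_real,
         scale_kind = as.character(sub$scale_kind[1])),
    class = "encoded_sequence"
  )
}

#' @export
print.encoded_sequence <- function(x, ...) {
  cat("<encoded_sequence>", x$patient_id, "|", nrow(x$steps), "steps (",
      x$n_real_steps, "real ) | target", x$target_score, "on",
      x$target_drug, "\n")
  invisible(x)
}

#' Patient-level train/validation split
#'
#' Randomly partitions patients (never visits) into a training and a
#' validation set. The training size is `round-half-up(fraction * n)`, e.g.
#' 3358 patients at fraction 0.60 give 2015 training and 1343 validation
#' patients.
#'
#' @param x Visit data.frame with `patient_id`, or a character vector of ids.
#' @param fraction Training fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return List with `train` and `validation` character id vectors.
#' @export
split_train_validation <- function(x, fraction = 0.60, seed = 1L) {
  ids <- if (is.data.frame(x)) unique(x$patient_id) else unique(as.character(x))
  n <- length(ids)
  if (n < 2L) stop("need at least 2 patients to split", call. = FALSE)
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  k <- floor(fraction * n + 0.5)  # round half up
  with_seed(seed, {
    train <- sort(sample(ids, k))
  })
  list(train = train, validation = sort(setdiff(ids, train)))
}
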
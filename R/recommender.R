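#' Per-patient treatment of choice from counterfactual predictions
#'
#' Runs the fitted predictor once per candidate drug on a patient's sequence
#' and selects the drug whose predicted next-visit score is highest — the
#' neural-network treatment of choice (NNToC). Ties are broken by the
#' canonical drug order. The recommendation is concordant when the NNToC
#' equals the actually prescribed drug.
#'
#' @param model A `cog_model`.
#' @param sequence One `encoded_sequence`.
#' @param drug_set Non-empty subset of [dementia_drugs()]; use
#'   [achei_drugs()] for AChEI-only mode (memantine never recommended).
#' @return One-row data.frame: `patient_id`, `pred_<drug>` for each drug in
#'   `drug_set` (NA for excluded drugs), `nntoc`, `prescribed`, `concordant`.
#' @export
recommend <- function(model, sequence, drug_set = dementia_drugs()) {
  recommend_cohort(model, list(sequence), drug_set)
}

#' @rdname recommend
#' @param sequences List of encoded sequences (one per patient).
#' @return For `recommend_cohort`: a data.frame with one row per sequence.
#' @export
recommend_cohort <- function(model, sequences, drug_set = dementia_drugs()) {
  if (length(drug_set) == 0) stop("drug_set must be non-empty", call. = FALSE)
  if (!all(drug_set %in% dementia_drugs())) {
    stop("drug_set must be a subset of the four canonical drugs",
         call. = FALSE)
  }
  drugs <- dementia_drugs()
  drug_set <- drugs[drugs %in% drug_set]  # canonical order
  if (inherits(sequences, "encoded_sequence")) sequences <- list(sequences)
  n <- length(sequences)
  pred <- matrix(NA_real_, n, 4, dimnames = list(NULL, drugs))
  for (d in drug_set) {
    pred[, d] <- predict_score(model, sequences, drug = d)
  }
  sub <- pred[, drug_set, drop = FALSE]
  nntoc <- drug_set[apply(sub, 1, argmax_first)]
  prescribed <- vapply(sequences, `[[`, character(1), "target_drug")
  out <- data.frame(
    patient_id = vapply(sequences, `[[`, character(1), "patient_id"),
    stringsAsFactors = FALSE
  )
  for (d in drugs) out[[paste0("pred_", d)]] <- pred[, d]
  out$nntoc <- nntoc
  out$prescribed <- prescribed
  out$concordant <- nntoc == prescribed
  out
}

#' Shuffled-recommendation null
#'
#' Reassigns each patient the NNToC of another randomly selected patient (a
#' uniform permutation of the recommendation labels; fixed points are
#' allowed). The multiset of recommended drugs is preserved and concordance
#' flags are recomputed against the permuted labels.
#'
#' @param recommendations data.frame from [recommend_cohort()].
#' @param seed Permutation seed.
#' @return data.frame of the same shape with permuted `nntoc` and recomputed
#'   `concordant`.
#' @export
shuffle_recommendations <- function(recommendations, seed = 1L) {
  n <- nrow(recommendations)
  if (n < 2) stop("need at least 2 recommendations to shuffle",
                  call. = FALSE)
  with_seed(seed, {
    perm <- sample.int(n)
  })
  out <- recommendations
  out$nntoc <- recommendations$nntoc[perm]
  out$concordant <- out$nntoc == out$prescribed
  out
}

#' Split patients by recommendation concordance
#'
#' @param recommendations data.frame from [recommend_cohort()].
#' @return List: `concordant` and `discordant` patient-id vectors (disjoint,
#'   jointly exhaustive) and `rate` = share concordant.
#' @export
concordance_split <- function(recommendations) {
  conc <- recommendations$concordant
  list(concordant = recommendations$patient_id[conc],
       discordant = recommendations$patient_id[!conc],
       rate = if (nrow(recommendations)) mean(conc) else NA_real_)
}
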
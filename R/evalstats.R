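#' Binned decline trajectories for patient groups
#'
#' For each patient, decline at a follow-up visit is the score at treatment
#' initiation (the first prescribed visit) minus the score at that visit —
#' positive values mean worsening. Follow-ups within `horizon` years of
#' initiation are binned by time since initiation; a patient with several
#' visits in one bin contributes their mean. Per group and bin the summary
#' holds n, mean decline, SD and SE; when exactly two groups are supplied a
#' Welch t-test on the per-patient declines is attached to each bin. The
#' initiation visit itself forms bin 0 with decline 0 by construction.
#'
#' @param cohort Visit table (filtered; `drug` column uses `"none"` for
#'   unprescribed visits).
#' @param groups Named list of patient-id vectors (e.g. the output of
#'   [concordance_split()] `concordant` / `discordant`).
#' @param bin_width Bin width, years (default 0.25).
#' @param horizon Follow-up horizon, years (default 2).
#' @return data.frame of class `trajectory_summary`: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `group`, `n`, `mean_decline`, `sd`, `se`, and (two groups
#'   only) `t`, `df`, `p` repeated across the two rows of the bin. Bins with
#'   no observations keep `n = 0` and `NA` statistics — missing, never zero.
#' @export
trajectory_summary <- function(cohort, groups, bin_width = 0.25,
                               horizon = 2) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  cohort <- cohort[order(cohort$patient_id, cohort$time), , drop = FALSE]
  by_id <- split(cohort, cohort$patient_id)

  # per patient: vector of (bin, decline)
  patient_declines <- function(ids) {
    declines <- list()
    for (id in ids) {
      sub <- by_id[[id]]
      if (is.null(sub)) {
        stop("patient ", id, " not present in cohort", call. = FALSE)
      }
      on_drug <- which(sub$drug != "none")
      if (!length(on_drug)) next
      i0 <- on_drug[1]
      t0 <- sub$time[i0]
      s0 <- sub$score[i0]
      dt <- sub$time - t0
      keep <- dt > 0 & dt <= horizon
      if (!any(keep)) next
      bin <- ceiling(dt[keep] / bin_width)
      dec <- s0 - sub$score[keep]
      declines[[id]] <- vapply(split(dec, bin), mean, numeric(1))
    }
    declines
  }

  n_bins <- ceiling(horizon / bin_width)
  rows <- list()
  per_bin_values <- list()
  for (g in names(groups)) {
    decs <- patient_declines(groups[[g]])
    rows[[g]] <- data.frame(
      bin = 0:n_bins, group = g, n = 0L, mean_decline = NA_real_,
      sd = NA_real_, se = NA_real_, stringsAsFactors = FALSE
    )
    # bin 0: the index visit, decline 0 by construction
    rows[[g]]$n[1] <- length(decs)
    rows[[g]]$mean_decline[1] <- 0
    rows[[g]]$sd[1] <- 0
    rows[[g]]$se[1] <- 0
    vals <- vector("list", n_bins)
    for (b in seq_len(n_bins)) {
      v <- unlist(lapply(decs, function(d) d[as.character(b)]),
                  use.names = FALSE)
      v <- v[!is.na(v)]
      vals[[b]] <- v
      if (length(v)) {
        rows[[g]]$n[b + 1] <- length(v)
        rows[[g]]$mean_decline[b + 1] <- mean(v)
        rows[[g]]$sd[b + 1] <- stats::sd(v)
        rows[[g]]$se[b + 1] <- stats::sd(v) / sqrt(length(v))
      }
    }
    per_bin_values[[g]] <- vals
  }
  out <- do.call(rbind, rows)
  out$bin_lo <- pmax(0, (out$bin - 1)) * bin_width
  out$bin_lo[out$bin == 0] <- 0
  out$bin_hi <- out$bin * bin_width
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  out$t <- NA_real_; out$df <- NA_real_; out$p <- NA_real_
  if (length(groups) == 2) {
    g1 <- names(groups)[1]; g2 <- names(groups)[2]
    for (b in seq_len(n_bins)) {
      v1 <- per_bin_values[[g1]][[b]]; v2 <- per_bin_values[[g2]][[b]]
      if (length(v1) >= 2 && length(v2) >= 2 &&
          stats::sd(v1) > 0 && stats::sd(v2) > 0) {
        w <- welch_t(mean(v1), stats::sd(v1), length(v1),
                     mean(v2), stats::sd(v2), length(v2))
        sel <- out$bin == b
        out$t[sel] <- w$t; out$df[sel] <- w$df; out$p[sel] <- w$p
      }
    }
  }
  rownames(out) <- NULL
  out <- out[, c("bin", "bin_lo", "bin_hi", "bin_mid", "group", "n",
                 "mean_decline", "sd", "se", "t", "df", "p")]
  class(out) <- c("trajectory_summary", "data.frame")
  out
}

#' Mean decline over a window, per group
#'
#' Convenience summary on top of the same decline definition as
#' [trajectory_summary()]: each patient contributes the mean decline over
#' their follow-ups in `(from, to]` years since initiation; groups are then
#' compared with Welch's t-test.
#'
#' @param cohort Visit table.
#' @param groups Named list of two patient-id vectors.
#' @param from,to Window bounds in years since initiation (default the
#'   second year, capturing 2-year outcomes).
#' @return List: per-group `n`, `mean`, `sd`, `se`, plus `t`, `df`, `p`.
#' @export
decline_gap <- function(cohort, groups, from = 1, to = 2) {
  stopifnot(length(groups) == 2)
  ts <- trajectory_summary(cohort, groups, bin_width = to - from,
                           horizon = to)
  last <- ts[ts$bin == max(ts$bin), ]
  g <- last$group
  list(groups = g,
       n = stats::setNames(last$n, g),
       mean = stats::setNames(last$mean_decline, g),
       sd = stats::setNames(last$sd, g),
       se = stats::setNames(last$se, g),
       t = last$t[1], df = last$df[1], p = last$p[1])
}

#' Welch's two-sample t-test from summary statistics
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, computed from group means, SDs and sizes.
#'
#' @param mean1,sd1,n1 First group's mean, SD and size.
#' @param mean2,sd2,n2 Second group's mean, SD and size.
#' @return List: `t`, `df`, `p`.
#' @examples
#' # age comparison of two patient groups (means/SDs from a published table)
#' welch_t(81.12, 7.01, 222, 82.05, 6.73, 1550)
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("welch_t needs n >= 2 per group", call. = FALSE)
  if (!all(is.finite(c(mean1, sd1, mean2, sd2))) || sd1 <= 0 || sd2 <= 0) {
    stop("welch_t needs finite means and positive SDs", call. = FALSE)
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Wraps `stats::chisq.test` on the table `rbind(c(a, b), c(c, d))` with
#' Yates continuity correction on by default (1 df, two-sided).
#'
#' @param a,b First row (e.g. group 1: trait present / absent).
#' @param c,d Second row.
#' @param continuity Apply Yates correction (default `TRUE`).
#' @return List: `chi2`, `p`.
#' @examples
#' chi_square_2x2(76, 146, 648, 902)   # married vs not, two groups
#' @export
chi_square_2x2 <- function(a, b, c, d, continuity = TRUE) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  m <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("all table margins must be positive", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = continuity))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

# predictor name -> encoded column indices (incl. appended target block)
predictor_columns <- function(feature_names) {
  list(
    age = grep("^age$", feature_names),
    sex = grep("^sex_", feature_names),
    ethnicity = grep("^ethnicity_", feature_names),
    marital_status = grep("^marital_", feature_names),
    duration = c(grep("^duration$", feature_names),
                 grep("^target_duration$", feature_names)),
    score = c(grep("^score$", feature_names),
              grep("^score_missing$", feature_names)),
    drug = c(grep("^drug_", feature_names),
             grep("^target_drug_", feature_names))
  )
}

#' Permutation feature importance
#'
#' Percent increase in the model's validation MAE when one of the seven
#' predictors is randomly shuffled across patients. The predictor's whole
#' one-hot block (or continuous column, including its appended target-slot
#' columns for drug and duration) is permuted jointly, with one permutation
#' applied consistently across every step of each sequence, so within-patient
#' structure is preserved and only the patient-to-value assignment is broken.
#'
#' @param model A `cog_model`.
#' @param sequences Validation sequences.
#' @param predictor One of `"age"`, `"sex"`, `"ethnicity"`,
#'   `"marital_status"`, `"duration"`, `"score"`, `"drug"`, or a character
#'   vector of them (default: all seven).
#' @param repeats Shuffle repetitions averaged over (default 10).
#' @param seed Seed for the permutations.
#' @return data.frame of class `feature_importance`: `predictor`,
#'   `baseline_mae`, `permuted_mae` (mean over repeats), `pct_increase`,
#'   `repeats`, sorted by decreasing importance.
#' @export
permutation_importance <- function(model, sequences,
                                   predictor = names(predictor_columns(model$feature_names)),
                                   repeats = 10, seed = 1L) {
  stopifnot(repeats >= 1)
  blocks <- predictor_columns(model$feature_names)
  unknown <- setdiff(predictor, names(blocks))
  if (length(unknown)) {
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(names(blocks), collapse = ", "),
         call. = FALSE)
  }
  st <- stack_sequences(sequences)
  X <- st$X
  n <- dim(X)[1]
  predict_X <- function(Xp) predict_from_X(model, Xp, st$scale_kind)
  baseline_mae <- mean(abs(predict_X(X) - st$y))
  if (baseline_mae <= 0) {
    stop("baseline MAE is zero; percent increase undefined", call. = FALSE)
  }
  out <- data.frame(predictor = predictor, baseline_mae = baseline_mae,
                    permuted_mae = NA_real_, pct_increase = NA_real_,
                    repeats = as.integer(repeats),
                    stringsAsFactors = FALSE)
  with_seed(seed, {
    for (k in seq_along(predictor)) {
      cols <- blocks[[predictor[k]]]
      maes <- numeric(repeats)
      for (r in seq_len(repeats)) {
        perm <- sample.int(n)
        Xp <- X
        Xp[, , cols] <- X[perm, , cols, drop = FALSE]
        maes[r] <- mean(abs(predict_X(Xp) - st$y))
      }
      out$permuted_mae[k] <- mean(maes)
    }
  })
  out$pct_increase <- 100 * (out$permuted_mae - baseline_mae) / baseline_mae
  out <- out[order(-out$pct_increase), ]
  rownames(out) <- NULL
  class(out) <- c("feature_importance", "data.frame")
  out
}

#' Recommendation recovery rate against simulator ground truth
#'
#' Proportion of patients whose NNToC equals their planted best drug, with an
#' exact binomial confidence interval and test against the chance level
#' (default `1/|drug set|`).
#'
#' @param recommendations data.frame from [recommend_cohort()].
#' @param truth Truth table from [simulate_cohort()] (`patient_id`,
#'   `best_drug` or `effect_<drug>` columns).
#' @param chance Null match probability (default 1/4 for the full drug set).
#' @return List: `rate`, `n`, `matches`, `ci` (95% exact binomial), `p`
#'   (two-sided exact binomial vs `chance`), `chance`.
#' @export
recovery_rate <- function(recommendations, truth, chance = 0.25) {
  if (!"best_drug" %in% names(truth)) {
    truth$best_drug <- planted_best_drug(truth)
  }
  idx <- match(recommendations$patient_id, truth$patient_id)
  if (any(is.na(idx))) {
    stop("recommendation ids missing from truth table: ",
         paste(utils::head(recommendations$patient_id[is.na(idx)], 3),
               collapse = ", "), call. = FALSE)
  }
  matches <- sum(recommendations$nntoc == truth$best_drug[idx])
  n <- nrow(recommendations)
  bt <- stats::binom.test(matches, n, p = chance)
  list(rate = matches / n, n = n, matches = matches,
       ci = unname(bt$conf.int), p = bt$p.value, chance = chance)
}
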
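#' Configuration for the synthetic dementia cohort simulator
#'
#' Builds a validated configuration object for [simulate_cohort()]. Defaults
#' emulate a memory-clinic MMSE cohort: baseline score 21.1 (SD 5.41) on the
#' 0-30 scale, age 80.5 (SD 7.6) restricted to 59-102 years, untreated
#' cognitive decline around 2 points/year, irregular (log-normal) visit
#' spacing, prescriptions dominated by donepezil, and roughly 20%/25%
#' "not available" ethnicity/marital status.
#'
#' Per-patient drug response is planted through `drug_effect_matrix_spec`, a
#' function mapping the patient table to an n x 4 matrix of decline-slowing
#' effects (points/year, columns in canonical [dementia_drugs()] order). The
#' default rule partitions patients into four sex-by-age strata and gives each
#' stratum a different best drug, with effects
#' `1.0 + heterogeneity * {+0.75, +0.25, -0.25, -0.75}` points/year rotated
#' across strata, so the best-worst gap is `1.5 * heterogeneity` points/year.
#' `heterogeneity = 0` collapses all four effects to the common mean for every
#' patient.
#'
#' @param n_patients Number of patients.
#' @param age_mean,age_sd Age at first visit, years; draws are clamped to
#'   `age_range`.
#' @param age_range Permitted age window, years; must lie within \[59, 102\].
#' @param scale_kind `"MMSE"` or `"MoCA"` (both 0-30).
#' @param baseline_score_mean,baseline_score_sd First-visit score moments,
#'   scale points; draws clamped to \[0, 30\].
#' @param base_decline_rate_mean,base_decline_rate_sd Untreated decline rate,
#'   points/year (positive = worsening); draws truncated at 0.
#' @param drug_effect_matrix_spec `NULL` for the default stratum rule, or a
#'   `function(patients, heterogeneity)` returning an n x 4 numeric matrix of
#'   decline-slowing effects (points/year).
#' @param heterogeneity Non-negative scalar scaling the between-drug effect
#'   spread; 0 means all drugs identical for every patient.
#' @param noise_sd Visit-level observation noise, scale points.
#' @param visit_interval_mean Mean gap between visits, years (log-normal,
#'   `sdlog = 0.5`).
#' @param n_visits_range Integer `c(min, max)` visits drawn per patient
#'   (before the horizon truncation).
#' @param n_pretreatment_range Integer `c(min, max)` visits before the first
#'   prescription (drug `"none"`, untreated decline). Memory-clinic records
#'   start at first contact, not at first prescription, so patients carry
#'   some observation history into treatment initiation; capped so at least
#'   one treated follow-up remains.
#' @param horizon_years Visits after this time (years from first contact) are
#'   not generated.
#' @param plateau_years Post-initiation stabilisation period during which no
#'   decline accrues, years. Set 0 for a purely linear trajectory.
#' @param missingness_rates Named numeric, probabilities that `ethnicity` /
#'   `marital_status` are recorded as `"not_available"`.
#' @param drug_assignment_probs Length-4 probability vector over
#'   [dementia_drugs()] (must sum to 1).
#' @param confounded_assignment If `TRUE`, the prescription policy is tilted
#'   towards each stratum's planted best drug (mixing weight 0.3), making
#'   assignment depend on covariates; if `FALSE` (default) assignment is
#'   independent of covariates.
#' @param round_scores Round observed scores to integers (MMSE/MoCA are
#'   integer scales). Disable for exactness-limit tests.
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   cohort.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_patients = 2000,
                          age_mean = 80.5, age_sd = 7.6,
                          age_range = c(59, 102),
                          scale_kind = c("MMSE", "MoCA"),
                          baseline_score_mean = 21.1,
                          baseline_score_sd = 5.41,
                          base_decline_rate_mean = 2.0,
                          base_decline_rate_sd = 0.5,
                          drug_effect_matrix_spec = NULL,
                          heterogeneity = 1,
                          noise_sd = 1.5,
                          visit_interval_mean = 0.6,
                          n_visits_range = c(2L, 8L),
                          n_pretreatment_range = c(0L, 3L),
                          horizon_years = 3,
                          plateau_years = 0.5,
                          missingness_rates = c(ethnicity = 0.20,
                                                marital_status = 0.25),
                          drug_assignment_probs = c(0.6, 0.15, 0.15, 0.1),
                          confounded_assignment = FALSE,
                          round_scores = TRUE,
                          seed = 1L) {
  scale_kind <- match.arg(scale_kind)
  cfg <- list(
    n_patients = as.integer(n_patients),
    age_mean = age_mean, age_sd = age_sd, age_range = as.numeric(age_range),
    scale_kind = scale_kind,
    baseline_score_mean = baseline_score_mean,
    baseline_score_sd = baseline_score_sd,
    base_decline_rate_mean = base_decline_rate_mean,
    base_decline_rate_sd = base_decline_rate_sd,
    drug_effect_matrix_spec = drug_effect_matrix_spec,
    heterogeneity = heterogeneity,
    noise_sd = noise_sd,
    visit_interval_mean = visit_interval_mean,
    n_visits_range = as.integer(n_visits_range),
    n_pretreatment_range = as.integer(n_pretreatment_range),
    horizon_years = horizon_years,
    plateau_years = plateau_years,
    missingness_rates = missingness_rates,
    drug_assignment_probs = as.numeric(drug_assignment_probs),
    confounded_assignment = isTRUE(confounded_assignment),
    round_scores = isTRUE(round_scores),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid cohort configuration: ", msg,
                                 call. = FALSE)
  if (cfg$n_patients < 1) stop_cfg("n_patients must be >= 1")
  sds <- c(cfg$age_sd, cfg$baseline_score_sd, cfg$base_decline_rate_sd,
           cfg$noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) stop_cfg("negative SD")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] > cfg$age_range[2]) {
    stop_cfg("age_range must be c(lo, hi) with lo <= hi")
  }
  if (cfg$age_range[1] < 59 || cfg$age_range[2] > 102) {
    stop_cfg("age_range must lie within [59, 102]")
  }
  p <- cfg$drug_assignment_probs
  if (length(p) != 4 || any(p < 0) || any(p > 1) ||
      abs(sum(p) - 1) > 1e-12) {
    stop_cfg("drug_assignment_probs must be a 4-simplex (sum 1, entries in [0,1])")
  }
  mr <- cfg$missingness_rates
  if (any(mr < 0) || any(mr > 1)) stop_cfg("missingness rates outside [0,1]")
  if (!is.finite(cfg$heterogeneity) || cfg$heterogeneity < 0) {
    stop_cfg("heterogeneity must be >= 0")
  }
  if (cfg$visit_interval_mean <= 0) stop_cfg("visit_interval_mean must be > 0")
  if (length(cfg$n_visits_range) != 2 ||
      cfg$n_visits_range[1] < 1 ||
      cfg$n_visits_range[1] > cfg$n_visits_range[2]) {
    stop_cfg("n_visits_range must be c(min, max), min >= 1")
  }
  if (cfg$plateau_years < 0) stop_cfg("plateau_years must be >= 0")
  if (length(cfg$n_pretreatment_range) != 2 ||
      cfg$n_pretreatment_range[1] < 0 ||
      cfg$n_pretreatment_range[1] > cfg$n_pretreatment_range[2]) {
    stop_cfg("n_pretreatment_range must be c(min, max), min >= 0")
  }
  if (!is.null(cfg$drug_effect_matrix_spec) &&
      !is.function(cfg$drug_effect_matrix_spec)) {
    stop_cfg("drug_effect_matrix_spec must be NULL or a function")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$n_patients, "patients,", x$scale_kind,
      "| baseline", x$baseline_score_mean, "(", x$baseline_score_sd, ")",
      "| heterogeneity", x$heterogeneity,
      "| noise_sd", x$noise_sd, "| seed", x$seed, "\n")
  invisible(x)
}

# default planted drug-response rule: four sex-by-age strata, each with a
# different best drug; spread scales with heterogeneity
default_drug_effects <- function(patients, heterogeneity) {
  deltas <- c(0.75, 0.25, -0.25, -0.75) * heterogeneity
  stratum <- (patients$sex == "F") + 2L * (patients$age_at_first > 80)
  eff <- matrix(NA_real_, nrow(patients), 4,
                dimnames = list(NULL, dementia_drugs()))
  for (k in 0:3) {
    rows <- stratum == k
    # rotate so drug k+1 carries the +0.75*h advantage in stratum k
    eff[rows, ] <- matrix(1.0 + deltas[((0:3 - k) %% 4) + 1],
                          sum(rows), 4, byrow = TRUE)
  }
  eff
}

#' Simulate a synthetic longitudinal dementia cohort
#'
#' Generates a tidy visit table (one row per patient-visit) plus the
#' ground-truth per-patient drug-response profiles that real EHR data cannot
#' provide. Each patient's latent trajectory is
#' `baseline - (base_decline - effect[assigned drug]) * max(0, t - plateau)`,
#' observed with i.i.d. Gaussian noise, clamped to \[0, 30\] and (by default)
#' rounded to the integer scale. Patients are assigned exactly one drug, from
#' the first visit onwards.
#'
#' @param config A [cohort_config()].
#' @return A list with class `sim_cohort`:
#' \describe{
#'   \item{cohort}{data.frame, one row per visit: `patient_id`, `visit`,
#'     `time` (years from first contact), `age`, `sex`, `ethnicity`,
#'     `marital_status`, `scale_kind`, `score`, `drug`, `duration` (years
#'     since previous visit, 0 at the first).}
#'   \item{truth}{data.frame, one row per patient: latent `baseline_score`,
#'     `base_decline`, per-drug effects `effect_<drug>` (points/year
#'     decline-slowing), `best_drug` (argmax, canonical tie-break) and
#'     `stratum`.}
#' }
#' @examples
#' sim <- simulate_cohort(cohort_config(n_patients = 50, seed = 7))
#' head(sim$cohort)
#' table(sim$truth$best_drug)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  drugs <- dementia_drugs()
  with_seed(config$seed, {
    n <- config$n_patients
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.40, 0.60))
    age_at_first <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
                              config$age_range[1]), config$age_range[2])
    eth <- sample(c("white", "Asian", "black", "other"), n, replace = TRUE,
                  prob = c(0.988, 0.004, 0.003, 0.005))
    eth[runif(n) < config$missingness_rates[["ethnicity"]]] <- "not_available"
    mar <- sample(c("married", "separated", "single", "widowed"), n,
                  replace = TRUE, prob = c(0.566, 0.058, 0.041, 0.335))
    mar[runif(n) < config$missingness_rates[["marital_status"]]] <-
      "not_available"

    patients <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      sex = sex, ethnicity = eth, marital_status = mar,
      age_at_first = age_at_first,
      stringsAsFactors = FALSE
    )
    stratum <- (patients$sex == "F") + 2L * (patients$age_at_first > 80)

    eff_fun <- config$drug_effect_matrix_spec
    effects <- if (is.null(eff_fun)) {
      default_drug_effects(patients, config$heterogeneity)
    } else {
      eff_fun(patients, config$heterogeneity)
    }
    if (!is.matrix(effects) || nrow(effects) != n || ncol(effects) != 4 ||
        any(!is.finite(effects))) {
      stop("drug_effect_matrix_spec must return a finite n x 4 matrix",
           call. = FALSE)
    }
    best_drug <- drugs[apply(effects, 1, argmax_first)]

    base_decline <- pmax(rnorm(n, config$base_decline_rate_mean,
                               config$base_decline_rate_sd), 0)
    baseline <- pmin(pmax(rnorm(n, config$baseline_score_mean,
                                config$baseline_score_sd), 0), 30)

    # prescription policy: marginal probs, optionally tilted towards the
    # stratum's best drug (covariate confounding)
    assigned <- character(n)
    for (i in seq_len(n)) {
      p <- config$drug_assignment_probs
      if (config$confounded_assignment) {
        tilt <- as.numeric(drugs == best_drug[i])
        p <- 0.7 * p + 0.3 * tilt
      }
      assigned[i] <- sample(drugs, 1, prob = p)
    }
    eff_assigned <- effects[cbind(seq_len(n), match(assigned, drugs))]

    n_visits <- sample(seq(config$n_visits_range[1], config$n_visits_range[2]),
                       n, replace = TRUE)
    meanlog <- log(config$visit_interval_mean) - 0.5^2 / 2
    rows <- vector("list", n)
    pre_rng <- config$n_pretreatment_range
    n_pre <- sample(seq(pre_rng[1], pre_rng[2]), n, replace = TRUE)
    for (i in seq_len(n)) {
      gaps <- rlnorm(n_visits[i] - 1, meanlog = meanlog, sdlog = 0.5)
      times <- cumsum(c(0, gaps))
      keep <- times <= config$horizon_years
      times <- times[keep]
      # untreated decline up to initiation, plateau, then the treated slope
      k_pre <- min(n_pre[i], max(length(times) - 2L, 0L))
      t_rx <- times[k_pre + 1L]
      slope <- base_decline[i] - eff_assigned[i]
      latent <- baseline[i] - base_decline[i] * pmin(times, t_rx) -
        slope * pmax(0, times - t_rx - config$plateau_years)
      score <- latent + rnorm(length(times), 0, config$noise_sd)
      score <- pmin(pmax(score, 0), 30)
      if (config$round_scores) score <- round(score)
      drug_col <- rep(assigned[i], length(times))
      if (k_pre > 0) drug_col[seq_len(k_pre)] <- "none"
      rows[[i]] <- data.frame(
        patient_id = patients$patient_id[i],
        visit = seq_along(times),
        time = times,
        age = patients$age_at_first[i] + times,
        sex = patients$sex[i],
        ethnicity = patients$ethnicity[i],
        marital_status = patients$marital_status[i],
        scale_kind = config$scale_kind,
        score = score,
        drug = drug_col,
        duration = c(0, diff(times)),
        stringsAsFactors = FALSE
      )
      n_pre[i] <- k_pre
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL

    truth <- data.frame(
      patient_id = patients$patient_id,
      sex = patients$sex,
      age_at_first = patients$age_at_first,
      stratum = stratum,
      baseline_score = baseline,
      base_decline = base_decline,
      stringsAsFactors = FALSE
    )
    for (j in seq_along(drugs)) {
      truth[[paste0("effect_", drugs[j])]] <- effects[, j]
    }
    truth$assigned_drug <- assigned
    truth$n_pretreatment <- n_pre
    truth$best_drug <- best_drug

    structure(list(cohort = cohort, truth = truth, config = config),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", nrow(x$truth), "patients,", nrow(x$cohort),
      "visits (", x$config$scale_kind, ")\n")
  invisible(x)
}

#' Planted best drug of a drug-response profile
#'
#' Argmax of a profile's per-drug decline-slowing effects, ties broken by the
#' canonical drug order ([dementia_drugs()]).
#'
#' @param profile Either a numeric 4-vector of effects (canonical order), a
#'   matrix with 4 columns, or a truth data.frame from [simulate_cohort()]
#'   holding `effect_<drug>` columns.
#' @return Character: the best drug (vector when given multiple profiles).
#' @examples
#' planted_best_drug(c(0.2, 1.7, 0.9, 1.1))  # "galantamine"
#' planted_best_drug(c(1, 1, 1, 1))          # tie -> "donepezil"
#' @export
planted_best_drug <- function(profile) {
  drugs <- dementia_drugs()
  if (is.data.frame(profile)) {
    profile <- as.matrix(profile[, paste0("effect_", drugs)])
  }
  if (is.matrix(profile)) {
    stopifnot(ncol(profile) == 4, all(is.finite(profile)))
    return(drugs[apply(profile, 1, argmax_first)])
  }
  stopifnot(length(profile) == 4, all(is.finite(profile)))
  drugs[argmax_first(profile)]
}

#' Write / read the simulator's CSV interchange files
#'
#' Plain-CSV serialisation of a simulated cohort: the visit table and the
#' ground-truth profile table.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param cohort_file,truth_file Output CSV paths (`truth_file` optional).
#' @return `write_cohort_csv`: invisibly, the paths written.
#'   `read_cohort_csv`: the visit data.frame.
#' @export
write_cohort_csv <- function(sim, cohort_file, truth_file = NULL) {
  stopifnot(inherits(sim, "sim_cohort"))
  utils::write.csv(sim$cohort, cohort_file, row.names = FALSE)
  if (!is.null(truth_file)) {
    utils::write.csv(sim$truth, truth_file, row.names = FALSE)
  }
  invisible(c(cohort_file, truth_file))
}

#' @rdname write_cohort_csv
#' @param file CSV path of a visit table.
#' @export
read_cohort_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
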
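#' Model specification
#'
#' Hyperparameters for the score predictor and its baselines. The recurrent
#' model is a stack of fully connected layers (a feature extractor applied to
#' every step) feeding a two-layer LSTM whose final hidden state is mapped to
#' the predicted (normalised) score. `recurrent_layers` is fixed at 2 for
#' `kind = "lstm"`.
#'
#' @param kind One of `"lstm"`, `"ridge"`, `"random_forest"`, `"cnn1d"`.
#' @param frontend_widths Widths of the fully connected frontend layers.
#' @param recurrent_hidden LSTM hidden width.
#' @param recurrent_layers Number of LSTM layers; must be 2 for `"lstm"`.
#' @param learning_rate,epochs,batch_size Adam training schedule.
#' @param patience Early-stopping patience (epochs without validation-MAE
#'   improvement) when a validation set is supplied.
#' @param l2_penalty Ridge penalty (lambda) for `kind = "ridge"`.
#' @param n_trees,max_depth Random-forest size (`max_depth = 0` means
#'   unlimited).
#' @param kernel_width,n_filters 1D-CNN temporal kernel width and filter
#'   count.
#' @param drug_blind Zero out every drug input feature at train and predict
#'   time (ablation switch; predictions then cannot depend on the drug).
#' @param n_ensemble Number of independently initialised recurrent networks
#'   trained and averaged at prediction time (variance reduction for the
#'   counterfactual argmax; applies to `"lstm"` only).
#' @param seed Default training seed.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(kind = c("lstm", "ridge", "random_forest", "cnn1d"),
                       frontend_widths = c(32, 16),
                       recurrent_hidden = 32,
                       recurrent_layers = 2,
                       learning_rate = 1e-3,
                       epochs = 200,
                       batch_size = 64,
                       patience = 20,
                       l2_penalty = 1e-3,
                       n_trees = 300,
                       max_depth = 0,
                       kernel_width = 2,
                       n_filters = 32,
                       drug_blind = FALSE,
                       n_ensemble = 1,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "lstm" && recurrent_layers != 2) {
    stop("recurrent_layers is fixed at 2 for the LSTM model", call. = FALSE)
  }
  stopifnot(all(frontend_widths >= 1), recurrent_hidden >= 1,
            learning_rate > 0, epochs >= 1, batch_size >= 1,
            l2_penalty >= 0, n_trees >= 1, kernel_width >= 1, n_filters >= 1,
            n_ensemble >= 1)
  structure(list(kind = kind, frontend_widths = as.integer(frontend_widths),
                 recurrent_hidden = as.integer(recurrent_hidden),
                 recurrent_layers = as.integer(recurrent_layers),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 l2_penalty = l2_penalty, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 kernel_width = as.integer(kernel_width),
                 n_filters = as.integer(n_filters),
                 drug_blind = isTRUE(drug_blind),
                 n_ensemble = as.integer(n_ensemble),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$kind, "| frontend", paste(x$frontend_widths,
      collapse = "-"), "| hidden", x$recurrent_hidden, "x",
      x$recurrent_layers, "| lr", x$learning_rate, "| epochs", x$epochs, "\n")
  invisible(x)
}

SCORE_SCALE <- 30

# last-step normalised score per sequence: the anchor for residual
# (score-change) prediction
last_step_score <- function(X) {
  X[, dim(X)[2], dimnames(X)[[3]] == "score"]
}

# stack a list of encoded_sequence into an array n x T x D; age is rescaled
# to decades-of-a-century (age/100) for optimiser conditioning
stack_sequences <- function(sequences) {
  if (inherits(sequences, "encoded_sequence")) sequences <- list(sequences)
  stopifnot(length(sequences) >= 1)
  Tn <- nrow(sequences[[1]]$steps)
  D <- ncol(sequences[[1]]$steps)
  nms <- colnames(sequences[[1]]$steps)
  X <- array(0, c(length(sequences), Tn, D),
             dimnames = list(NULL, NULL, nms))
  for (i in seq_along(sequences)) {
    st <- sequences[[i]]$steps
    if (!identical(dim(st), c(Tn, D))) {
      stop("sequences have inconsistent encoding dimensions", call. = FALSE)
    }
    X[i, , ] <- st
  }
  X[, , "age"] <- X[, , "age"] / 100
  list(X = X,
       y = vapply(sequences, `[[`, numeric(1), "target_score"),
       drug = vapply(sequences, `[[`, character(1), "target_drug"),
       ids = vapply(sequences, `[[`, character(1), "patient_id"),
       scale_kind = vapply(sequences, `[[`, character(1), "scale_kind"),
       feature_names = nms, window = Tn)
}

drug_feature_cols <- function(feature_names) {
  c(grep("^drug_", feature_names), grep("^target_drug_", feature_names))
}

# zero the drug inputs (ablation mode)
blind_drugs <- function(X) {
  X[, , drug_feature_cols(dimnames(X)[[3]])] <- 0
  X
}

# substitute counterfactual drug d into the appended target slot and into the
# per-step drug block of every step that records a prescription; padded steps
# and pre-treatment ("none") visits are left untouched, matching the
# structure of observable windows
substitute_drug <- function(X, drug) {
  drugs <- dementia_drugs()
  if (!drug %in% drugs) stop("unknown drug: ", drug, call. = FALSE)
  hot <- as.numeric(drugs == drug)
  for (j in seq_along(drugs)) {
    X[, , paste0("target_drug_", drugs[j])] <- hot[j]
  }
  step_cols <- paste0("drug_", drugs)
  on_drug <- X[, , step_cols[1], drop = FALSE] * 0
  for (j in seq_along(drugs)) {
    on_drug <- on_drug + X[, , step_cols[j], drop = FALSE]
  }
  on_drug <- on_drug[, , 1] > 0
  for (j in seq_along(drugs)) {
    cur <- X[, , step_cols[j]]
    X[, , step_cols[j]] <- ifelse(on_drug, hot[j], cur)
  }
  X
}

lstm_arch <- function(spec, d_in, n_out = 1) {
  list(kind = "lstm", d_in = d_in,
       frontend_widths = spec$frontend_widths,
       hidden = spec$recurrent_hidden, n_layers = spec$recurrent_layers,
       n_out = n_out)
}

new_cog_model <- function(kind, spec, fit, arch = NULL, loss_trace = NULL,
                          feature_names, window, scale_kind, multitask = FALSE,
                          best_epoch = NA_integer_) {
  structure(list(kind = kind, spec = spec, fit = fit, arch = arch,
                 loss_trace = loss_trace, feature_names = feature_names,
                 window = window, scale_kind = scale_kind,
                 multitask = multitask, best_epoch = best_epoch),
            class = "cog_model")
}

#' @export
print.cog_model <- function(x, ...) {
  cat("<cog_model>", x$kind, if (x$multitask) "(multitask)" else "",
      "| window", x$window, "| scales:",
      paste(unique(x$scale_kind), collapse = "+"), "\n")
  if (!is.null(x$loss_trace)) {
    cat("  final training loss", signif(utils::tail(x$loss_trace, 1), 4),
        "over", length(x$loss_trace), "epochs\n")
  }
  invisible(x)
}

#' Train the recurrent cognitive-score predictor
#'
#' Fits the frontend-MLP + two-layer-LSTM model by minimising mean squared
#' error between predicted and observed next-visit scores (on the normalised
#' 0-1 scale) using Adam. Fully deterministic under a fixed seed
#' (single-threaded). If `validation` sequences are supplied, training stops
#' early once validation MAE has not improved for `spec$patience` epochs and
#' the best parameters are restored.
#'
#' @param sequences List of `encoded_sequence` ([build_sequences()]).
#' @param spec A [model_spec()] with `kind = "lstm"`.
#' @param seed Training seed (defaults to `spec$seed`).
#' @param validation Optional list of held-out sequences for early stopping.
#' @return A `cog_model` with the fitted parameters and the per-epoch
#'   training-loss trace.
#' @export
train_score_model <- function(sequences, spec = model_spec(),
                              seed = spec$seed, validation = NULL) {
  stopifnot(inherits(spec, "model_spec"), spec$kind == "lstm",
            length(sequences) >= 1)
  tr <- stack_sequences(sequences)
  X <- if (spec$drug_blind) blind_drugs(tr$X) else tr$X
  # the network predicts the normalised score CHANGE from the last observed
  # score; the anchor is added back at prediction time
  y <- matrix(tr$y / SCORE_SCALE - last_step_score(X), ncol = 1)
  mask <- matrix(1, length(tr$y), 1)
  arch <- lstm_arch(spec, d_in = dim(X)[3])
  val <- NULL
  if (!is.null(validation)) {
    va <- stack_sequences(validation)
    vX <- if (spec$drug_blind) blind_drugs(va$X) else va$X
    val <- list(X = vX,
                y = matrix(va$y / SCORE_SCALE - last_step_score(vX), ncol = 1),
                mask = matrix(1, length(va$y), 1))
  }
  fits <- train_ensemble(X, y, mask, arch, spec, seed, val)
  new_cog_model("lstm", spec, fits$members, arch = arch,
                loss_trace = fits$loss_trace,
                feature_names = tr$feature_names,
                window = tr$window, scale_kind = unique(tr$scale_kind),
                best_epoch = fits$best_epoch)
}

# train spec$n_ensemble networks from distinct seeds; predictions average
train_ensemble <- function(X, y, mask, arch, spec, seed, val) {
  members <- vector("list", spec$n_ensemble)
  fit1 <- NULL
  for (k in seq_len(spec$n_ensemble)) {
    fit <- nn_train(X, y, mask, arch, learning_rate = spec$learning_rate,
                    epochs = spec$epochs, batch_size = spec$batch_size,
                    seed = (seed + (k - 1) * 7919) %% 2147483647,
                    validation = val, patience = spec$patience)
    if (k == 1) fit1 <- fit
    members[[k]] <- fit$params
  }
  list(members = members, loss_trace = fit1$loss_trace,
       best_epoch = fit1$best_epoch)
}

#' Predict a (counterfactual) next-visit score
#'
#' Runs the fitted predictor on one or more encoded sequences. When `drug` is
#' given, the counterfactual "patient on `drug`" input is formed by
#' substituting that drug into the appended target-drug slot and into the
#' drug block of every real (non-padded) step before prediction. Predictions
#' are returned in scale points, clamped to \[0, 30\].
#'
#' @param model A `cog_model`.
#' @param sequences One `encoded_sequence` or a list of them.
#' @param drug `NULL` (predict under the recorded prescription) or one of
#'   [dementia_drugs()].
#' @return Numeric vector of predicted scores (points).
#' @export
predict_score <- function(model, sequences, drug = NULL) {
  stopifnot(inherits(model, "cog_model"))
  st <- stack_sequences(sequences)
  if (!identical(st$feature_names, model$feature_names)) {
    stop("sequence encoding does not match the model's feature space",
         call. = FALSE)
  }
  X <- st$X
  if (!is.null(drug)) X <- substitute_drug(X, drug)
  predict_from_X(model, X, st$scale_kind)
}

# shared prediction path over a stacked input array (residual + anchor,
# denormalised and clamped to the 0-30 scale)
predict_from_X <- function(model, X, scale_kind) {
  if (model$spec$drug_blind) X <- blind_drugs(X)
  resid <- switch(model$kind,
    lstm = {
      outs <- lapply(model$fit, function(p) nn_predict(p, model$arch, X))
      out <- Reduce(`+`, outs) / length(outs)
      if (model$multitask) {
        head <- ifelse(scale_kind == "MoCA", 2L, 1L)
        out[cbind(seq_len(nrow(out)), head)]
      } else {
        out[, 1]
      }
    },
    cnn1d = {
      out <- nn_predict(model$fit, model$arch, X)
      out[, 1]
    },
    ridge = {
      as.numeric(stats::predict(model$fit, flatten_X(X)))
    },
    random_forest = {
      stats::predict(model$fit, data.frame(flatten_X(X)))$predictions
    }
  )
  yhat <- resid + last_step_score(X)
  pmin(pmax(yhat * SCORE_SCALE, 0), SCORE_SCALE)
}

flatten_X <- function(X) {
  n <- dim(X)[1]
  M <- matrix(X, n, dim(X)[2] * dim(X)[3])
  colnames(M) <- paste0("f", seq_len(ncol(M)))
  M
}

#' Mean absolute prediction error on a sequence set
#'
#' MAE (scale points) of the model's predictions under the recorded
#' prescription, against the observed next-visit scores.
#'
#' @param model A `cog_model`.
#' @param sequences List of encoded sequences.
#' @return Numeric scalar, points.
#' @export
prediction_mae <- function(model, sequences) {
  st <- stack_sequences(sequences)
  mean(abs(predict_score(model, sequences) - st$y))
}

#' Train a comparison baseline
#'
#' Ridge regression and random forest consume the window flattened to one
#' long feature vector; the 1D CNN convolves along the step axis. All three
#' predict the same normalised next-visit score as the LSTM.
#'
#' @param kind `"ridge"`, `"random_forest"` or `"cnn1d"`.
#' @param sequences Training sequences.
#' @param spec A [model_spec()].
#' @param seed Training seed.
#' @param validation Optional held-out sequences (early stopping, cnn1d only).
#' @return A `cog_model`.
#' @export
train_baseline <- function(kind = c("ridge", "random_forest", "cnn1d"),
                           sequences, spec = model_spec(kind = kind),
                           seed = spec$seed, validation = NULL) {
  kind <- match.arg(kind)
  tr <- stack_sequences(sequences)
  X <- if (spec$drug_blind) blind_drugs(tr$X) else tr$X
  y01 <- tr$y / SCORE_SCALE - last_step_score(X)
  if (kind == "ridge") {
    fit <- glmnet::glmnet(flatten_X(X), y01, alpha = 0,
                          lambda = spec$l2_penalty, standardize = FALSE,
                          thresh = 1e-14, maxit = 10^7)
    return(new_cog_model("ridge", spec, fit,
                         feature_names = tr$feature_names,
                         window = tr$window,
                         scale_kind = unique(tr$scale_kind)))
  }
  if (kind == "random_forest") {
    dat <- data.frame(flatten_X(X))
    dat$.y <- y01
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = spec$n_trees,
      max.depth = if (spec$max_depth > 0) spec$max_depth else NULL,
      seed = seed, num.threads = 1
    )
    return(new_cog_model("random_forest", spec, fit,
                         feature_names = tr$feature_names,
                         window = tr$window,
                         scale_kind = unique(tr$scale_kind)))
  }
  # cnn1d
  arch <- list(kind = "cnn1d", d_in = dim(X)[3],
               kernel_width = min(spec$kernel_width, tr$window),
               n_filters = spec$n_filters, n_out = 1)
  val <- NULL
  if (!is.null(validation)) {
    va <- stack_sequences(validation)
    vX <- if (spec$drug_blind) blind_drugs(va$X) else va$X
    val <- list(X = vX,
                y = matrix(va$y / SCORE_SCALE - last_step_score(vX), ncol = 1),
                mask = matrix(1, length(va$y), 1))
  }
  fit <- nn_train(X, matrix(y01, ncol = 1),
                  matrix(1, length(y01), 1), arch,
                  learning_rate = spec$learning_rate, epochs = spec$epochs,
                  batch_size = spec$batch_size, seed = seed,
                  validation = val, patience = spec$patience)
  new_cog_model("cnn1d", spec, fit$params, arch = arch,
                loss_trace = fit$loss_trace, feature_names = tr$feature_names,
                window = tr$window, scale_kind = unique(tr$scale_kind),
                best_epoch = fit$best_epoch)
}

#' Grid search over hyperparameters
#'
#' Trains one model per grid point and selects the combination with the
#' lowest validation MAE.
#'
#' @param kind Model kind (any of the four).
#' @param grid Named list of hyperparameter vectors (names must be
#'   [model_spec()] arguments); the Cartesian product is searched.
#' @param train_sequences,validation_sequences Sequence sets.
#' @param base_spec Spec supplying all non-searched hyperparameters.
#' @param seed Training seed used for every grid point.
#' @return List: `best_spec`, `best_model`, `results` (data.frame of grid
#'   points and their validation MAE).
#' @export
grid_search <- function(kind, grid, train_sequences, validation_sequences,
                        base_spec = model_spec(kind = kind), seed = 1L) {
  stopifnot(is.list(grid), length(grid) >= 1, !is.null(names(grid)))
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  maes <- numeric(nrow(pts))
  models <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    sp <- base_spec
    for (nm in names(pts)) sp[[nm]] <- pts[[nm]][i]
    sp <- do.call(model_spec, sp[setdiff(names(sp), NULL)])
    models[[i]] <- if (kind == "lstm") {
      train_score_model(train_sequences, sp, seed = seed,
                        validation = validation_sequences)
    } else {
      train_baseline(kind, train_sequences, sp, seed = seed,
                     validation = validation_sequences)
    }
    maes[i] <- prediction_mae(models[[i]], validation_sequences)
  }
  best <- which.min(maes)
  results <- cbind(pts, validation_mae = maes)
  list(best_spec = models[[best]]$spec, best_model = models[[best]],
       results = results)
}

#' Oversample minority-drug sequences
#'
#' Randomly duplicates sequences of under-represented target drugs until
#' every represented drug class has as many sequences as the largest class
#' (donepezil in realistic cohorts). Duplicates are exact copies; all
#' original sequences are retained.
#'
#' @param sequences Training sequences.
#' @param seed Seed for the duplicate draws.
#' @return Augmented list of sequences (balanced per target drug).
#' @export
oversample_minority <- function(sequences, seed = 1L) {
  drug <- vapply(sequences, `[[`, character(1), "target_drug")
  counts <- table(drug[drug %in% dementia_drugs()])
  if (length(counts) == 0) stop("no sequences with a target drug",
                                call. = FALSE)
  target <- max(counts)
  with_seed(seed, {
    extra <- list()
    for (d in names(counts)) {
      deficit <- target - counts[[d]]
      if (deficit > 0) {
        pool <- which(drug == d)
        extra <- c(extra, sequences[sample(pool, deficit, replace = TRUE)])
      }
    }
    c(sequences, extra)
  })
}

#' Train the multitask (MMSE + MoCA) predictor
#'
#' One shared network with two output heads, one per scale. No patient has
#' both scales at a visit, so every sequence carries exactly one label; the
#' loss masks the absent scale's head per sample, and masked label slots
#' cannot influence the loss (bit-exactly).
#'
#' @param sequences Sequences whose `scale_kind` is `"MMSE"` or `"MoCA"`.
#' @param spec A [model_spec()] with `kind = "lstm"`.
#' @param seed Training seed.
#' @param validation Optional held-out sequences.
#' @return A multitask `cog_model`; [predict_score()] routes each sequence to
#'   the head matching its scale.
#' @export
train_multitask <- function(sequences, spec = model_spec(), seed = spec$seed,
                            validation = NULL) {
  stopifnot(spec$kind == "lstm")
  tr <- stack_sequences(sequences)
  if (any(!tr$scale_kind %in% c("MMSE", "MoCA")) || any(is.na(tr$y))) {
    stop("every sequence must carry exactly one labelled scale",
         call. = FALSE)
  }
  n <- length(tr$y)
  y <- matrix(0, n, 2)
  mask <- matrix(0, n, 2)
  col <- ifelse(tr$scale_kind == "MoCA", 2L, 1L)
  X <- if (spec$drug_blind) blind_drugs(tr$X) else tr$X
  y[cbind(seq_len(n), col)] <- tr$y / SCORE_SCALE - last_step_score(X)
  mask[cbind(seq_len(n), col)] <- 1
  arch <- lstm_arch(spec, d_in = dim(X)[3], n_out = 2)
  val <- NULL
  if (!is.null(validation)) {
    va <- stack_sequences(validation)
    nv <- length(va$y)
    vy <- matrix(0, nv, 2); vm <- matrix(0, nv, 2)
    vcol <- ifelse(va$scale_kind == "MoCA", 2L, 1L)
    vX <- if (spec$drug_blind) blind_drugs(va$X) else va$X
    vy[cbind(seq_len(nv), vcol)] <- va$y / SCORE_SCALE - last_step_score(vX)
    vm[cbind(seq_len(nv), vcol)] <- 1
    val <- list(X = vX, y = vy, mask = vm)
  }
  fits <- train_ensemble(X, y, mask, arch, spec, seed, val)
  new_cog_model("lstm", spec, fits$members, arch = arch,
                loss_trace = fits$loss_trace,
                feature_names = tr$feature_names,
                window = tr$window, scale_kind = unique(tr$scale_kind),
                multitask = TRUE, best_epoch = fits$best_epoch)
}
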
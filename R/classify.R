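# Eight-direction classification on the four input representations
# (EMG-input, IC-input, EMG-synergy, ICA-synergy) in extrinsic and
# intrinsic coordinate frames, with stratified fivefold cross-validation.

#' Assemble classifier inputs of one type from a pipeline container
#'
#' All four input types are epoched identically (25 points at 50 Hz around
#' the cursor-defined onset) and share the same trial order and labels:
#' `"emg"` uses the 95 rectified-downsampled channels, `"ic"` the retained
#' independent components, `"emg_synergy"` / `"ica_synergy"` the synergy
#' activations `T` from the full-dataset factorization of the respective
#' envelope matrix.
#'
#' @param container A pipeline container (see [run_pipeline()]).
#' @param input_type One of `"emg"`, `"ic"`, `"emg_synergy"`,
#'   `"ica_synergy"`.
#' @param frame `"extrinsic"` or `"intrinsic"`.
#' @return A `trial_set`, with `input_type` attached.
#' @export
assemble_inputs <- function(container,
                            input_type = c("emg", "ic", "emg_synergy",
                                           "ica_synergy"),
                            frame = c("extrinsic", "intrinsic")) {
  input_type <- match.arg(input_type)
  frame <- match.arg(frame)
  pp <- container$preproc
  if (is.null(pp)) stop("missing upstream stage: preprocess")
  x <- switch(input_type,
    emg = pp$cls_emg50,
    ic = {
      if (is.null(container$ica)) stop("missing upstream stage: ica")
      container$ica$cls_ic50
    },
    emg_synergy = {
      if (is.null(container$synergy)) stop("missing upstream stage: synergy")
      t(container$synergy$emg$conditions$Total$T)
    },
    ica_synergy = {
      if (is.null(container$synergy)) stop("missing upstream stage: synergy")
      t(container$synergy$ica$conditions$Total$T)
    }
  )
  ts <- epoch(x, pp$onsets_s, pp$labels, fs = pp$fs50)
  ts$input_type <- input_type
  ts$labels$direction_extrinsic <- ts$labels$direction
  relabel_frame(ts, frame,
                rotation_sign = container$config$preprocess$rotation_sign)
}

# Stratified fold assignment by extrinsic direction x posture, identical
# across frames (uses the preserved extrinsic labels).
make_folds <- function(labels, folds, seed) {
  dir_strat <- labels$direction_extrinsic %||% labels$direction
  cell <- interaction(dir_strat, labels$posture, drop = TRUE)
  if (min(table(cell)) < folds) {
    stop("a direction x posture cell has fewer trials than folds")
  }
  assign <- integer(nrow(labels))
  with_seed(seed, {
    for (cl in levels(cell)) {
      idx <- sample(which(cell == cl))
      assign[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
  })
  assign
}

#' Stratified k-fold cross-validation of the CNN
#'
#' Folds are stratified jointly by direction and posture (on the extrinsic
#' labels, so both coordinate frames use identical splits). Features are
#' z-scored per (channel, time point) using training-fold statistics only.
#'
#' @param trialset A `trial_set` from [assemble_inputs()] (or [epoch()]).
#' @param config A [cnn_config()].
#' @return List of class `classifier_report`: `input_type`, `frame`,
#'   `fold_accuracies`, `mean_accuracy`, `confusion` (8 x 8, rows = true),
#'   `n_inputs`, `n_trials`.
#' @export
crossval_cnn <- function(trialset, config = cnn_config()) {
  stopifnot(inherits(trialset, "trial_set"))
  X <- trialset$data
  y <- trialset$labels$direction
  n_classes <- 8
  folds <- make_folds(trialset$labels, config$folds, config$seed)
  conf <- matrix(0L, n_classes, n_classes,
                 dimnames = list(true = 1:8, predicted = 1:8))
  accs <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    mu <- apply(X[tr, , , drop = FALSE], c(2, 3), mean)
    sdv <- apply(X[tr, , , drop = FALSE], c(2, 3), stats::sd)
    sdv[sdv < 1e-12] <- 1
    std <- function(idx) {
      Xi <- X[idx, , , drop = FALSE]
      sweep(sweep(Xi, c(2, 3), mu, "-"), c(2, 3), sdv, "/")
    }
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, paste0("fold", f))
    model <- cnn_train(std(tr), y[tr], cfg_f, n_classes = n_classes)
    pred <- cnn_predict(model, std(te))
    accs[f] <- mean(pred == y[te])
    for (i in seq_along(te)) {
      conf[y[te[i]], pred[i]] <- conf[y[te[i]], pred[i]] + 1L
    }
  }
  structure(
    list(input_type = trialset$input_type %||% "unknown",
         frame = trialset$frame, fold_accuracies = accs,
         mean_accuracy = mean(accs), confusion = conf,
         n_inputs = dim(X)[2], n_trials = dim(X)[1]),
    class = "classifier_report"
  )
}

#' Classify all input types in both frames and compare
#'
#' Produces the 4 input types x 2 frames grid of cross-validated reports
#' plus Welch t-tests over fold accuracies for the four standard contrasts
#' (within the intrinsic frame): EMG-input vs EMG-synergy, IC-input vs
#' ICA-synergy, EMG-input vs IC-input, EMG-synergy vs ICA-synergy.
#'
#' @param container Pipeline container with all upstream stages present.
#' @param config A [cnn_config()].
#' @return List: `reports` (named `<type>.<frame>`), `summary` data frame,
#'   `contrasts` data frame.
#' @export
run_comparison <- function(container, config = cnn_config()) {
  types <- c("emg", "ic", "emg_synergy", "ica_synergy")
  frames <- c("extrinsic", "intrinsic")
  reports <- list()
  for (ty in types) {
    for (fr in frames) {
      ts <- assemble_inputs(container, ty, fr)
      reports[[paste(ty, fr, sep = ".")]] <- crossval_cnn(ts, config)
    }
  }
  summary <- do.call(rbind, lapply(reports, function(r) {
    data.frame(input_type = r$input_type, frame = r$frame,
               mean_accuracy = r$mean_accuracy, n_inputs = r$n_inputs)
  }))
  rownames(summary) <- NULL
  pairs <- list(c("emg", "emg_synergy"), c("ic", "ica_synergy"),
                c("emg", "ic"), c("emg_synergy", "ica_synergy"))
  contrasts <- do.call(rbind, lapply(pairs, function(pr) {
    a <- reports[[paste0(pr[1], ".intrinsic")]]$fold_accuracies
    b <- reports[[paste0(pr[2], ".intrinsic")]]$fold_accuracies
    cmp <- compare_tuning_weights(a, b)  # same Welch machinery
    data.frame(a = pr[1], b = pr[2], mean_a = cmp$mean_a, mean_b = cmp$mean_b,
               t = cmp$t_statistic, p = cmp$p_value)
  }))
  list(reports = reports, summary = summary, contrasts = contrasts)
}
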
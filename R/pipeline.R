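# Pipeline orchestration: simulate -> preprocess -> ica -> synergy ->
# modules/tuning -> classify, driven by one nested configuration with a
# single global seed, producing a container object holding every stage's
# outputs plus a reproducibility manifest.

#' Default pipeline configuration
#'
#' Nested sections mirror the stage parameters; one global seed
#' deterministically derives per-stage seeds. Defaults are the desk-scale
#' study conditions (see [sim_config()]).
#'
#' @param seed Global integer seed.
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    sim = list(config = sim_config(seed = derive_seed(seed, "simulate")),
               sources = NULL),
    preprocess = list(filter = filter_spec(), target_hz = 50,
                      rotation_sign = -1),
    ica = list(n_components = 20, flatness_max = 0.6, autocorr_min = 0.2,
               est_samples = 40000),
    synergy = list(s_min = 3, s_max_emg = 20, s_max_ic = 12, n_seeds = 2,
                   vaf_min = 0.9, slope_mse_max = 1e-4, max_iter = 120,
                   tol = 1e-5),
    modules = list(threshold = 0.75, normalize = "max", w_floor = 1e-6),
    classify = list(cnn = cnn_config(seed = derive_seed(seed, "classify")))
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Rejects unknown sections or keys (typos fail loudly rather than being
#' silently ignored).
#'
#' @param config A `pipeline_config` (possibly modified).
#' @return `config`, invisibly, on success.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in setdiff(names(ref), c("seed"))) {
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad)) {
      stop("unknown key(s) in config$", sec, ": ", paste(bad, collapse = ", "))
    }
  }
  invisible(config)
}

stage_simulate <- function(container) {
  cfg <- container$config
  container$sim <- simulate_dataset(cfg$sim$config, sources = cfg$sim$sources)
  container
}

stage_preprocess <- function(container) {
  cfg <- container$config
  rec <- container$sim$recording
  filt <- apply_filters(rec, cfg$preprocess$filter)
  gr <- select_ground_reference(filt)
  rec95 <- gr$recording
  labels <- container$sim$truth$labels
  # cursor-defined onsets, per trial segment
  simc <- container$sim$config
  nc_tr <- round(simc$trial_duration_s * simc$fs_cursor)
  nc_gap <- round(simc$gap_s * simc$fs_cursor)
  onsets <- vapply(seq_len(nrow(labels)), function(i) {
    ic0 <- (i - 1) * (nc_tr + nc_gap)
    seg <- rec$cursor[, ic0 + seq_len(nc_tr), drop = FALSE]
    labels$t_start_s[i] + detect_onset(seg, simc$fs_cursor)
  }, numeric(1))
  ds <- downsample(abs(rec95$emg), rec95$fs_emg, cfg$preprocess$target_hz)
  fs50 <- ds$fs
  n50 <- ncol(ds$x)
  t50 <- (seq_len(n50) - 1) / fs50
  posture_per_row <- rep(NA_real_, n50)
  trial_per_row <- rep(NA_integer_, n50)
  for (i in seq_len(nrow(labels))) {
    in_tr <- t50 >= labels$t_start_s[i] &
      t50 < labels$t_start_s[i] + simc$trial_duration_s
    posture_per_row[in_tr] <- labels$posture[i]
    trial_per_row[in_tr] <- i
  }
  container$preproc <- list(
    recording = rec95, ground_index = gr$ground_index,
    kept_channels = gr$kept_channels, labels = labels, onsets_s = onsets,
    cls_emg50 = ds$x, fs50 = fs50, t50 = t50,
    posture_per_row = posture_per_row, trial_per_row = trial_per_row
  )
  container
}

stage_ica <- function(container) {
  cfg <- container$config
  pp <- container$preproc
  dec <- fit_ica(pp$recording$emg,
                 n_components = cfg$ica$n_components,
                 seed = derive_seed(container$config$seed, "ica"),
                 est_samples = cfg$ica$est_samples)
  fspec <- cfg$preprocess$filter
  band <- c(fspec$band_hz[1],
            min(fspec$band_hz[2], 0.45 * pp$recording$fs_emg))
  dec <- select_components(dec, fs = pp$recording$fs_emg,
                           flatness_max = cfg$ica$flatness_max,
                           autocorr_min = cfg$ica$autocorr_min,
                           band = band)
  S_ret <- dec$S[dec$retained_mask, , drop = FALSE]
  dec$cls_ic50 <- downsample(abs(S_ret), pp$recording$fs_emg,
                             cfg$preprocess$target_hz)$x
  dec$A_retained <- dec$A[, dec$retained_mask, drop = FALSE]
  container$ica <- dec
  container
}

# Envelope matrix at 50 Hz (time x signals) from full-rate signals.
envelope_50 <- function(signals, fs, target_hz) {
  env <- to_pseudo_torque(signals, fs)
  e50 <- downsample(t(env$E), fs, target_hz)$x
  pmax(t(e50), 0)
}

stage_synergy <- function(container) {
  cfg <- container$config
  pp <- container$preproc
  sy <- cfg$synergy
  seed <- derive_seed(container$config$seed, "synergy")
  S_ret <- container$ica$S[container$ica$retained_mask, , drop = FALSE]
  E_emg <- envelope_50(pp$recording$emg, pp$recording$fs_emg, pp$fs50)
  E_ic <- envelope_50(S_ret, pp$recording$fs_emg, pp$fs50)
  run_type <- function(E, s_max, label) {
    s_max <- min(s_max, ncol(E) - 1)
    s_min <- min(sy$s_min, s_max)
    sel <- select_rank(E, s_min, s_max, seed = derive_seed(seed, label),
                       n_seeds = sy$n_seeds, vaf_min = sy$vaf_min,
                       slope_mse_max = sy$slope_mse_max,
                       max_iter = sy$max_iter, tol = sy$tol)
    conds <- list()
    for (cond in c("Total", "Elbow0", "Elbow90")) {
      conds[[cond]] <- condition_synergies(
        E, pp$posture_per_row, cond, rank = sel$selected_rank,
        seed = derive_seed(seed, paste0(label, cond)), n_seeds = sy$n_seeds,
        max_iter = sy$max_iter, tol = sy$tol)
    }
    list(E = E, selection = sel, selected_rank = sel$selected_rank,
         conditions = conds)
  }
  container$synergy <- list(
    emg = run_type(E_emg, sy$s_max_emg, "emg"),
    ica = run_type(E_ic, sy$s_max_ic, "ica")
  )
  container
}

# Per-trial mean activation of each synergy over the 25-point epoch window,
# for the trials belonging to a condition fit.
condition_trial_means <- function(fit, condition, pp, window_s = c(-0.2, 0.3)) {
  rows_cond <- switch(condition,
    Total = seq_along(pp$posture_per_row),
    Elbow0 = which(pp$posture_per_row == 0),
    Elbow90 = which(pp$posture_per_row == 90)
  )
  trials <- switch(condition,
    Total = seq_len(nrow(pp$labels)),
    Elbow0 = which(pp$labels$posture == 0),
    Elbow90 = which(pp$labels$posture == 90)
  )
  n_pts <- round((window_s[2] - window_s[1]) * pp$fs50)
  tm <- matrix(NA_real_, length(trials), fit$rank)
  for (j in seq_along(trials)) {
    i <- trials[j]
    s0 <- round((pp$onsets_s[i] + window_s[1]) * pp$fs50) + 1
    gl <- s0 + seq_len(n_pts) - 1
    loc <- match(gl, rows_cond)
    loc <- loc[!is.na(loc)]
    tm[j, ] <- colMeans(fit$T[loc, , drop = FALSE])
  }
  list(trial_means = tm, labels = pp$labels[trials, , drop = FALSE])
}

stage_modules <- function(container) {
  cfg <- container$config$modules
  pp <- container$preproc
  montage <- pp$recording$montage
  out <- list()
  for (ty in c("emg", "ica")) {
    syn <- container$synergy[[ty]]
    members <- data.frame(condition = character(0), index = integer(0))
    vecs <- list(); chan_w <- list()
    for (cond in c("Total", "Elbow0", "Elbow90")) {
      M <- syn$conditions[[cond]]$M
      for (k in seq_len(nrow(M))) {
        members <- rbind(members,
                         data.frame(condition = cond, index = k))
        vecs[[length(vecs) + 1]] <- M[k, ]
        chan_w[[length(chan_w) + 1]] <- if (ty == "ica") {
          synergy_channel_weights(M[k, ], container$ica$A_retained)
        } else M[k, ]
      }
    }
    n <- length(vecs)
    sp <- diag(1, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        sp[i, j] <- sp[j, i] <- scalar_product(vecs[[i]], vecs[[j]])
      }
    }
    members$module <- upgma_cluster(sp, cfg$threshold)
    # tuning per synergy within its condition (extrinsic labels; Elbow-90
    # compensation happens inside pd_error)
    tune <- vector("list", n)
    for (cond in c("Total", "Elbow0", "Elbow90")) {
      ctm <- condition_trial_means(syn$conditions[[cond]], cond, pp)
      rows <- which(members$condition == cond)
      for (r in rows) {
        k <- members$index[r]
        m <- direction_means(ctm$trial_means[, k], ctm$labels, "extrinsic")
        tune[[r]] <- cosine_tune(m, normalize = cfg$normalize,
                                 w_floor = cfg$w_floor)
      }
    }
    members$pd_deg <- vapply(tune, function(t) t$pd_deg, numeric(1))
    members$w <- vapply(tune, function(t) t$w, numeric(1))
    members$r_squared <- vapply(tune, function(t) t$r_squared, numeric(1))
    members$posture <- c(Total = 0, Elbow0 = 0, Elbow90 = 90)[members$condition]
    # per-module report
    mods <- sort(unique(members$module))
    report <- do.call(rbind, lapply(mods, function(mid) {
      rows <- which(members$module == mid)
      wsum <- Reduce(`+`, chan_w[rows]) / length(rows)
      err <- suppressWarnings(
        pd_error(members$pd_deg[rows], members$posture[rows],
                 rotation_sign = container$config$preprocess$rotation_sign))
      data.frame(module = mid, n_members = length(rows),
                 type = classify_module_type(wsum, montage,
                                             channels = pp$kept_channels),
                 mean_w = mean(members$w[rows]),
                 pd_error_deg = err)
    }))
    out[[ty]] <- list(members = members, sp_matrix = sp, report = report,
                      mean_w = mean(members$w),
                      mean_pd_error_deg = mean(report$pd_error_deg, na.rm = TRUE))
  }
  container$modules <- out
  container
}

stage_classify <- function(container) {
  container$classify <- run_comparison(container,
                                       container$config$classify$cnn)
  container
}

pipeline_stages <- c("simulate", "preprocess", "ica", "synergy", "modules",
                     "classify")

stage_output_name <- c(simulate = "sim", preprocess = "preproc",
                       ica = "ica", synergy = "synergy",
                       modules = "modules", classify = "classify")

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> ica -> synergy -> modules -> classify.
#' When a `container` from a previous (possibly partial) run is supplied,
#' stages whose outputs are already present are skipped, so deleting a
#' stage's output and re-running recomputes only that stage and its
#' dependents.
#'
#' @param config A [default_config()] (validated; unknown keys rejected).
#' @param container Optional container from a previous run, for resuming.
#' @param stages Stages to (re)run if missing; default all.
#' @return The container: a list of class `emg_container` with elements
#'   `config`, `sim`, `preproc`, `ica`, `synergy`, `modules`, `classify`,
#'   and `manifest` (per-stage seeds, wall times, counts).
#' @export
run_pipeline <- function(config = default_config(), container = NULL,
                         stages = pipeline_stages) {
  validate_config(config)
  if (is.null(container)) {
    container <- structure(list(config = config), class = "emg_container")
  } else {
    container$config <- config
  }
  manifest <- container$manifest %||% list(
    config = config, package_version = as.character(utils::packageVersion("emgsynergy")),
    stages = list())
  stages <- pipeline_stages[pipeline_stages %in% stages]
  # invalidate downstream outputs of any stage about to run
  for (st in stages) {
    out_nm <- stage_output_name[[st]]
    if (!is.null(container[[out_nm]])) next
    downstream <- pipeline_stages[seq(match(st, pipeline_stages),
                                      length(pipeline_stages))]
    for (d in downstream[-1]) {
      if (d %in% stages) container[[stage_output_name[[d]]]] <- NULL
    }
    break
  }
  for (st in stages) {
    out_nm <- stage_output_name[[st]]
    if (!is.null(container[[out_nm]])) next
    fn <- switch(st, simulate = stage_simulate, preprocess = stage_preprocess,
                 ica = stage_ica, synergy = stage_synergy,
                 modules = stage_modules, classify = stage_classify)
    t0 <- proc.time()[["elapsed"]]
    container <- tryCatch(fn(container), error = function(e) {
      stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[st]] <- list(
      seed = derive_seed(config$seed, st),
      wall_time_s = proc.time()[["elapsed"]] - t0)
  }
  manifest$counts <- list(
    channels_kept = if (!is.null(container$preproc))
      nrow(container$preproc$recording$emg) else NULL,
    ics_retained = if (!is.null(container$ica))
      sum(container$ica$retained_mask) else NULL,
    emg_synergy_rank = container$synergy$emg$selected_rank,
    ica_synergy_rank = container$synergy$ica$selected_rank
  )
  manifest$notes <- paste(
    "IC white-noise rejection uses an automated spectral-flatness +",
    "envelope-autocorrelation criterion (a stand-in for expert screening).")
  container$manifest <- manifest
  container
}

#' Validate a pipeline container
#'
#' Checks schema, shapes and invariants: presence and dimensions of the
#' recording, label completeness, non-negativity of synergy factors, and
#' retained-mask lengths. Problems are reported by location.
#'
#' @param container An `emg_container` (or a path to an RDS file holding
#'   one).
#' @return List with `valid` (logical) and `problems` (character vector).
#' @export
validate_container <- function(container) {
  if (is.character(container)) {
    if (!file.exists(container)) stop("unreadable file: ", container)
    container <- readRDS(container)
  }
  probs <- character(0)
  note <- function(...) probs <<- c(probs, paste0(...))
  if (is.null(container$sim)) {
    note("sim: missing")
  } else {
    rec <- container$sim$recording
    n_exp <- with(container$sim$config,
                  n_reps * length(directions_deg) * length(postures_deg) *
                    (round(trial_duration_s * fs_emg) + round(gap_s * fs_emg)))
    if (ncol(rec$emg) != n_exp) {
      note("sim$recording$emg: expected ", n_exp, " samples, found ",
           ncol(rec$emg))
    }
    lb <- container$sim$truth$labels
    tab <- table(lb$direction, lb$posture)
    if (any(tab != container$sim$config$n_reps)) {
      note("sim$truth$labels: direction x posture cells are unbalanced")
    }
    if (anyNA(rec$emg)) note("sim$recording$emg: contains NA")
  }
  if (!is.null(container$ica)) {
    if (length(container$ica$retained_mask) != ncol(container$ica$A)) {
      note("ica$retained_mask: length != number of components")
    }
  }
  if (!is.null(container$synergy)) {
    for (ty in names(container$synergy)) {
      for (cond in names(container$synergy[[ty]]$conditions)) {
        f <- container$synergy[[ty]]$conditions[[cond]]
        if (min(f$M) < 0 || min(f$T) < 0) {
          note("synergy$", ty, "$conditions$", cond,
               ": negative factor entries")
        }
      }
    }
  }
  list(valid = length(probs) == 0, problems = probs)
}
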
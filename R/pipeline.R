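#' Configuration of an end-to-end synthetic study
#'
#' Bundles every stage's configuration with a single master seed.
#' Defaults mirror a full study: 18 subjects, 400 trials each, the
#' calibrated race-model responder, pilot-calibrated EEG gains, the
#' standard Morlet axis, and 2000-iteration cluster tests at a 0.005
#' cluster-forming threshold (strict enough that behavioral leakage of
#' planted effects into crossed covariate-lock pairs stays subthreshold;
#' see the methods vignette). Analysis windows per lock restrict the
#' correlation maps to the post-event intervals of interest.
#'
#' @param n_subjects Number of simulated subjects.
#' @param task A [task_config()] template.
#' @param race A [race_config()].
#' @param observer Generative [observer_params()].
#' @param grid [fit_grid()] for per-subject fitting, or `NULL` to skip
#'   fitting and use `observer` directly for the attached traces.
#' @param tf A [tf_config()].
#' @param eeg Named list of [eeg_sim_config()] templates per lock
#'   (`fixation`, `go`, `stop`); each template's seed is rederived per
#'   subject and lock.
#' @param analysis_windows Named list of time ranges (s) to which each
#'   lock's maps are cropped before correlation.
#' @param zmap_n_perm Within-subject permutations.
#' @param threshold_p Cluster-forming threshold.
#' @param n_iter Group-level sign-flip iterations.
#' @param time_step Decimation of the time-frequency time axis.
#' @param master_seed Master integer seed; all per-subject and per-lock
#'   seeds derive from it (`master + 1000 * subject + lock offset`).
#' @return A `study_config` object.
#' @export
study_config <- function(n_subjects = 18L, task = task_config(),
                         race = race_config(),
                         observer = observer_params(0.78, 0.14),
                         grid = fit_grid(), tf = tf_config(),
                         eeg = list(fixation = default_eeg_config("fixation"),
                                    go = default_eeg_config("go"),
                                    stop = default_eeg_config("stop")),
                         analysis_windows = list(fixation = c(0, 0.5),
                                                 go = c(0, 0.8),
                                                 stop = c(0, 0.5)),
                         zmap_n_perm = 1000L, threshold_p = 0.005,
                         n_iter = 2000L, time_step = 2L,
                         master_seed = 1L) {
  stopifnot(n_subjects >= 1, inherits(task, "task_config"),
            inherits(race, "race_config"),
            inherits(observer, "observer_params"),
            is.null(grid) || inherits(grid, "fit_grid"),
            inherits(tf, "tf_config"),
            all(c("fixation", "go", "stop") %in% names(eeg)))
  structure(list(n_subjects = as.integer(n_subjects), task = task,
                 race = race, observer = observer, grid = grid, tf = tf,
                 eeg = eeg, analysis_windows = analysis_windows,
                 zmap_n_perm = as.integer(zmap_n_perm),
                 threshold_p = threshold_p, n_iter = as.integer(n_iter),
                 time_step = as.integer(time_step),
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

# covariate values for a lock's retained trials
.lock_covariate <- function(trials, lock, trial_index) {
  v <- switch(lock,
              fixation = trials$pstop,
              go = trials$rt_ms,
              stop = trials$pe)
  v[match(trial_index, trials$trial)]
}

#' Run the end-to-end synthetic study
#'
#' Simulates the behavioral cohort, (optionally) fits the observer per
#' subject and recomputes every subject's P(stop)/PE trace with the
#' group-averaged parameters, simulates the three event-locked EEG
#' streams, rejects artifact epochs, computes baseline-corrected Morlet
#' power, builds within-subject z-maps, and runs group cluster tests for
#' the three planted covariate-lock pairs (P(stop) x fixation, RT x go,
#' PE x stop) and the two null pairs (P(stop) x go, RT x fixation),
#' followed by the trial-wise power correlation between the P(stop) and
#' RT clusters when both exist. Everything derives from `master_seed`.
#'
#' @param cfg A [study_config()].
#' @param out_dir Optional directory; when given, per-subject trial
#'   tables, the cluster tables and a machine-readable `summary.json`
#'   are written there.
#' @param verbose Print stage progress.
#' @return A `study_report` list: `behavioral` (per-subject summary
#'   data.frame), `group_params`, `cluster_tests` (per pair), `pairs`
#'   (data.frame of pair, n_clusters, min p), `cluster_power`.
#' @export
run_study <- function(cfg, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("[behavior] simulating %d subjects x %d trials", cfg$n_subjects,
      cfg$task$n_trials)
  cohort <- simulate_cohort(cfg$n_subjects, cfg$task, cfg$race,
                            cfg$observer, seed = cfg$master_seed)

  if (!is.null(cfg$grid)) {
    say("[fit] grid search over %d x %d parameter values",
        length(cfg$grid$alpha_values), length(cfg$grid$pm_values))
    fits <- lapply(cohort, fit_observer, grid = cfg$grid,
                   readout = cfg$observer$readout,
                   grid_size = cfg$observer$grid_size)
    group_params <- group_average_params(fits)
  } else {
    fits <- NULL
    group_params <- cfg$observer
  }
  cohort <- lapply(cohort, attach_observer, params = group_params)

  say("[metrics] behavioral summaries")
  behav <- do.call(rbind, lapply(seq_along(cohort), function(i)
    data.frame(subject = i, as.data.frame(behavior_summary(cohort[[i]])))))

  locks <- c("fixation", "go", "stop")
  lock_off <- c(fixation = 101L, go = 102L, stop = 103L)
  say("[eeg/tfr] simulating and decomposing 3 locks x %d subjects",
      cfg$n_subjects)
  tfs <- lapply(locks, function(lk) {
    lapply(seq_along(cohort), function(i) {
      ec <- cfg$eeg[[lk]]
      ec$seed <- cfg$master_seed + 1000L * i + lock_off[[lk]]
      ep <- simulate_epochs(cohort[[i]], ec, lk)
      ep <- reject_artifacts(ep)
      tf <- morlet_transform(ep, cfg$tf, time_step = cfg$time_step)
      tf <- baseline_correct(tf, cfg$tf)
      crop_tfr(tf, time_range = cfg$analysis_windows[[lk]])
    })
  })
  names(tfs) <- locks

  pairs <- list(c("pstop", "fixation"), c("rt", "go"), c("pe", "stop"),
                c("pstop", "go"), c("rt", "fixation"))
  tests <- list()
  pair_rows <- list()
  for (p in pairs) {
    covn <- p[1L]; lk <- p[2L]
    key <- paste(covn, lk, sep = "_x_")
    say("[cluster] %s", key)
    zs <- lapply(seq_along(cohort), function(i) {
      tf <- tfs[[lk]][[i]]
      cv <- switch(covn,
                   pstop = cohort[[i]]$pstop,
                   rt = cohort[[i]]$rt_ms,
                   pe = cohort[[i]]$pe)[match(tf$trial_index,
                                              cohort[[i]]$trial)]
      ok <- is.finite(cv)               # e.g. RT on omitted-go trials
      tf <- subset_tfr(tf, ok)
      cv <- cv[ok]
      zm <- subject_zmap(tf, cv, n_perm = cfg$zmap_n_perm,
                         seed = cfg$master_seed + 10000L + i)
      zm$covariate_name <- covn
      zm
    })
    res <- group_cluster_test(zs, threshold_p = cfg$threshold_p,
                              n_iter = cfg$n_iter,
                              seed = cfg$master_seed + 20000L +
                                as.integer(lock_off[[lk]]) +
                                match(covn, c("pstop", "rt", "pe")))
    res$covariate_name <- covn
    tests[[key]] <- res
    min_p <- if (length(res$clusters)) min(vapply(res$clusters,
                                                  `[[`, numeric(1), "p_perm"))
             else NA_real_
    pair_rows[[key]] <- data.frame(pair = key,
                                   n_clusters = length(res$clusters),
                                   min_p_perm = min_p,
                                   significant = isTRUE(min_p < 0.05))
  }
  pair_tbl <- do.call(rbind, pair_rows)
  rownames(pair_tbl) <- NULL

  # trial-wise power correlation between the P(stop) and RT clusters
  cl_a <- tests[["pstop_x_fixation"]]$clusters
  cl_b <- tests[["rt_x_go"]]$clusters
  cpc <- NULL
  if (length(cl_a) && length(cl_b)) {
    pick <- function(cls) cls[[which.max(vapply(cls, function(c) abs(c$summed_t),
                                                numeric(1)))]]
    say("[cluster] power correlation between P(stop) and RT clusters")
    cpc <- cluster_power_correlation(tfs$fixation, pick(cl_a)$bins,
                                     tfs$go, pick(cl_b)$bins)
  }

  report <- structure(list(behavioral = behav, group_params = group_params,
                           fits = fits, cluster_tests = tests,
                           pairs = pair_tbl, cluster_power = cpc,
                           master_seed = cfg$master_seed),
                      class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(cohort))
      write_trials(cohort[[i]],
                   file.path(out_dir, sprintf("subject%02d_trials.tsv", i)))
    utils::write.table(behav, file.path(out_dir, "behavioral_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(pair_tbl, file.path(out_dir, "cluster_pairs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(master_seed = cfg$master_seed,
           group_alpha = group_params$alpha, group_pm = group_params$pm,
           behavioral_means = as.list(colMeans(behav[-1L])),
           pairs = pair_tbl,
           cluster_power_median_r = if (is.null(cpc)) NULL else cpc$median_r,
           cluster_power_wilcoxon_p = if (is.null(cpc)) NULL else cpc$wilcoxon_p),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic stop-signal study report\n")
  cat(sprintf("  subjects: %d, group alpha = %.2f, pm = %.2f\n",
              nrow(x$behavioral), x$group_params$alpha, x$group_params$pm))
  bm <- colMeans(x$behavioral[-1L])
  cat(sprintf("  stop success %.1f%%, go-RT %.0f ms, SSRT %.0f ms, sequential r %.2f\n",
              100 * bm[["stop_success_rate"]], bm[["go_rt_mean"]],
              bm[["ssrt_ms"]], bm[["sequential_r"]]))
  print(x$pairs)
  if (!is.null(x$cluster_power))
    cat(sprintf("  cluster power correlation: median r = %.3f, Wilcoxon p = %.4g\n",
                x$cluster_power$median_r, x$cluster_power$wilcoxon_p))
  invisible(x)
}
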
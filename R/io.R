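# Tabular I/O (wide/long CSV and TSV dialects), pipeline configuration and
# the end-to-end pipeline runner.

#' Write / read a broadband recording (long CSV + JSON metadata sidecar)
#'
#' The main file holds one row per (channel, wavelength, time) with columns
#' `channel`, `wavelength_nm`, `time_s`, `attenuation_od` (natural OD
#' change). A JSON sidecar at `<path>.meta.json` stores the per-channel mean
#' intensity counts and the probe layout. All times are in seconds.
#'
#' @param rec A `bnirs_recording`.
#' @param path CSV file path.
#' @export
write_bnirs <- function(rec, path) {
  dims <- dim(rec$attenuation)
  d <- data.frame(
    channel = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
    wavelength_nm = rep(rep(rec$wavelengths_nm, each = dims[1]), times = dims[3]),
    time_s = rep(rec$time_s, each = dims[1] * dims[2]),
    attenuation_od = as.vector(rec$attenuation))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    intensity_counts = rec$intensity_counts,
    separation_cm = rec$layout$separation_cm,
    n_sources = rec$layout$n_sources,
    n_detectors = rec$layout$n_detectors,
    channel_pairs = rec$layout$channel_pairs
  ), paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bnirs
#' @export
read_bnirs <- function(path) {
  stop_if_not(file.exists(path), paste("no such file:", path))
  d <- utils::read.csv(path)
  need <- c("channel", "wavelength_nm", "time_s", "attenuation_od")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("bNIRS file lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  meta_path <- paste0(path, ".meta.json")
  stop_if_not(file.exists(meta_path),
              paste("missing metadata sidecar:", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  channels <- sort(unique(d$channel))
  wl <- sort(unique(d$wavelength_nm))
  time_s <- sort(unique(d$time_s))
  att <- array(NA_real_, dim = c(length(channels), length(wl), length(time_s)))
  att[cbind(match(d$channel, channels), match(d$wavelength_nm, wl),
            match(d$time_s, time_s))] <- d$attenuation_od
  stop_if_not(!anyNA(att), "bNIRS file is not a complete (channel, wavelength, time) grid")
  layout <- probe_layout(meta$n_sources, meta$n_detectors,
                         as.data.frame(meta$channel_pairs),
                         meta$separation_cm)
  structure(list(attenuation = att, wavelengths_nm = wl, time_s = time_s,
                 intensity_counts = as.numeric(meta$intensity_counts),
                 layout = layout),
            class = "bnirs_recording")
}

#' Write / read an EEG recording (wide CSV, one column per channel, uV)
#'
#' First column `time_s`; remaining columns are the montage labels. The
#' sampling rate is recovered from the time column. An optional logical
#' `attention` sidecar column list is stored at `<path>.attention.json`.
#'
#' @param rec An `eeg_recording`.
#' @param path CSV file path.
#' @export
write_eeg <- function(rec, path) {
  nt <- ncol(rec$signal)
  d <- data.frame(time_s = (seq_len(nt) - 1) / rec$fs)
  for (i in seq_along(rec$labels)) d[[rec$labels[i]]] <- rec$signal[i, ]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  if (!is.null(rec$attention_mask)) {
    jsonlite::write_json(list(attention_mask = rec$attention_mask),
                         paste0(path, ".attention.json"), auto_unbox = FALSE)
  }
  invisible(path)
}

#' @rdname write_eeg
#' @param montage Optional character vector of expected channel labels; a
#'   mismatch in count or names is an error.
#' @export
read_eeg <- function(path, montage = NULL) {
  stop_if_not(file.exists(path), paste("no such file:", path))
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(d)) {
    stop("EEG file lacks the time_s column; sampling rate (fs) cannot be determined",
         call. = FALSE)
  }
  labels <- setdiff(names(d), "time_s")
  if (!is.null(montage)) {
    if (length(labels) != length(montage) || !setequal(labels, montage)) {
      stop(sprintf("EEG channel set (%d) does not match the montage (%d)",
                   length(labels), length(montage)), call. = FALSE)
    }
  }
  dt <- diff(d$time_s)
  stop_if_not(all(abs(dt - dt[1]) < 1e-9 + 1e-6 * dt[1]),
              "EEG time grid is not uniform")
  att_path <- paste0(path, ".attention.json")
  mask <- NULL
  if (file.exists(att_path)) {
    mask <- as.logical(jsonlite::read_json(att_path,
                                           simplifyVector = TRUE)$attention_mask)
  }
  structure(list(signal = t(as.matrix(d[labels])), fs = 1 / dt[1],
                 labels = labels, attention_mask = mask),
            class = "eeg_recording")
}

#' Write one synthetic subject session to a directory
#'
#' Produces the tabular dataset for one subject: bNIRS long CSV (+ metadata
#' sidecar), EEG wide CSV (+ attention sidecar), schedule TSV, and a ground
#' truth JSON sidecar describing any planted couplings.
#'
#' @param session A session list from [simulate_subject()].
#' @param dir Output directory (created if needed).
#' @param id Subject identifier used in file names.
#' @return Named list of written paths.
#' @export
write_subject <- function(session, dir, id = "sub01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    bnirs = file.path(dir, paste0(id, "_bnirs.csv")),
    eeg = file.path(dir, paste0(id, "_eeg.csv")),
    schedule = file.path(dir, paste0(id, "_schedule.tsv")),
    truth = file.path(dir, paste0(id, "_truth.json")))
  write_bnirs(session$bnirs, paths$bnirs)
  write_eeg(session$eeg, paths$eeg)
  write_schedule(session$schedule, paths$schedule)
  jsonlite::write_json(list(rng_seed = session$seed,
                            coupling = session$coupling),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  paths
}

#' Pipeline configuration with the analysis defaults
#'
#' Every stage threshold of the analysis is present with its default: DPF
#' 5.13, wavelet tuning alpha 0.8, bNIRS band-pass 0.01-0.4 Hz (order 4),
#' fit range 780-900 nm, QC count bounds 2000/40000 with 60% subject
#' exclusion, EEG band-pass 0.1-100 Hz with 48-52 Hz notch, 200 uV artifact
#' threshold, the five analysis bands, the 5-15 / 5-20 / 2-6 response grid,
#' and FDR level q = 0.05. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults by name.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    dpf = 5.13,
    wavelet_alpha = 0.8,
    bnirs_band_hz = c(0.01, 0.4),
    bnirs_filter_order = 4,
    fit_range_nm = c(780, 900),
    qc_low_counts = 2000,
    qc_high_counts = 40000,
    qc_subject_threshold = 0.60,
    eeg_band_hz = c(0.1, 100),
    eeg_notch_hz = c(48, 52),
    artifact_uv = 200,
    bands = eeg_bands(),
    hrf_delays = 5:15,
    hrf_undershoots = 5:20,
    hrf_ratios = 2:6,
    hrf_event_duration_s = 10,
    hrf_window_s = 24,
    fdr_q = 0.05,
    baseline_keep_s = 8,
    stimulus_keep_s = 8,
    coupling_channels = select_coupling_channels(reported_coupling_channels()),
    coupling_eeg_channels = NULL,
    coupling_bands = NULL,
    fit_hrf = TRUE,
    extinction = "synthetic",
    rng_seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$bands)) raw$bands <- as.data.frame(raw$bands)
  do.call(pipeline_config, raw)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full multimodal analysis on an in-memory cohort
#'
#' Orchestrates every stage over a cohort of subject sessions (as produced by
#' [simulate_cohort()] or assembled from [read_bnirs()] / [read_eeg()] /
#' [read_schedule()]): bNIRS QC, wavelet motion correction, UCLn inversion,
#' band-pass filtering and block averaging; EEG filtering, average reference,
#' segmentation, artifact rejection, band RMS, block baseline correction and
#' trial averaging; group EEG condition statistics; grand-average response
#' function grid search per chromophore (or the supplied response functions);
#' subject-level coupling GLMs and group coupling statistics with the
#' social-vs-nonsocial contrast. Stage progress and counts go to `stderr`.
#'
#' @param cohort List of sessions, each a list with `schedule`, `bnirs`,
#'   `eeg` (ground truth entries are ignored).
#' @param config A `pipeline_config`.
#' @param rf_list Optional named list of `response_function`s per
#'   chromophore; if NULL and `config$fit_hrf`, they are reconstructed from
#'   the cohort grand averages, otherwise the infant defaults are used.
#' @return List with `qc` (per subject), `eeg_stats`, `grid_search` (per
#'   chromophore, or NULL), `rf_params`, `coupling`, `contrast`,
#'   `subject_betas`, `n_subjects_included`.
#' @export
run_cohort_analysis <- function(cohort, config = pipeline_config(),
                                rf_list = NULL) {
  extinction <- if (identical(config$extinction, "synthetic")) {
    synthetic_extinction()
  } else if (inherits(config$extinction, "extinction_table")) {
    config$extinction
  } else {
    read_extinction(config$extinction)
  }

  qc_list <- list()
  bnirs_avgs <- list()
  eeg_avgs <- list()
  kept <- 0L
  for (si in seq_along(cohort)) {
    sub <- cohort[[si]]
    qc <- qc_channels(sub$bnirs, config$qc_low_counts, config$qc_high_counts,
                      config$qc_subject_threshold)
    qc_list[[si]] <- qc
    if (qc$subject_excluded) {
      stage_log("qc", "subject %d excluded (%.0f%% channels out of range)",
                si, 100 * qc$exclusion_fraction)
      bnirs_avgs[[si]] <- list(NULL)
      eeg_avgs[[si]] <- list(NULL)
      next
    }
    rec <- wavelet_motion_correct(sub$bnirs, config$wavelet_alpha)
    chromo <- ucln_invert(rec, extinction, config$dpf, config$fit_range_nm)
    chromo <- suppressWarnings(
      bandpass_bnirs(chromo, config$bnirs_band_hz[1], config$bnirs_band_hz[2],
                     config$bnirs_filter_order))
    if (length(qc$excluded_channels)) {
      chromo$conc[qc$excluded_channels, , ] <- NA_real_
      chromo$excluded_channels <- qc$excluded_channels
    }
    ba <- list()
    for (cond in c("social", "non-social")) {
      ba[[cond]] <- tryCatch(
        block_average_bnirs(chromo, sub$schedule, cond,
                            window_s = config$hrf_window_s),
        error = function(e) NULL)
    }
    bnirs_avgs[[si]] <- ba

    eeg <- filter_eeg(sub$eeg, config$eeg_band_hz, config$eeg_notch_hz)
    eeg <- rereference_average(eeg)
    bad <- detect_bad_channels(eeg, config$artifact_uv)
    if (length(bad)) {
      stage_log("eeg", "subject %d: interpolating %d bad channel(s): %s",
                si, length(bad), paste(bad, collapse = ", "))
      eeg <- interpolate_bad_channels(eeg, bad)
    }
    seg <- segment_and_baseline(eeg, sub$schedule)
    seg <- reject_artifact_segments(seg, config$artifact_uv)
    stage_log("eeg", "subject %d: %d segments retained", si,
              attr(seg, "n_retained"))
    bp <- band_rms(seg, config$bands)
    eeg_avgs[[si]] <- tryCatch(
      block_baseline_correct_and_average(bp, config$baseline_keep_s,
                                         config$stimulus_keep_s),
      error = function(e) NULL)
    kept <- kept + 1L
  }
  stage_log("qc", "%d of %d subjects retained", kept, length(cohort))

  usable <- which(!vapply(eeg_avgs, is.null, logical(1)) &
                    vapply(eeg_avgs, function(x) !is.null(attr(x, "bands")),
                           logical(1)))
  eeg_stats <- if (length(usable) >= 3) {
    eeg_condition_stats(eeg_avgs[usable], alpha = config$fdr_q)
  } else NULL

  channels <- config$coupling_channels
  grid_results <- NULL
  if (is.null(rf_list)) {
    if (isTRUE(config$fit_hrf)) {
      grand <- cohort_grand_average(bnirs_avgs, channels)
      events <- data.frame(onset_s = 0,
                           duration_s = config$hrf_event_duration_s)
      grid_results <- lapply(seq_along(CHROMOPHORES), function(ci) {
        grid_search_hrf(grand$mean[ci, ], grand$time_s, events,
                        config$hrf_delays, config$hrf_undershoots,
                        config$hrf_ratios)
      })
      names(grid_results) <- CHROMOPHORES
      for (ci in CHROMOPHORES) {
        b <- grid_results[[ci]]$best
        stage_log("hrf", "%s best fit: delay %g s, undershoot %g s, ratio %g",
                  ci, b$delay_response_s, b$delay_undershoot_s,
                  b$ratio_response_undershoot)
      }
      rf_list <- lapply(grid_results, function(g) {
        double_gamma(g$best, sample_period_s = 1)
      })
    } else {
      rf_list <- infant_rf()
    }
  }

  betas <- list()
  for (si in seq_along(cohort)) {
    if (is.null(eeg_avgs[[si]]) || is.null(attr(eeg_avgs[[si]], "bands"))) next
    ba <- bnirs_avgs[[si]]
    if (is.null(ba$social) && is.null(ba$`non-social`)) next
    betas[[length(betas) + 1]] <- subject_coupling(
      ba, eeg_avgs[[si]], rf_list, channels,
      eeg_channels = config$coupling_eeg_channels,
      bands = config$coupling_bands,
      stimulus_keep_s = config$stimulus_keep_s, subject_id = si)
  }
  subject_betas <- do.call(rbind, betas)
  subject_betas <- subject_betas[is.finite(subject_betas$beta), , drop = FALSE]
  coupling <- group_coupling_stats(subject_betas, channels,
                                   alpha = config$fdr_q)
  contrast <- tryCatch(
    condition_contrast(subject_betas, channels, alpha = config$fdr_q),
    error = function(e) NULL)
  stage_log("coupling", "%d cells tested, %d FDR-significant",
            nrow(coupling), sum(coupling$sig_fdr, na.rm = TRUE))

  list(qc = qc_list, eeg_stats = eeg_stats, grid_search = grid_results,
       rf_params = lapply(rf_list, `[[`, "params"),
       coupling = coupling, contrast = contrast,
       subject_betas = subject_betas, n_subjects_included = kept)
}

# Grand-average chromophore response: pool conditions, average the selected
# channels, then average subjects.
cohort_grand_average <- function(bnirs_avgs, channels) {
  acc <- NULL; n <- 0L; time_s <- NULL
  for (ba in bnirs_avgs) {
    conds <- intersect(c("social", "non-social"), names(ba))
    if (!length(conds)) next
    sub_acc <- NULL
    for (cond in conds) {
      m <- ba[[cond]]$mean[channels, , , drop = FALSE]
      chan_mean <- apply(m, c(2, 3), mean, na.rm = TRUE)
      sub_acc <- if (is.null(sub_acc)) chan_mean else sub_acc + chan_mean
      time_s <- ba[[cond]]$time_s
    }
    sub_acc <- sub_acc / length(conds)
    if (anyNA(sub_acc)) next
    acc <- if (is.null(acc)) sub_acc else acc + sub_acc
    n <- n + 1L
  }
  stop_if_not(n > 0, "no subject contributes a grand average")
  # restrict to post-onset samples for the fit
  keep <- time_s >= 0
  list(mean = (acc / n)[, keep, drop = FALSE], time_s = time_s[keep],
       n_subjects = n)
}

#' Run the pipeline from files on disk
#'
#' File-based front end: reads per-subject bNIRS CSV, EEG CSV and schedule
#' TSV, runs [run_cohort_analysis()], and writes the result tables (QC
#' report, EEG statistics, grid-search tables + best-parameter JSON, group
#' coupling and contrast tables) as TSV under `out_dir`. Deterministic given
#' the config seed.
#'
#' @param subjects Data frame with columns `bnirs`, `eeg`, `schedule` (file
#'   paths), one row per subject.
#' @param out_dir Output directory.
#' @param config A `pipeline_config`.
#' @return The [run_cohort_analysis()] result, invisibly; side effect: TSV /
#'   JSON files under `out_dir`.
#' @export
run_pipeline <- function(subjects, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- lapply(seq_len(nrow(subjects)), function(i) {
    stage_log("io", "reading subject %d", i)
    list(bnirs = read_bnirs(subjects$bnirs[i]),
         eeg = read_eeg(subjects$eeg[i]),
         schedule = read_schedule(subjects$schedule[i]))
  })
  res <- run_cohort_analysis(cohort, config)

  qc_tab <- do.call(rbind, lapply(seq_along(res$qc), function(i) {
    cbind(subject = i, res$qc[[i]]$channels,
          subject_excluded = res$qc[[i]]$subject_excluded)
  }))
  utils::write.table(qc_tab, file.path(out_dir, "qc_report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(res$eeg_stats)) {
    utils::write.table(res$eeg_stats, file.path(out_dir, "eeg_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(res$grid_search)) {
    for (ci in names(res$grid_search)) {
      write_grid_search(res$grid_search[[ci]],
                        file.path(out_dir, sprintf("grid_search_%s.tsv", ci)),
                        file.path(out_dir, sprintf("rf_best_%s.json", ci)))
    }
  }
  write_coupling_table(res$coupling, file.path(out_dir, "coupling.tsv"))
  if (!is.null(res$contrast)) {
    write_coupling_table(res$contrast, file.path(out_dir, "contrast.tsv"))
  }
  invisible(res)
}
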
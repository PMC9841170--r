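# End-to-end orchestration: simulate cohort -> stage -> spectra / coherence
# -> cross-recurrence -> wavelet patterns -> SNR/ANN protocol -> group
# statistics -> report files.

#' Default pipeline configuration
#'
#' All seeds are explicit; every tunable of the downstream modules is
#' reachable here. Values follow the package defaults: 100-s Welch windows
#' with 50-s overlap, Bartlett taper, Daniell windows of 0.03 Hz (power) and
#' 0.13 Hz (coherence), fixed 10% recurrence rate with lmin = 2 at a 25-Hz
#' CRA analysis rate, Morlet wavelet patterns at 50 Hz, and the
#' 90-500-50-500-50-1 network trained per subject.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    cohort = list(n_per_group = 7, length_s = 600, sampling_interval_s = 5e-4,
                  analysis_hz = 250),
    welch = list(window_s = 100, overlap_s = 50, taper = "bartlett",
                 daniell_psd_hz = 0.03, daniell_coh_hz = 0.13),
    bands = list(power = c("delta_slow", "delta_wide"),
                 coherence = c("theta", "delta_slow"),
                 cra = c("theta", "delta_wide"),
                 patterns = c("theta")),
    cra = list(analysis_hz = list(theta = 25, delta_wide = 10, default = 25),
               window_s = 100, rr_target = 0.1, lmin = 2, m_max = 6),
    wavelet = list(analysis_hz = 25, k_floor = 2.5),
    ann = list(train_stride = 15, test_stride = 90, threshold = 0.5,
               positive_state = "obbb", negative_state = "wake",
               hyperparams = list()),
    out_dir = NULL
  )
}

#' Load a pipeline configuration from YAML
#'
#' Entries present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' Per-subject metrics for one recording
#'
#' Computes the subject-level metric row used by the pipeline: band powers
#' (from the Daniell-smoothed Welch PSD of the first EEG lead), theta
#' coherence of the lead pair, the five CRA indices per CRA band, and the
#' mean wavelet pattern duration per pattern band.
#'
#' @param rec an [recording()].
#' @param config configuration list (see [default_config()]).
#' @return one-row data.frame.
#' @export
subject_metrics <- function(rec, config = default_config()) {
  dt <- rec$sampling_interval_s
  w <- config$welch
  eegs <- eeg_labels(rec)
  x <- rec_channel(rec, eegs[1])
  y <- rec_channel(rec, eegs[min(2, length(eegs))])
  out <- data.frame(subject_id = rec$subject_id,
                    state = rec$state %||% NA_character_)
  sp <- daniell_smooth(welch_psd(x, dt, w$window_s, w$overlap_s, w$taper),
                       w$daniell_psd_hz)
  for (bn in config$bands$power) {
    out[[paste0("power_", bn)]] <- band_power(sp, bn)
  }
  co <- coherence(x, y, dt, w$window_s, w$overlap_s, w$daniell_coh_hz, w$taper)
  for (bn in config$bands$coherence) {
    out[[paste0("coherence_", bn)]] <- band_coherence(co, bn)
  }
  for (bn in config$bands$cra) {
    hz <- config$cra$analysis_hz
    hz <- if (is.list(hz)) (hz[[bn]] %||% hz$default) else hz
    ci <- cra_band_index(x, y, dt, bn, index_name = "all",
                         analysis_hz = hz,
                         window_s = config$cra$window_s,
                         rr_target = config$cra$rr_target,
                         lmin = config$cra$lmin, m_max = config$cra$m_max)
    for (nm in c("RR", "DET", "L", "MDL", "ENTR")) {
      out[[paste0("cra_", nm, "_", bn)]] <- ci[[nm]]
    }
  }
  for (bn in config$bands$patterns) {
    ps <- band_patterns(x, dt, bn, analysis_hz = config$wavelet$analysis_hz,
                        k_floor = config$wavelet$k_floor)
    out[[paste0("tbar_", bn)]] <- as.numeric(mean_duration(ps))
    out[[paste0("n_patterns_", bn)]] <- nrow(ps$events)
  }
  out
}

# SNR fragments per subject and state for the ANN protocol.
cohort_fragments <- function(cohort, stride = 45) {
  frags <- list()
  for (item in cohort) {
    rec <- item$recording
    sid <- sub("^[a-z]+_", "s", rec$subject_id)
    st <- rec$state
    snr <- snr_series(rec_channel(rec, eeg_labels(rec)[1]),
                      rec$sampling_interval_s)
    if (is.null(frags[[sid]])) frags[[sid]] <- list()
    frags[[sid]][[st]] <- fragment_features(snr, stride = stride)
  }
  frags
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort (per `config$cohort` with [default_profiles()] unless
#' `profiles` is given), decimates the recordings to
#' `config$cohort$analysis_hz` (all analysed EEG content lies well below that
#' rate, and the narrowband filters are only stable at moderate rates),
#' scores hypnograms, computes all per-subject metrics,
#' runs the leave-one-subject ANN protocol, and produces group summaries with
#' Mann-Whitney p-values for every metric and state pair. When
#' `config$out_dir` is set, CSV tables and a manifest (file checksums, seed,
#' package version) are written there.
#'
#' @param config configuration list (see [default_config()]).
#' @param profiles optional named list of [state_profile()]s.
#' @return list with `metrics` (per subject), `cs` (ANN protocol result),
#'   `group_summary`, `group_tests`, `hypnograms`, `staging_agreement`, and
#'   `manifest` (when files were written); invisibly.
#' @export
run_pipeline <- function(config = default_config(), profiles = NULL) {
  profiles <- profiles %||%
    (if (!is.null(config$profiles)) profiles_from_config(config$profiles)) %||%
    default_profiles(config$cohort$sampling_interval_s)
  cohort <- generate_cohort(profiles,
                            n_per_group = config$cohort$n_per_group,
                            length_s = config$cohort$length_s,
                            seed = config$seed,
                            sampling_interval_s = config$cohort$sampling_interval_s)
  fs <- 1 / config$cohort$sampling_interval_s
  ahz <- config$cohort$analysis_hz %||% fs
  if (fs > ahz) {
    cohort <- lapply(cohort, function(it) {
      it$recording$samples <- apply(it$recording$samples, 2, decimate_to,
                                    dt = it$recording$sampling_interval_s,
                                    target_hz = ahz)
      colnames(it$recording$samples) <- it$recording$channel_labels
      it$recording$sampling_interval_s <- 1 / ahz
      it
    })
  }

  metrics <- do.call(rbind, lapply(cohort, function(it)
    subject_metrics(it$recording, config)))
  rownames(metrics) <- NULL

  # staging with a cohort-wide EMG threshold (recordings are single-state)
  all_rms <- unlist(lapply(cohort, function(it) {
    vapply(epochize(it$recording, 10, channels = "EMG"),
           function(e) sqrt(mean(e$samples^2)), numeric(1))
  }))
  emg_thr <- median(all_rms)
  hypno <- lapply(cohort, function(it)
    score_recording(it$recording, emg_threshold = emg_thr))
  agree <- vapply(seq_along(cohort), function(i) {
    gt <- cohort[[i]]$ground_truth$stage_labels
    lab <- hypno[[i]]$label[seq_along(gt)]
    mean(lab == ifelse(gt == "wake", "WAKE", gt))
  }, numeric(1))
  staging <- data.frame(subject_id = names(cohort),
                        state = metrics$state, agreement = agree)

  cs <- leave_one_subject_protocol(
    cohort_fragments(cohort, config$ann$test_stride),
    positive_state = config$ann$positive_state,
    negative_state = config$ann$negative_state,
    hyperparams = config$ann$hyperparams,
    threshold = config$ann$threshold,
    seed = mix_seed(config$seed, 77L),
    train_fragments = cohort_fragments(cohort, config$ann$train_stride))

  metric_cols <- setdiff(names(metrics), c("subject_id", "state"))
  states <- unique(metrics$state)
  gs <- do.call(rbind, lapply(metric_cols, function(mc) {
    d <- group_summary(split(metrics[[mc]], metrics$state))
    d$metric <- mc
    d
  }))
  pairs <- utils::combn(states, 2, simplify = FALSE)
  gt_rows <- list()
  for (mc in metric_cols) {
    for (pr in pairs) {
      a <- metrics[[mc]][metrics$state == pr[1]]
      b <- metrics[[mc]][metrics$state == pr[2]]
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        metric = mc, group_a = pr[1], group_b = pr[2],
        mean_a = mean(a), mean_b = mean(b),
        p_value = mww_test(a, b))
    }
  }
  group_tests <- do.call(rbind, gt_rows)
  group_tests$significant <- group_tests$p_value < 0.05

  out <- list(metrics = metrics, cs = cs, group_summary = gs,
              group_tests = group_tests, hypnograms = hypno,
              staging_agreement = staging, emg_threshold = emg_thr,
              config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) {
      p <- file.path(config$out_dir, f)
      utils::write.csv(d, p, row.names = FALSE)
      p
    }
    files <- c(
      wr(metrics, "subject_metrics.csv"),
      wr(gs, "group_summary.csv"),
      wr(group_tests, "group_tests.csv"),
      wr(cs$per_network, "cs_per_network.csv"),
      wr(cs$summary, "cs_summary.csv"),
      wr(staging, "staging_agreement.csv"),
      wr(do.call(rbind, lapply(seq_along(hypno), function(i) {
        h <- hypno[[i]][, c("epoch", "start_s", "label")]
        h$subject_id <- names(cohort)[i]
        h
      })), "hypnograms.csv")
    )
    manifest <- data.frame(file = basename(files),
                           md5 = as.character(tools::md5sum(files)),
                           seed = config$seed,
                           package_version = as.character(
                             utils::packageVersion("ldsbeeg")))
    wr(manifest, "manifest.csv")
    out$manifest <- manifest
  }
  invisible(out)
}
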
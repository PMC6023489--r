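#' Analysis pipeline configuration
#'
#' Collects every tunable parameter of the detection pipeline so a run can
#' be reproduced from its manifest alone.
#'
#' @param alpha Significance level for all tests (default 0.05).
#' @param feature Feature driving selection and classification:
#'   `"entropy"` (default) or `"energy"`.
#' @param lengths Window lengths (s) for the sweep (default `1:20`).
#' @param priors LDA priors, see [fit_lda()].
#' @param analysis_rate,order,frame_duration,max_formants,radius_floor,taper
#'   Formant-tracking parameters, see [track_formants()].
#' @param window_s,hop_frac,window Spectrogram parameters, see
#'   [compute_spectrogram()].
#' @param eps_rel Entropy floor constant, see [entropy_feature()].
#' @param var_equal Pooled-variance t-tests (default TRUE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, feature = c("entropy", "energy"),
                            lengths = 1:20, priors = "empirical",
                            analysis_rate = 8000, order = 8L,
                            frame_duration = 0.032, max_formants = 4L,
                            radius_floor = 0.7, taper = "hamming",
                            window_s = 0.032, hop_frac = 0.5,
                            window = "hann", eps_rel = 1e-12,
                            var_equal = TRUE) {
  feature <- match.arg(feature)
  structure(
    list(alpha = alpha, feature = feature, lengths = lengths,
         priors = priors, analysis_rate = analysis_rate, order = order,
         frame_duration = frame_duration, max_formants = max_formants,
         radius_floor = radius_floor, taper = taper, window_s = window_s,
         hop_frac = hop_frac, window = window, eps_rel = eps_rel,
         var_equal = var_equal),
    class = "pipeline_config")
}

# Per-recording front end with failure capture. Returns the frame-series
# list or NULL (failure recorded by the caller).
safe_feature_frames <- function(rec, cfg) {
  formant_feature_frames(
    rec, analysis_rate = cfg$analysis_rate, order = cfg$order,
    frame_duration = cfg$frame_duration, max_formants = cfg$max_formants,
    radius_floor = cfg$radius_floor, taper = cfg$taper,
    window_s = cfg$window_s, hop_frac = cfg$hop_frac, window = cfg$window,
    eps_rel = cfg$eps_rel)
}

feature_from_series <- function(ff, formant, kind, L) {
  contrib <- if (kind == "entropy") ff$entropy[, formant]
             else ff$energy[, formant]
  segment_mean(ff$frame_times, contrib, ff$duration, L)
}

#' Run the full PAH detection pipeline on a cohort
#'
#' Executes the stages in order: ingest, resample, formant tracking,
#' sine-wave replicas, spectrogram features, site/formant ranking (on the
#' whole-recording feature), window-length sweep at the selected site and
#' formant, then LDA with leave-one-out cross-validation at the optimal
#' window length. Per-recording failures are logged and skipped; the run
#' aborts only if a whole stage cannot proceed.
#'
#' @param cohort A `pcg_cohort` (from [synth_cohort()] / [read_cohort()])
#'   or a path to a cohort metadata table.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when set, every stage's table plus a
#'   run manifest are written as delimited text.
#' @param verbose Print stage progress (default FALSE).
#' @return A `pipeline_result`: list with `site_formant_tests`,
#'   `window_sweep`, `selection` (site, formant, window length),
#'   `classification` (a [loo_evaluate()] result), `features_full`,
#'   `features_sweep`, `failures`, and `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "pcg_cohort"),
            inherits(config, "pipeline_config"))
  md <- cohort$metadata
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage 1/4: feature extraction on %d recordings", nrow(md))
  series <- vector("list", nrow(md))
  failures <- character(0)
  for (i in seq_len(nrow(md))) {
    series[[i]] <- tryCatch(
      safe_feature_frames(cohort$recordings[[i]], config),
      error = function(e) {
        failures <<- c(failures, sprintf("%s/%s: %s", md$subject_id[i],
                                         md$site[i], conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(series, is.null, logical(1))
  if (length(failures))
    warning(length(failures), " recording(s) failed feature extraction ",
            "and were skipped")
  if (!any(ok)) stop("feature extraction failed for every recording")
  md <- md[ok, , drop = FALSE]
  series <- series[ok]

  # whole-recording features for every site x formant
  full_L <- min(vapply(series, `[[`, numeric(1), "duration"))
  features_full <- do.call(rbind, lapply(seq_len(nrow(md)), function(i) {
    data.frame(subject_id = md$subject_id[i], group = md$group[i],
               site = md$site[i], formant = seq_len(config$max_formants),
               feature = config$feature, window_length_s = full_L,
               value = vapply(seq_len(config$max_formants), function(f)
                 feature_from_series(series[[i]], f, config$feature, full_L),
                 numeric(1)))
  }))

  say("stage 2/4: site/formant ranking")
  tests <- rank_sites_formants(features_full, alpha = config$alpha,
                               var_equal = config$var_equal)
  sel_site <- tests$site[1]
  sel_formant <- tests$formant[1]

  say("stage 3/4: window sweep at %s / formant %d", sel_site, sel_formant)
  lengths <- config$lengths[config$lengths <= full_L + 1e-9]
  if (length(lengths) == 0L)
    stop("no window length in the grid fits the recording duration (",
         signif(full_L, 4), " s)")
  if (length(lengths) < length(config$lengths))
    warning("dropped ", length(config$lengths) - length(lengths),
            " window length(s) exceeding the recording duration")
  config$lengths <- lengths
  sel_idx <- which(md$site == sel_site)
  features_sweep <- do.call(rbind, lapply(sel_idx, function(i) {
    data.frame(subject_id = md$subject_id[i], group = md$group[i],
               site = md$site[i], formant = sel_formant,
               feature = config$feature,
               window_length_s = config$lengths,
               value = vapply(config$lengths, function(L)
                 feature_from_series(series[[i]], sel_formant,
                                     config$feature, L), numeric(1)))
  }))
  sweep <- sweep_window_lengths(features_sweep, lengths = config$lengths,
                                var_equal = config$var_equal)
  L_opt <- attr(sweep, "optimal_length")

  say("stage 4/4: LDA / leave-one-out at L = %g s", L_opt)
  sel_rows <- features_sweep[abs(features_sweep$window_length_s - L_opt) < 1e-9, ]
  cls <- loo_evaluate(sel_rows$value, sel_rows$group, priors = config$priors)

  result <- structure(
    list(site_formant_tests = tests, window_sweep = sweep,
         selection = list(site = sel_site, formant = sel_formant,
                          window_length_s = L_opt),
         classification = cls, features_full = features_full,
         features_sweep = features_sweep, failures = failures,
         config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<pipeline_result>\n",
    "  selected: site %s, formant %d, window %g s\n",
    "  corrected p at optimum: %.3g\n",
    "  LOO: TP=%d FP=%d TN=%d FN=%d | sensitivity %.2f%%, specificity %.2f%%\n"),
    x$selection$site, x$selection$formant, x$selection$window_length_s,
    min(x$window_sweep$p_corrected), x$classification$TP,
    x$classification$FP, x$classification$TN, x$classification$FN,
    x$classification$sensitivity, x$classification$specificity))
  if (length(x$failures))
    cat(sprintf("  %d recording(s) skipped\n", length(x$failures)))
  invisible(x)
}

# Persist every stage table plus a run manifest.
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(result$features_full, "features_full.tsv")
  wt(result$features_sweep, "features_sweep.tsv")
  wt(result$site_formant_tests, "site_formant_tests.tsv")
  wt(result$window_sweep, "window_sweep.tsv")
  wt(result$classification$predictions, "predictions.tsv")
  cls <- result$classification
  summary_lines <- c(
    sprintf("selected_site\t%s", result$selection$site),
    sprintf("selected_formant\t%d", result$selection$formant),
    sprintf("optimal_window_s\t%g", result$selection$window_length_s),
    sprintf("TP\t%d", cls$TP), sprintf("FP\t%d", cls$FP),
    sprintf("TN\t%d", cls$TN), sprintf("FN\t%d", cls$FN),
    sprintf("sensitivity_pct\t%.4f", cls$sensitivity),
    sprintf("specificity_pct\t%.4f", cls$specificity))
  writeLines(summary_lines, file.path(out_dir, "summary.tsv"))
  cfg <- result$config
  manifest <- c(
    sprintf("package\tphonoformant %s",
            as.character(utils::packageVersion("phonoformant"))),
    sprintf("timestamp\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    vapply(names(cfg), function(k)
      sprintf("%s\t%s", k, paste(format(cfg[[k]]), collapse = ",")),
      character(1)),
    sprintf("n_failures\t%d", length(result$failures)),
    if (length(result$failures)) paste0("failure\t", result$failures))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
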
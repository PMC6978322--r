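#' Heuristic elongation-window detection from the probe channel
#'
#' The transcript probe hybridises shortly after elongation starts and
#' departs at termination, so the probe-present interval brackets the usable
#' elongation fit window.  Probe presence is called by thresholding the
#' probe channel halfway between its low and high levels.
#'
#' @param trace An [intensity_trace()].
#' @return `c(t_start, t_end)` in seconds, or `NULL` when no probe interval
#'   is found.
#' @export
detect_elongation_window <- function(trace) {
  y <- trace$I_probe
  thr <- (quantile(y, 0.05) + quantile(y, 0.95)) / 2
  on <- which(y > thr)
  if (length(on) < 5L) return(NULL)
  c(trace$time_s[min(on)], trace$time_s[max(on)])
}

#' Analyse one simulated molecule end-to-end
#'
#' Calibrates the elongation decay on the ground-truth window, derives the
#' elongation rate and post-termination position trace, and classifies
#' sliding and secondary initiation.  Used by [run_pipeline()]; exported for
#' stepwise use.
#'
#' @param sim One element of [simulate_cohort()] output (`trace` plus
#'   `truth` row), or the result of [simulate_trace()].
#' @param config The [trace_sim_config()] used to generate the cohort
#'   (supplies template geometry).
#' @param window_s Diffusion window length, s.
#' @param D_threshold Sliding threshold, bp^2 s^-1.
#' @return A one-row data.frame with the fitted `lambda`, `r_RNAP`, flags
#'   `slid`, `antisense`, `sense_reinit`, the fitted secondary `rate`, and
#'   `max_D`.
#' @export
analyze_molecule <- function(sim, config, window_s = 50, D_threshold = 2.2e4) {
  tru <- sim$truth
  trace <- sim$trace
  na_row <- data.frame(molecule = tru$molecule, lambda = NA_real_,
                       r_RNAP = NA_real_, slid = NA, antisense = NA,
                       sense_reinit = NA, rate = NA_real_, max_D = NA_real_)
  fit <- tryCatch(
    fit_elongation_decay(trace, c(tru$t_start, tru$t_T),
                         orientation = config$tether_orientation),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(na_row)
  I_T <- fit$I_P * exp(-fit$lambda * diff(fit$window)) + fit$I_mn
  er <- tryCatch(
    compute_elongation_rate(fit, I_T, config$z_P, config$z_T),
    error = function(e) NULL)
  if (is.null(er) || er$unphysical) return(na_row)

  post <- trace$time_s > tru$t_T &
    trace$time_s < min(tru$t_rnap_depart, Inf, na.rm = TRUE)
  pos <- suppressWarnings(intensity_to_position(
    fit, er$r_RNAP, trace, config$z_P, frames = post,
    template_length = config$template_length,
    orientation = config$tether_orientation, z_T = config$z_T))
  wins <- if (sum(is.finite(pos$z)) > 12 &&
              diff(range(pos$time_s)) >= window_s)
    window_diffusion(pos$time_s, pos$z, window = window_s)
  else data.frame(D = numeric())
  slid <- if (nrow(wins)) classify_sliding(wins, D_threshold) else FALSE
  call <- classify_secondary_initiation(trace, fit, tru$t_T)
  data.frame(molecule = tru$molecule, lambda = fit$lambda,
             r_RNAP = er$r_RNAP, slid = slid, antisense = call$antisense,
             sense_reinit = call$sense_reinit, rate = call$rate,
             max_D = if (nrow(wins)) max(wins$D) else NA_real_)
}

#' Departure records from cohort ground truth
#'
#' @param truth The `truth` data.frame of [simulate_cohort()].
#' @return A data.frame with `probe_departure`, `rnap_departure`,
#'   `censored`, and post-termination `duration` for retained molecules.
#' @export
departure_records <- function(truth) {
  data.frame(
    molecule = truth$molecule,
    probe_departure = truth$t_T,
    rnap_departure = ifelse(truth$rnap_censored, NA_real_,
                            truth$t_rnap_depart),
    censored = truth$rnap_censored,
    duration = ifelse(truth$rnap_censored,
                      truth$t_acq_end - truth$t_T,
                      truth$t_rnap_depart - truth$t_T))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a cohort of single-molecule traces and a Rend-seq track set,
#' analyses both with the package's estimators, and writes a reproducible
#' report.  All randomness derives from `seed`; re-running with the same
#' seed produces byte-identical outputs.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param n_molecules Cohort size.
#' @param trace_config Optional [trace_sim_config()]; default uses the
#'   package defaults with `seed`.
#' @param rend_config Optional [rend_sim_config()]; default builds a
#'   [synthetic_genome()] and simulates tracks with `seed`.
#' @param n_control_reps Control replicates for the Rend-seq stage.
#' @param write_tables Write traces/track/table files alongside the report.
#' @return The report as a list (also written to `report.json`), containing
#'   cohort fractions, the lifetime estimate, Rend-seq peak summaries, the
#'   distance profile, the control p-value and a manifest (package version,
#'   seed, parameter hash).
#' @export
run_pipeline <- function(outdir, seed = 1L, n_molecules = 20L,
                         trace_config = NULL, rend_config = NULL,
                         n_control_reps = 20L, write_tables = TRUE) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(trace_config)) trace_config <- trace_sim_config(seed = seed)
  if (is.null(rend_config)) {
    g <- synthetic_genome()
    rend_config <- rend_sim_config(g$genome_length, g$genes, g$terminators,
                                   seed = seed + 1L)
  }

  coh <- simulate_cohort(trace_config, n_molecules)
  calls <- do.call(rbind, lapply(seq_len(n_molecules), function(i)
    analyze_molecule(list(trace = coh$traces[[i]],
                          truth = coh$truth[i, ]), trace_config)))

  dep <- departure_records(coh$truth)
  dcls <- classify_departures(dep$probe_departure, dep$rnap_departure,
                              dep$censored)
  retained <- coh$truth$retained
  lt <- NULL
  ret_idx <- which(retained & dep$duration > 0)
  if (sum(!dep$censored[ret_idx]) > 0)
    lt <- correct_photobleaching(dep$duration[ret_idx],
                                 dep$censored[ret_idx],
                                 k_PB = trace_config$k_PB,
                                 seed = seed + 2L)

  rs <- simulate_rendseq(rend_config)
  term <- filter_terminators(rend_config$terminators, rend_config$genes)
  peaks <- terminator_peaks(rs$tracks, term)
  prof <- distance_profile(rs$tracks, term)
  obs0 <- prof$fraction[prof$distance == 0]
  ctrl <- control_replicates(rs$tracks, rend_config$genes, term,
                             observed_fraction = obs0,
                             n_reps = n_control_reps,
                             n_loc = sum(term$eligible), seed = seed + 3L)

  cfg_txt <- tempfile()
  writeLines(c(deparse(trace_config[setdiff(names(trace_config),
                                            "antisense_offset")]),
               sprintf("n_molecules=%d seed=%d", n_molecules, seed)),
             cfg_txt)
  manifest <- list(
    package = "termcycle",
    version = as.character(utils::packageVersion("termcycle")),
    seed = seed,
    n_molecules = n_molecules,
    config_hash = unname(tools::md5sum(cfg_txt)))
  unlink(cfg_txt)

  report <- list(
    manifest = manifest,
    departures = list(fractions = as.list(dcls$fractions),
                      se = as.list(dcls$se), n = dcls$n),
    retained_fraction = mean(retained),
    slid_fraction = mean(calls$slid, na.rm = TRUE),
    antisense_fraction = mean(calls$antisense, na.rm = TRUE),
    lifetime = if (is.null(lt)) NULL else
      list(k_obs = lt$k_obs, k_RNAP = lt$k_RNAP, lifetime_s = lt$lifetime,
           lifetime_se = lt$lifetime_se, ci = lt$ci),
    rendseq = list(
      n_terminators = nrow(term),
      n_eligible = sum(term$eligible),
      n_strong_antisense = sum(peaks$zscore > 12, na.rm = TRUE),
      terminator_bin_fraction = obs0,
      control_p_value = ctrl$p_value))

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  if (write_tables) {
    write_traces(coh$traces, file.path(outdir, "traces.tsv"))
    write.table(coh$truth, file.path(outdir, "trace_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(calls, file.path(outdir, "behavior_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(peaks, file.path(outdir, "terminator_peaks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(prof, file.path(outdir, "distance_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_end_tracks(rs$tracks, outdir)
  }
  invisible(report)
}
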
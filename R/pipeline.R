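# End-to-end orchestration: EEG-PSI -> dFC -> grid selection -> surrogate
# significance -> epilepsy-related flags -> network characterization.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its conventional default:
#' 2.5 s PSI segments, 3-10 Hz band, 15-TR windows stepped by 2 TRs, l1
#' dictionary learning with PCA initialization over k = 2..20 and an
#' automatic five-point lambda grid, 100 surrogates.
#'
#' @param bold R x T_scan matrix, or path to a `bold.tsv`.
#' @param TR repetition time in seconds.
#' @param eeg channels x samples matrix, or path to an `eeg.tsv`; ignored
#'   when `psi` is given.
#' @param fs EEG sampling rate (Hz).
#' @param psi optional precomputed EEG-PSI metric (one value per TR), or
#'   path to a two-column TSV (segment, value); skips the EEG stage.
#' @param parcel_groups optional vector of group labels (length R) for the
#'   characterization stage.
#' @param out_dir optional run directory; stage outputs are written there.
#' @param segment_sec,band,freqs,n_cycles PSI stage parameters.
#' @param lowpass_hz BOLD low-pass cutoff in Hz (`NA` to skip).
#' @param L,s window length and step in TRs.
#' @param sweep window lengths (TRs) for [run_sweep()].
#' @param method,init,k_range,lambda_grid factorization grid, see
#'   [grid_select()].
#' @param psi_align window alignment of the metric, see [psi_to_windows()].
#' @param target_n,pct_range,ctrl_factor selection statistics, see
#'   [rho_dfc()] and [rho_ctrl()].
#' @param n_surr,alpha surrogate test parameters.
#' @param z_thresh ROI-level network threshold on `|Z|`.
#' @param seed integer seed used for every stochastic stage.
#' @param n_rep k-means restarts.
#' @param n_iter,tol dictionary-learning iteration controls.
#' @return A list of class `dfc_config`.
#' @export
pipeline_config <- function(bold, TR, eeg = NULL, fs = NULL, psi = NULL,
                            parcel_groups = NULL, out_dir = NULL,
                            segment_sec = 2.5, band = c(3, 10), freqs = 2:20,
                            n_cycles = 6, lowpass_hz = 0.1, L = 15L, s = 2L,
                            sweep = c(12L, 15L, 18L, 21L, 24L),
                            method = "l1dl", init = "pca", k_range = 2:20,
                            lambda_grid = NULL, psi_align = "mean",
                            target_n = 5L, pct_range = c(0.90, 0.95),
                            ctrl_factor = 1.10, n_surr = 100L, alpha = 0.05,
                            z_thresh = 2.3, seed = 1L, n_rep = 100L,
                            n_iter = 100L, tol = 1e-5) {
  cfg <- as.list(environment())
  class(cfg) <- "dfc_config"
  cfg
}

load_bold <- function(cfg) {
  m <- if (is.character(cfg$bold)) read_tsv_matrix(cfg$bold) else
    as.matrix(cfg$bold)
  ts <- roi_timeseries(m, cfg$TR)
  if (is.finite(cfg$lowpass_hz)) ts <- lowpass_bold(ts, cfg$lowpass_hz)
  ts
}

load_psi_metric <- function(cfg) {
  if (!is.null(cfg$psi)) {
    if (is.character(cfg$psi)) {
      df <- utils::read.table(cfg$psi, sep = "\t", header = TRUE)
      return(list(metric = df[[2L]], source = "file"))
    }
    return(list(metric = as.numeric(cfg$psi), source = "supplied"))
  }
  if (is.null(cfg$eeg)) stop("either eeg or psi must be provided")
  eeg <- if (is.character(cfg$eeg)) read_tsv_matrix(cfg$eeg) else
    as.matrix(cfg$eeg)
  if (is.null(cfg$fs)) stop("fs required with raw EEG input")
  ps <- eeg_psi(eeg, fs = cfg$fs, segment_sec = cfg$segment_sec,
                band = cfg$band, freqs = cfg$freqs, n_cycles = cfg$n_cycles)
  list(metric = ps$metric, source = "eeg", psi_series = ps)
}

#' Run the full dFC state pipeline
#'
#' Stages: EEG-PSI (skipped when a metric is supplied), BOLD low-pass,
#' sliding-window dFC, EEG-guided grid selection, phase-randomization
#' surrogate test, Bonferroni-corrected epilepsy-related flagging, high/low
#' PSI spatial correlations, and (when parcel groups are given) HRF-GLM
#' network mapping with group-strength averaging.
#'
#' @param cfg a [pipeline_config()].
#' @return An object of class `dfc_run`: list with `psi_metric`, `dfc`,
#'   `selection`, `surrogate`, `related` (epilepsy-related flags and
#'   p-values), `rho_dfc`, `rho_ctrl`, `network` (or NULL), `strengths`
#'   (or NULL), `summary` (flat record of headline numbers), `config`.
#'   With `cfg$out_dir` set, stage outputs and `summary.json` are written
#'   there.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "dfc_config"))
  ts <- load_bold(cfg)
  psi <- load_psi_metric(cfg)
  if (length(psi$metric) < ncol(ts$data))
    stop(sprintf("PSI metric (%d) shorter than scan (%d TRs)",
                 length(psi$metric), ncol(ts$data)))
  metric <- psi$metric[seq_len(ncol(ts$data))]
  dfc <- build_dfc(ts, L = cfg$L, s = cfg$s)
  psi_win <- psi_to_windows(metric, dfc$windows, method = cfg$psi_align)
  sel <- grid_select(dfc$C, psi_win, method = cfg$method,
                     k_range = cfg$k_range, lambda_grid = cfg$lambda_grid,
                     init = cfg$init, seed = cfg$seed, n_rep = cfg$n_rep,
                     n_iter = cfg$n_iter, tol = cfg$tol)
  sn <- surrogate_null(dfc$C, sel, n_surr = cfg$n_surr, seed = cfg$seed,
                       alpha = cfg$alpha)
  rel <- epilepsy_related(sel$W, psi_win, significant = sn$significant_state,
                          alpha = cfg$alpha, use_abs = sel$use_abs)
  d_best <- sel$fit$D[, sel$best_state]
  rd <- rho_dfc(dfc$C, psi_win, d_best, pct_range = cfg$pct_range,
                target_n = cfg$target_n)
  rc <- rho_ctrl(dfc$C, psi_win, d_best, factor = cfg$ctrl_factor)
  network <- NULL
  strengths <- NULL
  design <- hrf_regressor(metric, cfg$TR)
  network <- roi_glm(ts, design, z_thresh = cfg$z_thresh)
  if (!is.null(cfg$parcel_groups)) {
    groups <- cfg$parcel_groups
    sel_groups <- unique(as.character(groups[network$selected]))
    er_states <- which(rel$epilepsy_related)
    if (length(sel_groups) && length(er_states)) {
      strengths <- lapply(er_states, function(i)
        group_strength(sel$fit$D[, i], dfc$R, groups, sel_groups))
      names(strengths) <- paste0("state", er_states)
    }
  }
  summary <- list(
    method = cfg$method, init = cfg$init,
    chosen_k = sel$chosen_k, chosen_lambda = sel$chosen_lambda,
    rho_max = sel$rho_max, rho_star_max = sel$rho_star_max,
    best_state = sel$best_state,
    rho_dfc = rd$rho_dfc, rho_dfc_pct = rd$pct, rho_ctrl = rc$rho_ctrl,
    significant_states = which(sn$significant_state),
    epilepsy_related_states = which(rel$epilepsy_related),
    n_windows = ncol(dfc$C), L = cfg$L, s = cfg$s, seed = cfg$seed,
    psi_source = psi$source,
    input_dims = list(R = nrow(ts$data), T_scan = ncol(ts$data)))
  run <- structure(list(psi_metric = metric, dfc = dfc, selection = sel,
                        surrogate = sn, related = rel, rho_dfc = rd,
                        rho_ctrl = rc, network = network,
                        strengths = strengths, summary = summary,
                        config = cfg),
                   class = "dfc_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

#' @export
print.dfc_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("dFC pipeline run (%s, init %s)\n",
           "  chosen k = %d, lambda = %s\n",
           "  rho*_max = %.3f, rho_dFC = %.3f, rho_CTRL = %.3f\n",
           "  significant states: %s\n  epilepsy-related states: %s\n"),
    s$method, s$init, s$chosen_k, format(s$chosen_lambda, digits = 4),
    s$rho_star_max, s$rho_dfc, s$rho_ctrl,
    paste(s$significant_states, collapse = ", "),
    if (length(s$epilepsy_related_states))
      paste(s$epilepsy_related_states, collapse = ", ") else "none"))
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_matrix(run$dfc$C, file.path(dir, "dfc.tsv"), row_label = "pair")
  jsonlite::write_json(
    list(windows = run$dfc$windows, L = run$dfc$window_len_tr,
         s = run$dfc$step_tr, TR = run$dfc$TR,
         pair_order = "row-major upper triangle, 0-based (i, j), i < j"),
    file.path(dir, "windows.json"), auto_unbox = TRUE, digits = NA)
  write_tsv_matrix(run$selection$fit$D, file.path(dir, "states.tsv"),
                   row_label = "pair")
  write_tsv_matrix(run$selection$fit$A, file.path(dir, "weights.tsv"),
                   row_label = "state")
  write_tsv_matrix(run$selection$W, file.path(dir, "nonsparse_weights.tsv"),
                   row_label = "state")
  utils::write.table(
    data.frame(segment = seq_along(run$psi_metric), value = run$psi_metric),
    file.path(dir, "psi_metric.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(rho_table = run$selection$rho_table,
         chosen_k = run$selection$chosen_k,
         chosen_lambda = run$selection$chosen_lambda,
         rho_max = run$selection$rho_max,
         rho_star_max = run$selection$rho_star_max,
         best_state = run$selection$best_state),
    file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(E_real = run$surrogate$E_real, threshold = run$surrogate$threshold,
         significant = run$surrogate$significant_state,
         n_surr = run$surrogate$n_surr, seed = run$surrogate$seed),
    file.path(dir, "surrogate.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(run$network))
    utils::write.table(run$network, file.path(dir, "network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$strengths)) {
    for (nm in names(run$strengths))
      write_tsv_matrix(run$strengths[[nm]],
                       file.path(dir, paste0("strengths_", nm, ".tsv")),
                       row_label = "group")
  }
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Window-length robustness sweep
#'
#' Reruns dFC estimation and grid selection at each window length in
#' `cfg$sweep`, then reports the pairwise spatial correlations of the best
#' state (dFC_max) across lengths and the spread of the selection
#' statistics.
#'
#' @param cfg a [pipeline_config()] with at least two lengths in `sweep`.
#' @return List with `per_length` (data.frame: L, chosen_k, chosen_lambda,
#'   rho_star_max, rho_dfc, rho_ctrl), `dfc_max_cor` (lengths x lengths
#'   matrix), and `stat_sd` (sd of each statistic across lengths).
#' @export
run_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "dfc_config"))
  if (length(cfg$sweep) < 2L) stop("need at least 2 window lengths")
  ts <- load_bold(cfg)
  psi <- load_psi_metric(cfg)
  metric <- psi$metric[seq_len(ncol(ts$data))]
  res <- lapply(cfg$sweep, function(L) {
    dfc <- build_dfc(ts, L = L, s = cfg$s)
    psi_win <- psi_to_windows(metric, dfc$windows, method = cfg$psi_align)
    sel <- grid_select(dfc$C, psi_win, method = cfg$method,
                       k_range = cfg$k_range, lambda_grid = cfg$lambda_grid,
                       init = cfg$init, seed = cfg$seed, n_rep = cfg$n_rep,
                       n_iter = cfg$n_iter, tol = cfg$tol)
    d_best <- sel$fit$D[, sel$best_state]
    rd <- rho_dfc(dfc$C, psi_win, d_best, pct_range = cfg$pct_range,
                  target_n = cfg$target_n)
    rc <- rho_ctrl(dfc$C, psi_win, d_best, factor = cfg$ctrl_factor)
    list(L = L, sel = sel, d_best = d_best, rho_dfc = rd$rho_dfc,
         rho_ctrl = rc$rho_ctrl)
  })
  n <- length(res)
  cormat <- diag(1, n)
  dimnames(cormat) <- list(paste0("L", cfg$sweep), paste0("L", cfg$sweep))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a != b)
      cormat[a, b] <- stats::cor(res[[a]]$d_best, res[[b]]$d_best)
  }
  per_length <- data.frame(
    L = cfg$sweep,
    chosen_k = vapply(res, function(r) r$sel$chosen_k, integer(1L)),
    chosen_lambda = vapply(res, function(r)
      as.numeric(r$sel$chosen_lambda), numeric(1L)),
    rho_star_max = vapply(res, function(r) r$sel$rho_star_max, numeric(1L)),
    rho_dfc = vapply(res, function(r) r$rho_dfc, numeric(1L)),
    rho_ctrl = vapply(res, function(r) r$rho_ctrl, numeric(1L)))
  list(per_length = per_length, dfc_max_cor = cormat,
       stat_sd = c(rho_star_max = stats::sd(per_length$rho_star_max),
                   rho_dfc = stats::sd(per_length$rho_dfc),
                   rho_ctrl = stats::sd(per_length$rho_ctrl)))
}

#' One-command synthetic demonstration
#'
#' Generates the default synthetic scene and runs the full pipeline on it,
#' using the planted EEG; the scene's ground truth is attached for
#' comparison.
#'
#' @param seed integer seed.
#' @param out_dir optional run directory.
#' @param ... overrides passed to [pipeline_config()] (e.g. `k_range`,
#'   `n_surr`).
#' @return A `dfc_run` with an extra element `scene`.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, ...) {
  scene <- synth_scene(seed = seed)
  cfg <- pipeline_config(bold = scene$bold$data, TR = scene$params$TR,
                         eeg = scene$eeg, fs = scene$fs, out_dir = out_dir,
                         seed = seed, ...)
  run <- run_all(cfg)
  run$scene <- scene
  run
}
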
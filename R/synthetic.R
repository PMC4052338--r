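#' Ground truth for synthetic ROI datasets
#'
#' Bundles a generating model with the statistical structure the analysis
#' assumes: per-node baseline, AR(1)-correlated Gaussian noise scaled to a
#' target signal-to-noise ratio, a slow cosine drift the 256-s high-pass
#' must remove, the HRF, and between-subject parameter jitter.
#'
#' SNR is defined at the volume grid as the standard deviation of the
#' noise-free stimulus-locked signal over the noise standard deviation.
#' The drift amplitude is expressed relative to the noise sd.
#'
#' @param model The generating [dcm_model()].
#' @param baseline Per-node baseline (arbitrary units; scalar recycled).
#' @param snr Target signal-to-noise ratio (> 0; `Inf` gives noiseless
#'   data).
#' @param ar1 AR(1) coefficient of the noise, in `[0, 1)`.
#' @param drift_amplitude Cosine drift amplitude as a multiple of the noise
#'   sd.
#' @param drift_period_s Drift period in seconds (default 300 s).
#' @param subject_sd Gaussian jitter sd applied to each free parameter per
#'   subject (truncated to stability by resampling).
#' @param hrf An [hrf_spec()].
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(model, baseline = 100, snr = 2, ar1 = 0.3,
                         drift_amplitude = 1, drift_period_s = 300,
                         subject_sd = 0.05, hrf = hrf_spec()) {
  stopifnot(inherits(model, "dcm_model"), snr > 0, ar1 >= 0, ar1 < 1,
            drift_amplitude >= 0, drift_period_s > 0, subject_sd >= 0)
  n <- length(model$nodes)
  baseline <- rep_len(baseline, n)
  structure(
    list(model = model, baseline = baseline, snr = snr, ar1 = ar1,
         drift_amplitude = drift_amplitude, drift_period_s = drift_period_s,
         subject_sd = subject_sd, hrf = hrf),
    class = "ground_truth"
  )
}

#' Preset ground truth with the qualitative winning-model pattern
#'
#' A five-node ground truth whose sign pattern matches the effect the
#' analysis is built to recover: positive input-driven coupling into and
#' between the auditory cortices, right-to-left flow between the lateral
#' nodes with an inhibited left-to-right back connection, inhibitory
#' feedback from the planum temporale to all four AC nodes, and a negative
#' place-of-articulation modulation of the right-lateral-AC -> PT
#' connection.
#'
#' @param strength Magnitude (Hz) of the PoA modulation; the B entry is
#'   `-abs(strength)`.
#' @param ... Passed to [ground_truth()] (e.g. `snr`, `subject_sd`).
#' @return A [ground_truth()].
#' @export
scenario_poa_inhibition <- function(strength = 0.4, ...) {
  nodes <- auditory_nodes()
  n <- length(nodes)
  mask <- build_connectivity_mask(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  set_a <- function(from, to, v) A[to, from] <<- v
  set_a("L-medial-AC", "L-lateral-AC", 0.2)
  set_a("L-lateral-AC", "L-medial-AC", 0.2)
  set_a("R-medial-AC", "R-lateral-AC", 0.3)   # stronger medial-to-lateral
  set_a("R-lateral-AC", "R-medial-AC", 0.2)
  set_a("L-medial-AC", "R-medial-AC", 0.2)
  set_a("R-medial-AC", "L-medial-AC", 0.2)
  set_a("R-lateral-AC", "L-lateral-AC", 0.3)  # right-to-left flow
  set_a("L-lateral-AC", "R-lateral-AC", -0.2) # inhibited back connection
  for (ac in nodes[nodes != "L-PT"]) {
    set_a(ac, "L-PT", 0.3)                    # forward to PT
    set_a("L-PT", ac, -0.2)                   # inhibitory PT feedback
  }
  diag(A) <- -0.5
  B <- matrix(0, n, n, dimnames = list(nodes, nodes))
  B["L-PT", "R-lateral-AC"] <- -abs(strength)
  C <- matrix(0, n, 1, dimnames = list(nodes, "phonetic"))
  C[nodes != "L-PT", 1] <- 0.4
  mask_B <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  mask_B["L-PT", "R-lateral-AC"] <- TRUE
  model <- dcm_model(nodes, A, B = list(poa = B), C = C,
                     mask_A = mask,
                     mask_B = list(poa = mask_B),
                     mask_C = C != 0)
  ground_truth(model, ...)
}

# Jitter the free parameters of the ground-truth model for one subject,
# resampling (<= 10 tries) until the jittered model is stable.
jitter_model <- function(gt, Umod) {
  pri <- prior_spec(gt$model)
  th <- model_to_theta(gt$model, pri)
  for (try in seq_len(10L)) {
    th_j <- th + rnorm(length(th), sd = gt$subject_sd)
    mats <- theta_to_model(th_j, pri, gt$model)
    cand <- gt$model
    cand$A <- mats$A; cand$B <- mats$B; cand$C <- mats$C
    if (model_is_stable(cand, Umod)) return(cand)
  }
  stop("could not draw a stable jittered model in 10 tries", call. = FALSE)
}

#' Simulate one subject's ROI BOLD time series
#'
#' Neural states are integrated from a subject-jittered copy of the
#' ground-truth model, observed through the HRF, and corrupted with additive
#' cosine drift plus AR(1)-filtered Gaussian noise scaled to the target SNR.
#' Deterministic given `seed`.
#'
#' @param gt A [ground_truth()].
#' @param design A [generate_design()] result.
#' @param seed Integer seed.
#' @param dt_s Micro-time integration step.
#' @return A [roi_ts()]; the noise-free signal is attached as attribute
#'   `"signal"` and the jittered model as `"subject_model"`.
#' @export
generate_subject <- function(gt, design, seed, dt_s = 0.125) {
  inputs <- build_input_functions(design, dt_s = dt_s)
  inp <- as_dcm_inputs(inputs, gt$model)
  with_seed(seed, {
    subj_model <- jitter_model(gt, inp$Umod)
    sig <- forward_predict(subj_model, inputs, hrf = gt$hrf)
    Y <- sig$data
    n_vol <- nrow(Y)
    t_s <- (seq_len(n_vol) - 1) * sig$tr_s
    for (k in seq_len(ncol(Y))) {
      sig_sd <- sd(Y[, k])
      sigma_n <- if (is.finite(gt$snr)) sig_sd / gt$snr else 0
      e <- rnorm(n_vol)
      if (gt$ar1 > 0)
        e <- as.numeric(stats::filter(e, gt$ar1, method = "recursive")) *
          sqrt(1 - gt$ar1^2)
      phase <- runif(1, 0, 2 * pi)
      drift <- gt$drift_amplitude * sigma_n *
        cos(2 * pi * t_s / gt$drift_period_s + phase)
      Y[, k] <- gt$baseline[k] + Y[, k] + sigma_n * e + drift
    }
    out <- roi_ts(Y, tr_s = sig$tr_s, run_lengths = sig$run_lengths)
    attr(out, "signal") <- sig$data
    attr(out, "subject_model") <- subj_model
    out
  })
}

#' Simulate a multi-subject dataset with known ground truth
#'
#' Each subject gets an independent design realization and noise stream
#' from a seed sequence derived from the master seed; regeneration from the
#' same `(master_seed, configuration)` is byte-identical.
#'
#' @param gt A [ground_truth()].
#' @param n_subjects Number of subjects (default 10).
#' @param master_seed Master seed.
#' @param n_runs Runs per subject (default 5).
#' @param design_overrides Overrides passed to [generate_design()].
#' @param dt_s Micro-time step.
#' @return Object of class `synthetic_dataset`: `subjects` (list of
#'   `list(design, ts)`), `ground_truth`, `master_seed`.
#' @export
generate_group <- function(gt, n_subjects = 10L, master_seed = 1L,
                           n_runs = 5L, design_overrides = list(),
                           dt_s = 0.125) {
  stopifnot(n_subjects >= 1)
  seeds <- seed_sequence(master_seed, 2L * n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    design <- generate_design(seeds[s], n_runs = n_runs,
                              overrides = design_overrides)
    ts <- generate_subject(gt, design, seed = seeds[n_subjects + s],
                           dt_s = dt_s)
    list(design = design, ts = ts)
  })
  structure(list(subjects = subjects, ground_truth = gt,
                 master_seed = master_seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  n <- length(x$subjects)
  d <- x$subjects[[1]]$ts
  cat("<synthetic_dataset> ", n, " subject(s) x ", nrow(d$data),
      " volumes x ", ncol(d$data), " nodes (master seed ", x$master_seed,
      ")\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic dataset directory
#'
#' Layout: `sub-XX/events.tsv`, `sub-XX/roi_timeseries.tsv` (+ JSON
#' sidecar) per subject, and `ground_truth.json` at the root. The round
#' trip through [read_dataset()] is lossless for designs and time series.
#'
#' @param ds A [generate_group()] result.
#' @param dir Output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` a
#'   `synthetic_dataset` (the ground-truth noise spec and model are restored
#'   from JSON).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(ds$subjects)) {
    sub_dir <- file.path(dir, sprintf("sub-%02d", s))
    dir.create(sub_dir, showWarnings = FALSE)
    write_events_tsv(ds$subjects[[s]]$design,
                     file.path(sub_dir, "events.tsv"))
    write_roi_tsv(ds$subjects[[s]]$ts,
                  file.path(sub_dir, "roi_timeseries.tsv"))
  }
  gt <- ds$ground_truth
  model_path <- file.path(dir, "ground_truth_model.json")
  write_dcm_json(gt$model, model_path)
  jsonlite::write_json(
    list(baseline = gt$baseline, snr = gt$snr, ar1 = gt$ar1,
         drift_amplitude = gt$drift_amplitude,
         drift_period_s = gt$drift_period_s, subject_sd = gt$subject_sd,
         hrf = unclass(gt$hrf), master_seed = ds$master_seed,
         n_subjects = length(ds$subjects)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
  model <- read_dcm_json(file.path(dir, "ground_truth_model.json"))
  gt <- ground_truth(model, baseline = meta$baseline, snr = meta$snr,
                     ar1 = meta$ar1, drift_amplitude = meta$drift_amplitude,
                     drift_period_s = meta$drift_period_s,
                     subject_sd = meta$subject_sd,
                     hrf = do.call(hrf_spec, as.list(meta$hrf)))
  subjects <- lapply(seq_len(meta$n_subjects), function(s) {
    sub_dir <- file.path(dir, sprintf("sub-%02d", s))
    trials <- read_events_tsv(file.path(sub_dir, "events.tsv"))
    ts <- read_roi_tsv(file.path(sub_dir, "roi_timeseries.tsv"))
    n_runs <- length(ts$run_lengths)
    design <- structure(
      list(trials = trials, run_length_volumes = ts$run_lengths[1],
           tr_s = ts$tr_s,
           params = modifyList(design_defaults(),
                               list(n_runs = n_runs,
                                    volumes_per_run = ts$run_lengths[1],
                                    tr_s = ts$tr_s))),
      class = "cv_design")
    list(design = design, ts = ts)
  })
  structure(list(subjects = subjects, ground_truth = gt,
                 master_seed = meta$master_seed),
            class = "synthetic_dataset")
}
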
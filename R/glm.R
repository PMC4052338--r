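#' Discrete-cosine high-pass basis
#'
#' DCT basis over the concatenated series whose columns span fluctuations
#' slower than `1/highpass_s` Hz; the constant term is included as the
#' first column (`hp_0`).
#'
#' @param n_vol Number of volumes.
#' @param tr_s Repetition time.
#' @param highpass_s High-pass cutoff in seconds (default 256).
#' @return Matrix `n_vol x (K + 1)` with columns `hp_0 .. hp_K`.
#' @export
dct_highpass_basis <- function(n_vol, tr_s, highpass_s = 256) {
  if (highpass_s <= 2 * tr_s)
    stop("highpass_s must exceed twice the TR", call. = FALSE)
  total_s <- n_vol * tr_s
  K <- max(1L, floor(2 * total_s / highpass_s))
  v <- seq_len(n_vol) - 0.5
  X <- vapply(0:K, function(k) cos(pi * k * v / n_vol), numeric(n_vol))
  colnames(X) <- paste0("hp_", 0:K)
  X
}

#' Build the parametric first-level design matrix
#'
#' Runs are concatenated and treated as one: an HRF-convolved onset
#' regressor over all non-target trials (the "phonetic input"), convolved
#' mean-centered PoA / VOT / interaction modulators, a separate target-trial
#' regressor, four run-baseline indicator columns (runs 2-5 with the default
#' five runs), and a discrete-cosine high-pass basis below `1/highpass_s`
#' Hz. Modulators are mean-centered before convolution.
#'
#' @param design A [generate_design()] result with at least one trial.
#' @param hrf An [hrf_spec()].
#' @param highpass_s High-pass cutoff in seconds (default 256).
#' @param dt_s Micro-time step for convolution.
#' @param coding Modulator coding (see [default_coding()]).
#' @return Object of class `design_matrix`: the numeric matrix `X` (volumes
#'   x regressors, named), `tr_s`, and the task-column names.
#' @export
build_design_matrix <- function(design, hrf = hrf_spec(), highpass_s = 256,
                                dt_s = 0.125, coding = default_coding()) {
  stopifnot(inherits(design, "cv_design"))
  if (nrow(design$trials) == 0L)
    stop("design contains no trials", call. = FALSE)
  inputs <- build_input_functions(design, dt_s = dt_s, coding = coding)
  tr <- design$tr_s
  n_vol <- inputs$n_runs * inputs$run_length_volumes
  kern <- hrf_kernel(hrf, dt_s)
  U <- cbind(phonetic = inputs$u_phonetic, poa = inputs$u_poa,
             vot = inputs$u_vot, inter = inputs$u_inter,
             target = inputs$u_target)
  task <- hrf_downsample(U, kern, dt_s, tr, n_vol)
  colnames(task) <- colnames(U)

  run_lengths <- rep(inputs$run_length_volumes, inputs$n_runs)
  Xb <- NULL
  if (inputs$n_runs > 1) {
    ends <- cumsum(run_lengths)
    starts <- c(1, ends[-length(ends)] + 1)
    Xb <- vapply(2:inputs$n_runs, function(r) {
      col <- numeric(n_vol)
      col[starts[r]:ends[r]] <- 1
      col
    }, numeric(n_vol))
    colnames(Xb) <- paste0("run", 2:inputs$n_runs)
  }
  hp <- dct_highpass_basis(n_vol, tr, highpass_s)
  X <- cbind(task, Xb, hp)
  structure(list(X = X, tr_s = tr, task_columns = colnames(task),
                 run_lengths = run_lengths),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " volumes x ", ncol(x$X),
      " regressors\n", sep = "")
  invisible(x)
}

#' Fit the GLM to ROI time series
#'
#' Ordinary least squares per ROI column. A rank-deficient design is an
#' error naming the collinear columns.
#'
#' @param ts A [roi_ts()] (or plain matrix) of BOLD data.
#' @param X A [build_design_matrix()] result (or plain matrix).
#' @return Object of class `glm_fit`: `betas` (regressor x ROI),
#'   `residuals`, `df_residual`.
#' @export
fit_glm <- function(ts, X) {
  Y <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  Xm <- if (inherits(X, "design_matrix")) X$X else as.matrix(X)
  if (nrow(Y) != nrow(Xm))
    stop("data and design matrix row counts differ", call. = FALSE)
  qx <- qr(Xm)
  if (qx$rank < ncol(Xm)) {
    bad <- colnames(Xm)[qx$pivot[(qx$rank + 1):ncol(Xm)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  betas <- qr.coef(qx, Y)
  fitted <- Xm %*% betas
  res <- Y - fitted
  rownames(betas) <- colnames(Xm)
  structure(list(betas = betas, residuals = res,
                 df_residual = nrow(Y) - ncol(Xm)),
            class = "glm_fit")
}

#' One-sample group test on per-subject contrast values
#'
#' Two-sided one-sample t test against zero with `n - 1` degrees of
#' freedom. Zero-variance input is flagged degenerate instead of producing
#' a spurious p value.
#'
#' @param values Numeric vector of per-subject contrast values (length >=
#'   2).
#' @return List with `estimate`, `t`, `df`, `p`, `degenerate`.
#' @export
group_contrast_test <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("at least 2 subjects are required", call. = FALSE)
  if (sd(values) == 0) {
    return(list(estimate = mean(values), t = NA_real_,
                df = length(values) - 1L, p = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(values, mu = 0)
  list(estimate = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
}

#' Group contrast table over ROIs
#'
#' Applies [group_contrast_test()] to each task contrast and ROI of a list
#' of first-level fits.
#'
#' @param fits List of per-subject [fit_glm()] results.
#' @param contrasts Regressor names to test (default the four parametric
#'   contrasts).
#' @param nodes ROI columns to test (default all).
#' @return Data frame with one row per contrast x ROI.
#' @export
group_contrast_table <- function(fits,
                                 contrasts = c("phonetic", "poa", "vot",
                                               "inter"),
                                 nodes = NULL) {
  nodes <- nodes %||% colnames(fits[[1]]$betas)
  rows <- list()
  for (cn in contrasts) {
    for (nd in nodes) {
      vals <- vapply(fits, function(f) f$betas[cn, nd], numeric(1))
      r <- group_contrast_test(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = cn, node = nd, estimate = r$estimate, t = r$t,
        df = r$df, p = r$p, degenerate = r$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
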
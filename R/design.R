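#' Default parameters of the blocked syllable design
#'
#' The defaults realize the study design this package emulates: five runs of
#' 220 volumes at TR = 2 s; per run, three 20-s ON blocks for each of the four
#' PoA x VOT cells (alveolar/bilabial x short/long), interleaved 1:1 with 16-s
#' OFF blocks; ten 700-ms consonant-vowel trials per block; one monaural
#' target trial per block (10\% of trials).
#'
#' @return Named list of design parameters.
#' @export
design_defaults <- function() {
  list(
    n_runs = 5L,
    volumes_per_run = 220L,
    tr_s = 2,
    blocks_per_cell = 3L,
    trials_per_block = 10L,
    block_s = 20,
    off_s = 16,
    trial_s = 0.7,
    n_voices = 8L,
    vowels = c("a", "o")
  )
}

validate_design_params <- function(p) {
  if (p$n_runs < 1L)
    stop("configuration error: n_runs must be >= 1", call. = FALSE)
  if (p$block_s < p$trials_per_block * p$trial_s)
    stop("configuration error: block_s (", p$block_s,
         " s) is shorter than trials_per_block * trial_s (",
         p$trials_per_block * p$trial_s, " s)", call. = FALSE)
  n_blocks <- 4L * p$blocks_per_cell
  run_s <- p$volumes_per_run * p$tr_s
  if (n_blocks * (p$block_s + p$off_s) > run_s)
    stop("configuration error: total ON+OFF time (",
         n_blocks * (p$block_s + p$off_s),
         " s) exceeds run length (", run_s, " s)", call. = FALSE)
  invisible(p)
}

consonant_for <- function(poa, vot) {
  key <- paste(poa, vot, sep = ".")
  c(alveolar.short = "d", alveolar.long = "t",
    bilabial.short = "b", bilabial.long = "p")[key]
}

#' Generate the blocked consonant-vowel syllable design
#'
#' Produces the trial table of the blocked design: each run holds three ON
#' blocks per PoA x VOT cell in seeded-random order, each block ten 700-ms
#' trials placed with random inter-trial silence so the block spans exactly
#' 20 s, and one randomly chosen target trial per block. Onsets are
#' run-relative seconds (0-based, half-open trial intervals).
#'
#' @param seed Integer seed; identical `(seed, parameters)` give
#'   byte-identical designs.
#' @param n_runs Number of runs (default 5).
#' @param overrides Named list overriding entries of [design_defaults()].
#' @return An object of class `cv_design`: a list with `trials` (data frame
#'   with columns `run`, `onset`, `duration`, `trial_type`, `poa`, `vot`,
#'   `voice`, `vowel`, `is_target`), `run_length_volumes`, `tr_s`, `params`.
#' @examples
#' d <- generate_design(seed = 7)
#' nrow(d$trials)          # 600 trials
#' sum(!d$trials$is_target) # 540 non-target trials
#' @export
generate_design <- function(seed, n_runs = 5L, overrides = list()) {
  p <- design_defaults()
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown))
    stop("configuration error: unknown design parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  p[names(overrides)] <- overrides
  if (!("n_runs" %in% names(overrides))) p$n_runs <- as.integer(n_runs)
  validate_design_params(p)

  cells <- expand.grid(poa = c("alveolar", "bilabial"),
                       vot = c("short", "long"),
                       stringsAsFactors = FALSE)
  ntb <- p$trials_per_block
  slack <- p$block_s - ntb * p$trial_s

  trials <- with_seed(seed, {
    out <- vector("list", p$n_runs)
    for (r in seq_len(p$n_runs)) {
      blocks <- cells[rep(seq_len(nrow(cells)), p$blocks_per_cell), ,
                      drop = FALSE]
      blocks <- blocks[sample.int(nrow(blocks)), , drop = FALSE]
      rows <- vector("list", nrow(blocks))
      for (b in seq_len(nrow(blocks))) {
        b_start <- (b - 1) * (p$block_s + p$off_s)
        # Gaps after each trial, uniform over the simplex summing to `slack`,
        # so the 10 trials plus their silences span exactly block_s seconds.
        gaps <- diff(c(0, sort(runif(ntb - 1)), 1)) * slack
        onsets <- b_start + (seq_len(ntb) - 1) * p$trial_s +
          cumsum(c(0, gaps[-ntb]))
        target <- sample.int(ntb, 1L)
        voice <- sample.int(p$n_voices, ntb, replace = TRUE)
        vowel <- sample(p$vowels, ntb, replace = TRUE)
        cons <- consonant_for(blocks$poa[b], blocks$vot[b])
        rows[[b]] <- data.frame(
          run = r,
          onset = onsets,
          duration = p$trial_s,
          trial_type = paste0(cons, vowel),
          poa = blocks$poa[b],
          vot = blocks$vot[b],
          voice = voice,
          vowel = vowel,
          is_target = seq_len(ntb) == target,
          stringsAsFactors = FALSE
        )
      }
      out[[r]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
  })
  rownames(trials) <- NULL

  structure(
    list(trials = trials, run_length_volumes = p$volumes_per_run,
         tr_s = p$tr_s, params = p),
    class = "cv_design"
  )
}

#' @export
print.cv_design <- function(x, ...) {
  cat("<cv_design> ", x$params$n_runs, " run(s), ",
      nrow(x$trials), " trials (", sum(x$trials$is_target), " targets), TR ",
      x$tr_s, " s, ", x$run_length_volumes, " volumes/run\n", sep = "")
  invisible(x)
}

#' Default parametric modulator coding
#'
#' Symmetric +/-1 coding: PoA +1 alveolar / -1 bilabial, VOT +1 long /
#' -1 short; the interaction is their product. With this coding the phonetic
#' regressor carries the cell mean and the modulators orthogonal increments.
#'
#' @return Named list with `poa` and `vot` level codes.
#' @export
default_coding <- function() {
  list(poa = c(alveolar = 1, bilabial = -1),
       vot = c(long = 1, short = -1))
}

#' Sample the design into micro-time input functions
#'
#' Converts the trial table into sampled signals on a micro-time grid shared
#' by the neural model and the GLM: a 0/1 boxcar over every non-target trial
#' ("phonetic input"), mean-centered PoA / VOT / interaction modulator
#' signals supported only where the phonetic input is nonzero, and a separate
#' target-trial nuisance boxcar. Runs are laid out consecutively.
#'
#' @param design A `cv_design`.
#' @param dt_s Micro-time step in seconds; must divide the TR.
#' @param coding Modulator coding, see [default_coding()].
#' @return An object of class `cv_inputs` with fields `dt_s`, `n_samples`,
#'   `u_phonetic`, `u_poa`, `u_vot`, `u_inter`, `u_target`, plus grid
#'   metadata (`tr_s`, `n_runs`, `run_length_volumes`).
#' @export
build_input_functions <- function(design, dt_s = 0.125,
                                  coding = default_coding()) {
  stopifnot(inherits(design, "cv_design"))
  tr <- design$tr_s
  stride <- tr / dt_s
  if (abs(stride - round(stride)) > 1e-9)
    stop("dt_s must divide tr_s (sampling must align with the volume grid)",
         call. = FALSE)
  n_runs <- design$params$n_runs
  run_s <- design$run_length_volumes * tr
  n_samples <- as.integer(round(n_runs * run_s / dt_s))

  u_phon <- numeric(n_samples)
  u_poa <- numeric(n_samples)
  u_vot <- numeric(n_samples)
  u_inter <- numeric(n_samples)
  u_target <- numeric(n_samples)

  tr_tab <- design$trials
  if (nrow(tr_tab)) {
    onset_global <- (tr_tab$run - 1) * run_s + tr_tab$onset
    if (any(onset_global + tr_tab$duration > n_runs * run_s + 1e-9))
      stop("trial onsets fall outside the sampled runs", call. = FALSE)
    n_on <- ceiling(tr_tab$duration / dt_s)
    idx0 <- floor(onset_global / dt_s)
    for (i in seq_len(nrow(tr_tab))) {
      idx <- idx0[i] + seq_len(n_on[i])
      idx <- idx[idx <= n_samples]
      if (tr_tab$is_target[i]) {
        u_target[idx] <- 1
      } else {
        cp <- unname(coding$poa[tr_tab$poa[i]])
        cv <- unname(coding$vot[tr_tab$vot[i]])
        u_phon[idx] <- 1
        u_poa[idx] <- cp
        u_vot[idx] <- cv
        u_inter[idx] <- cp * cv
      }
    }
    support <- u_phon != 0
    if (any(support)) {
      u_poa[support] <- u_poa[support] - mean(u_poa[support])
      u_vot[support] <- u_vot[support] - mean(u_vot[support])
      u_inter[support] <- u_inter[support] - mean(u_inter[support])
    }
  }

  structure(
    list(dt_s = dt_s, n_samples = n_samples,
         u_phonetic = u_phon, u_poa = u_poa, u_vot = u_vot,
         u_inter = u_inter, u_target = u_target,
         tr_s = tr, n_runs = n_runs,
         run_length_volumes = design$run_length_volumes,
         coding = coding),
    class = "cv_inputs"
  )
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated, UTF-8, LF line endings, '.' decimal separator, columns
#' `onset`, `duration`, `trial_type`, `poa`, `vot`, `voice`, `vowel`,
#' `is_target`, `run`. Numeric columns are written with 17 significant
#' digits so a write/read round trip is lossless.
#'
#' @param design A `cv_design`.
#' @param path Output TSV path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the trials data frame.
#' @export
write_events_tsv <- function(design, path) {
  tr <- design$trials
  out <- data.frame(
    onset = formatC(tr$onset, digits = 17, format = "g"),
    duration = formatC(tr$duration, digits = 17, format = "g"),
    trial_type = tr$trial_type,
    poa = tr$poa, vot = tr$vot,
    voice = tr$voice, vowel = tr$vowel,
    is_target = as.integer(tr$is_target),
    run = tr$run,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$is_target <- as.logical(d$is_target)
  d
}
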
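#' Node labels of the default auditory network
#'
#' Five regions: left/right medial and lateral auditory cortex and the left
#' planum temporale. Labels encode hemisphere and role, which the
#' connectivity rule parses.
#'
#' @return Character vector of length 5.
#' @export
auditory_nodes <- function() {
  c("L-medial-AC", "L-lateral-AC", "L-PT", "R-medial-AC", "R-lateral-AC")
}

#' MNI peak coordinates of the five regions (metadata only)
#'
#' @return 5 x 3 matrix of MNI coordinates, rows in [auditory_nodes()]
#'   order.
#' @export
auditory_node_coords <- function() {
  m <- rbind(`L-lateral-AC` = c(-65, -12, 3),
             `L-medial-AC` = c(-48, -15, 6),
             `L-PT` = c(-60, -34, 15),
             `R-medial-AC` = c(50, -13, 1),
             `R-lateral-AC` = c(63, -22, 7))
  colnames(m) <- c("x", "y", "z")
  m[auditory_nodes(), ]
}

#' Construct a bilinear dynamic causal model
#'
#' The neural model is `dz/dt = (A + sum_j u_j B_j) z + C u`: `A` is the
#' fixed coupling (Hz; column = source node, row = target node), each `B`
#' matrix the modulator-dependent change in coupling, and `C` the driving
#' input weights. Structural masks declare which entries are free; entries
#' outside a mask must be exactly zero. Self-connections (the diagonal of
#' `A`) must be strictly negative, and `B` carries no diagonal entries.
#'
#' @param nodes Node labels.
#' @param A n x n coupling matrix with strictly negative diagonal.
#' @param B Named list of n x n modulatory matrices (may be empty).
#' @param C n x m input weight matrix; column names identify the inputs.
#' @param mask_A,mask_B,mask_C Logical permission masks; defaults are
#'   derived from the nonzero patterns (`mask_A` covers off-diagonal
#'   entries only; the diagonal is always free).
#' @return Object of class `dcm_model`.
#' @export
dcm_model <- function(nodes, A, B = list(), C,
                      mask_A = NULL, mask_B = NULL, mask_C = NULL) {
  n <- length(nodes)
  A <- as.matrix(A); C <- as.matrix(C)
  stopifnot(nrow(A) == n, ncol(A) == n, nrow(C) == n)
  if (any(diag(A) >= 0))
    stop("diagonal of A (self-decay) must be strictly negative",
         call. = FALSE)
  if (is.null(mask_A)) {
    mask_A <- A != 0
    diag(mask_A) <- FALSE
  }
  if (is.null(mask_C)) mask_C <- C != 0
  if (is.null(mask_B)) mask_B <- lapply(B, function(b) b != 0)
  if (length(B)) {
    if (is.null(names(B)) || any(!nzchar(names(B))))
      stop("B matrices must be named after their modulators", call. = FALSE)
    for (nm in names(B)) {
      b <- as.matrix(B[[nm]])
      stopifnot(nrow(b) == n, ncol(b) == n)
      if (any(diag(mask_B[[nm]])) || any(diag(b) != 0))
        stop("B carries no diagonal entries", call. = FALSE)
      if (any(b[!mask_B[[nm]]] != 0))
        stop("entries outside the structural mask of B[['", nm,
             "']] must be zero", call. = FALSE)
    }
  }
  off <- A; diag(off) <- 0
  if (any(off[!mask_A] != 0))
    stop("off-diagonal entries of A outside the structural mask must be zero",
         call. = FALSE)
  if (any(C[!mask_C] != 0))
    stop("entries of C outside the structural mask must be zero",
         call. = FALSE)
  dimnames(A) <- list(nodes, nodes)
  dimnames(mask_A) <- list(nodes, nodes)
  rownames(C) <- nodes
  if (is.null(colnames(C))) colnames(C) <- paste0("u", seq_len(ncol(C)))
  structure(
    list(nodes = nodes, A = A, B = lapply(B, as.matrix), C = C,
         mask_A = mask_A, mask_B = mask_B, mask_C = mask_C),
    class = "dcm_model"
  )
}

#' @export
print.dcm_model <- function(x, ...) {
  cat("<dcm_model> ", length(x$nodes), " nodes, ",
      sum(x$mask_A), " free inter-regional connections, ",
      length(x$B), " modulator(s), ", sum(x$mask_C), " input weight(s)\n",
      sep = "")
  invisible(x)
}

# Normalize inputs to matrices aligned with the model's inputs/modulators.
# Accepts a cv_inputs (phonetic drives C's "phonetic" column, u_poa/u_vot
# feed same-named modulators) or a raw list(dt_s, U, Umod).
as_dcm_inputs <- function(inputs, model) {
  if (inherits(inputs, "cv_inputs")) {
    m <- ncol(model$C)
    U <- matrix(0, inputs$n_samples, m,
                dimnames = list(NULL, colnames(model$C)))
    for (nm in colnames(model$C)) {
      U[, nm] <- switch(nm,
        phonetic = inputs$u_phonetic,
        target = inputs$u_target,
        stop("model input '", nm, "' has no matching signal", call. = FALSE))
    }
    k <- length(model$B)
    Umod <- matrix(0, inputs$n_samples, k,
                   dimnames = list(NULL, names(model$B)))
    for (nm in names(model$B)) {
      Umod[, nm] <- switch(nm,
        poa = inputs$u_poa,
        vot = inputs$u_vot,
        inter = inputs$u_inter,
        stop("modulator '", nm, "' has no matching signal", call. = FALSE))
    }
    list(dt_s = inputs$dt_s, U = U, Umod = Umod)
  } else {
    stopifnot(is.list(inputs), !is.null(inputs$dt_s), !is.null(inputs$U))
    U <- as.matrix(inputs$U)
    Umod <- inputs$Umod
    if (is.null(Umod)) Umod <- matrix(0, nrow(U), 0)
    list(dt_s = inputs$dt_s, U = U, Umod = as.matrix(Umod))
  }
}

# TRUE if A + sum_j u_j B_j has only negative real-part eigenvalues at every
# combination of modulator extremes.
model_is_stable <- function(model, Umod = NULL) {
  k <- length(model$B)
  if (k == 0L || is.null(Umod) || ncol(Umod) == 0L) {
    return(max(Re(eigen(model$A, only.values = TRUE)$values)) < 0)
  }
  lo <- apply(Umod, 2, min); hi <- apply(Umod, 2, max)
  grid <- expand.grid(rep(list(c(1, 2)), k))
  for (g in seq_len(nrow(grid))) {
    M <- model$A
    for (j in seq_len(k)) {
      w <- if (grid[g, j] == 1) lo[j] else hi[j]
      M <- M + w * model$B[[j]]
    }
    if (max(Re(eigen(M, only.values = TRUE)$values)) >= 0) return(FALSE)
  }
  TRUE
}

#' Integrate the bilinear neural state equation
#'
#' Fixed-step 4th-order Runge-Kutta integration of
#' `dz/dt = (A + sum_j u_j B_j) z + C u` with inputs held constant over each
#' micro-time step. If the coupling matrix has an eigenvalue with positive
#' real part at any modulator extreme the result is flagged unstable and a
#' warning is raised.
#'
#' @param model A [dcm_model()].
#' @param inputs A `cv_inputs` or a list with `dt_s`, `U` (samples x inputs)
#'   and optionally `Umod` (samples x modulators).
#' @param z0 Initial state (default zero).
#' @return Object of class `neural_state`: `z` (samples x nodes), `dt_s`,
#'   `unstable` flag.
#' @export
integrate_states <- function(model, inputs, z0 = NULL) {
  inp <- as_dcm_inputs(inputs, model)
  n <- length(model$nodes)
  if (is.null(z0)) z0 <- numeric(n)
  stopifnot(length(z0) == n, ncol(inp$U) == ncol(model$C))
  unstable <- !model_is_stable(model, inp$Umod)
  if (unstable)
    warning("model is unstable at the observed input extremes",
            call. = FALSE)
  Z <- rk4_bilinear(model$A, unname(model$B), model$C, inp$U, inp$Umod,
                    inp$dt_s, as.numeric(z0))
  colnames(Z) <- model$nodes
  structure(list(z = Z, dt_s = inp$dt_s, unstable = unstable),
            class = "neural_state")
}

#' Predict ROI BOLD series from a model and inputs
#'
#' Integrates the neural states, convolves each node trajectory with the
#' double-gamma HRF kernel sampled at the micro-time step, and samples the
#' result on the volume grid. Linear in the neural trajectory.
#'
#' @inheritParams integrate_states
#' @param hrf An [hrf_spec()].
#' @param tr_s Repetition time of the volume grid; taken from `inputs` when
#'   it is a `cv_inputs`.
#' @param run_lengths Volumes per run for the output container; taken from
#'   `inputs` when available.
#' @return A [roi_ts()] with one column per node; carries an `unstable`
#'   attribute when the neural model was flagged.
#' @export
forward_predict <- function(model, inputs, hrf = hrf_spec(), tr_s = NULL,
                            run_lengths = NULL) {
  inp <- as_dcm_inputs(inputs, model)
  if (inherits(inputs, "cv_inputs")) {
    tr_s <- tr_s %||% inputs$tr_s
    run_lengths <- run_lengths %||%
      rep(inputs$run_length_volumes, inputs$n_runs)
  }
  if (is.null(tr_s)) stop("tr_s is required", call. = FALSE)
  stride <- tr_s / inp$dt_s
  if (abs(stride - round(stride)) > 1e-9)
    stop("dt_s must divide tr_s", call. = FALSE)
  n_vol <- as.integer(floor(nrow(inp$U) / round(stride)))
  if (is.null(run_lengths)) run_lengths <- n_vol
  unstable <- !model_is_stable(model, inp$Umod)
  if (unstable)
    warning("model is unstable at the observed input extremes",
            call. = FALSE)
  kern <- hrf_kernel(hrf, inp$dt_s)
  Y <- dcm_forward_cpp(model$A, unname(model$B), model$C, inp$U, inp$Umod,
                       inp$dt_s, kern, tr_s, n_vol,
                       numeric(length(model$nodes)))
  colnames(Y) <- model$nodes
  out <- roi_ts(Y, tr_s = tr_s, run_lengths = run_lengths)
  attr(out, "unstable") <- unstable
  out
}

#' ROI time-series container
#'
#' @param data Numeric matrix, volumes x nodes; column names label nodes.
#' @param tr_s Repetition time in seconds.
#' @param run_lengths Integer vector of volumes per run; must sum to
#'   `nrow(data)`.
#' @return Object of class `roi_ts`.
#' @export
roi_ts <- function(data, tr_s, run_lengths = nrow(data)) {
  data <- as.matrix(data)
  if (sum(run_lengths) != nrow(data))
    stop("run_lengths must sum to the number of volumes", call. = FALSE)
  structure(list(data = data, tr_s = tr_s,
                 run_lengths = as.integer(run_lengths),
                 nodes = colnames(data)),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("<roi_ts> ", nrow(x$data), " volumes x ", ncol(x$data), " nodes, TR ",
      x$tr_s, " s, ", length(x$run_lengths), " run(s)\n", sep = "")
  invisible(x)
}

#' Write / read an ROI time-series TSV with JSON sidecar
#'
#' The TSV holds a `time` column (seconds) and one column per node; the
#' sidecar JSON records TR, run lengths, and node labels. Values are written
#' with 17 significant digits so the round trip is lossless.
#'
#' @param ts A [roi_ts()].
#' @param path TSV path; the sidecar defaults to the same path with a
#'   `.json` extension.
#' @param sidecar Sidecar JSON path.
#' @return `write_roi_tsv` returns `path` invisibly; `read_roi_tsv` a
#'   [roi_ts()].
#' @export
write_roi_tsv <- function(ts, path,
                          sidecar = sub("\\.tsv$", ".json", path)) {
  time <- (seq_len(nrow(ts$data)) - 1) * ts$tr_s
  out <- cbind(time = time, ts$data)
  txt <- apply(out, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  con <- file(path, open = "wb")
  writeLines(c(paste(c("time", colnames(ts$data)), collapse = "\t"), txt),
             con, sep = "\n")
  close(con)
  jsonlite::write_json(
    list(tr_s = ts$tr_s, run_lengths = ts$run_lengths, nodes = ts$nodes),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @export
read_roi_tsv <- function(path, sidecar = sub("\\.tsv$", ".json", path)) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- read.delim(path, check.names = FALSE)
  roi_ts(as.matrix(d[, meta$nodes, drop = FALSE]), tr_s = meta$tr_s,
         run_lengths = meta$run_lengths)
}

#' Serialize / deserialize a model as JSON
#'
#' Dense matrices are stored row-major along with their masks and node
#' labels.
#'
#' @param model A [dcm_model()].
#' @param path JSON path.
#' @return `write_dcm_json` returns `path` invisibly; `read_dcm_json` a
#'   [dcm_model()].
#' @export
write_dcm_json <- function(model, path) {
  obj <- list(
    nodes = model$nodes,
    A = as.vector(t(model$A)),
    mask_A = as.vector(t(model$mask_A)),
    B = lapply(model$B, function(b) as.vector(t(b))),
    mask_B = lapply(model$mask_B, function(b) as.vector(t(b))),
    C = as.vector(t(model$C)),
    mask_C = as.vector(t(model$mask_C)),
    inputs = colnames(model$C),
    modulators = names(model$B)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dcm_json
#' @export
read_dcm_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(o$nodes)
  unflat <- function(v) matrix(v, n, byrow = TRUE)
  B <- lapply(o$B, unflat)
  mB <- lapply(o$mask_B, function(v) unflat(as.logical(v)))
  C <- matrix(o$C, n, byrow = TRUE)
  colnames(C) <- o$inputs
  dcm_model(o$nodes, unflat(o$A), B = B, C = C,
            mask_A = unflat(as.logical(o$mask_A)), mask_B = mB,
            mask_C = unflat(as.logical(o$mask_C)))
}
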
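parse_node_roles <- function(nodes) {
  hemi <- ifelse(grepl("^L-", nodes), "L",
                 ifelse(grepl("^R-", nodes), "R", NA))
  role <- ifelse(grepl("medial", nodes), "medial",
                 ifelse(grepl("lateral", nodes), "lateral",
                        ifelse(grepl("PT", nodes), "PT", NA)))
  if (any(is.na(hemi)) || any(is.na(role)))
    stop("unknown node role in: ",
         paste(nodes[is.na(hemi) | is.na(role)], collapse = ", "),
         call. = FALSE)
  data.frame(node = nodes, hemi = hemi, role = role,
             stringsAsFactors = FALSE)
}

#' Build the constrained auditory connectivity mask
#'
#' Implements the neighbor + planum temporale + homolog rule: each auditory
#' cortex node is reciprocally connected to its within-hemisphere neighbor
#' (medial <-> lateral), to its homolog in the other hemisphere (medial <->
#' medial, lateral <-> lateral), and to the planum temporale — but not to
#' the non-homolog area of the other hemisphere. On the default five-node
#' network this yields exactly 16 permitted directed inter-regional
#' connections.
#'
#' @param nodes Node labels encoding hemisphere and role (see
#'   [auditory_nodes()]).
#' @return Logical n x n matrix (row = target, column = source), symmetric
#'   as a relation, with an all-`FALSE` diagonal.
#' @export
build_connectivity_mask <- function(nodes = auditory_nodes()) {
  info <- parse_node_roles(nodes)
  n <- length(nodes)
  mask <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ri <- info[i, ]; rj <- info[j, ]
      ac_i <- ri$role %in% c("medial", "lateral")
      ac_j <- rj$role %in% c("medial", "lateral")
      permitted <-
        (ac_i && ac_j && ri$hemi == rj$hemi) ||               # neighbor
        (ac_i && ac_j && ri$role == rj$role) ||               # homolog
        (xor(ri$role == "PT", rj$role == "PT"))               # AC <-> PT
      mask[i, j] <- permitted
    }
  }
  mask
}

#' Enumerate the single-connection modulation model space
#'
#' One member model per permitted connection in the mask: all members share
#' the same fixed-coupling mask and driving-input nodes, and differ only in
#' which single connection the modulator is allowed to change. With the
#' default auditory mask this produces the 16-model space. Members are
#' ordered column-major over the mask (by source node, then target node).
#'
#' @param mask Logical connectivity mask from [build_connectivity_mask()].
#' @param inputs_to Nodes receiving the driving input; defaults to the four
#'   auditory-cortex nodes (all but the planum temporale).
#' @param modulator Modulator name (default `"poa"`); swap to `"vot"` for
#'   the exploratory voice-onset-time space.
#' @param input_name Driving input name (default `"phonetic"`).
#' @return Object of class `model_space`: `mask_A`, `input_nodes`,
#'   `modulator`, `nodes`, and `members`, a list of [dcm_model()] skeletons.
#' @export
enumerate_poa_models <- function(mask, inputs_to = NULL,
                                 modulator = "poa",
                                 input_name = "phonetic") {
  nodes <- rownames(mask)
  if (is.null(nodes)) stop("mask must carry node labels", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (is.null(inputs_to)) {
    info <- parse_node_roles(nodes)
    inputs_to <- nodes[info$role != "PT"]
  }
  if (!all(inputs_to %in% nodes))
    stop("input nodes must be a subset of the mask's nodes", call. = FALSE)
  n <- length(nodes)
  A <- matrix(0, n, n)
  diag(A) <- -0.5
  C <- matrix(0, n, 1, dimnames = list(nodes, input_name))
  mask_C <- matrix(FALSE, n, 1)
  mask_C[match(inputs_to, nodes), 1] <- TRUE

  idx <- which(mask)
  members <- lapply(idx, function(k) {
    mB <- matrix(FALSE, n, n, dimnames = dimnames(mask))
    mB[k] <- TRUE
    B <- list(matrix(0, n, n))
    names(B) <- modulator
    dcm_model(nodes, A, B = B, C = C,
              mask_A = mask, mask_B = stats::setNames(list(mB), modulator),
              mask_C = mask_C)
  })
  structure(
    list(mask_A = mask, input_nodes = inputs_to, modulator = modulator,
         nodes = nodes, members = members),
    class = "model_space"
  )
}

#' @export
print.model_space <- function(x, ...) {
  cat("<model_space> ", length(x$members), " member models, modulator '",
      x$modulator, "', inputs to ", paste(x$input_nodes, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Human-readable labels of a model space's modulated connections
#' @param space A [enumerate_poa_models()] result.
#' @return Character vector, one label per member.
#' @export
member_labels <- function(space) {
  vapply(space$members, function(m) {
    k <- which(m$mask_B[[space$modulator]], arr.ind = TRUE)
    paste0(space$nodes[k[1, 2]], "->", space$nodes[k[1, 1]])
  }, character(1))
}

check_log_evidence <- function(log_evidences) {
  L <- as.matrix(log_evidences)
  if (any(!is.finite(L)))
    stop("log-evidence matrix contains non-finite values", call. = FALSE)
  if (ncol(L) < 2) stop("at least 2 models are required", call. = FALSE)
  if (nrow(L) < 1) stop("at least 1 subject is required", call. = FALSE)
  L
}

#' Bayesian model selection over a group log-evidence matrix
#'
#' Fixed-effects: posterior model probabilities are the softmax of the
#' summed log-evidences under a uniform model prior. Random-effects: the
#' variational Dirichlet scheme over population model frequencies, reporting
#' expected frequencies (as `pP`) and exceedance probabilities. The winner
#' is the argmax of `pP`; ties break to the lowest model index.
#'
#' @param log_evidences Subjects x models matrix of log evidences (nats).
#' @param mode `"rfx"` (default) or `"ffx"`.
#' @param alpha0 Dirichlet prior count per model (random effects).
#' @param xp_draws Monte-Carlo draws for exceedance probabilities.
#' @param xp_seed Seed for the exceedance draws (results are deterministic).
#' @return Object of class `bms_result`: `pP` (sums to 1), `winner`, `mode`,
#'   and mode-specific fields (`summed_log_evidence` for ffx; `alpha`,
#'   `expected_freq`, `xp` for rfx).
#' @export
bms <- function(log_evidences, mode = c("rfx", "ffx"), alpha0 = 1,
                xp_draws = 20000L, xp_seed = 1L) {
  mode <- match.arg(mode)
  L <- check_log_evidence(log_evidences)
  M <- ncol(L)
  if (mode == "ffx") {
    s <- colSums(L)
    pP <- softmax(s)
    res <- list(mode = mode, pP = pP, winner = which.max(pP),
                summed_log_evidence = s)
  } else {
    alpha <- rep(alpha0, M)
    for (it in seq_len(500L)) {
      lg <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
      g <- t(apply(lg, 1, softmax))
      if (nrow(L) == 1L) g <- matrix(softmax(lg[1, ]), 1L, M)
      alpha_new <- alpha0 + colSums(g)
      if (max(abs(alpha_new - alpha)) < 1e-8) {
        alpha <- alpha_new
        break
      }
      alpha <- alpha_new
    }
    ef <- alpha / sum(alpha)
    xp <- with_seed(xp_seed, {
      draws <- matrix(stats::rgamma(xp_draws * M, shape = rep(alpha,
                                                              each = xp_draws)),
                      xp_draws, M)
      tabulate(max.col(draws), nbins = M) / xp_draws
    })
    res <- list(mode = mode, pP = ef, winner = which.max(ef),
                alpha = alpha, expected_freq = ef, xp = xp)
  }
  class(res) <- "bms_result"
  res
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> mode ", x$mode, ", winner model ", x$winner,
      " (pP = ", format(max(x$pP), digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Compare families of models
#'
#' Families must partition the model set. Fixed-effects: family probability
#' is the normalized evidence mass, i.e. the softmax over families of the
#' log-sum-exp of each family's summed log-evidences. Random-effects: the
#' expected model frequencies from [bms()] are summed by family.
#'
#' @param log_evidences Subjects x models matrix.
#' @param families Named list of model-index vectors partitioning
#'   `1:ncol(log_evidences)`.
#' @param mode `"ffx"` or `"rfx"`.
#' @param ... Passed to [bms()] in random-effects mode.
#' @return Named numeric vector of family probabilities (sums to 1).
#' @export
family_compare <- function(log_evidences, families, mode = c("ffx", "rfx"),
                           ...) {
  mode <- match.arg(mode)
  L <- check_log_evidence(log_evidences)
  M <- ncol(L)
  all_idx <- sort(unlist(families))
  if (!identical(as.integer(all_idx), seq_len(M)))
    stop("families must partition the model set 1..", M, call. = FALSE)
  if (is.null(names(families)))
    names(families) <- paste0("family", seq_along(families))
  if (mode == "ffx") {
    s <- colSums(L)
    lmass <- vapply(families, function(ix) logsumexp(s[ix]), numeric(1))
    softmax(lmass)
  } else {
    r <- bms(L, mode = "rfx", ...)
    vapply(families, function(ix) sum(r$expected_freq[ix]), numeric(1))
  }
}

#' Bayesian model averaging of connection strengths
#'
#' Averages posterior parameter estimates over the model space, weighted by
#' the model posterior probabilities, then averages across subjects. A
#' connection absent from every model contributes exactly zero. With
#' `n_samples = 1` (default) the average is the deterministic weighted mean
#' of posterior means; with `n_samples > 1` models and parameters are
#' sampled (model index from the weights, parameters from each model's
#' Gaussian posterior).
#'
#' @param fits Per-subject list of per-model [invert_model()] results (a
#'   single subject's list of results is also accepted).
#' @param weights A [bms()] result or numeric weight vector over models.
#' @param n_samples Posterior samples per subject (1 = means only).
#' @param seed Seed for sampling mode.
#' @return Object of class `bma_result` with averaged `A`, `B` (list per
#'   modulator), `C`, the `weights` used, and `n_samples`.
#' @export
bma <- function(fits, weights, n_samples = 1L, seed = 1L) {
  if (inherits(fits[[1]], "inversion_result")) fits <- list(fits)
  w <- if (inherits(weights, "bms_result")) weights$pP else as.numeric(weights)
  n_models <- length(fits[[1]])
  if (length(w) != n_models)
    stop("weights are misaligned with the model list (", length(w), " vs ",
         n_models, ")", call. = FALSE)
  for (s in seq_along(fits))
    if (length(fits[[s]]) != n_models)
      stop("model lists are misaligned across subjects", call. = FALSE)
  w <- w / sum(w)

  proto <- fits[[1]][[1]]
  zero_like <- function() {
    list(A = proto$A * 0,
         B = lapply(proto$B, function(b) b * 0),
         C = proto$C * 0)
  }
  add_scaled <- function(acc, mats, wt) {
    acc$A <- acc$A + wt * mats$A
    for (nm in names(acc$B)) acc$B[[nm]] <- acc$B[[nm]] + wt * mats$B[[nm]]
    acc$C <- acc$C + wt * mats$C
    acc
  }

  subj_means <- lapply(seq_along(fits), function(s) {
    acc <- zero_like()
    if (n_samples <= 1L) {
      for (m in seq_len(n_models)) {
        f <- fits[[s]][[m]]
        acc <- add_scaled(acc, list(A = f$A, B = f$B, C = f$C), w[m])
      }
      acc
    } else {
      with_seed(seed + s, {
        picks <- sample.int(n_models, n_samples, replace = TRUE, prob = w)
        for (m in picks) {
          f <- fits[[s]][[m]]
          ch <- chol(f$posterior_cov +
                       diag(1e-10, nrow(f$posterior_cov)))
          th <- f$posterior_mean +
            drop(t(ch) %*% rnorm(length(f$posterior_mean)))
          pri <- list(map = f$map)
          mats <- theta_to_model(th, pri,
                                 list(nodes = f$nodes, A = f$A, B = f$B,
                                      C = f$C))
          acc <- add_scaled(acc, mats, 1 / n_samples)
        }
        acc
      })
    }
  })

  out <- zero_like()
  for (sm in subj_means) out <- add_scaled(out, sm, 1 / length(subj_means))
  structure(list(A = out$A, B = out$B, C = out$C, weights = w,
                 n_samples = n_samples),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat("<bma_result> averaged over ", length(x$weights), " models (",
      x$n_samples, " sample(s)/subject)\n", sep = "")
  invisible(x)
}
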
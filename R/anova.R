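#' Reconstruct condition responses from parametric betas
#'
#' Inverts the modulator parameterization: with symmetric +/-1 coding the
#' expected response of cell (PoA = p, VOT = v) at a node is
#' `phonetic + p * poa + v * vot + p * v * inter`. Cells are arranged as
#' Hemisphere x ROI x PoA x VOT over the four auditory-cortex nodes
#' (medial / lateral per hemisphere).
#'
#' @param betas Regressor x node matrix from a [fit_glm()] (must contain the
#'   `phonetic`, `poa`, `vot`, `inter` rows and the four AC node columns).
#' @param coding Modulator coding used in the design matrix.
#' @return Numeric array `2 x 2 x 2 x 2` with dimnames
#'   `hemisphere (L, R) x roi (medial, lateral) x poa x vot`.
#' @export
extract_condition_responses <- function(betas, coding = default_coding()) {
  need <- c("phonetic", "poa", "vot", "inter")
  if (!all(need %in% rownames(betas)))
    stop("missing regressor(s): ",
         paste(setdiff(need, rownames(betas)), collapse = ", "),
         call. = FALSE)
  hemis <- c("L", "R")
  rois <- c("medial", "lateral")
  poas <- c("alveolar", "bilabial")
  vots <- c("short", "long")
  out <- array(NA_real_, c(2, 2, 2, 2),
               dimnames = list(hemisphere = hemis, roi = rois,
                               poa = poas, vot = vots))
  for (h in hemis) for (r in rois) {
    node <- paste0(h, "-", r, "-AC")
    if (!(node %in% colnames(betas)))
      stop("betas lack node column '", node, "'", call. = FALSE)
    for (pp in poas) for (vv in vots) {
      cp <- unname(coding$poa[pp])
      cv <- unname(coding$vot[vv])
      out[h, r, pp, vv] <- betas["phonetic", node] +
        cp * betas["poa", node] + cv * betas["vot", node] +
        cp * cv * betas["inter", node]
    }
  }
  out
}

#' Stack per-subject condition responses
#'
#' @param fits List of per-subject [fit_glm()] results.
#' @param coding Modulator coding.
#' @return Array `subjects x 2 x 2 x 2 x 2` suitable for [rm_anova()].
#' @export
condition_responses_group <- function(fits, coding = default_coding()) {
  cells <- lapply(fits, function(f)
    extract_condition_responses(f$betas, coding))
  out <- array(NA_real_, c(length(fits), dim(cells[[1]])),
               dimnames = c(list(subject = NULL), dimnames(cells[[1]])))
  for (s in seq_along(cells)) out[s, , , , ] <- cells[[s]]
  out
}

# Orthonormal effect contrasts: rows of t(contr.poly(l)) are orthonormal.
orthonorm_contrasts <- function(l) t(contr.poly(l))

#' Repeated-measures factorial ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject factorial ANOVA computed effect-by-effect from
#' orthonormal contrast scores: for each effect, the univariate F is the
#' ratio of the contrast-mean sum of squares to its subject-by-contrast
#' error, and the Greenhouse-Geisser epsilon is estimated from the
#' covariance of the contrast scores (exactly 1 for single-df effects,
#' i.e. for 2-level factors). Degenerate all-equal data yield F = 0.
#'
#' @param cells Numeric array, subjects first, one further dimension per
#'   within-subject factor, with named dimnames (e.g. from
#'   [condition_responses_group()]).
#' @return Data frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `epsilon`, `p` (Greenhouse-Geisser corrected) and `p_uncorrected`.
#' @export
rm_anova <- function(cells) {
  dm <- dim(cells)
  if (length(dm) < 2) stop("cells must have factor dimensions", call. = FALSE)
  if (any(!is.finite(cells)))
    stop("cells are incomplete (non-finite entries)", call. = FALSE)
  n <- dm[1]
  if (n < 2) stop("at least 2 subjects are required", call. = FALSE)
  levels <- dm[-1]
  k <- length(levels)
  fac_names <- names(dimnames(cells))[-1]
  if (is.null(fac_names) || any(!nzchar(fac_names)))
    fac_names <- paste0("F", seq_len(k))
  Y <- matrix(cells, nrow = n)   # columns vary the first factor fastest

  mean_vec <- function(l) matrix(rep(1, l) / sqrt(l), nrow = 1)
  effects <- unlist(lapply(seq_len(k), function(m)
    utils::combn(seq_len(k), m, simplify = FALSE)), recursive = FALSE)

  rows <- lapply(effects, function(ix) {
    mats <- lapply(seq_len(k), function(f)
      if (f %in% ix) orthonorm_contrasts(levels[f]) else mean_vec(levels[f]))
    M <- Reduce(kronecker, rev(mats))
    D <- Y %*% t(M)
    q <- ncol(D)
    dbar <- colMeans(D)
    ss_eff <- n * sum(dbar^2)
    ss_err <- sum(sweep(D, 2, dbar)^2)
    # sums of squares at rounding-noise level count as exact zeros
    tol <- 1e-18 * max(1, sum(Y^2))
    if (ss_eff < tol && ss_err < tol) {
      Fv <- 0; eps <- 1; p <- 1; pu <- 1
    } else if (ss_err < tol) {
      Fv <- Inf; eps <- 1; p <- 0; pu <- 0
    } else {
      ms_eff <- ss_eff / q
      ms_err <- ss_err / ((n - 1) * q)
      Fv <- ms_eff / ms_err
      if (q == 1) {
        eps <- 1
      } else {
        S <- cov(D)
        eps <- sum(diag(S))^2 / (q * sum(S^2))
        eps <- min(max(eps, 1 / q), 1)
      }
      pu <- pf(Fv, q, (n - 1) * q, lower.tail = FALSE)
      p <- pf(Fv, eps * q, eps * (n - 1) * q, lower.tail = FALSE)
    }
    data.frame(effect = paste(fac_names[ix], collapse = ":"),
               df1 = q, df2 = (n - 1) * q, F = Fv, epsilon = eps,
               p = p, p_uncorrected = pu, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher LSD post hoc comparisons
#'
#' Uncorrected pairwise paired t tests between the marginal means of the
#' requested factor combination (collapsing the remaining factors by
#' averaging), following the Fisher least-significant-difference
#' convention after a significant omnibus effect.
#'
#' @param cells Array as for [rm_anova()].
#' @param factors Character vector of factor names to compare over.
#' @return Data frame of pairwise comparisons: levels, mean difference, t,
#'   df, uncorrected p.
#' @export
lsd_posthoc <- function(cells, factors) {
  fac_names <- names(dimnames(cells))[-1]
  if (!all(factors %in% fac_names))
    stop("unknown factor(s): ",
         paste(setdiff(factors, fac_names), collapse = ", "), call. = FALSE)
  keep <- c(1L, 1L + match(factors, fac_names))
  marg <- apply(cells, keep, mean)
  n <- dim(marg)[1]
  marg <- matrix(marg, nrow = n)
  lev <- do.call(expand.grid, dimnames(cells)[factors])
  labels <- apply(lev, 1, paste, collapse = ".")
  pairs <- utils::combn(length(labels), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    d <- marg[, a] - marg[, b]
    if (sd(d) == 0) {
      tv <- NA_real_; pv <- NA_real_
    } else {
      tt <- t.test(d, mu = 0)
      tv <- unname(tt$statistic); pv <- tt$p.value
    }
    data.frame(level_a = labels[a], level_b = labels[b],
               diff = mean(d), t = tv, df = n - 1L, p = pv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
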
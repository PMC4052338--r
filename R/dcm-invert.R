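#' Gaussian priors over the free model parameters
#'
#' One row per free (unmasked) parameter. Off-diagonal coupling and
#' modulatory parameters get N(0, 0.25) priors, input weights N(0, 1), and
#' self-connections are parameterized as `-0.5 * exp(theta)` Hz with
#' `theta ~ N(0, 0.0625)` so stability of the decay is structural.
#' Structurally masked entries are simply absent (equivalently, prior
#' variance 0, fixed at zero).
#'
#' @param model A [dcm_model()] supplying the structural masks.
#' @param a_var,b_var,c_var,self_var Prior variances.
#' @param noise_floor Floor on the per-node ML noise variance used inside
#'   the likelihood (guards the profiled estimate on noiseless data).
#' @return Object of class `prior_spec`: a data frame of parameter
#'   locations with prior means/variances, plus the noise floor.
#' @export
prior_spec <- function(model, a_var = 0.25, b_var = 0.25, c_var = 1,
                       self_var = 0.0625, noise_floor = 1e-8) {
  stopifnot(a_var > 0, b_var > 0, c_var > 0, self_var > 0)
  n <- length(model$nodes)
  rows <- list()
  idx <- which(model$mask_A)          # column-major, fixed ordering
  if (length(idx)) {
    ij <- arrayInd(idx, c(n, n))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "A", slot = "", i = ij[, 1], j = ij[, 2],
      mean = 0, var = a_var, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    kind = "self", slot = "", i = seq_len(n), j = seq_len(n),
    mean = 0, var = self_var, stringsAsFactors = FALSE)
  for (nm in names(model$B)) {
    idx <- which(model$mask_B[[nm]])
    if (length(idx)) {
      ij <- arrayInd(idx, c(n, n))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "B", slot = nm, i = ij[, 1], j = ij[, 2],
        mean = 0, var = b_var, stringsAsFactors = FALSE)
    }
  }
  idx <- which(model$mask_C)
  if (length(idx)) {
    ij <- arrayInd(idx, dim(model$C))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "C", slot = "", i = ij[, 1], j = ij[, 2],
      mean = 0, var = c_var, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  map$name <- param_names(map, model)
  structure(list(map = map, noise_floor = noise_floor), class = "prior_spec")
}

param_names <- function(map, model) {
  nodes <- model$nodes
  inputs <- colnames(model$C)
  ifelse(map$kind == "A",
         paste0("A:", nodes[map$j], "->", nodes[map$i]),
  ifelse(map$kind == "self",
         paste0("self:", nodes[map$i]),
  ifelse(map$kind == "B",
         paste0("B[", map$slot, "]:", nodes[map$j], "->", nodes[map$i]),
         paste0("C:", inputs[map$j], "->", nodes[map$i]))))
}

# Fill model matrices from a parameter vector (and back).
theta_to_model <- function(theta, priors, model) {
  map <- priors$map
  n <- length(model$nodes)
  A <- matrix(0, n, n, dimnames = dimnames(model$A))
  B <- lapply(model$B, function(b) matrix(0, n, n, dimnames = dimnames(model$A)))
  C <- matrix(0, nrow(model$C), ncol(model$C), dimnames = dimnames(model$C))
  for (r in seq_len(nrow(map))) {
    v <- theta[r]
    switch(map$kind[r],
           A = { A[map$i[r], map$j[r]] <- v },
           self = { A[map$i[r], map$i[r]] <- -0.5 * exp(v) },
           B = { B[[map$slot[r]]][map$i[r], map$j[r]] <- v },
           C = { C[map$i[r], map$j[r]] <- v })
  }
  list(A = A, B = B, C = C)
}

model_to_theta <- function(model, priors) {
  map <- priors$map
  th <- numeric(nrow(map))
  for (r in seq_len(nrow(map))) {
    th[r] <- switch(map$kind[r],
                    A = model$A[map$i[r], map$j[r]],
                    self = log(model$A[map$i[r], map$i[r]] / -0.5),
                    B = model$B[[map$slot[r]]][map$i[r], map$j[r]],
                    C = model$C[map$i[r], map$j[r]])
  }
  names(th) <- map$name
  th
}

#' Inversion settings
#'
#' @param max_iter Maximum Gauss-Newton iterations (default 128).
#' @param tol Convergence threshold on the free-energy increase in nats
#'   (default 1e-4).
#' @param lambda0 Initial Levenberg damping.
#' @param lambda_max Damping ceiling; reaching it ends the search.
#' @param fd_step Finite-difference step for the prediction Jacobian.
#' @return Named list of settings.
#' @export
invert_settings <- function(max_iter = 128L, tol = 1e-4, lambda0 = 1e-2,
                            lambda_max = 1e8, fd_step = 1e-4) {
  list(max_iter = as.integer(max_iter), tol = tol, lambda0 = lambda0,
       lambda_max = lambda_max, fd_step = fd_step)
}

# Residual-forming projection onto the complement of the per-run baseline
# space (intercept + indicators for runs 2..R), mirroring the GLM's
# treatment of the concatenated runs.
baseline_matrix <- function(run_lengths) {
  n <- sum(run_lengths)
  R <- length(run_lengths)
  X <- matrix(1, n, 1)
  if (R > 1) {
    ends <- cumsum(run_lengths)
    starts <- c(1, ends[-R] + 1)
    for (r in 2:R) {
      col <- numeric(n)
      col[starts[r]:ends[r]] <- 1
      X <- cbind(X, col)
    }
  }
  X
}

#' Invert a dynamic causal model
#'
#' MAP estimation of the free parameters under Gaussian priors by damped
#' Gauss-Newton (Levenberg) ascent on a Laplace approximation to the log
#' model evidence. Observation noise is independent Gaussian per node with
#' its variance profiled at the ML value each evaluation; per-run baselines
#' are projected out of data and predictions. Steps that do not increase the
#' free energy are rejected with the damping doubled, so the free energy is
#' non-decreasing across accepted steps. Deterministic: optimization starts
#' at the prior means.
#'
#' @param data A [roi_ts()] whose columns match `model$nodes`.
#' @param model A [dcm_model()] skeleton (masks define the free parameters).
#' @param inputs Inputs as for [integrate_states()].
#' @param priors A [prior_spec()]; must cover exactly the unmasked
#'   parameters of `model`.
#' @param hrf An [hrf_spec()] for the observation model.
#' @param settings See [invert_settings()].
#' @return Object of class `inversion_result` with `posterior_mean` (named),
#'   `posterior_cov`, `free_energy`, `accuracy`, `complexity`, `F_trace`,
#'   `sigma2`, `n_iterations`, `converged`, posterior-mean matrices
#'   (`A`, `B`, `C`), and the prior map.
#' @export
invert_model <- function(data, model, inputs, priors = prior_spec(model),
                         hrf = hrf_spec(), settings = invert_settings()) {
  stopifnot(inherits(data, "roi_ts"))
  inp <- as_dcm_inputs(inputs, model)
  tr <- data$tr_s
  stride <- round(tr / inp$dt_s)
  n_vol <- nrow(data$data)
  if (abs(tr / inp$dt_s - stride) > 1e-9)
    stop("input micro-time step must divide the data TR", call. = FALSE)
  if (floor(nrow(inp$U) / stride) < n_vol)
    stop("inputs are shorter than the data", call. = FALSE)
  n <- length(model$nodes)
  stopifnot(ncol(data$data) == n)

  kern <- hrf_kernel(hrf, inp$dt_s)
  Xb <- baseline_matrix(data$run_lengths)
  XtXi <- solve(crossprod(Xb))
  project <- function(M) M - Xb %*% (XtXi %*% crossprod(Xb, M))

  Y <- project(data$data)
  map <- priors$map
  p <- nrow(map)
  mu0 <- map$mean
  v0 <- map$var
  P0 <- diag(1 / v0, p)
  floor_ <- priors$noise_floor
  z0 <- numeric(n)

  n_forwards <- 0L
  n_screen_pass <- 0L
  forward <- function(theta) {
    n_forwards <<- n_forwards + 1L
    m <- theta_to_model(theta, priors, model)
    project(dcm_forward_cpp(m$A, unname(m$B), m$C, inp$U, inp$Umod,
                            inp$dt_s, kern, tr, n_vol, z0))
  }

  safe_inv <- function(H) {
    tryCatch(chol2inv(chol(H)), error = function(e) {
      warning("singular curvature; ridge-regularized", call. = FALSE)
      chol2inv(chol(H + diag(1e-6 * mean(diag(H)) + 1e-12, nrow(H))))
    })
  }
  # complexity = KL( N(theta, Sigma) || N(mu0, diag(v0)) ) >= 0
  kl_term <- function(theta, Sigma) {
    ld <- determinant(Sigma, logarithm = TRUE)$modulus[1]
    0.5 * (sum(diag(Sigma) / v0) + sum((theta - mu0)^2 / v0) - p +
             sum(log(v0)) - ld)
  }
  lik_parts <- function(G) {
    if (any(!is.finite(G)))   # diverged trajectory: reject outright
      return(list(Rres = NULL, sigma2 = NULL, accuracy = -Inf))
    Rres <- Y - G
    rss <- colSums(Rres^2)
    sigma2 <- pmax(rss / n_vol, floor_)
    list(Rres = Rres, sigma2 = sigma2,
         accuracy = -0.5 * sum(n_vol * log(2 * pi * sigma2) + rss / sigma2))
  }

  # Full evaluation at theta: prediction, Jacobian, curvature, free energy.
  evaluate <- function(theta) {
    G <- forward(theta)
    lp <- lik_parts(G)
    if (!is.finite(lp$accuracy))
      stop("prediction diverged at the expansion point", call. = FALSE)
    h <- settings$fd_step
    J <- array(0, c(n_vol, n, p))
    for (q in seq_len(p)) {
      tq <- theta
      tq[q] <- tq[q] + h
      J[, , q] <- (forward(tq) - G) / h
    }
    J[!is.finite(J)] <- 0
    gram <- vector("list", n)
    H <- matrix(0, p, p)
    grad <- numeric(p)
    for (k in seq_len(n)) {
      Jk <- matrix(J[, k, ], n_vol, p)
      gram[[k]] <- crossprod(Jk)
      H <- H + gram[[k]] / lp$sigma2[k]
      grad <- grad + crossprod(Jk, lp$Rres[, k])[, 1] / lp$sigma2[k]
    }
    grad <- grad - (theta - mu0) / v0
    Hpost <- H + P0
    Sigma <- safe_inv(Hpost)
    kl <- kl_term(theta, Sigma)
    list(theta = theta, G = G, sigma2 = lp$sigma2, accuracy = lp$accuracy,
         complexity = kl, F = lp$accuracy - kl, H = Hpost, grad = grad,
         Sigma = Sigma, gram = gram)
  }

  # Cheap screen of a candidate: one forward pass, curvature approximated
  # with the Gram matrices of the current expansion point.
  screen_F <- function(theta, gram) {
    lp <- lik_parts(forward(theta))
    if (!is.finite(lp$accuracy)) return(-Inf)
    H <- P0
    for (k in seq_len(n)) H <- H + gram[[k]] / lp$sigma2[k]
    lp$accuracy - kl_term(theta, safe_inv(H))
  }

  theta <- mu0
  ev <- evaluate(theta)
  lambda <- settings$lambda0
  F_trace <- ev$F
  iter <- 0L
  converged <- FALSE
  screen_bias <- 0   # running screen-vs-full mismatch, keeps screens honest
  while (iter < settings$max_iter) {
    iter <- iter + 1L
    Hd <- ev$H + lambda * diag(diag(ev$H), nrow(ev$H))
    delta <- tryCatch(solve(Hd, ev$grad), error = function(e) {
      warning("singular curvature; ridge-regularized", call. = FALSE)
      solve(Hd + diag(1e-6 * mean(diag(Hd)) + 1e-12, nrow(Hd)), ev$grad)
    })
    theta_new <- ev$theta + delta
    accepted <- FALSE
    sF <- screen_F(theta_new, ev$gram)
    if (sF - screen_bias > ev$F) {
      n_screen_pass <- n_screen_pass + 1L
      cand <- evaluate(theta_new)
      screen_bias <- max(0, sF - cand$F)
      if (cand$F > ev$F) {
        accepted <- TRUE
        dF <- cand$F - ev$F
        ev <- cand
        F_trace <- c(F_trace, ev$F)
        lambda <- max(lambda / 2, 1e-8)
        if (dF < settings$tol) {
          converged <- TRUE
          break
        }
      }
    } else {
      screen_bias <- screen_bias / 2  # decay so screens cannot lock out ascent
    }
    if (!accepted) {
      lambda <- lambda * 2
      if (lambda > settings$lambda_max) {
        converged <- TRUE  # no admissible ascent direction remains
        break
      }
    }
  }

  post <- theta_to_model(ev$theta, priors, model)
  mean_named <- ev$theta
  names(mean_named) <- map$name
  structure(
    list(posterior_mean = mean_named, posterior_cov = ev$Sigma,
         free_energy = ev$F, accuracy = ev$accuracy,
         complexity = ev$complexity, F_trace = F_trace,
         sigma2 = ev$sigma2, n_iterations = iter, converged = converged,
         n_forwards = n_forwards, n_screen_pass = n_screen_pass,
         A = post$A, B = post$B, C = post$C, map = map,
         nodes = model$nodes),
    class = "inversion_result"
  )
}

#' @export
print.inversion_result <- function(x, ...) {
  cat("<inversion_result> F = ", format(x$free_energy, digits = 6), " nats (",
      x$n_iterations, " iterations, ",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  invisible(x)
}

#' Decompose the free energy into accuracy and complexity
#'
#' The Laplace free energy is `accuracy - complexity`, where accuracy is the
#' Gaussian log-likelihood at the posterior mode and complexity the KL
#' divergence from the Gaussian posterior to the prior (always >= 0; zero
#' when the posterior equals the prior).
#'
#' @param result An [invert_model()] result.
#' @return Named numeric vector `c(accuracy =, complexity =)`.
#' @export
free_energy_components <- function(result) {
  stopifnot(inherits(result, "inversion_result"))
  c(accuracy = result$accuracy, complexity = result$complexity)
}

#' Serialize an inversion result as JSON
#'
#' @param result An [invert_model()] result.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_inversion_json <- function(result, path) {
  obj <- list(
    parameter_names = names(result$posterior_mean),
    posterior_mean = unname(result$posterior_mean),
    posterior_cov = as.vector(t(result$posterior_cov)),
    free_energy = result$free_energy,
    accuracy = result$accuracy,
    complexity = result$complexity,
    sigma2 = unname(result$sigma2),
    n_iterations = result$n_iterations,
    converged = result$converged
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
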
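# Hand-shape classifier: one left-to-right Gaussian-mixture HMM per hand
# shape, trained by Baum-Welch (EM), scored by the forward algorithm in log
# space, decided by maximum likelihood.
#
# Topology: no skip transitions (state i may only stay or advance to i+1),
# initial distribution degenerate at state 1. Emissions are mixtures of
# diagonal-covariance Gaussians with a variance floor — 20-D frames and
# small training sets make fuller covariances ill-conditioned.

#' HMM training configuration
#'
#' @param n_states Number of hidden states (default 5).
#' @param n_mix Gaussian mixture components per state (default 3).
#' @param max_iter Maximum Baum-Welch iterations.
#' @param tol Stop when the training log-likelihood improves by less than
#'   this (> 0).
#' @param seed Integer seed for the k-means-style emission initialisation.
#' @param var_floor Lower bound on every emission variance entry.
#' @return A list of class `hmm_config`.
#' @export
hmm_config <- function(n_states = 5L, n_mix = 3L, max_iter = 40L,
                       tol = 1e-4, seed = 1L, var_floor = 1e-6) {
  stopifnot(n_states >= 1L, n_mix >= 1L, max_iter >= 1L)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  structure(list(n_states = as.integer(n_states), n_mix = as.integer(n_mix),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), var_floor = var_floor),
            class = "hmm_config")
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# Per-frame log emission densities. Returns list(logB = T x N matrix of
# per-state mixture densities, logN = T x N x M array of per-component
# densities including the log mixture weight).
hmm_log_emissions <- function(model, X) {
  N <- model$n_states; M <- model$n_mix; d <- model$dim
  T_len <- nrow(X)
  logN <- array(-Inf, c(T_len, N, M))
  logW <- log(model$weights)
  for (j in seq_len(N)) {
    for (m in seq_len(M)) {
      if (!is.finite(logW[j, m])) next
      mu <- model$means[[j]][m, ]
      v <- model$vars[[j]][m, ]
      cst <- -0.5 * (d * log(2 * pi) + sum(log(v)))
      q <- colSums((t(X) - mu)^2 / v)
      logN[, j, m] <- logW[j, m] + cst - 0.5 * q
    }
  }
  logB <- matrix(-Inf, T_len, N)
  for (j in seq_len(N)) {
    logB[, j] <- row_logsumexp(matrix(logN[, j, ], T_len, M))
  }
  list(logB = logB, logN = logN)
}

hmm_forward <- function(model, logB) {
  T_len <- nrow(logB); N <- ncol(logB)
  logA <- log(model$A)
  la <- matrix(-Inf, T_len, N)
  la[1, ] <- log(model$pi) + logB[1, ]
  if (T_len > 1L) {
    for (t in 2:T_len) {
      v <- logA + la[t - 1L, ]
      la[t, ] <- apply(v, 2L, logsumexp) + logB[t, ]
    }
  }
  la
}

hmm_backward <- function(model, logB) {
  T_len <- nrow(logB); N <- ncol(logB)
  logA <- log(model$A)
  lb <- matrix(0, T_len, N)
  if (T_len > 1L) {
    for (t in (T_len - 1L):1L) {
      w <- sweep(logA, 2L, logB[t + 1L, ] + lb[t + 1L, ], "+")
      lb[t, ] <- apply(w, 1L, logsumexp)
    }
  }
  lb
}

# Left-to-right transition skeleton: stay or advance, final state absorbing.
lr_transition_init <- function(N) {
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    if (i < N) {
      A[i, i] <- 0.6
      A[i, i + 1L] <- 0.4
    } else {
      A[i, i] <- 1
    }
  }
  A
}

# Uniform-segmentation + k-means emission initialisation.
hmm_init <- function(sequences, cfg, d) {
  N <- cfg$n_states; M <- cfg$n_mix
  pooled <- do.call(rbind, sequences)
  g_mean <- colMeans(pooled)
  g_var <- pmax(apply(pooled, 2L, var), cfg$var_floor)
  state_frames <- vector("list", N)
  for (X in sequences) {
    T_len <- nrow(X)
    s <- pmin(N, floor((seq_len(T_len) - 1L) / T_len * N) + 1L)
    for (j in unique(s)) {
      state_frames[[j]] <- rbind(state_frames[[j]], X[s == j, , drop = FALSE])
    }
  }
  weights <- matrix(1 / M, N, M)
  means <- vector("list", N)
  vars <- vector("list", N)
  for (j in seq_len(N)) {
    F_j <- state_frames[[j]]
    if (is.null(F_j) || nrow(F_j) < 2L) {
      means[[j]] <- matrix(rep(g_mean, each = M), M, d) *
        (1 + 0.01 * (seq_len(M) - 1))
      vars[[j]] <- matrix(rep(g_var, each = M), M, d)
      next
    }
    assign_m <- NULL
    if (nrow(F_j) > M && nrow(unique(F_j)) >= M) {
      km <- tryCatch(kmeans(F_j, centers = M, nstart = 2L, iter.max = 25L),
                     error = function(e) NULL)
      if (!is.null(km)) assign_m <- km$cluster
    }
    if (is.null(assign_m)) {
      assign_m <- rep_len(seq_len(M), nrow(F_j))
    }
    mu <- matrix(0, M, d)
    vv <- matrix(0, M, d)
    for (m in seq_len(M)) {
      Fm <- F_j[assign_m == m, , drop = FALSE]
      if (nrow(Fm) == 0L) {
        mu[m, ] <- g_mean
        vv[m, ] <- g_var
        weights[j, m] <- 1e-3
      } else {
        mu[m, ] <- colMeans(Fm)
        vm <- if (nrow(Fm) >= 2L) apply(Fm, 2L, var) else g_var
        vv[m, ] <- pmax(vm, cfg$var_floor)
        weights[j, m] <- nrow(Fm)
      }
    }
    weights[j, ] <- weights[j, ] / sum(weights[j, ])
    means[[j]] <- mu
    vars[[j]] <- vv
  }
  structure(list(n_states = N, n_mix = M, dim = d,
                 A = lr_transition_init(N),
                 pi = c(1, rep(0, N - 1L)),
                 weights = weights, means = means, vars = vars,
                 loglik_trace = numeric(0), converged = FALSE,
                 class_index = NA_integer_),
            class = "hmm_model")
}

#' Fit a left-to-right Gaussian-mixture HMM by Baum-Welch
#'
#' Emissions are initialised by segmenting each sequence uniformly across
#' states and clustering the pooled frames of each state into `n_mix`
#' components; EM updates then run until the training log-likelihood
#' improves by less than `tol` or `max_iter` is reached. The left-to-right
#' structure and the degenerate initial distribution are preserved by every
#' update, and the log-likelihood trace is non-decreasing (up to numerical
#' slack from the variance floor).
#'
#' @param sequences List of observation sequences (T x d matrices, T >= 1),
#'   e.g. from [emg_observation_sequence()].
#' @param cfg An [hmm_config()].
#' @return An object of class `hmm_model` with the fitted parameters and
#'   `loglik_trace`.
#' @export
fit_hmm <- function(sequences, cfg = hmm_config()) {
  if (!is.list(sequences) || length(sequences) == 0L) {
    stop("need at least one observation sequence", call. = FALSE)
  }
  sequences <- lapply(sequences, function(X) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (nrow(X) < 1L) stop("empty observation sequence", call. = FALSE)
    X
  })
  d <- ncol(sequences[[1]])
  if (!all(vapply(sequences, ncol, integer(1)) == d)) {
    stop("all sequences must share the same frame dimension", call. = FALSE)
  }
  model <- withr::with_seed(cfg$seed, hmm_init(sequences, cfg, d))
  N <- cfg$n_states; M <- cfg$n_mix

  trace <- numeric(0)
  for (iter in seq_len(cfg$max_iter)) {
    total_ll <- 0
    Xi_sum <- matrix(0, N, N)
    R <- matrix(0, N, M)
    Sx <- lapply(seq_len(N), function(j) matrix(0, M, d))
    Sxx <- lapply(seq_len(N), function(j) matrix(0, M, d))
    logA <- log(model$A)
    logW <- log(model$weights)

    for (X in sequences) {
      T_len <- nrow(X)
      em <- hmm_log_emissions(model, X)
      la <- hmm_forward(model, em$logB)
      lb <- hmm_backward(model, em$logB)
      ll <- logsumexp(la[T_len, ])
      if (!is.finite(ll)) {
        stop("zero-probability sequence under current model", call. = FALSE)
      }
      total_ll <- total_ll + ll
      Gamma <- exp(la + lb - ll)
      if (T_len > 1L) {
        for (t in seq_len(T_len - 1L)) {
          lx <- sweep(logA + la[t, ], 2L,
                      em$logB[t + 1L, ] + lb[t + 1L, ], "+") - ll
          Xi_sum <- Xi_sum + exp(lx)
        }
      }
      for (j in seq_len(N)) {
        lr <- matrix(em$logN[, j, ], T_len, M) - em$logB[, j]
        lr[!is.finite(em$logB[, j]), ] <- -Inf
        r <- Gamma[, j] * exp(lr)
        R[j, ] <- R[j, ] + colSums(r)
        Sx[[j]] <- Sx[[j]] + t(r) %*% X
        Sxx[[j]] <- Sxx[[j]] + t(r) %*% (X^2)
      }
    }
    trace <- c(trace, total_ll)

    # M-step (pi stays degenerate at state 1)
    for (i in seq_len(N)) {
      s <- sum(Xi_sum[i, ])
      if (s > 0) model$A[i, ] <- Xi_sum[i, ] / s
    }
    for (j in seq_len(N)) {
      sR <- sum(R[j, ])
      if (sR <= 1e-12) next
      for (m in seq_len(M)) {
        if (R[j, m] <= 1e-10) {
          model$weights[j, m] <- R[j, m] / sR
          next
        }
        model$weights[j, m] <- R[j, m] / sR
        mu <- Sx[[j]][m, ] / R[j, m]
        vv <- Sxx[[j]][m, ] / R[j, m] - mu^2
        model$means[[j]][m, ] <- mu
        model$vars[[j]][m, ] <- pmax(vv, cfg$var_floor)
      }
      model$weights[j, ] <- model$weights[j, ] / sum(model$weights[j, ])
    }

    if (iter > 1L && (trace[iter] - trace[iter - 1L]) < cfg$tol) {
      model$converged <- TRUE
      break
    }
  }
  model$loglik_trace <- trace
  model
}

#' Forward-algorithm log-likelihood
#'
#' `log P(O | lambda)` of an observation sequence under a fitted HMM,
#' computed by the forward recursion in log space (numerically equivalent
#' to the classical scaled recursion).
#'
#' @param model A fitted [fit_hmm()] model.
#' @param seq Observation sequence, T x d matrix with T >= 1.
#' @return Log-likelihood (finite unless some frame has zero density under
#'   every reachable state, in which case `-Inf`).
#' @export
forward_loglik <- function(model, seq) {
  stopifnot(inherits(model, "hmm_model"))
  seq <- as.matrix(seq)
  if (nrow(seq) < 1L) stop("empty observation sequence", call. = FALSE)
  if (ncol(seq) != model$dim) {
    stop(sprintf("sequence dimension %d does not match model dimension %d",
                 ncol(seq), model$dim), call. = FALSE)
  }
  em <- hmm_log_emissions(model, seq)
  la <- hmm_forward(model, em$logB)
  logsumexp(la[nrow(seq), ])
}

#' Classify a hand shape by maximum likelihood
#'
#' Scores the observation sequence under every class HMM with the forward
#' algorithm and returns the class of the maximum log-likelihood; ties break
#' toward the lowest class index.
#'
#' @param models List of fitted `hmm_model`s ordered by class index
#'   (13 models for the full hand-shape task).
#' @param seq Observation sequence (T x d matrix).
#' @return List with `class` (integer index into `models`) and the `loglik`
#'   vector ordered by class index.
#' @export
classify_handshape <- function(models, seq) {
  if (!is.list(models) || length(models) == 0L ||
      !all(vapply(models, inherits, logical(1), "hmm_model"))) {
    stop("`models` must be a list of fitted hmm_model objects", call. = FALSE)
  }
  ll <- vapply(models, forward_loglik, numeric(1), seq = seq)
  list(class = which.max(ll), loglik = ll)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf(
    "<hmm_model> %d states (left-to-right), %d mixtures, dim %d | %d EM iterations%s\n",
    x$n_states, x$n_mix, x$dim, length(x$loglik_trace),
    if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}

#' @rdname fit_hmm
#' @param x An `hmm_model`.
#' @param ... Unused.
#' @method tidy hmm_model
#' @export
tidy.hmm_model <- function(x, ...) {
  N <- x$n_states
  tibble::tibble(
    from = rep(seq_len(N), each = N),
    to = rep(seq_len(N), N),
    probability = as.vector(t(x$A))
  ) |> dplyr::filter(.data$probability > 0)
}

#' @rdname fit_hmm
#' @method glance hmm_model
#' @export
glance.hmm_model <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states, n_mix = x$n_mix, dim = x$dim,
    log_likelihood = if (length(x$loglik_trace)) tail(x$loglik_trace, 1) else NA_real_,
    iterations = length(x$loglik_trace),
    converged = isTRUE(x$converged)
  )
}
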
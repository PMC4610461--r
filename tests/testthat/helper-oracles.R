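# Independent oracles used to cross-check the dynamic-programming and
# forward-algorithm implementations, plus small constructors for hand-built
# models.

# Exhaustive enumeration of all monotone warping paths from (1,1) to (N,N)
# within the slope corridor, carrying accumulated squared-difference cost
# along each partial path. Independent of the DP recursion.
brute_dtw <- function(t, r, slope_max = 2) {
  N <- length(t)
  in_corridor <- function(m, n) {
    (n - 1) <= slope_max * (m - 1) & (m - 1) <= slope_max * (n - 1) &
      (N - n) <= slope_max * (N - m) & (N - m) <= slope_max * (N - n)
  }
  best <- Inf
  frontier <- matrix(c(1, 1, (t[1] - r[1])^2), nrow = 1)
  while (nrow(frontier) > 0) {
    done <- frontier[, 1] == N & frontier[, 2] == N
    if (any(done)) best <- min(best, frontier[done, 3])
    frontier <- frontier[!done, , drop = FALSE]
    if (nrow(frontier) == 0) break
    moves <- rbind(c(1, 0), c(1, 1), c(0, 1))
    nxt <- do.call(rbind, lapply(1:3, function(k) {
      cbind(frontier[, 1] + moves[k, 1], frontier[, 2] + moves[k, 2],
            frontier[, 3])
    }))
    nxt <- nxt[nxt[, 1] <= N & nxt[, 2] <= N, , drop = FALSE]
    if (nrow(nxt) == 0) break
    nxt <- nxt[in_corridor(nxt[, 1], nxt[, 2]), , drop = FALSE]
    if (nrow(nxt) == 0) break
    nxt[, 3] <- nxt[, 3] + (t[nxt[, 1]] - r[nxt[, 2]])^2
    frontier <- nxt
  }
  best
}

# Hand-built GMM-HMM with diagonal covariances.
# means/vars: lists (one per state) of M x d matrices; weights: N x M.
make_hmm <- function(A, pi, weights, means, vars) {
  structure(list(n_states = nrow(A), n_mix = ncol(weights),
                 dim = ncol(means[[1]]), A = A, pi = pi,
                 weights = weights, means = means, vars = vars,
                 loglik_trace = numeric(0), converged = TRUE,
                 class_index = NA_integer_),
            class = "hmm_model")
}

# Mixture emission density computed directly from dnorm products.
mixture_density <- function(model, j, x) {
  sum(vapply(seq_len(model$n_mix), function(m) {
    model$weights[j, m] *
      prod(dnorm(x, model$means[[j]][m, ], sqrt(model$vars[[j]][m, ])))
  }, numeric(1)))
}

# log P(O | lambda) by exhaustive summation over all N^T state paths.
enum_forward_loglik <- function(model, X) {
  N <- model$n_states
  T_len <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_len)))
  total <- 0
  for (p in seq_len(nrow(paths))) {
    s <- paths[p, ]
    pr <- model$pi[s[1]] * mixture_density(model, s[1], X[1, ])
    if (T_len > 1) {
      for (t in 2:T_len) {
        pr <- pr * model$A[s[t - 1], s[t]] * mixture_density(model, s[t], X[t, ])
      }
    }
    total <- total + pr
  }
  log(total)
}

# Random left-to-right 2-state mixture model plus a random test sequence.
random_two_state_case <- function(d = 2, n_mix = 2, t_max = 4) {
  a11 <- runif(1, 0.3, 0.9)
  A <- matrix(c(a11, 1 - a11, 0, 1), 2, 2, byrow = TRUE)
  weights <- matrix(runif(2 * n_mix, 0.2, 1), 2, n_mix)
  weights <- weights / rowSums(weights)
  means <- lapply(1:2, function(j) matrix(rnorm(n_mix * d, sd = 2), n_mix, d))
  vars <- lapply(1:2, function(j) matrix(runif(n_mix * d, 0.2, 1.5), n_mix, d))
  T_len <- sample.int(t_max, 1)
  X <- matrix(rnorm(T_len * d, sd = 2), T_len, d)
  list(model = make_hmm(A, c(1, 0), weights, means, vars), X = X)
}

# Sample one observation sequence from a fitted hmm_model (independent
# re-implementation of the generative process).
simulate_hmm_oracle <- function(model, n_frames) {
  N <- model$n_states
  s <- integer(n_frames)
  s[1] <- sample.int(N, 1, prob = model$pi)
  for (t in seq_len(n_frames)[-1]) {
    s[t] <- sample.int(N, 1, prob = model$A[s[t - 1], ])
  }
  X <- matrix(0, n_frames, model$dim)
  for (t in seq_len(n_frames)) {
    m <- sample.int(model$n_mix, 1, prob = model$weights[s[t], ])
    X[t, ] <- rnorm(model$dim, model$means[[s[t]]][m, ],
                    sqrt(model$vars[[s[t]]][m, ]))
  }
  X
}

# Sample sequences from a left-to-right HMM with one Gaussian per state
# (independent sampler for the Baum-Welch parameter-recovery check).
sample_lr_sequences <- function(A, means, sds, n_seq, t_len) {
  N <- nrow(A)
  d <- ncol(means)
  lapply(seq_len(n_seq), function(i) {
    s <- integer(t_len)
    s[1] <- 1L
    for (t in 2:t_len) s[t] <- sample.int(N, 1, prob = A[s[t - 1], ])
    X <- matrix(0, t_len, d)
    for (t in seq_len(t_len)) X[t, ] <- rnorm(d, means[s[t], ], sds[s[t], ])
    X
  })
}
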
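# Left-to-right GMM-HMM training, scoring and classification.

test_that("a 1-state 1-mixture fit reduces to the frame mean (EM fixed point)", {
  withr::with_seed(3, X <- matrix(rnorm(40, mean = 2), 20, 2))
  m <- fit_hmm(list(X), hmm_config(n_states = 1, n_mix = 1, max_iter = 5))
  expect_equal(as.numeric(m$means[[1]]), colMeans(X), tolerance = 1e-8)
  expect_equal(m$A, matrix(1, 1, 1))
})

test_that("Baum-Welch preserves stochasticity and left-to-right structure", {
  withr::with_seed(4, seqs <- lapply(1:5, function(i) matrix(rnorm(60), 20, 3)))
  m <- fit_hmm(seqs, hmm_config(n_states = 4, n_mix = 2, max_iter = 10))
  expect_equal(rowSums(m$A), rep(1, 4))
  expect_equal(m$pi, c(1, 0, 0, 0))
  # no backward or skip transitions
  for (i in 1:4) for (j in 1:4) {
    if (j < i || j > i + 1) expect_equal(m$A[i, j], 0)
  }
  expect_equal(rowSums(m$weights), rep(1, 4))
  expect_true(all(unlist(m$vars) >= 1e-6 - 1e-12))
})

test_that("the training log-likelihood trace is non-decreasing", {
  for (s in 1:3) {
    withr::with_seed(s, {
      seqs <- lapply(1:8, function(i) {
        matrix(rnorm(25 * 4, mean = rep(c(0, 3), each = 25 * 2)), 25, 4)
      })
    })
    m <- fit_hmm(seqs, hmm_config(n_states = 3, n_mix = 2, max_iter = 25,
                                  seed = s))
    expect_true(all(diff(m$loglik_trace) >= -1e-8))
  }
})

test_that("all-identical frames engage the variance floor instead of failing", {
  X <- matrix(1, 10, 3)
  m <- fit_hmm(list(X), hmm_config(n_states = 2, n_mix = 1, max_iter = 3))
  expect_true(all(unlist(m$vars) >= 1e-6 - 1e-12))
  expect_true(is.finite(forward_loglik(m, X)))
})

test_that("a 1-state model's forward log-likelihood is the summed emission density", {
  withr::with_seed(7, {
    mu <- matrix(rnorm(3), 1, 3)
    vv <- matrix(runif(3, 0.5, 2), 1, 3)
    m <- make_hmm(matrix(1, 1, 1), 1, matrix(1, 1, 1), list(mu), list(vv))
    X <- matrix(rnorm(15), 5, 3)
  })
  manual <- sum(vapply(1:5, function(t) {
    sum(dnorm(X[t, ], mu[1, ], sqrt(vv[1, ]), log = TRUE))
  }, numeric(1)))
  expect_equal(forward_loglik(m, X), manual, tolerance = 1e-10)
})

test_that("forward log-likelihood matches exhaustive state-path summation", {
  withr::with_seed(19, {
    for (trial in 1:20) {
      case <- random_two_state_case()
      expect_equal(forward_loglik(case$model, case$X),
                   enum_forward_loglik(case$model, case$X), tolerance = 1e-9)
    }
  })
})

test_that("an absurd outlier frame collapses the log-likelihood", {
  withr::with_seed(8, X <- matrix(rnorm(40), 10, 4))
  m <- fit_hmm(list(X), hmm_config(n_states = 2, n_mix = 1, max_iter = 5))
  ll <- forward_loglik(m, X)
  ll_bad <- forward_loglik(m, rbind(X, rep(1e6, 4)))
  expect_lt(ll_bad, ll - 1e3)
  expect_error(forward_loglik(m, X[0, , drop = FALSE]), "empty")
})

test_that("classification is argmax over per-class log-likelihoods", {
  withr::with_seed(9, {
    seqs1 <- lapply(1:5, function(i) matrix(rnorm(30, 0), 10, 3))
    seqs2 <- lapply(1:5, function(i) matrix(rnorm(30, 5), 10, 3))
    m1 <- fit_hmm(seqs1, hmm_config(2, 1, max_iter = 10))
    m2 <- fit_hmm(seqs2, hmm_config(2, 1, max_iter = 10))
    probe <- matrix(rnorm(30, 5), 10, 3)
  })
  res <- classify_handshape(list(m1, m2), probe)
  expect_equal(res$class, 2L)
  expect_length(res$loglik, 2L)
  # identical models tie toward the lowest class index
  res_tie <- classify_handshape(list(m1, m1, m1), probe)
  expect_equal(res_tie$class, 1L)
  expect_error(classify_handshape(list(), probe), "hmm_model")
})

test_that("left-to-right self-transitions are recovered from sampled sequences", {
  A_true <- matrix(c(0.8, 0.2, 0,
                     0, 0.7, 0.3,
                     0, 0, 1), 3, 3, byrow = TRUE)
  means <- matrix(c(-4, 0, 4, 0, -4, 4), 3, 2)
  sds <- matrix(0.7, 3, 2)
  withr::with_seed(29, seqs <- sample_lr_sequences(A_true, means, sds, 30, 25))
  m <- fit_hmm(seqs, hmm_config(n_states = 3, n_mix = 1, max_iter = 40))
  expect_lt(max(abs(diag(m$A)[1:2] - diag(A_true)[1:2])), 0.1)
})

test_that("round-trip: sequences sampled from one class's model classify to it", {
  withr::with_seed(33, {
    models <- lapply(1:4, function(c) {
      seqs <- lapply(1:6, function(i) matrix(rnorm(36, mean = 2 * c), 12, 3))
      fit_hmm(seqs, hmm_config(3, 1, max_iter = 10, seed = c))
    })
    for (c in c(1, 3)) {
      probe <- simulate_hmm_oracle(models[[c]], 12)
      expect_equal(classify_handshape(models, probe)$class, c)
    }
  })
})

test_that("more training repetitions do not degrade hand-shape accuracy", {
  params <- test_params()
  classes <- c(2, 6, 10)
  train_obs <- function(cls, reps, seed) {
    lapply(seq_len(reps), function(i) {
      burst_observation(cls, c("U", "D", "R", "L")[(i - 1) %% 4 + 1],
                        seed = seed + 17 * i)
    })
  }
  acc_at <- function(reps) {
    models <- lapply(classes, function(cl) {
      fit_hmm(train_obs(cl, reps, seed = 600 + cl), hmm_config(seed = cl))
    })
    probes <- unlist(lapply(classes, function(cl) {
      lapply(1:4, function(i) burst_observation(cl, "R", seed = 900 + cl * 7 + i))
    }), recursive = FALSE)
    truth <- rep(seq_along(classes), each = 4)
    pred <- vapply(probes, function(p) classify_handshape(models, p)$class,
                   integer(1))
    mean(pred == truth)
  }
  a_small <- acc_at(3)
  a_large <- acc_at(10)
  expect_gte(a_large, a_small - 0.05)
  expect_gte(a_large, 0.9)
})
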
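# Per-class Gaussian orientation classifier.

ldc_toy <- function(mu1 = c(0, 0), mu2 = c(4, 0), n = 20, sd = 1, seed = 2) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * 2, mu1, sd), n, 2, byrow = TRUE),
               matrix(rnorm(n * 2, mu2, sd), n, 2, byrow = TRUE))
  })
  fit_ldc(X, rep(c("Inward", "Downward"), each = n))
}

test_that("degenerate point clusters get the regularised identity covariance", {
  X <- rbind(matrix(c(1, 2, 3, 4), 2, 4, byrow = TRUE),
             matrix(c(5, 6, 7, 8), 2, 4, byrow = TRUE))
  m <- fit_ldc(X, c("Inward", "Inward", "Downward", "Downward"))
  expect_equal(m$means[[1]], c(1, 2, 3, 4), ignore_attr = TRUE)
  expect_equal(m$means[[2]], c(5, 6, 7, 8), ignore_attr = TRUE)
  expect_equal(m$covs[[1]], 1e-6 * diag(4))
  expect_equal(unname(m$prior), c(0.5, 0.5))
})

test_that("class means are recovered from Gaussian samples", {
  mu <- list(Inward = c(1, 0, 0, 0.05), Downward = c(0, 0, 1, 0.001))
  sd_true <- 0.1
  n <- 500
  withr::with_seed(14, {
    X <- rbind(
      matrix(rnorm(n * 4, rep(mu$Inward, each = n), sd_true), n, 4),
      matrix(rnorm(n * 4, rep(mu$Downward, each = n), sd_true), n, 4))
  })
  m <- fit_ldc(X, rep(c("Inward", "Downward"), each = n))
  se <- sd_true / sqrt(n)
  expect_true(all(abs(m$means[[1]] - mu$Inward) < 3 * se))
  expect_true(all(abs(m$means[[2]] - mu$Downward) < 3 * se))
  expect_error(fit_ldc(X[c(1, 2, n + 1), ], c("Inward", "Inward", "Downward")),
               "at least 2")
})

test_that("classification is maximum posterior with ties toward Inward", {
  m <- ldc_toy()
  # at a class mean the posterior favours that class
  r2 <- classify_orientation(m, m$means[[which(m$classes == "Downward")]])
  expect_equal(r2$class, "Downward")
  expect_gt(r2$posterior[["Downward"]], 0.5)

  # symmetric construction: equal spherical covariances, x at the midpoint
  ms <- m
  ms$means <- list(c(0, 0), c(2, 0))
  ms$covs <- list(diag(2), diag(2))
  ms$prior <- c(Inward = 0.5, Downward = 0.5)
  tie <- classify_orientation(ms, c(1, 0))
  expect_equal(unname(tie$posterior), c(0.5, 0.5))
  expect_equal(tie$class, "Inward")

  expect_error(classify_orientation(m, c(1, NA)), "finite")
})

test_that("posteriors match the closed-form weighted Gaussian densities", {
  m <- ldc_toy(mu1 = c(-1, 2), mu2 = c(3, -1), sd = 1.5, seed = 5)
  dens <- function(x, mu, S) {
    as.numeric(exp(-0.5 * t(x - mu) %*% solve(S) %*% (x - mu)) /
                 sqrt((2 * pi)^length(mu) * det(S)))
  }
  withr::with_seed(31, xs <- replicate(20, rnorm(2, sd = 3), simplify = FALSE))
  for (x in xs) {
    got <- classify_orientation(m, x)
    w <- vapply(1:2, function(i) {
      m$prior[i] * dens(x, m$means[[i]], m$covs[[i]])
    }, numeric(1))
    expect_equal(unname(got$posterior), unname(w / sum(w)), tolerance = 1e-12)
    expect_equal(sum(got$posterior), 1, tolerance = 1e-12)
  }
})

test_that("equal-prior fitting is available for unknown class frequencies", {
  X <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(20, 5), 10, 2))
  m <- fit_ldc(X, c(rep("Inward", 20), rep("Downward", 10)), priors = "equal")
  expect_equal(unname(m$prior), c(0.5, 0.5))
  mf <- fit_ldc(X, c(rep("Inward", 20), rep("Downward", 10)))
  expect_equal(unname(mf$prior), c(2 / 3, 1 / 3))
})

test_that("simulated palm orientations are perfectly separated", {
  params <- test_params()
  make_feats <- function(labels, seed) {
    sess <- simulate_session(protocol_from_labels(labels, seed = seed), params)
    segs <- segments_from_annotations(sess)
    dplyr::bind_rows(lapply(seq_len(nrow(segs)), function(i) {
      orientation_features(extract_acc(sess, segs$acc_on[i], segs$acc_off[i]))
    }))
  }
  train_in <- make_feats(paste0(rep(1:5, each = 4), c("U", "D", "R", "L")),
                         seed = 41)
  train_dn <- make_feats(rep("00", 20), seed = 43)
  model <- fit_ldc(rbind(train_in, train_dn),
                   rep(c("Inward", "Downward"), each = 20))

  test_idx <- withr::with_seed(45, sample(1:13, 50, replace = TRUE))
  test_labels <- c(paste0(test_idx, rep_len(c("U", "D", "R", "L"), 50)),
                   rep("00", 50))
  test_feats <- make_feats(test_labels, seed = 47)
  pred <- vapply(seq_len(nrow(test_feats)), function(i) {
    classify_orientation(model, test_feats[i, ])$class
  }, character(1))
  truth <- ifelse(test_labels == "00", "Downward", "Inward")
  expect_equal(mean(pred == truth), 1)
})
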
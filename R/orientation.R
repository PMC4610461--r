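# Palm-orientation classifier.
#
# Two-class Bayes classifier with one multivariate Gaussian per class over
# the 4-D orientation features. The literature often files this under
# "linear discriminant", but with class-specific covariance matrices the
# decision boundary is quadratic; the per-class Gaussian density model is
# implemented exactly as written.

#' Fit the per-class Gaussian orientation classifier
#'
#' Estimates, per class, the sample mean and covariance of the orientation
#' features, regularising the covariance by `eps * I` with
#' `eps = 1e-6 * mean(diag(Sigma))` (falling back to `1e-6` when the class
#' is a degenerate point cluster). Priors default to class frequencies.
#'
#' @param features Data frame or matrix of orientation feature rows
#'   (e.g. stacked [orientation_features()] output).
#' @param labels Class label per row; two or more classes, each with at
#'   least 2 samples. `"Inward"`, if present, is ordered first so that
#'   posterior ties continue down the pipeline.
#' @param priors `"frequency"` (default) or `"equal"`.
#' @return An object of class `ldc_model`.
#' @export
fit_ldc <- function(features, labels, priors = c("frequency", "equal")) {
  priors <- match.arg(priors)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) {
    stop("`features` and `labels` lengths differ", call. = FALSE)
  }
  classes <- unique(labels)
  if ("Inward" %in% classes) {
    classes <- c("Inward", setdiff(classes, "Inward"))
  }
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) {
    stop("every class needs at least 2 samples", call. = FALSE)
  }
  fit_one <- function(cl) {
    Xc <- X[labels == cl, , drop = FALSE]
    sigma <- cov(Xc)
    md <- mean(diag(sigma))
    eps <- if (md > 0) 1e-6 * md else 1e-6
    list(mean = colMeans(Xc), cov = sigma + eps * diag(ncol(X)))
  }
  pars <- lapply(classes, fit_one)
  prior <- if (priors == "equal") {
    rep(1 / length(classes), length(classes))
  } else {
    as.numeric(counts) / sum(counts)
  }
  structure(list(classes = classes,
                 means = lapply(pars, `[[`, "mean"),
                 covs = lapply(pars, `[[`, "cov"),
                 prior = stats::setNames(prior, classes),
                 d = ncol(X)),
            class = "ldc_model")
}

#' Classify palm orientation
#'
#' Evaluates the prior-weighted Gaussian density of each class at `x` and
#' returns the maximum-posterior class; posteriors are normalised across
#' classes. Exact ties go to the first stored class (`"Inward"` when
#' present), so tied cases continue down the pipeline.
#'
#' @param model A fitted [fit_ldc()] model.
#' @param x A single feature vector (length `model$d`) or one-row data frame.
#' @return List with `class` and the named `posterior` vector.
#' @export
classify_orientation <- function(model, x) {
  stopifnot(inherits(model, "ldc_model"))
  x <- as.numeric(as.matrix(x))
  if (length(x) != model$d || !all(is.finite(x))) {
    stop(sprintf("`x` must be %d finite features", model$d), call. = FALSE)
  }
  logp <- vapply(seq_along(model$classes), function(i) {
    log(model$prior[i]) + dmvnorm_log(x, model$means[[i]], model$covs[[i]])
  }, numeric(1))
  post <- exp(logp - logsumexp(logp))
  names(post) <- model$classes
  list(class = model$classes[which.max(post)], posterior = post)
}

#' @export
print.ldc_model <- function(x, ...) {
  cat(sprintf("<ldc_model> %d classes (%s), %d features\n",
              length(x$classes), paste(x$classes, collapse = ", "), x$d))
  invisible(x)
}

#' @rdname fit_ldc
#' @param x An `ldc_model`.
#' @param ... Unused.
#' @method tidy ldc_model
#' @export
tidy.ldc_model <- function(x, ...) {
  purrr::map2_dfr(x$classes, x$means, function(cl, mu) {
    tibble::tibble(class = cl, feature = names(mu) %||% paste0("x", seq_along(mu)),
                   mean = unname(mu), prior = unname(x$prior[cl]))
  })
}

#' @rdname fit_ldc
#' @method glance ldc_model
#' @export
glance.ldc_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), n_features = x$d)
}
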
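#' Fuse markers into a single predicted probability
#'
#' Fits a maximum-likelihood logistic regression of the class label on
#' one or more markers by iteratively reweighted least squares (at most
#' `max_iter` iterations, convergence when the log-likelihood changes by
#' less than `tol`) and returns each subject's predicted probability of
#' the positive class. The predicted probability serves as a single
#' fused marker for downstream ROC analysis, which depends only on its
#' ordering; complete or quasi-complete separation is therefore detected
#' and flagged, not penalized, though a small ridge stabilizer is
#' available.
#'
#' @param markers numeric vector, matrix or data.frame of per-subject
#'   marker values (subjects in rows); no missing values.
#' @param labels per-subject class labels.
#' @param positive label of the positive class (default `"MCI"`).
#' @param ridge L2 penalty on the slopes (default 0; `1e-6` stabilizes
#'   separated fits).
#' @param max_iter,tol IRLS iteration cap and log-likelihood tolerance.
#' @return Object of class `kd_combined`: `coefficients` (intercept
#'   first), `probabilities` in \[0, 1\], `separation_flag`, `converged`,
#'   `iterations`, `log_likelihood`.
#' @export
fit_logistic_combiner <- function(markers, labels, positive = "MCI",
                                  ridge = 0, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(markers)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X)))
    kd_validation_error("markers must be finite and non-missing")
  classes <- unique(labels)
  if (length(classes) != 2)
    kd_validation_error("labels must be binary (exactly two classes)")
  if (!positive %in% classes)
    kd_validation_error(sprintf("positive class '%s' not present", positive))
  y <- as.numeric(labels == positive)
  if (nrow(X) != length(y))
    kd_validation_error("markers and labels must have equal length")

  if (is.null(colnames(X)))
    colnames(X) <- paste0("marker", seq_len(ncol(X)))
  constant <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(constant)) {
    warning("constant marker(s) dropped: ",
            paste(colnames(X)[constant], collapse = ", "),
            if (all(constant)) "; intercept-only fit" else "")
    X <- X[, !constant, drop = FALSE]
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(ridge, p - 1)), p)

  beta <- numeric(p)
  ll_old <- -Inf; ll <- NA_real_; converged <- FALSE; it <- 0L
  repeat {
    it <- it + 1L
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(Xd, Xd * w) + pen
    beta <- tryCatch(drop(solve(A, crossprod(Xd, w * z))),
                     error = function(e)
                       drop(solve(A + diag(1e-10, p), crossprod(Xd, w * z))))
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
  }
  separation <- max(abs(eta)) > 30

  structure(list(coefficients = stats::setNames(beta, colnames(Xd)),
                 probabilities = mu,
                 separation_flag = separation,
                 converged = converged,
                 iterations = it,
                 log_likelihood = ll),
            class = "kd_combined")
}

#' @export
print.kd_combined <- function(x, ...) {
  cat(sprintf("<kd_combined: %d coefficients, logLik %.4f%s%s>\n",
              length(x$coefficients), x$log_likelihood,
              if (x$separation_flag) ", SEPARATION" else "",
              if (!x$converged) ", not converged" else ""))
  print(round(x$coefficients, 6))
  invisible(x)
}
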
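# Lean IRLS for the profiled binomial-logit fits used in the split search.
# The candidate scan warm-starts each fit from a neighbouring solution, so
# most calls converge in 2-3 iterations; anything irregular (rank
# deficiency, non-finite work vectors, failure to converge) falls back to
# stats::glm.fit. Returns list(coefficients, deviance, converged) or NULL.
logit_irls <- function(X, y, start, maxit = 100L, eps = 1e-8) {
  k <- ncol(X)
  beta <- if (is.null(start)) numeric(k) else start
  eta <- drop(X %*% beta)
  dev <- binomial_dev(y, eta)
  if (!is.finite(dev)) { beta <- numeric(k); eta <- rep(0, length(y)); dev <- binomial_dev(y, eta) }
  for (it in seq_len(maxit)) {
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    sw <- sqrt(w)
    fit <- .lm.fit(X * sw, z * sw)
    if (fit$rank < k) return(NULL)
    bn <- numeric(k)
    bn[fit$pivot] <- fit$coefficients
    eta_n <- drop(X %*% bn)
    dev_n <- binomial_dev(y, eta_n)
    # step-halve towards the current iterate if the update misbehaves
    h <- 0L
    while ((!is.finite(dev_n) || dev_n > dev + 1e-8) && h < 12L) {
      bn <- (bn + beta) / 2
      eta_n <- drop(X %*% bn)
      dev_n <- binomial_dev(y, eta_n)
      h <- h + 1L
    }
    if (!is.finite(dev_n)) return(NULL)
    done <- abs(dev_n - dev) / (abs(dev_n) + 0.1) < eps
    beta <- bn; eta <- eta_n; dev <- dev_n
    if (done) return(list(coefficients = beta, deviance = dev, converged = TRUE))
  }
  list(coefficients = beta, deviance = dev, converged = FALSE)
}

# binomial deviance (-2 log-likelihood) for 0/1 responses on the logit scale
binomial_dev <- function(y, eta) {
  # log(1 + exp(-|eta|)) is stable; y in {0,1}
  2 * sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
}
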
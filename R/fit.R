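#' Fit the log-linear Bradley-Terry model
#'
#' Maximum-likelihood fit of the two-cell Poisson representation of the
#' Bradley-Terry model, with the per-comparison nuisance parameters profiled
#' out analytically: because each pair of cells is constrained to sum to its
#' observed total of 1, the structural parameters can equivalently be
#' estimated by a binomial-logit fit on the binary outcomes with linear
#' predictor `2 * (lambda_i,h - lambda_j,h)`. The reported deviance is the
#' Poisson deviance over the cells, which coincides with the binomial
#' residual deviance of the profiled fit.
#'
#' @param design An [build_design()] object.
#' @param start Optional starting coefficients.
#' @return An object of class `llbt_fit` with components `coefficients`,
#'   `lambda` (object worths, reference object fixed at 0), `beta_main`
#'   (covariate-by-object matrix), `beta_region`, `deviance`, `df_residual`,
#'   `fitted` (per-comparison probability that the lower-indexed object
#'   wins), `pearson`, `dispersion` (Pearson chi-square / residual df),
#'   `se`, `se_corrected` (`se * sqrt(dispersion)`), `vcov`, `converged`
#'   and `boundary`. Non-convergence is flagged, not raised.
#' @examples
#' p <- pairs_from_rankings(rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3)))
#' fit <- llbt_fit(build_design(p))
#' fit$lambda
#' @export
llbt_fit <- function(design, start = NULL) {
  stopifnot(inherits(design, "llbt_design"))
  X2 <- 2 * design$X
  y <- design$y
  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100L)
  warn <- character(0)
  fit <- withCallingHandlers(
    stats::glm.fit(X2, y, family = stats::binomial(), start = start,
                   control = ctl),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  coefs <- fit$coefficients
  dropped <- names(coefs)[is.na(coefs)]
  coefs[is.na(coefs)] <- 0
  p <- fit$fitted.values
  boundary <- any(p < 1e-10 | p > 1 - 1e-10)

  # observed information for the structural parameters
  w <- pmax(p * (1 - p), 1e-12)
  XtWX <- crossprod(X2 * sqrt(w))
  vc <- tryCatch(solve(XtWX),
                 error = function(e) matrix(NA_real_, ncol(X2), ncol(X2)))
  dimnames(vc) <- list(colnames(design$X), colnames(design$X))
  se <- sqrt(pmax(diag(vc), 0))

  n_o <- length(design$objects)
  lambda <- c(coefs[seq_len(n_o - 1L)], 0)
  names(lambda) <- design$objects

  beta_main <- NULL
  if (length(design$covariate_names)) {
    beta_main <- matrix(coefs[n_o:(n_o - 1 + length(design$covariate_names) * (n_o - 1))],
                        nrow = length(design$covariate_names),
                        ncol = n_o - 1L, byrow = TRUE,
                        dimnames = list(design$covariate_names,
                                        design$objects[seq_len(n_o - 1L)]))
  }
  beta_region <- NULL
  if (length(design$region_names)) {
    k0 <- (n_o - 1L) * (1L + length(design$covariate_names))
    beta_region <- matrix(coefs[(k0 + 1L):(k0 + length(design$region_names) * (n_o - 1L))],
                          nrow = length(design$region_names),
                          ncol = n_o - 1L, byrow = TRUE,
                          dimnames = list(design$region_names,
                                          design$objects[seq_len(n_o - 1L)]))
  }

  np <- length(y)
  pearson <- sum((y - p)^2 / w)
  df <- np - (ncol(design$X) - length(dropped))
  dispersion <- if (df > 0) pearson / df else NA_real_

  structure(list(coefficients = coefs, lambda = lambda,
                 beta_main = beta_main, beta_region = beta_region,
                 deviance = fit$deviance, df_residual = df,
                 fitted = p, y = y, pearson = pearson,
                 dispersion = dispersion,
                 se = se, se_corrected = se * sqrt(dispersion),
                 vcov = vc, design = design,
                 converged = isTRUE(fit$converged) && !boundary,
                 boundary = boundary, dropped = dropped,
                 messages = unique(warn)),
            class = "llbt_fit")
}

#' Preference probability from two worths
#'
#' The probability that an object with worth `lambda_i` is preferred to one
#' with worth `lambda_j` on the half-log-worth scale:
#' `exp(2 (lambda_i - lambda_j)) / (1 + exp(2 (lambda_i - lambda_j)))`.
#' Numerically stable for large differences.
#'
#' @param lambda_i,lambda_j Worth parameters (vectorized).
#' @return Probabilities in (0, 1).
#' @examples
#' preference_probability(0.9, 0)  # ~0.858
#' @export
preference_probability <- function(lambda_i, lambda_j) {
  stats::plogis(2 * (lambda_i - lambda_j))
}

#' Poisson deviance over cells
#'
#' `D = 2 * sum(y * log(y / m))` with the convention `0 * log(0/m) = 0`;
#' fitted means are clipped to `[1e-10, 1 - 1e-10]` before the log.
#'
#' @param y Observed cell counts.
#' @param m Fitted cell means.
#' @return The deviance.
#' @export
poisson_deviance <- function(y, m) {
  stopifnot(length(y) == length(m))
  m <- pmin(pmax(m, 1e-10), 1 - 1e-10)
  pos <- y > 0
  2 * sum(y[pos] * log(y[pos] / m[pos]))
}

#' Overdispersion of a fitted model
#'
#' Pearson chi-square divided by the residual degrees of freedom; corrected
#' standard errors are the raw ones times `sqrt(dispersion)`.
#'
#' @param fit An [llbt_fit()] object.
#' @return The dispersion estimate (NA when the residual df is not positive).
#' @export
estimate_dispersion <- function(fit) {
  stopifnot(inherits(fit, "llbt_fit"))
  fit$dispersion
}

#' @export
print.llbt_fit <- function(x, ...) {
  n_o <- length(x$lambda)
  cat(sprintf("Log-linear Bradley-Terry fit: %d objects, deviance %.2f on %d df\n",
              n_o, x$deviance, x$df_residual))
  cat("Worth parameters (reference fixed at 0):\n")
  print(round(x$lambda, 4))
  if (!x$converged) cat("NOTE: fit flagged as non-converged or on the boundary\n")
  invisible(x)
}

#' @export
coef.llbt_fit <- function(object, ...) object$coefficients

#' @export
vcov.llbt_fit <- function(object, ...) object$vcov

#' @export
deviance.llbt_fit <- function(object, ...) object$deviance

#' Coefficient table of a fitted model
#'
#' @param object An `llbt_fit`.
#' @param ... Unused.
#' @return Data frame with estimate, raw and overdispersion-corrected
#'   standard errors per structural coefficient.
#' @export
summary.llbt_fit <- function(object, ...) {
  out <- data.frame(coefficient = names(object$coefficients),
                    estimate = unname(object$coefficients),
                    se = unname(object$se),
                    se_corrected = unname(object$se_corrected),
                    stringsAsFactors = FALSE)
  attr(out, "deviance") <- object$deviance
  attr(out, "dispersion") <- object$dispersion
  class(out) <- c("summary.llbt_fit", "data.frame")
  out
}

#' @export
print.summary.llbt_fit <- function(x, ...) {
  cat(sprintf("Deviance %.2f, dispersion %.3f\n",
              attr(x, "deviance"), attr(x, "dispersion")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
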
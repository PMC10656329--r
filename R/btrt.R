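#' Fit a Bradley-Terry regression trunk
#'
#' The main modelling interface. Converts complete rankings to paired
#' comparisons (if needed), fits the log-linear Bradley-Terry model with
#' linear covariate main effects, grows a regression trunk of threshold
#' interactions by the deviance-driven split search, cross-validates the
#' case-wise deviance at the judge level, and prunes the trunk with the
#' c standard error rule.
#'
#' @param rankings Complete rankings ([as_rankings()]) or paired
#'   comparisons ([as_pairs()]).
#' @param covariates Data frame with a `judge` column and numeric
#'   subject-specific covariates (dichotomous ones coded 0/1).
#' @param mode Split search mode: `"ms"` (multiple splitting, default) or
#'   `"oso"` (one split only per covariate).
#' @param max_terminals Maximum number of terminal nodes grown before
#'   pruning.
#' @param min_bucket Minimum number of judges per child node.
#' @param folds Number of cross-validation folds `V`.
#' @param c Pruning multiplier for the c standard error rule.
#' @param cv_repeats Repetitions of the V-fold cross-validation (averaged).
#' @param prune If `FALSE`, the full-grown trunk is kept (no CV).
#' @param seed Optional seed controlling the fold assignment.
#' @return An object of class `btrt` with components `trunk`, `cv`
#'   (a [cv_profile()] object or `NULL`), `size` (selected number of
#'   splits), `fit` (the selected [llbt_fit()]), `pairs`, `covariates`,
#'   `rankings` (when recoverable) and `call`. Methods: `print`, `summary`,
#'   `coef`, `vcov`, `deviance`, `predict`, `residuals`, `simulate`,
#'   `plot`.
#' @examples
#' sim <- simulate_preferences(scenario_config(3, judges = 80, effect = "high"),
#'                             seed = 7)
#' m <- btrt(sim$pairs, sim$covariates, mode = "oso", max_terminals = 3,
#'           folds = 5, c = 0.5, seed = 1)
#' m
#' @export
btrt <- function(rankings, covariates, mode = c("ms", "oso"),
                 max_terminals = 5, min_bucket = 5, folds = 10, c = 0.5,
                 cv_repeats = 1, prune = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (inherits(rankings, "btrt_pairs")) {
    pairs <- rankings
    rk <- if (isTRUE(attr(pairs, "derived_from_rankings")))
      as_rankings(ranks_from_pairs(pairs)) else NULL
  } else {
    rk <- as_rankings(rankings)
    pairs <- pairs_from_rankings(rk)
  }
  trunk <- grow_trunk(pairs, covariates, mode = mode,
                      max_terminals = max_terminals, min_bucket = min_bucket)
  n_grown <- nrow(trunk$split_history)
  cv <- NULL
  size <- n_grown
  if (prune && n_grown > 0) {
    cv <- cv_profile(trunk, V = folds, repeats = cv_repeats, seed = seed)
    size <- prune_select(cv, c = c)
  }
  structure(list(trunk = trunk, cv = cv, c = c, size = size,
                 fit = trunk$fits[[size + 1L]],
                 pairs = pairs, covariates = covariates, rankings = rk,
                 call = cl),
            class = "btrt")
}

#' @export
print.btrt <- function(x, ...) {
  cat("Bradley-Terry regression trunk\n")
  cat(sprintf("  mode %s, %d split%s grown, %d retained after pruning (c = %g)\n",
              toupper(x$trunk$mode), nrow(x$trunk$split_history),
              if (nrow(x$trunk$split_history) == 1) "" else "s",
              x$size, x$c))
  if (x$size > 0) {
    h <- x$trunk$split_history[seq_len(x$size), ]
    for (s in seq_len(nrow(h)))
      cat(sprintf("  split %d: node %d, %s <= %g\n",
                  s, h$node[s], h$covariate[s], h$value[s]))
  }
  cat(sprintf("  deviance %.2f on %d df, dispersion %.3f\n",
              x$fit$deviance, x$fit$df_residual, x$fit$dispersion))
  cat("Worth intercepts (reference region, covariates at 0; last object = 0):\n")
  print(round(x$fit$lambda, 4))
  invisible(x)
}

#' @export
coef.btrt <- function(object, ...) object$fit$coefficients

#' @export
vcov.btrt <- function(object, ...) object$fit$vcov

#' @export
deviance.btrt <- function(object, ...) object$fit$deviance

#' @rdname btrt
#' @param object,x A fitted `btrt` object.
#' @param ... Passed on or ignored.
#' @export
summary.btrt <- function(object, ...) {
  out <- list(call = object$call,
              coefficients = summary(object$fit),
              splits = split_table(object$trunk),
              size = object$size, c = object$c,
              cv = if (!is.null(object$cv)) object$cv$profile,
              regions = lapply(region_predicates(object$trunk, object$size),
                               predicate_string),
              consensus = NULL)
  if (!is.null(object$rankings) &&
      length(object$trunk$objects) <= 6)
    out$consensus <- consensus_by_node(object$trunk, object$rankings,
                                       t = object$size)
  class(out) <- "summary.btrt"
  out
}

#' @export
print.summary.btrt <- function(x, ...) {
  cat("Bradley-Terry regression trunk\n\nSplit sequence:\n")
  print(format(x$splits, digits = 6), row.names = FALSE)
  if (!is.null(x$cv)) {
    cat(sprintf("\nCross-validated deviance (selected model %d at c = %g):\n",
                x$size, x$c))
    print(format(x$cv, digits = 4), row.names = FALSE)
  }
  cat("\nTerminal regions (R1 = reference):\n")
  for (nm in names(x$regions)) cat(sprintf("  %s: %s\n", nm, x$regions[[nm]]))
  if (!is.null(x$consensus)) {
    cat("\nPer-node consensus rankings:\n")
    print(format(x$consensus, digits = 3), row.names = FALSE)
  }
  cat("\nCoefficients:\n")
  print(x$coefficients)
  invisible(x)
}

# worth matrix lambda_{i,h} for a covariate table under a size-t model of a
# trunk: consensus worths + covariate main effects + region effects, with
# region membership determined by the trunk's threshold predicates
model_worths <- function(fit, trunk, t, newdata) {
  n_o <- length(fit$lambda)
  L <- matrix(fit$lambda, nrow(newdata), n_o, byrow = TRUE,
              dimnames = list(NULL, names(fit$lambda)))
  if (!is.null(fit$beta_main)) {
    xm <- as.matrix(newdata[rownames(fit$beta_main)])
    L[, seq_len(n_o - 1L)] <- L[, seq_len(n_o - 1L)] + xm %*% fit$beta_main
  }
  if (!is.null(fit$beta_region)) {
    preds <- region_predicates(trunk, t)
    for (rn in rownames(fit$beta_region)) {
      member <- eval_predicate(preds[[rn]], newdata)
      L[, seq_len(n_o - 1L)] <- L[, seq_len(n_o - 1L)] +
        as.numeric(member) %o% fit$beta_region[rn, ]
    }
  }
  L
}

btrt_worths <- function(object, newdata) {
  model_worths(object$fit, object$trunk, object$size, newdata)
}

#' Predict worths or pairwise preference probabilities
#'
#' @param object A fitted [btrt()] model.
#' @param newdata Data frame of covariates (defaults to the training
#'   judges). Judges are assigned to trunk regions by the fitted threshold
#'   predicates.
#' @param type `"worth"` for the judge-by-object worth matrix
#'   `lambda_{i,h}`, `"pair"` for the probability that the lower-indexed
#'   object of each pair is preferred.
#' @param ... Unused.
#' @return A matrix (judges in rows).
#' @export
predict.btrt <- function(object, newdata = NULL,
                         type = c("worth", "pair"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$covariates
  newdata <- as.data.frame(newdata)
  L <- btrt_worths(object, newdata)
  if (!is.null(newdata$judge)) rownames(L) <- as.character(newdata$judge)
  if (type == "worth") return(L)
  pg <- pair_grid(ncol(L))
  P <- preference_probability(L[, pg[, "i"], drop = FALSE],
                              L[, pg[, "j"], drop = FALSE])
  colnames(P) <- paste(colnames(L)[pg[, "i"]], colnames(L)[pg[, "j"]],
                       sep = ">")
  rownames(P) <- rownames(L)
  P
}

#' @export
residuals.btrt <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  y <- object$fit$y
  p <- pmin(pmax(object$fit$fitted, 1e-10), 1 - 1e-10)
  if (type == "pearson") (y - p) / sqrt(p * (1 - p))
  else sign(y - p) * sqrt(-2 * log(ifelse(y == 1, p, 1 - p)))
}

#' Simulate paired comparisons from a fitted trunk model
#'
#' Draws new pairwise outcomes for the training judges from the fitted
#' preference probabilities, optionally projecting each judge's pattern
#' onto the closest permutation so the result corresponds to rankings.
#'
#' @param object A fitted [btrt()] model.
#' @param nsim Number of datasets.
#' @param seed Optional seed (RNG state restored).
#' @param project Apply the transitivity projection (default `TRUE`).
#' @param ... Unused.
#' @return A list of `btrt_pairs` objects of length `nsim`.
#' @export
simulate.btrt <- function(object, nsim = 1, seed = NULL, project = TRUE, ...) {
  with_seed(seed, {
    L <- btrt_worths(object, as.data.frame(object$covariates))
    judges <- as.character(object$covariates$judge)
    n_o <- ncol(L)
    pg <- pair_grid(n_o)
    np <- nrow(pg)
    pr <- preference_probability(L[, pg[, "i"], drop = FALSE],
                                 L[, pg[, "j"], drop = FALSE])
    lapply(seq_len(nsim), function(s) {
      ymat <- matrix(stats::rbinom(length(pr), 1L, pr), nrow(L), np)
      if (project) for (h in seq_len(nrow(L)))
        if (!check_transitivity(ymat[h, ], n_o)$allowed)
          ymat[h, ] <- project_to_nearest_permutation(ymat[h, ], n_o)
      new_pairs(data.frame(judge = rep(judges, each = np),
                           i = rep(pg[, "i"], nrow(L)),
                           j = rep(pg[, "j"], nrow(L)),
                           y = as.integer(t(ymat)), stringsAsFactors = FALSE),
                objects = object$trunk$objects, derived = project)
    })
  })
}

#' Plot a fitted regression trunk
#'
#' `what = "trunk"` draws the pruned tree with split conditions and leaf
#' sizes; `what = "cv"` plots the cross-validated deviance profile with
#' one-SE whiskers and marks the selected size.
#'
#' @param x A fitted [btrt()] model.
#' @param what `"trunk"` or `"cv"`.
#' @param ... Further graphical parameters (ignored).
#' @return Invisibly, `x`.
#' @export
plot.btrt <- function(x, what = c("trunk", "cv"), ...) {
  what <- match.arg(what)
  if (what == "cv") {
    if (is.null(x$cv)) stop("model was fitted without cross-validation")
    pr <- x$cv$profile
    graphics::plot(pr$model, pr$Dcv, type = "b", pch = 19,
                   xlab = "number of splits", ylab = "cross-validated deviance",
                   ylim = range(pr$Dcv - pr$SEcv, pr$Dcv + pr$SEcv))
    graphics::arrows(pr$model, pr$Dcv - pr$SEcv, pr$model, pr$Dcv + pr$SEcv,
                     angle = 90, code = 3, length = 0.03)
    graphics::abline(v = x$size, lty = 2)
    return(invisible(x))
  }
  ord <- terminals_at_size(x$trunk, x$size)
  pos <- new.env()
  assign_pos <- function(id) {
    if (id %in% ord) {
      p <- match(id, ord)
    } else {
      p <- mean(c(assign_pos(2L * id), assign_pos(2L * id + 1L)))
    }
    assign(as.character(id), p, envir = pos)
    p
  }
  assign_pos(1L)
  depth_of <- function(id) floor(log2(id))
  ids <- c(1L)
  all_ids <- function(id) {
    if (id %in% ord) return(id)
    c(id, all_ids(2L * id), all_ids(2L * id + 1L))
  }
  ids <- all_ids(1L)
  graphics::plot(NULL, xlim = c(0.5, length(ord) + 0.5),
                 ylim = c(-max(vapply(ids, depth_of, numeric(1))) - 0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "")
  for (id in ids) {
    xx <- get(as.character(id), envir = pos)
    yy <- -depth_of(id)
    nd <- x$trunk$nodes[[as.character(id)]]
    if (!id %in% ord) {
      for (ch in c(2L * id, 2L * id + 1L)) {
        graphics::segments(xx, yy, get(as.character(ch), envir = pos),
                           -depth_of(ch))
      }
      graphics::text(xx, yy + 0.18,
                     sprintf("%s <= %g", nd$split$covariate, nd$split$value),
                     cex = 0.8)
      graphics::points(xx, yy, pch = 21, bg = "white", cex = 2)
    } else {
      graphics::points(xx, yy, pch = 22, bg = "grey90", cex = 2.4)
      graphics::text(xx, yy - 0.25, sprintf("n=%d", length(nd$judges)),
                     cex = 0.8)
    }
  }
  invisible(x)
}
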
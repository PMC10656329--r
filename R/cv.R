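#' Assign judges to cross-validation folds
#'
#' Judges are partitioned at random into `V` folds of as equal size as
#' possible; all design rows of a judge share its fold, so no judge's
#' comparisons are split between training and test sets.
#'
#' @param judges Vector of judge identifiers.
#' @param V Number of folds, `2 <= V <= length(judges)`.
#' @param seed Optional seed (the RNG state is restored afterwards).
#' @return Integer vector of fold labels `1..V`, named by judge.
#' @export
assign_folds <- function(judges, V, seed = NULL) {
  H <- length(judges)
  if (V < 2 || V > H) stop("V must be between 2 and the number of judges")
  f <- with_seed(seed, sample(rep_len(seq_len(V), H)))
  names(f) <- judges
  f
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# case-wise deviance pieces for a set of comparisons: per design row,
# d_i = 2 * y_i * log(y_i / yhat_i); only the observed cell of each
# comparison contributes, its sibling cell contributes 0. Held-out
# probabilities are clipped to keep the log finite.
casewise_contributions <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  obs <- ifelse(y == 1L, p, 1 - p)
  cbind(obs = -2 * log(obs), other = 0)
}

#' Judge-level cross-validated deviance profile of a trunk
#'
#' For each fold, a trunk of the same maximum size is regrown from scratch
#' on the `V - 1` training folds (same mode, minimum bucket and split
#' search); for each size `t = 0..T-1` the fold's size-`t` model predicts
#' the held-out judges' cell means, assigning them to regions via the
#' fold-trunk's threshold predicates. Regrowing the structure inside each
#' fold keeps the split selection honest: thresholds chosen on the full
#' data would leak information about the held-out judges and spurious
#' splits would look beneficial out-of-fold. A fold whose trunk admits
#' fewer than `t` splits carries its largest model forward.
#'
#' The pooled case-wise cross-validation deviance over all `n` design rows
#' is `Dcv = (1/n) * 2 * sum(y * log(y / yhat))`, with standard error
#' `SEcv = (1/n) * sqrt((1/n) * sum((d_i - Dcv)^2))` computed from the
#' per-row contributions `d_i = 2 * y_i * log(y_i / yhat_i)`.
#' With `repeats > 1` the whole procedure is repeated on fresh fold
#' assignments and the profiles averaged.
#'
#' @param trunk A [grow_trunk()] result.
#' @param V Number of folds (default 10).
#' @param folds Optional precomputed fold assignment from [assign_folds()].
#' @param repeats Number of repetitions of the V-fold procedure.
#' @param seed Optional seed for the fold assignment(s).
#' @return An object of class `btrt_cv`: a data frame `profile` with
#'   columns `model` (number of splits), `D` (training deviance of the
#'   full-data trunk), `Dcv`, `SEcv`, plus the fold assignments used.
#' @export
cv_profile <- function(trunk, V = 10, folds = NULL, repeats = 1, seed = NULL) {
  stopifnot(inherits(trunk, "btrt_trunk"))
  if (!length(trunk$fits)) stop("trunk carries no fitted model sequence")
  dat <- trunk$data
  pairs <- dat$pairs
  judges <- trunk$judges
  cov_df <- data.frame(judge = judges, dat$covmat, stringsAsFactors = FALSE,
                       check.names = FALSE)
  n_sizes <- nrow(trunk$split_history) + 1L
  n <- 2L * length(dat$design$y)

  assignments <- if (!is.null(folds)) list(folds) else with_seed(seed,
    lapply(seq_len(repeats), function(r) assign_folds(judges, V)))

  prof_one <- function(assign) {
    d_rows <- vector("list", n_sizes)
    for (v in sort(unique(assign))) {
      trainj <- judges[assign[judges] != v]
      testj <- setdiff(judges, trainj)
      ft <- suppressWarnings(grow_trunk(
        subset_pairs(pairs, trainj),
        cov_df[match(trainj, cov_df$judge), , drop = FALSE],
        mode = trunk$mode, max_terminals = trunk$max_terminals,
        min_bucket = trunk$min_bucket))
      test_cov <- cov_df[match(testj, cov_df$judge), , drop = FALSE]
      te <- which(pairs$judge %in% testj)
      jh <- match(pairs$judge[te], testj)
      for (s in seq_len(n_sizes)) {
        tt <- min(s - 1L, nrow(ft$split_history))
        fit <- ft$fits[[tt + 1L]]
        L <- model_worths(fit, ft, tt, test_cov)
        p <- preference_probability(L[cbind(jh, pairs$i[te])],
                                    L[cbind(jh, pairs$j[te])])
        d_rows[[s]] <- c(d_rows[[s]],
                         as.vector(casewise_contributions(pairs$y[te], p)))
      }
    }
    Dcv <- vapply(d_rows, function(d) sum(d) / n, numeric(1))
    SEcv <- vapply(seq_len(n_sizes), function(s)
      sqrt(mean((d_rows[[s]] - Dcv[s])^2)) / n, numeric(1))
    cbind(Dcv, SEcv)
  }

  acc <- lapply(assignments, prof_one)
  profile <- data.frame(
    model = seq_len(n_sizes) - 1L,
    D = vapply(trunk$fits, function(f) f$deviance, numeric(1)),
    Dcv = rowMeans(sapply(acc, function(a) a[, "Dcv"])),
    SEcv = rowMeans(sapply(acc, function(a) a[, "SEcv"])))
  structure(list(profile = profile, folds = assignments, V = V,
                 repeats = length(assignments)),
            class = "btrt_cv")
}

#' @export
print.btrt_cv <- function(x, ...) {
  cat(sprintf("%d-fold judge-level cross-validation (%d repeat%s)\n",
              x$V, x$repeats, if (x$repeats > 1) "s" else ""))
  print(format(x$profile, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Select the trunk size by the c standard error rule
#'
#' Let `t*` be the size minimizing the cross-validated deviance (smallest
#' size on ties). The selected size `t**` is the smallest `t` with
#' `Dcv_t <= Dcv_t* + c * SEcv_t*`. With `c = 0` this is the minimizer
#' itself; larger `c` never selects a larger trunk.
#'
#' @param profile A [cv_profile()] object, or any data frame with columns
#'   `Dcv` and `SEcv` (and optionally `model`).
#' @param c Nonnegative pruning multiplier.
#' @return The selected model index (number of splits).
#' @examples
#' prof <- data.frame(model = 0:2, Dcv = c(0.60, 0.55, 0.56),
#'                    SEcv = c(0.01, 0.01, 0.01))
#' prune_select(prof, c = 0)    # 1
#' prune_select(prof, c = 5)    # 0
#' @export
prune_select <- function(profile, c = 0.5) {
  stopifnot(c >= 0)
  df <- if (inherits(profile, "btrt_cv")) profile$profile else as.data.frame(profile)
  if (is.null(df$model)) df$model <- seq_len(nrow(df)) - 1L
  t_star <- which.min(df$Dcv)
  thr <- df$Dcv[t_star] + c * df$SEcv[t_star]
  df$model[which(df$Dcv <= thr)[1L]]
}
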
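# Simulated effect sizes for the three data-generating scenarios.
# Rows: covariates x1..x4 plus the threshold-interaction effect; columns:
# objects, last object always 0 (reference). Scenario 1 uses x1 only,
# scenario 2 adds x2..x4, scenario 3 adds the interaction row.
beta_table <- function(n_objects, effect) {
  if (n_objects == 4) {
    low <- rbind(x1 = c(0.30, 0.20, 0.10, 0.00),
                 x2 = c(0.20, 0.30, 0.10, 0.00),
                 x3 = c(0.10, 0.20, 0.30, 0.00),
                 x4 = c(0.30, 0.10, 0.20, 0.00),
                 interaction = c(0.25, 0.15, 0.35, 0.00))
    high <- rbind(x1 = c(0.90, 0.80, 0.70, 0.00),
                  x2 = c(0.80, 0.70, 0.90, 0.00),
                  x3 = c(0.70, 0.90, 0.80, 0.00),
                  x4 = c(0.90, 0.70, 0.80, 0.00),
                  interaction = c(0.55, 0.65, 0.45, 0.00))
  } else if (n_objects == 5) {
    low <- rbind(x1 = c(0.40, 0.30, 0.20, 0.10, 0.00),
                 x2 = c(0.30, 0.20, 0.10, 0.40, 0.00),
                 x3 = c(0.20, 0.10, 0.30, 0.40, 0.00),
                 x4 = c(0.10, 0.20, 0.40, 0.30, 0.00),
                 interaction = c(0.25, 0.15, 0.35, 0.45, 0.00))
    high <- rbind(x1 = c(0.90, 0.80, 0.70, 0.60, 0.00),
                  x2 = c(0.80, 0.90, 0.60, 0.70, 0.00),
                  x3 = c(0.70, 0.60, 0.80, 0.90, 0.00),
                  x4 = c(0.90, 0.70, 0.60, 0.80, 0.00),
                  interaction = c(0.55, 0.65, 0.45, 0.60, 0.00))
  } else stop("n_objects must be 4 or 5")
  b <- if (effect == "low") low else high
  colnames(b) <- LETTERS[seq_len(n_objects)]
  b
}

#' Specify a data-generating scenario for simulated preference data
#'
#' Three scenarios over four standard-normal subject covariates: (1) a
#' single active covariate `x1`; (2) four active covariates; (3) four
#' active covariates plus a threshold interaction
#' `I(x1 > 0 & x2 > 0.5)` with its own object effects. The consensus worths
#' are `(0.9, 0.4, 0.3, 0)` for four objects and `(0.8, 0.4, 0.2, 0.1, 0)`
#' for five; covariate effects come in a low and a high effect-size version.
#' All four covariates are always generated and supplied to the fitted
#' model; inactive ones have zero coefficients.
#'
#' @param scenario 1, 2 or 3.
#' @param n_objects 4 or 5.
#' @param judges Number of judges `H`.
#' @param effect `"low"` or `"high"`.
#' @return An object of class `btrt_scenario`.
#' @export
scenario_config <- function(scenario = 1, n_objects = 4, judges = 100,
                            effect = c("low", "high")) {
  effect <- match.arg(effect)
  stopifnot(scenario %in% 1:3)
  lambda <- if (n_objects == 4) c(0.9, 0.4, 0.3, 0.0)
            else c(0.8, 0.4, 0.2, 0.1, 0.0)
  names(lambda) <- LETTERS[seq_len(n_objects)]
  b <- beta_table(n_objects, effect)
  beta <- b[paste0("x", 1:4), , drop = FALSE]
  if (scenario == 1) beta[c("x2", "x3", "x4"), ] <- 0
  beta_int <- if (scenario == 3) b["interaction", ] else NULL
  structure(list(scenario = scenario, n_objects = n_objects,
                 judges = judges, effect = effect,
                 lambda = lambda, beta = beta, beta_interaction = beta_int),
            class = "btrt_scenario")
}

#' @export
print.btrt_scenario <- function(x, ...) {
  cat(sprintf("DGP scenario %d: %d objects, %d judges, %s effect%s\n",
              x$scenario, x$n_objects, x$judges, x$effect,
              if (x$scenario == 3) ", interaction I(x1 > 0 & x2 > 0.5)" else ""))
  invisible(x)
}

# judge-level worths lambda_{i,h} under a scenario
scenario_worths <- function(config, xmat) {
  L <- matrix(config$lambda, nrow(xmat), config$n_objects, byrow = TRUE)
  L <- L + xmat %*% config$beta
  if (!is.null(config$beta_interaction)) {
    act <- as.numeric(xmat[, "x1"] > 0 & xmat[, "x2"] > 0.5)
    L <- L + act %o% config$beta_interaction
  }
  colnames(L) <- names(config$lambda)
  L
}

#' Simulate paired-comparison preference data under a scenario
#'
#' Draws four standard-normal covariates per judge, computes judge-level
#' worths under the scenario, draws each pairwise outcome as a Bernoulli
#' variable with success probability
#' `exp(2 (lambda_i,h - lambda_j,h)) / (1 + exp(2 (lambda_i,h - lambda_j,h)))`,
#' and (by default) replaces any intransitive outcome pattern by the closest
#' permutation pattern (Hamming distance, uniform tie-break), so the output
#' always corresponds to complete rankings.
#'
#' @param config A [scenario_config()] object.
#' @param seed Optional seed (RNG state restored on exit).
#' @param project If `FALSE`, raw Bernoulli patterns are returned without
#'   the transitivity projection (useful for calibration checks).
#' @return A list with `pairs` (a `btrt_pairs` object), `covariates` (data
#'   frame with `judge`, `x1..x4`), `worths` (the generating worth matrix)
#'   and `n_projected` (judges whose pattern needed projection).
#' @export
simulate_preferences <- function(config, seed = NULL, project = TRUE) {
  stopifnot(inherits(config, "btrt_scenario"))
  with_seed(seed, {
    H <- config$judges
    n_o <- config$n_objects
    xmat <- matrix(stats::rnorm(H * 4), H, 4,
                   dimnames = list(NULL, paste0("x", 1:4)))
    L <- scenario_worths(config, xmat)
    pg <- pair_grid(n_o)
    np <- nrow(pg)
    pr <- preference_probability(L[, pg[, "i"], drop = FALSE],
                                 L[, pg[, "j"], drop = FALSE])
    ymat <- matrix(stats::rbinom(H * np, 1L, pr), H, np)
    n_proj <- 0L
    if (project) {
      for (h in seq_len(H)) {
        chk <- check_transitivity(ymat[h, ], n_o)
        if (!chk$allowed) {
          ymat[h, ] <- project_to_nearest_permutation(ymat[h, ], n_o)
          n_proj <- n_proj + 1L
        }
      }
    }
    judges <- sprintf("j%03d", seq_len(H))
    pairs <- new_pairs(data.frame(judge = rep(judges, each = np),
                                  i = rep(pg[, "i"], H),
                                  j = rep(pg[, "j"], H),
                                  y = as.integer(t(ymat)),
                                  stringsAsFactors = FALSE),
                       objects = names(config$lambda), derived = project)
    list(pairs = pairs,
         covariates = data.frame(judge = judges, xmat,
                                 stringsAsFactors = FALSE),
         worths = L, n_projected = n_proj)
  })
}

#' Estimate type I error or power of the pruning rule by simulation
#'
#' Replicates the pipeline simulate -> grow (to `max_terminals`) ->
#' cross-validate -> prune at each `c`. Under scenarios 1 and 2 (no true
#' interaction) the reported metric is the type I error: the proportion of
#' replicates whose pruned trunk retains at least one split. Under scenario
#' 3 it is the power: the proportion whose pruned trunk splits on exactly
#' the truly interacting covariates {x1, x2}.
#'
#' @param config A [scenario_config()] object.
#' @param c_grid Numeric vector of pruning multipliers to evaluate.
#' @param reps Number of simulation replicates.
#' @param V Folds for the judge-level cross-validation.
#' @param max_terminals,min_bucket,mode Passed to [grow_trunk()]; the
#'   default mode is one-split-only so that distinct covariates split
#'   distinct nodes.
#' @param seed Optional master seed; per-replicate substreams are derived
#'   from it.
#' @return An object of class `btrt_study`: a table with one row per `c`
#'   (`metric`, `events`, `reps`), the binary replicate outcomes, and the
#'   count of failed replicates (excluded, with the error messages kept).
#' @export
run_study <- function(config, c_grid = c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1),
                      reps = 25, V = 10, max_terminals = 5, min_bucket = 5,
                      mode = "oso", seed = NULL) {
  stopifnot(inherits(config, "btrt_scenario"), reps >= 1)
  with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max, reps)
    outcomes <- matrix(NA, reps, length(c_grid),
                       dimnames = list(NULL, paste0("c", c_grid)))
    sizes <- matrix(NA_integer_, reps, length(c_grid))
    failures <- character(0)
    for (r in seq_len(reps)) {
      res <- tryCatch({
        sim <- simulate_preferences(config, seed = rep_seeds[r])
        trunk <- suppressWarnings(
          grow_trunk(sim$pairs, sim$covariates, mode = mode,
                     max_terminals = max_terminals, min_bucket = min_bucket))
        cv <- suppressWarnings(cv_profile(trunk, V = V))
        vapply(c_grid, function(cc) {
          t2 <- prune_select(cv, cc)
          if (config$scenario == 3) {
            covs <- trunk$split_history$covariate[seq_len(t2)]
            as.numeric(setequal(covs, c("x1", "x2")) && t2 == 2L)
          } else as.numeric(t2 >= 1L)
        }, numeric(1))
      }, error = function(e) e)
      if (inherits(res, "error")) failures <- c(failures, conditionMessage(res))
      else outcomes[r, ] <- res
    }
    ok <- !is.na(outcomes[, 1])
    tab <- data.frame(c = c_grid,
                      metric = colMeans(outcomes[ok, , drop = FALSE]),
                      events = colSums(outcomes[ok, , drop = FALSE]),
                      reps = sum(ok))
    structure(list(table = tab, outcomes = outcomes, config = config,
                   metric = if (config$scenario == 3) "power" else "type I error",
                   n_failed = sum(!ok), failures = failures),
              class = "btrt_study")
  })
}

#' @export
print.btrt_study <- function(x, ...) {
  print(x$config)
  cat(sprintf("Metric: %s over %d replicates%s\n", x$metric, x$table$reps[1],
              if (x$n_failed) sprintf(" (%d failed, excluded)", x$n_failed) else ""))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Parameter recovery of the root model under a scenario
#'
#' Repeatedly simulates data under `config`, fits the main-effects model,
#' and compares each covariate-by-object coefficient with its generating
#' value using the overdispersion-corrected standard errors.
#'
#' @param config A [scenario_config()] with at least one nonzero effect.
#' @param reps Number of replicates.
#' @param seed Optional master seed.
#' @param k Half-width of the recovery interval in corrected SEs.
#' @return An object of class `btrt_recovery`: per-replicate coefficient
#'   table (`estimate`, `truth`, `se_corrected`, `covered`), the overall
#'   coverage proportion, and the proportion of replicates whose estimated
#'   worth ordering matches the generating consensus order.
#' @export
recover_parameters <- function(config, reps = 20, seed = NULL, k = 3) {
  stopifnot(inherits(config, "btrt_scenario"))
  with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max, reps)
    rows <- list()
    order_ok <- logical(reps)
    for (r in seq_len(reps)) {
      sim <- simulate_preferences(config, seed = rep_seeds[r])
      fit <- llbt_fit(build_design(sim$pairs, sim$covariates))
      n_o <- config$n_objects
      truth <- config$beta[, seq_len(n_o - 1L), drop = FALSE]
      est <- fit$beta_main
      semat <- matrix(fit$se_corrected[(n_o):(n_o - 1L + 4L * (n_o - 1L))],
                      nrow = 4, byrow = TRUE, dimnames = dimnames(est))
      rows[[r]] <- data.frame(rep = r,
                              coefficient = paste(rep(rownames(est), ncol(est)),
                                                  rep(colnames(est), each = nrow(est)),
                                                  sep = ":"),
                              estimate = as.vector(est),
                              truth = as.vector(truth),
                              se_corrected = as.vector(semat),
                              stringsAsFactors = FALSE)
      order_ok[r] <- identical(order(-fit$lambda), order(-config$lambda))
    }
    out <- do.call(rbind, rows)
    out$covered <- abs(out$estimate - out$truth) <= k * out$se_corrected
    structure(list(coefficients = out, coverage = mean(out$covered), k = k,
                   order_recovery = mean(order_ok), config = config),
              class = "btrt_recovery")
  })
}

#' @export
print.btrt_recovery <- function(x, ...) {
  print(x$config)
  cat(sprintf("Coverage within %g corrected SEs: %.1f%%; consensus order recovered in %.0f%% of replicates\n",
              x$k, 100 * x$coverage, 100 * x$order_recovery))
  invisible(x)
}
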
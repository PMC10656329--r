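# fixtures built in code: random complete rankings and small covariate tables

random_rankings <- function(H, n_o) {
  m <- t(vapply(seq_len(H), function(h) sample.int(n_o), integer(n_o)))
  as_rankings(m)
}

random_covariates <- function(judges, P = 2) {
  x <- matrix(rnorm(length(judges) * P), length(judges), P,
              dimnames = list(NULL, paste0("x", seq_len(P))))
  data.frame(judge = judges, x, stringsAsFactors = FALSE)
}

# a scenario config with every covariate effect silenced (pure consensus BT)
null_scenario <- function(n_objects = 4, judges = 100) {
  cfg <- scenario_config(1, n_objects = n_objects, judges = judges)
  cfg$beta[] <- 0
  cfg
}

# independent first-split oracle: exhaustive candidate scan re-fitting the
# full model per candidate through the public design/fit interface
oracle_first_split <- function(pairs, covariates, min_bucket = 5) {
  cm <- as.matrix(covariates[setdiff(names(covariates), "judge")])
  f0 <- llbt_fit(build_design(pairs, covariates))
  best <- NULL
  for (p in seq_len(ncol(cm))) {
    vals <- sort(unique(cm[, p]))
    for (v in vals[-length(vals)]) {
      nl <- sum(cm[, p] <= v)
      if (nl < min_bucket || nrow(cm) - nl < min_bucket) next
      reg <- list(R2 = covariates$judge[cm[, p] <= v])
      f <- llbt_fit(build_design(pairs, covariates, regions = reg))
      if (is.null(best) || f$deviance < best$deviance - 1e-6)
        best <- list(covariate = colnames(cm)[p], value = v,
                     deviance = f$deviance, drop = f0$deviance - f$deviance)
    }
  }
  best
}
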
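#' Build the log-linear Bradley-Terry design
#'
#' Assembles the design for the two-cell-per-comparison Poisson
#' representation of the Bradley-Terry model with subject covariates and
#' optional trunk-region indicators. Each (judge, pair) comparison occupies
#' two cells sharing a nuisance parameter that fixes the pair total at 1;
#' structural columns use the signed contrast coding, with the last object
#' in label order as reference.
#'
#' The full design has `n = n_o * (n_o - 1) * H` rows. Structural columns
#' comprise `n_o - 1` object contrasts, `P * (n_o - 1)` covariate-by-object
#' columns and `(T - 1) * (n_o - 1)` region-by-object columns, matching the
#' parameter count `(n_o - 1) * (1 + P + T - 1)`.
#'
#' @param pairs A [as_pairs()]/[pairs_from_rankings()] object.
#' @param covariates Optional data frame with a `judge` column and numeric
#'   subject-specific covariates, one row per judge (dichotomous covariates
#'   coded 0/1). `NULL` for an intercept-only model.
#' @param regions Optional named list of disjoint judge subsets defining the
#'   non-reference terminal regions of a trunk; each element is a logical
#'   vector over the judges (in `unique(pairs$judge)` order) or a character
#'   vector of judge identifiers.
#' @return An object of class `llbt_design` holding the condensed (one row
#'   per comparison) response and structural matrix used for fitting;
#'   `as.data.frame()` expands it to the audit-friendly two-rows-per-cell
#'   layout with cell identifiers and signs.
#' @seealso [llbt_fit()], [count_parameters()]
#' @examples
#' p <- pairs_from_rankings(rbind(c(1, 2, 3), c(2, 1, 3)))
#' d <- build_design(p)
#' head(as.data.frame(d))
#' @export
build_design <- function(pairs, covariates = NULL, regions = list()) {
  pairs <- as_pairs(pairs)
  objs <- attr(pairs, "objects")
  n_o <- length(objs)
  judges <- unique(pairs$judge)
  H <- length(judges)
  jrow <- match(pairs$judge, judges)

  covmat <- NULL
  cov_names <- character(0)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > (1 + 0)) {
    covariates <- as.data.frame(covariates)
    if (!"judge" %in% names(covariates))
      stop("covariates must contain a 'judge' column")
    m <- match(judges, as.character(covariates$judge))
    if (anyNA(m))
      stop(sprintf("judges without covariates: %s",
                   paste(judges[is.na(m)], collapse = ", ")))
    covmat <- as.matrix(covariates[m, setdiff(names(covariates), "judge"),
                                   drop = FALSE])
    if (anyNA(covmat)) stop("missing covariate values")
    rownames(covmat) <- judges
    cov_names <- colnames(covmat)
  }

  reg <- normalize_regions(regions, judges)

  # object contrasts: column per non-reference object a,
  # entry (a == i) - (a == j) for the row's pair
  C <- matrix(0, nrow(pairs), n_o - 1L)
  for (a in seq_len(n_o - 1L))
    C[, a] <- (pairs$i == a) - (pairs$j == a)
  colnames(C) <- objs[seq_len(n_o - 1L)]

  X <- C
  if (length(cov_names)) {
    Xc <- do.call(cbind, lapply(cov_names, function(v)
      C * covmat[jrow, v]))
    colnames(Xc) <- as.vector(outer(colnames(C), cov_names,
                                    function(o, v) paste(v, o, sep = ":")))
    X <- cbind(X, Xc)
  }
  if (length(reg)) {
    Xr <- do.call(cbind, lapply(seq_along(reg), function(t)
      C * as.numeric(reg[[t]][jrow])))
    colnames(Xr) <- as.vector(outer(colnames(C), names(reg),
                                    function(o, v) paste(v, o, sep = ":")))
    X <- cbind(X, Xr)
  }

  structure(list(X = X, y = pairs$y, judge = pairs$judge,
                 pair_i = pairs$i, pair_j = pairs$j,
                 cell = seq_len(nrow(pairs)),
                 objects = objs, judges = judges,
                 covariates = covmat, covariate_names = cov_names,
                 regions = reg, region_names = names(reg),
                 n = 2L * nrow(pairs)),
            class = "llbt_design")
}

normalize_regions <- function(regions, judges) {
  if (!length(regions)) return(list())
  if (is.null(names(regions)) || any(names(regions) == ""))
    names(regions) <- paste0("R", seq_along(regions) + 1L)
  reg <- lapply(regions, function(r) {
    if (is.character(r)) judges %in% r
    else if (is.logical(r) && length(r) == length(judges)) r
    else stop("each region must be a logical vector over judges or a character vector of judge ids")
  })
  if (length(reg) > 1L) {
    tot <- Reduce(`+`, lapply(reg, as.integer))
    if (any(tot > 1L)) stop("regions overlap")
  }
  reg
}

#' @export
print.llbt_design <- function(x, ...) {
  cat(sprintf(
    "LLBT design: %d objects, %d judges, %d cells (%d comparisons), %d structural columns\n",
    length(x$objects), length(x$judges), x$n, x$n / 2L, ncol(x$X)))
  invisible(x)
}

#' @export
as.data.frame.llbt_design <- function(x, ...) {
  np <- length(x$y)
  idx <- rep(seq_len(np), each = 2L)
  sgn <- rep(c(1L, -1L), np)
  df <- data.frame(judge = x$judge[idx],
                   object_i = x$objects[x$pair_i[idx]],
                   object_j = x$objects[x$pair_j[idx]],
                   cell = x$cell[idx], sign = sgn,
                   y = ifelse(sgn == 1L, x$y[idx], 1L - x$y[idx]),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(x$X[idx, , drop = FALSE] * sgn))
}

#' Number of structural parameters of a trunk model
#'
#' For `n_o` objects, `P` covariates and `T` terminal regions the model has
#' `(n_o - 1)` object intercepts, `P (n_o - 1)` covariate effects and
#' `(T - 1) (n_o - 1)` region effects.
#'
#' @param n_o Number of objects (>= 2).
#' @param P Number of subject-specific covariates.
#' @param T Number of terminal nodes of the trunk (1 = no splits).
#' @return Integer parameter count.
#' @examples
#' count_parameters(5, 7, 5)  # 48
#' @export
count_parameters <- function(n_o, P, T) {
  stopifnot(n_o >= 2, P >= 0, T >= 1)
  as.integer((n_o - 1) * (1 + P + (T - 1)))
}
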
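#' Construct a table of complete rankings
#'
#' Validates and stores complete rankings (orderings without ties) of
#' `n_o` objects expressed by `H` judges. Rank 1 denotes the most preferred
#' object; every judge's rank vector must be a permutation of `1..n_o`.
#'
#' @param x A data frame or matrix. If a data frame contains a column named
#'   `judge` (or a character/factor first column), it is used as the judge
#'   identifier; the remaining columns are the integer ranks of the objects.
#'   A plain matrix is taken as one row of ranks per judge.
#' @param objects Optional character vector of object labels; defaults to the
#'   rank column names.
#'
#' @return An object of class `btrt_rankings`: a list with elements `judge`
#'   (identifiers), `ranks` (an `H x n_o` integer matrix) and `objects`.
#' @examples
#' r <- as_rankings(data.frame(judge = c("a", "b"),
#'                             A = c(1, 3), B = c(2, 2), C = c(3, 1)))
#' r
#' @export
as_rankings <- function(x, objects = NULL) {
  if (inherits(x, "btrt_rankings")) return(x)
  if (is.matrix(x)) {
    judge <- rownames(x)
    if (is.null(judge)) judge <- as.character(seq_len(nrow(x)))
    ranks <- x
  } else {
    x <- as.data.frame(x)
    jcol <- if ("judge" %in% names(x)) "judge" else
      if (is.character(x[[1]]) || is.factor(x[[1]])) names(x)[1] else NULL
    if (is.null(jcol)) {
      judge <- as.character(seq_len(nrow(x)))
      ranks <- as.matrix(x)
    } else {
      judge <- as.character(x[[jcol]])
      ranks <- as.matrix(x[setdiff(names(x), jcol)])
    }
  }
  storage.mode(ranks) <- "integer"
  n_o <- ncol(ranks)
  if (n_o < 3L) stop("at least 3 objects are required")
  if (nrow(ranks) < 1L) stop("at least one judge is required")
  if (anyDuplicated(judge)) stop("duplicated judge identifiers")
  if (is.null(objects)) {
    objects <- colnames(ranks)
    if (is.null(objects)) objects <- LETTERS[seq_len(n_o)]
  }
  colnames(ranks) <- objects
  for (h in seq_len(nrow(ranks))) {
    rk <- ranks[h, ]
    if (anyNA(rk) || !setequal(rk, seq_len(n_o)))
      stop(sprintf(
        "ranks of judge '%s' are not a permutation of 1..%d (ties or out-of-range values)",
        judge[h], n_o))
  }
  structure(list(judge = judge, ranks = ranks, objects = objects),
            class = "btrt_rankings")
}

#' @export
print.btrt_rankings <- function(x, ...) {
  cat(sprintf("Complete rankings of %d objects (%s) by %d judges\n",
              length(x$objects), paste(x$objects, collapse = ", "),
              nrow(x$ranks)))
  invisible(x)
}

# pairs (i, j), i < j, enumerated lexicographically: (1,2), (1,3), ..., (2,3), ...
pair_grid <- function(n_o) {
  i <- rep.int(seq_len(n_o - 1L), (n_o - 1L):1L)
  j <- unlist(lapply(seq_len(n_o - 1L), function(a) (a + 1L):n_o))
  cbind(i = i, j = j)
}

#' Convert complete rankings to binary paired comparisons
#'
#' Each judge's ranking of `n_o` objects is expanded into the
#' `n_o * (n_o - 1) / 2` pairwise preferences it implies: for objects `i < j`
#' (in label order) the outcome is 1 when `i` is ranked ahead of `j`.
#'
#' @param rankings A [as_rankings()] object (or something coercible to one).
#' @return An object of class `btrt_pairs`: a data frame with columns
#'   `judge`, `i`, `j` (object indices, `i < j`) and `y` (1 if object `i`
#'   preferred), carrying the object labels as an attribute. Patterns derived
#'   from rankings are transitive by construction.
#' @examples
#' r <- as_rankings(rbind(c(1, 2, 3), c(3, 2, 1)))
#' pairs_from_rankings(r)
#' @export
pairs_from_rankings <- function(rankings) {
  rankings <- as_rankings(rankings)
  n_o <- length(rankings$objects)
  pg <- pair_grid(n_o)
  H <- nrow(rankings$ranks)
  np <- nrow(pg)
  y <- as.integer(t(rankings$ranks[, pg[, "i"], drop = FALSE] <
                    rankings$ranks[, pg[, "j"], drop = FALSE]))
  out <- data.frame(judge = rep(rankings$judge, each = np),
                    i = rep(pg[, "i"], H), j = rep(pg[, "j"], H), y = y,
                    stringsAsFactors = FALSE)
  new_pairs(out, rankings$objects, derived = TRUE)
}

new_pairs <- function(df, objects, derived = FALSE) {
  structure(df, objects = objects, derived_from_rankings = derived,
            class = c("btrt_pairs", "data.frame"))
}

#' Coerce a long table of paired comparisons
#'
#' @param x A data frame with columns `judge`, `object_i`, `object_j`
#'   (labels, or integer indices) and `y` (binary, 1 = first object
#'   preferred).
#' @param objects Character vector of all object labels, in the order that
#'   fixes pair enumeration and the reference object (the last one).
#' @return A `btrt_pairs` object with each comparison stored on the
#'   canonical `i < j` orientation.
#' @export
as_pairs <- function(x, objects = NULL) {
  if (inherits(x, "btrt_pairs")) return(x)
  x <- as.data.frame(x)
  nm <- names(x)
  oi <- if ("object_i" %in% nm) x$object_i else x$i
  oj <- if ("object_j" %in% nm) x$object_j else x$j
  if (is.null(objects)) {
    if (is.numeric(oi)) objects <- LETTERS[seq_len(max(oi, oj))]
    else objects <- sort(unique(c(as.character(oi), as.character(oj))))
  }
  i <- if (is.numeric(oi)) as.integer(oi) else match(as.character(oi), objects)
  j <- if (is.numeric(oj)) as.integer(oj) else match(as.character(oj), objects)
  if (anyNA(i) || anyNA(j)) stop("unknown object labels in paired comparisons")
  y <- as.integer(x$y)
  if (!all(y %in% 0:1)) stop("y must be binary")
  flip <- i > j
  if (any(flip)) {
    tmp <- i[flip]; i[flip] <- j[flip]; j[flip] <- tmp
    y[flip] <- 1L - y[flip]
  }
  if (any(i == j)) stop("self-comparisons are not allowed")
  out <- data.frame(judge = as.character(x$judge), i = i, j = j, y = y,
                    stringsAsFactors = FALSE)
  np <- length(objects) * (length(objects) - 1L) / 2L
  cnt <- table(out$judge)
  if (any(cnt != np))
    stop(sprintf("every judge must contribute exactly %d comparisons", np))
  new_pairs(out, objects, derived = FALSE)
}

# permutation patterns: n_o! x npairs binary matrix, row r = pairwise pattern
# of the r-th permutation (1 iff object i ranked ahead of j, pairs in
# pair_grid() order). Cached per n_o.
.pattern_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    for (s in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- append(sub[s, ], n, after = pos - 1L)
    }
  }
  out
}

permutation_patterns <- function(n_o) {
  key <- as.character(n_o)
  if (!is.null(.pattern_cache[[key]])) return(.pattern_cache[[key]])
  if (n_o > 7L) stop("pattern enumeration supported for up to 7 objects")
  perms <- all_permutations(n_o)  # each row: a vector of ranks
  pg <- pair_grid(n_o)
  pat <- (perms[, pg[, "i"], drop = FALSE] <
          perms[, pg[, "j"], drop = FALSE]) * 1L
  .pattern_cache[[key]] <- pat
  pat
}

#' Check the transitivity of a binary comparison pattern
#'
#' A vector of `n_o * (n_o - 1) / 2` binary pairwise outcomes corresponds to
#' a ranking only if it is transitive, i.e. equals the comparison pattern of
#' one of the `n_o!` permutations; the remaining patterns contain at least
#' one preference cycle.
#'
#' @param y Binary vector of pairwise outcomes, in the canonical pair order
#'   `(1,2), (1,3), ..., (2,3), ...`; entry 1 means the lower-indexed object
#'   is preferred.
#' @param n_o Number of objects.
#' @return A list with `allowed` (logical) and `n_allowed` (`n_o!`, the
#'   number of transitive patterns).
#' @examples
#' check_transitivity(c(1, 0, 1), 3)  # A>B, C>A, B>C: a cycle
#' @export
check_transitivity <- function(y, n_o) {
  np <- n_o * (n_o - 1L) / 2L
  if (length(y) != np)
    stop(sprintf("pattern must have length %d for %d objects", np, n_o))
  pat <- permutation_patterns(n_o)
  hit <- which(colSums(abs(t(pat) - as.integer(y))) == 0L)
  list(allowed = length(hit) > 0L, n_allowed = nrow(pat))
}

#' Project a comparison pattern onto the closest transitive pattern
#'
#' Replaces a (possibly intransitive) binary comparison pattern with the
#' pattern of the permutation at minimal Hamming distance; ties between
#' equally close permutations are broken uniformly at random using the
#' current RNG state. Transitive inputs are returned unchanged.
#'
#' @inheritParams check_transitivity
#' @return A binary vector of the same length that passes
#'   [check_transitivity()].
#' @export
project_to_nearest_permutation <- function(y, n_o) {
  np <- n_o * (n_o - 1L) / 2L
  if (length(y) != np)
    stop(sprintf("pattern must have length %d for %d objects", np, n_o))
  pat <- permutation_patterns(n_o)
  d <- colSums(abs(t(pat) - as.integer(y)))
  if (min(d) == 0L) return(as.integer(y))
  best <- which(d == min(d))
  pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
  pat[pick, ]
}

#' @export
print.btrt_pairs <- function(x, ...) {
  objs <- attr(x, "objects")
  cat(sprintf("Paired comparisons: %d objects (%s), %d judges, %d records\n",
              length(objs), paste(objs, collapse = ", "),
              length(unique(x$judge)), nrow(x)))
  NextMethod()
}

n_objects <- function(pairs) length(attr(pairs, "objects"))

# restrict a btrt_pairs object to a subset of judges, preserving attributes
subset_pairs <- function(pairs, judges) {
  keep <- pairs$judge %in% judges
  new_pairs(as.data.frame(pairs)[keep, , drop = FALSE],
            objects = attr(pairs, "objects"),
            derived = isTRUE(attr(pairs, "derived_from_rankings")))
}

# ranking matrix (judges x objects) back from transitive pairs
ranks_from_pairs <- function(pairs) {
  objs <- attr(pairs, "objects")
  n_o <- length(objs)
  judges <- unique(pairs$judge)
  wins <- matrix(0L, length(judges), n_o, dimnames = list(judges, objs))
  ji <- match(pairs$judge, judges)
  for (r in seq_len(nrow(pairs))) {
    if (pairs$y[r] == 1L) wins[ji[r], pairs$i[r]] <- wins[ji[r], pairs$i[r]] + 1L
    else wins[ji[r], pairs$j[r]] <- wins[ji[r], pairs$j[r]] + 1L
  }
  rk <- t(apply(wins, 1L, function(w) as.integer(n_o - w)))
  dimnames(rk) <- list(judges, objs)
  rk
}
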
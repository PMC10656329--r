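#' Enumerate all weak orders of n objects
#'
#' A weak order is a ranking with ties: an ordered partition of the objects
#' into preference classes. Encoded as rank vectors whose distinct values
#' form a contiguous set `1..k`. There are 13, 75, 541 and 4683 weak orders
#' of 3, 4, 5 and 6 objects.
#'
#' @param n_o Number of objects (<= 6; the count grows as the Fubini
#'   numbers).
#' @return Integer matrix, one weak order per row.
#' @export
weak_orders <- function(n_o) {
  stopifnot(n_o >= 1, n_o <= 6)
  out <- list()
  for (k in seq_len(n_o)) {
    # all functions 1..n_o -> 1..k, kept when surjective: each one is the
    # block-assignment of a distinct weak order with k classes
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_o)))
    pres <- vapply(seq_len(k), function(v) rowSums(grid == v) > 0,
                   logical(nrow(grid)))
    surj <- rowSums(matrix(pres, nrow = nrow(grid))) == k
    out[[k]] <- grid[surj, , drop = FALSE]
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

#' Emond-Mason tau-x rank correlation
#'
#' Rank correlation for (possibly tied) rankings based on score matrices
#' with `a_ij = 1` when object `i` is ranked ahead of or tied with `j`,
#' `-1` when behind, and 0 on the diagonal:
#' `tau_x = sum(a_ij * b_ij) / (n_o (n_o - 1))`. For complete rankings
#' without ties it coincides with Kendall's tau; ties are scored as
#' agreement.
#'
#' @param r1,r2 Rank vectors over the same objects (smaller = preferred;
#'   tied objects share a value).
#' @return A value in `[-1, 1]`; 1 for identical complete rankings, -1 for
#'   exact reversals.
#' @export
tau_x <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("rankings must cover the same objects")
  n <- length(r1)
  a <- tau_x_scores(r1)
  b <- tau_x_scores(r2)
  sum(a * b) / (n * (n - 1))
}

tau_x_scores <- function(r) {
  s <- outer(r, r, function(u, v) ifelse(u <= v, 1, -1))
  diag(s) <- 0
  s
}

#' Median (consensus) ranking by exhaustive search over weak orders
#'
#' Finds the weak order maximizing the average tau-x correlation with a set
#' of member rankings, by scanning all weak orders of the objects (exact
#' for up to 6 objects). Ties are allowed in the consensus, not in the
#' members.
#'
#' @param ranks Matrix of complete rankings, one judge per row, or a
#'   `btrt_rankings` object.
#' @return A list with `consensus` (first maximizer, as a rank vector),
#'   `optima` (matrix of all maximizers), `tau_bar` (the maximal average
#'   tau-x) and `C` (compact string encoding of the consensus, e.g.
#'   `"21234"`: object positions with tied objects sharing a value).
#' @examples
#' median_ranking(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 3, 2)))
#' @export
median_ranking <- function(ranks) {
  if (inherits(ranks, "btrt_rankings")) ranks <- ranks$ranks
  ranks <- as.matrix(ranks)
  n_o <- ncol(ranks)
  if (n_o > 6) stop("exhaustive search supported for up to 6 objects")
  W <- weak_orders(n_o)
  # total score against members factorizes through the summed member
  # score matrix, so the scan is independent of the number of judges
  B <- Reduce(`+`, lapply(seq_len(nrow(ranks)),
                          function(h) tau_x_scores(ranks[h, ])))
  score <- vapply(seq_len(nrow(W)), function(w)
    sum(tau_x_scores(W[w, ]) * B), numeric(1))
  best <- which(score == max(score))
  cons <- W[best[1L], ]
  list(consensus = cons, optima = W[best, , drop = FALSE],
       tau_bar = max(score) / (nrow(ranks) * n_o * (n_o - 1)),
       C = ranking_string(cons))
}

#' Compact string encoding of a (weak) ranking
#'
#' @param r Rank vector; tied objects share a value.
#' @return A string such as `"21234"` giving each object's rank position.
#' @export
ranking_string <- function(r) paste(r, collapse = "")

#' Per-node consensus summaries of a trunk
#'
#' For each terminal region of a trunk, computes the exact median ranking
#' of the member judges and the average tau-x between the consensus and the
#' members.
#'
#' @param trunk A `btrt_trunk` (or a [btrt()] fit).
#' @param rankings The judges' complete rankings (`btrt_rankings`); taken
#'   from the model object when available.
#' @param t Trunk size (number of splits); defaults to the full trunk.
#' @return Data frame with columns `region`, `node`, `H`, `C`, `tau_bar`.
#' @export
consensus_by_node <- function(trunk, rankings = NULL, t = NULL) {
  if (inherits(trunk, "btrt")) {
    if (is.null(rankings)) rankings <- trunk$rankings
    if (is.null(t)) t <- trunk$size
    trunk <- trunk$trunk
  }
  stopifnot(inherits(trunk, "btrt_trunk"))
  if (is.null(rankings)) stop("rankings are required")
  rankings <- as_rankings(rankings)
  m <- match(trunk$judges, rankings$judge)
  if (anyNA(m)) stop("rankings do not cover all judges in the trunk")
  ord <- terminals_at_size(trunk, t)
  ids <- c(ord[length(ord)], ord[-length(ord)])  # reference first
  rows <- lapply(seq_along(ids), function(s) {
    nd <- trunk$nodes[[as.character(ids[s])]]
    med <- median_ranking(rankings$ranks[m[nd$judges], , drop = FALSE])
    data.frame(region = paste0("R", s), node = ids[s],
               H = length(nd$judges), C = med$C, tau_bar = med$tau_bar,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
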
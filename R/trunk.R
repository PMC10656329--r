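#' Enumerate admissible split candidates in a node
#'
#' Every unique observed value of each eligible covariate, except its
#' maximum, is a candidate threshold for the dichotomizer `I(x_p <= v)`.
#' Candidates leaving fewer than `min_bucket` judges on either side are
#' dropped; a covariate constant within the node contributes none.
#'
#' @param x Matrix or data frame of covariate values for the judges in the
#'   node (one row per judge).
#' @param min_bucket Minimum number of judges in each child node.
#' @param exclude Covariate names not eligible (used for the one-split-only
#'   mode, where covariates already split on are excluded).
#' @return Data frame with columns `covariate`, `value`, `n_left`,
#'   `n_right`; zero rows when no admissible candidate exists.
#' @export
split_candidates <- function(x, min_bucket = 5, exclude = character(0)) {
  x <- as.matrix(x)
  out <- list()
  n <- nrow(x)
  for (v in setdiff(colnames(x), exclude)) {
    vals <- sort(unique(x[, v]))
    if (length(vals) < 2L) next
    thr <- vals[-length(vals)]
    nl <- vapply(thr, function(a) sum(x[, v] <= a), integer(1))
    keep <- nl >= min_bucket & (n - nl) >= min_bucket
    if (any(keep))
      out[[v]] <- data.frame(covariate = v, value = thr[keep],
                             n_left = nl[keep], n_right = n - nl[keep],
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(covariate = character(0), value = numeric(0),
                      n_left = integer(0), n_right = integer(0)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

new_node <- function(id, judges, depth, pred = NULL) {
  list(id = id, judges = judges, depth = depth, split = NULL,
       pred = pred %||% data.frame(covariate = character(0), op = character(0),
                                   value = numeric(0), stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# terminal ids in left-to-right (in-order) sequence
leaf_order <- function(nodes, id = 1L) {
  nd <- nodes[[as.character(id)]]
  if (is.null(nd$split)) return(id)
  c(leaf_order(nodes, 2L * id), leaf_order(nodes, 2L * id + 1L))
}

# region indicator list for the given terminal set; the rightmost terminal
# (always-">" path from the root) is the reference and gets no indicator.
# Labels R2..RT follow the left-to-right leaf order.
regions_from_terminals <- function(nodes, terminals, H) {
  ord <- leaf_order_subset(nodes, terminals)
  if (length(ord) <= 1L) return(list())
  keep <- ord[-length(ord)]
  reg <- lapply(keep, function(id) {
    ind <- rep(FALSE, H)
    ind[nodes[[as.character(id)]]$judges] <- TRUE
    ind
  })
  names(reg) <- paste0("R", seq_along(keep) + 1L)
  attr(reg, "leaf_ids") <- keep
  attr(reg, "reference") <- ord[length(ord)]
  reg
}

# leaf order restricted to a hypothetical terminal set (the set need not be
# the current terminals of `nodes`, e.g. during candidate evaluation)
leaf_order_subset <- function(nodes, terminals, id = 1L) {
  if (id %in% terminals) return(id)
  c(leaf_order_subset(nodes, terminals, 2L * id),
    leaf_order_subset(nodes, terminals, 2L * id + 1L))
}

#' Grow a Bradley-Terry regression trunk
#'
#' Starting from the main-effects model in the root node, repeatedly finds,
#' over all current terminal nodes jointly, the threshold split whose region
#' indicator (crossed with the object contrasts) yields the largest decrease
#' in model deviance when the full model is refitted, until `max_terminals`
#' terminal nodes are reached or no admissible split remains. In
#' one-split-only (`"oso"`) mode a covariate used in a previous split is no
#' longer a candidate; multiple-splitting (`"ms"`) mode keeps all covariates
#' eligible. The terminal region reached from the root by always taking the
#' `>` branch is the reference region and carries no indicator.
#'
#' @param pairs A `btrt_pairs` object.
#' @param covariates Data frame with a `judge` column and numeric covariates.
#' @param mode `"ms"` (multiple splitting) or `"oso"` (one split only).
#' @param max_terminals Maximum number of terminal nodes `T`.
#' @param min_bucket Minimum number of judges per child node.
#' @return An object of class `btrt_trunk`: nodes, the ordered split history
#'   with the deviance of the refitted model after each split, and the
#'   fitted model sequence `fits[[t + 1]]` for `t = 0, ..., T - 1` splits.
#' @seealso [cv_profile()], [prune_select()], [btrt()]
#' @export
grow_trunk <- function(pairs, covariates, mode = c("ms", "oso"),
                       max_terminals = 5, min_bucket = 5) {
  mode <- match.arg(mode)
  pairs <- as_pairs(pairs)
  d0 <- build_design(pairs, covariates)
  H <- length(d0$judges)
  n_o <- length(d0$objects)
  C <- d0$X[, seq_len(n_o - 1L), drop = FALSE]
  jrow <- match(pairs$judge, d0$judges)
  covmat <- d0$covariates
  if (is.null(covmat)) stop("trunk growth requires at least one covariate")

  fit_terminals <- function(nodes, terminals) {
    reg <- regions_from_terminals(nodes, terminals, H)
    d <- d0
    if (length(reg)) {
      Xr <- do.call(cbind, lapply(reg, function(r) C * as.numeric(r[jrow])))
      colnames(Xr) <- as.vector(outer(colnames(C), names(reg),
                                      function(o, v) paste(v, o, sep = ":")))
      d$X <- cbind(d0$X, Xr)
      d$regions <- reg
      d$region_names <- names(reg)
    }
    llbt_fit(d)
  }

  y <- d0$y
  n_obj_cols <- n_o - 1L
  k_main <- ncol(d0$X)
  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100L)

  nodes <- list("1" = new_node(1L, seq_len(H), 0L))
  terminals <- 1L
  fits <- list(fit_terminals(nodes, terminals))
  history <- data.frame(step = integer(0), node = integer(0),
                        covariate = character(0), value = numeric(0),
                        deviance = numeric(0), stringsAsFactors = FALSE)
  used <- character(0)

  while (length(terminals) < max_terminals) {
    cur_reg <- regions_from_terminals(nodes, terminals, H)
    leaf_ids <- attr(cur_reg, "leaf_ids")
    ref_id <- attr(cur_reg, "reference") %||% 1L
    cur_fit <- fits[[length(fits)]]
    main_coef <- cur_fit$coefficients[seq_len(k_main)]
    reg_cols <- lapply(cur_reg, function(r) C * as.numeric(r[jrow]))
    reg_coef <- function(s)
      cur_fit$coefficients[(k_main + (s - 1L) * n_obj_cols + 1L):(k_main + s * n_obj_cols)]
    best <- NULL
    for (nd_id in terminals) {
      nd <- nodes[[as.character(nd_id)]]
      if (length(nd$judges) < 2L * min_bucket) next
      cands <- split_candidates(covmat[nd$judges, , drop = FALSE], min_bucket,
                                exclude = if (mode == "oso") used)
      if (!nrow(cands)) next
      # candidate models for this node share one column layout: the main
      # effects, the untouched regions, and the two child indicators (one
      # when the node is the reference region, whose right child inherits
      # reference status); thresholds are swept with warm starts.
      isref <- nd_id == ref_id
      keep <- which(leaf_ids != nd_id)
      Xbase <- d0$X
      base_start <- main_coef
      if (length(keep)) {
        Xbase <- cbind(Xbase, do.call(cbind, reg_cols[keep]))
        base_start <- c(base_start, unlist(lapply(keep, reg_coef)))
      }
      nd_coef <- if (isref) rep(0, n_obj_cols) else reg_coef(which(leaf_ids == nd_id))
      for (cv in unique(cands$covariate)) {
        thr <- cands$value[cands$covariate == cv]
        prev <- NULL
        for (v in thr) {
          leftj <- nd$judges[covmat[nd$judges, cv] <= v]
          lind <- rep(FALSE, H); lind[leftj] <- TRUE
          newcols <- C * as.numeric(lind[jrow])
          if (!isref) {
            rind <- rep(FALSE, H); rind[setdiff(nd$judges, leftj)] <- TRUE
            newcols <- cbind(newcols, C * as.numeric(rind[jrow]))
          }
          start <- prev %||% c(base_start, rep(nd_coef, if (isref) 1L else 2L))
          Xc <- 2 * cbind(Xbase, newcols)
          f <- logit_irls(Xc, y, start)
          if (is.null(f))  # rank-deficient or degenerate: generic fallback
            f <- tryCatch(suppressWarnings(
              stats::glm.fit(Xc, y, family = stats::binomial(), control = ctl)),
              error = function(e) NULL)
          if (is.null(f) || !isTRUE(f$converged)) {
            warning(sprintf("candidate split %s <= %g in node %d failed to fit; skipped",
                            cv, v, nd_id))
            prev <- NULL
            next
          }
          cf <- f$coefficients; cf[is.na(cf)] <- 0
          prev <- cf
          cand <- list(node = nd_id, covariate = cv, value = v,
                       cov_idx = match(cv, colnames(covmat)),
                       deviance = f$deviance, left = leftj)
          if (is.null(best) ||
              cand$deviance < best$deviance - 1e-6 ||
              (abs(cand$deviance - best$deviance) <= 1e-6 &&
               (cand$cov_idx < best$cov_idx ||
                (cand$cov_idx == best$cov_idx && (cand$value < best$value ||
                 (cand$value == best$value && cand$node < best$node))))))
            best <- cand
        }
      }
    }
    if (is.null(best)) break
    pn <- nodes[[as.character(best$node)]]
    lid <- 2L * best$node; rid <- 2L * best$node + 1L
    nodes[[as.character(best$node)]]$split <-
      list(covariate = best$covariate, value = best$value)
    nodes[[as.character(lid)]] <- new_node(lid, best$left, pn$depth + 1L,
      rbind(pn$pred, data.frame(covariate = best$covariate, op = "<=",
                                value = best$value, stringsAsFactors = FALSE)))
    nodes[[as.character(rid)]] <- new_node(rid, setdiff(pn$judges, best$left),
      pn$depth + 1L,
      rbind(pn$pred, data.frame(covariate = best$covariate, op = ">",
                                value = best$value, stringsAsFactors = FALSE)))
    terminals <- c(setdiff(terminals, best$node), lid, rid)
    used <- union(used, best$covariate)
    fits[[length(fits) + 1L]] <- fit_terminals(nodes, terminals)
    history <- rbind(history, data.frame(
      step = nrow(history) + 1L, node = best$node,
      covariate = best$covariate, value = best$value,
      deviance = fits[[length(fits)]]$deviance, stringsAsFactors = FALSE))
  }

  structure(list(nodes = nodes, terminals = terminals,
                 split_history = history, fits = fits,
                 mode = mode, min_bucket = min_bucket,
                 max_terminals = max_terminals,
                 objects = d0$objects, judges = d0$judges,
                 covariate_names = colnames(covmat),
                 data = list(pairs = pairs, design = d0, C = C, jrow = jrow,
                             covmat = covmat)),
            class = "btrt_trunk")
}

#' Terminal node set after a given number of splits
#'
#' @param trunk A `btrt_trunk`.
#' @param t Number of splits (0 = root only). Defaults to the full trunk.
#' @return Integer vector of terminal node ids, in left-to-right order.
#' @export
terminals_at_size <- function(trunk, t = NULL) {
  h <- trunk$split_history
  if (is.null(t)) t <- nrow(h)
  stopifnot(t >= 0, t <= nrow(h))
  terminals <- 1L
  if (t > 0) for (s in seq_len(t)) {
    nd <- h$node[s]
    terminals <- c(setdiff(terminals, nd), 2L * nd, 2L * nd + 1L)
  }
  leaf_order_subset(trunk$nodes, terminals)
}

#' Region predicates of the trunk terminals
#'
#' @param trunk A `btrt_trunk` (or the trunk of a [btrt()] fit).
#' @param t Number of splits to use (defaults to the full trunk).
#' @return Named list (reference region `R1` first, then `R2`, ...) of data
#'   frames with columns `covariate`, `op`, `value`; each is the conjunction
#'   of threshold conditions on the path from the root.
#' @export
region_predicates <- function(trunk, t = NULL) {
  ord <- terminals_at_size(trunk, t)
  ref <- ord[length(ord)]
  ids <- c(ref, ord[-length(ord)])
  out <- lapply(ids, function(id) trunk$nodes[[as.character(id)]]$pred)
  names(out) <- paste0("R", seq_along(ids))
  attr(out, "node_ids") <- ids
  out
}

predicate_string <- function(pred) {
  if (!nrow(pred)) return("(root)")
  paste(sprintf("%s %s %g", pred$covariate, pred$op, pred$value),
        collapse = " & ")
}

# logical membership of newdata rows in a predicate
eval_predicate <- function(pred, data) {
  ok <- rep(TRUE, nrow(data))
  if (nrow(pred)) for (r in seq_len(nrow(pred))) {
    x <- data[[pred$covariate[r]]]
    ok <- ok & if (pred$op[r] == "<=") x <= pred$value[r] else x > pred$value[r]
  }
  ok
}

#' Build a trunk skeleton from an explicit split list
#'
#' Reconstructs the tree structure implied by an ordered list of splits
#' (node id, covariate, threshold) without data, e.g. to extract the region
#' predicates implied by a published split table.
#'
#' @param splits Data frame with columns `node`, `covariate`, `value`, in
#'   split order; each `node` must be terminal at its turn.
#' @return A `btrt_trunk`-classed skeleton (no fits, no judge membership).
#' @export
trunk_from_splits <- function(splits) {
  splits <- as.data.frame(splits)
  nodes <- list("1" = new_node(1L, integer(0), 0L))
  terminals <- 1L
  for (s in seq_len(nrow(splits))) {
    id <- as.integer(splits$node[s])
    if (!id %in% terminals)
      stop(sprintf("node %d is not terminal at step %d", id, s))
    nd <- nodes[[as.character(id)]]
    nodes[[as.character(id)]]$split <- list(covariate = splits$covariate[s],
                                            value = splits$value[s])
    nodes[[as.character(2L * id)]] <- new_node(2L * id, integer(0), nd$depth + 1L,
      rbind(nd$pred, data.frame(covariate = splits$covariate[s], op = "<=",
                                value = splits$value[s], stringsAsFactors = FALSE)))
    nodes[[as.character(2L * id + 1L)]] <- new_node(2L * id + 1L, integer(0), nd$depth + 1L,
      rbind(nd$pred, data.frame(covariate = splits$covariate[s], op = ">",
                                value = splits$value[s], stringsAsFactors = FALSE)))
    terminals <- c(setdiff(terminals, id), 2L * id, 2L * id + 1L)
  }
  structure(list(nodes = nodes, terminals = terminals,
                 split_history = data.frame(step = seq_len(nrow(splits)),
                                            node = as.integer(splits$node),
                                            covariate = splits$covariate,
                                            value = splits$value,
                                            deviance = NA_real_,
                                            stringsAsFactors = FALSE),
                 fits = list(), mode = NA_character_),
            class = "btrt_trunk")
}

#' Split table of a grown trunk
#'
#' One row per model in the nested sequence: the node split, the splitting
#' covariate, the threshold and the deviance of the refitted model.
#'
#' @param trunk A `btrt_trunk`.
#' @return Data frame in split order, with the main-effects model first.
#' @export
split_table <- function(trunk) {
  h <- trunk$split_history
  rbind(data.frame(model = 0L, node = NA_integer_, covariate = "(main effects)",
                   value = NA_real_,
                   deviance = if (length(trunk$fits)) trunk$fits[[1]]$deviance else NA_real_,
                   stringsAsFactors = FALSE),
        data.frame(model = h$step, node = h$node, covariate = h$covariate,
                   value = h$value, deviance = h$deviance,
                   stringsAsFactors = FALSE))
}

#' @export
print.btrt_trunk <- function(x, ...) {
  cat(sprintf("Bradley-Terry regression trunk (%s mode): %d terminal nodes\n",
              toupper(x$mode), length(x$terminals)))
  print_node <- function(id, indent) {
    nd <- x$nodes[[as.character(id)]]
    lab <- if (is.null(nd$split)) {
      sprintf("leaf %d (%d judges)", id, length(nd$judges))
    } else {
      sprintf("node %d: %s <= %g", id, nd$split$covariate, nd$split$value)
    }
    cat(strrep("  ", indent), lab, "\n", sep = "")
    if (!is.null(nd$split)) {
      print_node(2L * id, indent + 1L)
      print_node(2L * id + 1L, indent + 1L)
    }
  }
  print_node(1L, 0L)
  invisible(x)
}
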
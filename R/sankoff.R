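#' Transformation-cost matrix for ordered (Wagner) characters
#'
#' Ordered multistate characters live on a linear character-state graph with
#' n - 1 edges, so a change from state i to state j costs |i - j| steps.
#'
#' @param n_states number of states (36 for the alphanumeric alphabet).
#' @return an `n_states` x `n_states` integer cost matrix.
#' @export
ordered_cost_matrix <- function(n_states = 36L) {
  s <- 0:(n_states - 1L)
  abs(outer(s, s, "-"))
}

.as_cost_matrix <- function(cost, n_states = 36L) {
  if (is.null(cost)) return(ordered_cost_matrix(n_states))
  if (is.function(cost)) {
    s <- 0:(n_states - 1L)
    return(outer(s, s, Vectorize(cost)))
  }
  if (is.matrix(cost) && nrow(cost) == ncol(cost)) return(cost)
  stop("cost must be NULL, a function (i, j) -> cost, or a square matrix")
}

.match_leaf_states <- function(tree, leaf_states, n_states, missing_as_zero) {
  tips <- tree$tip.label
  if (is.null(names(leaf_states)))
    stop("leaf_states must be named by leaf label")
  miss <- setdiff(tips, names(leaf_states))
  st <- leaf_states[match(tips, names(leaf_states))]
  if (length(miss) > 0 || any(is.na(st))) {
    if (!missing_as_zero)
      stop("leaves without a state: ",
           paste(union(miss, tips[is.na(st)]), collapse = ", "))
    st[is.na(st)] <- 0L
  }
  st <- as.integer(st)
  if (any(st < 0L | st >= n_states))
    stop("leaf states must lie in 0..", n_states - 1L)
  names(st) <- tips
  st
}

#' Sankoff (generalized parsimony) machinery for one character
#'
#' Runs the dynamic program of generalized maximum parsimony over a rooted
#' tree for one multistate character: an up-pass computing per-node state
#' cost vectors (polytomies handled by summing child minima), and a
#' down-pass computing each node's *final set* - the states it takes in at
#' least one most-parsimonious reconstruction (MPR) - together with, for
#' every branch, the set of (ancestral, descendant) state pairs realized
#' across MPRs, and the total MPR count.
#'
#' @param tree rooted [ape::phylo] (polytomies allowed).
#' @param leaf_states named integer vector of observed states (0-based) for
#'   every leaf; `NA`/absent leaves are treated as state 0 (absence) unless
#'   `missing_as_zero = FALSE`, in which case they raise an error.
#' @param cost `NULL` for the ordered-character cost |i - j|, or a cost
#'   function `(i, j) -> cost`, or a full cost matrix.
#' @param n_states size of the state space (default 36).
#' @param missing_as_zero treat missing leaf states as absence (state 0).
#' @return a list with `min_cost`, `n_mpr`, `final_sets` (list over ape node
#'   numbers, 0-based state values), `edge` (preorder edge matrix),
#'   `edge_pairs` (per-edge matrix of realized (from, to) state pairs) and
#'   internals used by [enumerate_mprs()].
#' @references The per-edge realized pair sets follow from the conditional
#'   independence of subtree optima given the parent state, so they are
#'   exact without explicit enumeration.
#' @export
sankoff_fit <- function(tree, leaf_states, cost = NULL, n_states = 36L,
                        missing_as_zero = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have >= 2 leaves")
  C <- .as_cost_matrix(cost, n_states)
  S <- nrow(C)
  st <- .match_leaf_states(tree, leaf_states, S, missing_as_zero)
  edge <- ape::reorder.phylo(tree, "cladewise")$edge  # preorder
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  parent <- integer(nn)
  parent[edge[, 2]] <- edge[, 1]
  children <- vector("list", nn)
  for (k in seq_len(nrow(edge)))
    children[[edge[k, 1]]] <- c(children[[edge[k, 1]]], edge[k, 2])

  ## up-pass: CV[s, v] = min cost of subtree of v given v in state s-1;
  ## MC[t, v] = min over s of CV[s, v] + C[t, s] (v's contribution to its
  ## parent in state t-1); W[s, v] = number of MPRs of the subtree
  CV <- matrix(Inf, S, nn)
  W <- matrix(0, S, nn)
  for (v in seq_len(ntip)) {
    CV[st[v] + 1L, v] <- 0
    W[st[v] + 1L, v] <- 1
  }
  MC <- matrix(NA_real_, S, nn)
  internal_pre <- unique(edge[, 1])
  for (v in rev(internal_pre)) {  # postorder: descendants first
    acc <- numeric(S)
    wacc <- rep(1, S)
    for (ch in children[[v]]) {
      tmp <- C + matrix(CV[, ch], S, S, byrow = TRUE)  # [t, s]
      mc <- apply(tmp, 1, min)
      MC[, ch] <- mc
      acc <- acc + mc
      wch <- vapply(seq_len(S), function(t)
        sum(W[tmp[t, ] == mc[t], ch]), 0)
      wacc <- wacc * wch
    }
    CV[, v] <- acc
    W[, v] <- wacc
  }
  min_cost <- min(CV[, root])

  ## down-pass: final sets and realized per-branch (from, to) pairs
  Fset <- vector("list", nn)
  Fset[[root]] <- which(CV[, root] == min_cost)
  edge_pairs <- vector("list", nrow(edge))
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    pairs <- NULL
    allowed_all <- integer(0)
    for (t in Fset[[p]]) {
      a <- which(CV[, ch] + C[t, ] == MC[t, ch])
      allowed_all <- union(allowed_all, a)
      pairs <- rbind(pairs, cbind(t - 1L, a - 1L))
    }
    Fset[[ch]] <- sort(allowed_all)
    edge_pairs[[k]] <- unique(pairs)
  }
  n_mpr <- sum(W[Fset[[root]], root])

  list(min_cost = min_cost, n_mpr = n_mpr,
       final_sets = lapply(Fset, function(f) f - 1L),
       edge = edge, edge_pairs = edge_pairs,
       CV = CV, MC = MC, W = W, C = C, parent = parent,
       internal_pre = internal_pre, root = root, ntip = ntip,
       tip_states = st, tip_label = tree$tip.label)
}

#' Minimum parsimony cost of a character on a rooted tree
#'
#' @inheritParams sankoff_fit
#' @return the minimum total transformation cost over all ancestral state
#'   assignments.
#' @examples
#' tr <- parse_tree("((A,B),(C,D));")
#' sankoff_cost(tr, c(A = 0, B = 0, C = 2, D = 2))  # 2
#' @export
sankoff_cost <- function(tree, leaf_states, cost = NULL, n_states = 36L,
                         missing_as_zero = TRUE) {
  sankoff_fit(tree, leaf_states, cost, n_states, missing_as_zero)$min_cost
}

#' Enumerate all most-parsimonious reconstructions
#'
#' Explicitly lists every minimum-cost assignment of ancestral states. The
#' assignment at each internal node, conditional on its parent's state, must
#' minimize subtree cost plus transition cost; walking these choices in
#' preorder enumerates the MPR set exactly.
#'
#' @param fit result of [sankoff_fit()].
#' @param limit refuse to enumerate more than this many MPRs.
#' @return integer matrix (`n_mpr` rows, one column per ape node number) of
#'   0-based states; leaf columns repeat the observed states.
#' @export
enumerate_mprs <- function(fit, limit = 1e5) {
  if (fit$n_mpr > limit)
    stop("MPR count ", fit$n_mpr, " exceeds limit ", limit)
  nn <- ncol(fit$CV)
  S <- nrow(fit$CV)
  nodes <- c(fit$root, setdiff(fit$internal_pre, fit$root))
  assign_v <- integer(nn)
  assign_v[seq_len(fit$ntip)] <- fit$tip_states
  out <- matrix(NA_integer_, fit$n_mpr, nn)
  row <- 0L
  rec <- function(i) {
    if (i > length(nodes)) {
      row <<- row + 1L
      out[row, ] <<- assign_v
      return(invisible())
    }
    v <- nodes[i]
    opts <- if (v == fit$root) {
      which(fit$CV[, v] == fit$min_cost)
    } else {
      t <- assign_v[fit$parent[v]] + 1L
      which(fit$CV[, v] + fit$C[t, ] == fit$MC[t, v])
    }
    for (s in opts) {
      assign_v[v] <<- s - 1L
      rec(i + 1L)
    }
  }
  rec(1L)
  colnames(out) <- seq_len(nn)
  out
}

#' Most-parsimonious reconstruction summary for one character
#'
#' @inheritParams sankoff_fit
#' @param mpr_limit enumerate explicit MPR assignments only when the MPR
#'   count does not exceed this bound.
#' @param enumerate include the explicit MPR assignment matrix.
#' @return an object of class `mpr_result`: `min_cost`, `n_mpr`,
#'   `final_sets` (0-based states per ape node), and `mprs` (matrix from
#'   [enumerate_mprs()], or `NULL` when not enumerated).
#' @export
sankoff_mpr <- function(tree, leaf_states, cost = NULL, n_states = 36L,
                        missing_as_zero = TRUE, mpr_limit = 1e5,
                        enumerate = TRUE) {
  fit <- sankoff_fit(tree, leaf_states, cost, n_states, missing_as_zero)
  mprs <- NULL
  if (enumerate && fit$n_mpr <= mpr_limit) mprs <- enumerate_mprs(fit, mpr_limit)
  structure(list(min_cost = fit$min_cost, n_mpr = fit$n_mpr,
                 final_sets = fit$final_sets, mprs = mprs,
                 exact_enumeration = !is.null(mprs)),
            class = "mpr_result")
}

#' @export
print.mpr_result <- function(x, ...) {
  cat("MPR result: min cost ", x$min_cost, ", ", x$n_mpr,
      " most-parsimonious reconstruction(s)",
      if (x$exact_enumeration) " (enumerated)", "\n", sep = "")
  invisible(x)
}

#' Unambiguous character-state changes on a rooted tree
#'
#' A change i -> j (i != j) is *unambiguous* on a branch when every
#' most-parsimonious reconstruction assigns state i to the branch's
#' ancestral node and state j to its descendant node. When the MPR count is
#' within `mpr_limit` the criterion is evaluated by explicit MPR
#' enumeration; beyond the limit the singleton-final-set criterion is used
#' instead and the result carries an `approximate` attribute (the two
#' criteria coincide on trees, and the test suite verifies this).
#'
#' @inheritParams sankoff_mpr
#' @return data.frame with one row per unambiguous change: `parent`, `node`
#'   (ape node numbers), `label` (leaf label for terminal branches, `NA`
#'   otherwise), `from`, `to` (0-based state values). Branches appear in
#'   preorder. Attribute `approximate` records whether the fallback
#'   criterion was used.
#' @examples
#' tr <- parse_tree("((A,B),(C,D));")
#' unambiguous_changes(tr, c(A = 0, B = 0, C = 0, D = 1))
#' @export
unambiguous_changes <- function(tree, leaf_states, cost = NULL,
                                n_states = 36L, missing_as_zero = TRUE,
                                mpr_limit = 1e5) {
  fit <- sankoff_fit(tree, leaf_states, cost, n_states, missing_as_zero)
  approximate <- fit$n_mpr > mpr_limit
  if (!approximate) {
    mprs <- enumerate_mprs(fit, mpr_limit)
    keep <- from <- to <- integer(0)
    for (k in seq_len(nrow(fit$edge))) {
      p <- fit$edge[k, 1]; ch <- fit$edge[k, 2]
      pr <- unique(cbind(mprs[, p], mprs[, ch]))
      if (nrow(pr) == 1L && pr[1, 1] != pr[1, 2]) {
        keep <- c(keep, k); from <- c(from, pr[1, 1]); to <- c(to, pr[1, 2])
      }
    }
  } else {
    keep <- from <- to <- integer(0)
    for (k in seq_len(nrow(fit$edge))) {
      p <- fit$edge[k, 1]; ch <- fit$edge[k, 2]
      fp <- fit$final_sets[[p]]; fc <- fit$final_sets[[ch]]
      if (length(fp) == 1L && length(fc) == 1L && fp != fc) {
        keep <- c(keep, k); from <- c(from, fp); to <- c(to, fc)
      }
    }
  }
  node <- fit$edge[keep, 2]
  out <- data.frame(parent = fit$edge[keep, 1], node = node,
                    label = ifelse(node <= fit$ntip,
                                   fit$tip_label[pmin(node, fit$ntip)],
                                   NA_character_),
                    from = from, to = to, stringsAsFactors = FALSE)
  attr(out, "approximate") <- approximate
  attr(out, "n_mpr") <- fit$n_mpr
  out
}
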
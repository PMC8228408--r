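# Independent oracles used across the suite. Deliberately written with
# different algorithms than the package code paths they check.

# stack-based bracket matcher (round brackets only), returns 0-based pairs
oracle_match_brackets <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    if (chars[k] == ")") {
      pairs <- rbind(pairs, c(stack[length(stack)] - 1L, k - 1L))
      stack <- stack[-length(stack)]
    }
  }
  pairs[order(pairs[, 1]), , drop = FALSE]
}

# exhaustive per-residue classification of a pseudoknot-free dot-bracket:
# every residue gets a kind, by direct inspection of its loop context
oracle_classify_residues <- function(db) {
  chars <- strsplit(db, "")[[1]]
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  enclos <- rep(NA_integer_, n)   # opening position of enclosing pair
  for (k in seq_len(n)) {
    if (chars[k] == "(") {
      enclos[k] <- if (length(stack)) stack[length(stack)] else NA_integer_
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      o <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[k] <- o; partner[o] <- k
      enclos[k] <- enclos[o]
    } else {
      enclos[k] <- if (length(stack)) stack[length(stack)] else NA_integer_
    }
  }
  kind <- rep(NA_character_, n)
  paired <- !is.na(partner)
  kind[paired] <- "stem"
  # group unpaired runs
  k <- 1L
  while (k <= n) {
    if (paired[k]) { k <- k + 1L; next }
    j <- k
    while (j < n && !paired[j + 1L]) j <- j + 1L
    run <- k:j
    e <- enclos[k]   # same for the whole run
    if (is.na(e)) {
      kind[run] <- if (k == 1L) "free_end_5p" else if (j == n) "free_end_3p"
                   else "joint"
    } else {
      b <- partner[e]
      # direct child pairs of the loop closed by (e, b)
      inside <- which(!is.na(partner) & seq_len(n) > e & seq_len(n) < b &
                        partner > seq_len(n))
      children <- inside[vapply(inside, function(q) {
        isTRUE(enclos[q] == e)
      }, TRUE)]
      if (length(children) == 0L) kind[run] <- "hairpin_loop"
      else if (length(children) >= 2L) kind[run] <- "multiloop_segment"
      else {
        cpos <- children[1]
        left <- if (cpos - 1L >= e + 1L) sum(!paired[(e + 1L):(cpos - 1L)])
                else 0L
        right <- if (partner[cpos] + 1L <= b - 1L)
          sum(!paired[(partner[cpos] + 1L):(b - 1L)]) else 0L
        kind[run] <- if (left > 0L && right > 0L) "internal_loop" else "bulge"
      }
    }
    k <- j + 1L
  }
  kind
}

# random pseudoknot-free dot-bracket string of length <= max_len
random_dotbracket <- function(max_len = 60L) {
  n <- sample(4:max_len, 1)
  chars <- character(0)
  open <- 0L
  for (k in seq_len(n)) {
    left <- n - k + 1L
    if (open >= left) { chars <- c(chars, ")"); open <- open - 1L; next }
    u <- stats::runif(1)
    if (u < 0.33 && open < (left - open)) { chars <- c(chars, "("); open <- open + 1L }
    else if (u < 0.66 && open > 0L) { chars <- c(chars, ")"); open <- open - 1L }
    else chars <- c(chars, ".")
  }
  while (open > 0L) { chars <- c(chars, ")"); open <- open - 1L }
  paste(chars, collapse = "")
}

# brute-force generalized parsimony: enumerate every ancestral assignment
# over states 0..max_state and score it directly on the edges
oracle_sankoff <- function(tree, leaf_states, max_state) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  edge <- tree$edge
  internal <- (ntip + 1L):nn
  grid <- do.call(expand.grid, rep(list(0:max_state), length(internal)))
  S <- matrix(NA_integer_, nrow(grid), nn)
  S[, internal] <- as.matrix(grid)
  S[, seq_len(ntip)] <- matrix(leaf_states[tree$tip.label], nrow(grid),
                               ntip, byrow = TRUE)
  cost <- rowSums(abs(S[, edge[, 1], drop = FALSE] -
                        S[, edge[, 2], drop = FALSE]))
  mc <- min(cost)
  mprs <- S[cost == mc, , drop = FALSE]
  # per-branch changes identical across all MPRs
  keep <- from <- to <- integer(0)
  for (k in seq_len(nrow(edge))) {
    pr <- unique(cbind(mprs[, edge[k, 1]], mprs[, edge[k, 2]]))
    if (nrow(pr) == 1L && pr[1, 1] != pr[1, 2]) {
      keep <- c(keep, k); from <- c(from, pr[1, 1]); to <- c(to, pr[1, 2])
    }
  }
  list(min_cost = mc, n_mpr = nrow(mprs),
       changes = data.frame(parent = edge[keep, 1], node = edge[keep, 2],
                            from = from, to = to))
}

# random rooted tree with occasional polytomies
random_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   tip.label = paste0("t", seq_len(n_leaves)))
  if (n_leaves >= 4 && stats::runif(1) < 0.4)
    tr <- ape::di2multi(tr, tol = stats::quantile(tr$edge.length, 0.3))
  tr
}

# minimal char_matrix from an integer state matrix (all one class)
make_cm <- function(values, class = "helical", taxa = NULL, labels = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(values)))
  if (is.null(labels)) labels <- paste0("c", seq_len(ncol(values)))
  dimnames(values) <- list(taxa, labels)
  char_matrix(values, rep(class, length.out = ncol(values)))
}
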
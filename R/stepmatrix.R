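#' Step-matrix of unambiguous state changes over a character class
#'
#' Traces every character of one class (helical or unpaired) along a rooted
#' tree under ordered-character (Wagner) parsimony and sums the unambiguous
#' ancestral-to-descendant changes into a 36 x 36 step-matrix: cell (i, j)
#' counts changes from state i to state j, stasis (the diagonal) excluded.
#' This is the data behind bubble charts of character-state change
#' frequencies. The same routine serves trees of molecules and trees of
#' substructures; the tree's leaf set (which must match the matrix taxa)
#' decides which.
#'
#' @param tree rooted [ape::phylo] whose leaves are the matrix taxa.
#' @param cm a `char_matrix` from [build_character_matrix()] or
#'   [read_nexus_matrix()].
#' @param class_filter which character class to aggregate.
#' @param normalization `"mean"` reports per-character average frequencies
#'   (count / number of characters) in [export_bubble()]; `"raw"` reports
#'   plain counts.
#' @param mpr_limit passed to [unambiguous_changes()].
#' @return an object of class `step_matrix`: `counts` (36 x 36, dimnames are
#'   state symbols), `class`, `n_characters`, `n_changes`, `normalization`,
#'   `approximate` (whether any character used the fallback criterion).
#' @export
build_step_matrix <- function(tree, cm,
                              class_filter = c("helical", "unpaired"),
                              normalization = c("mean", "raw"),
                              mpr_limit = 1e5) {
  class_filter <- match.arg(class_filter)
  normalization <- match.arg(normalization)
  stopifnot(inherits(cm, "char_matrix"), inherits(tree, "phylo"))
  not_in_tree <- setdiff(cm$taxa, tree$tip.label)
  not_in_matrix <- setdiff(tree$tip.label, cm$taxa)
  if (length(not_in_tree) || length(not_in_matrix))
    stop("taxon/leaf mismatch;",
         if (length(not_in_tree)) paste0(" taxa missing from tree: ",
           paste(not_in_tree, collapse = ", ")),
         if (length(not_in_matrix)) paste0(" leaves missing from matrix: ",
           paste(not_in_matrix, collapse = ", ")))
  vals <- state_values(cm)
  chars <- which(cm$class == class_filter)
  counts <- matrix(0L, 36, 36, dimnames = list(state_symbols, state_symbols))
  approximate <- FALSE
  for (j in chars) {
    ch <- unambiguous_changes(tree, setNames(vals[, j], cm$taxa),
                              mpr_limit = mpr_limit)
    approximate <- approximate || isTRUE(attr(ch, "approximate"))
    for (r in seq_len(nrow(ch)))
      counts[ch$from[r] + 1L, ch$to[r] + 1L] <-
        counts[ch$from[r] + 1L, ch$to[r] + 1L] + 1L
  }
  structure(list(counts = counts, class = class_filter,
                 n_characters = length(chars),
                 n_changes = sum(counts),
                 normalization = normalization,
                 approximate = approximate),
            class = "step_matrix")
}

#' @export
print.step_matrix <- function(x, ...) {
  cat("Step-matrix (", x$class, "): ", x$n_changes,
      " unambiguous changes over ", x$n_characters, " characters\n", sep = "")
  invisible(x)
}

#' Add step-matrices of disjoint character sets
#'
#' Character transformations are additive in ordered characters, so the
#' step-matrix of a character set is the elementwise sum over its
#' characters.
#'
#' @param e1,e2 `step_matrix` objects of the same class and normalization.
#' @return their elementwise sum.
#' @export
`+.step_matrix` <- function(e1, e2) {
  stopifnot(inherits(e1, "step_matrix"), inherits(e2, "step_matrix"),
            e1$class == e2$class, e1$normalization == e2$normalization)
  structure(list(counts = e1$counts + e2$counts, class = e1$class,
                 n_characters = e1$n_characters + e2$n_characters,
                 n_changes = e1$n_changes + e2$n_changes,
                 normalization = e1$normalization,
                 approximate = e1$approximate || e2$approximate),
            class = "step_matrix")
}

#' Export a step-matrix as long-format bubble-chart data
#'
#' @param sm a `step_matrix`.
#' @param path optional TSV output path.
#' @return data.frame with columns `from`, `to` (state symbols),
#'   `from_value`, `to_value` (integer states), `count` and `frequency`
#'   (count / number of characters under `"mean"` normalization, the raw
#'   count under `"raw"`), one row per non-zero cell in row-major order.
#' @export
export_bubble <- function(sm, path = NULL) {
  stopifnot(inherits(sm, "step_matrix"))
  nz <- which(t(sm$counts) > 0)  # row-major order over (from, to)
  to_i <- (nz - 1L) %% 36L
  from_i <- (nz - 1L) %/% 36L
  count <- sm$counts[cbind(from_i + 1L, to_i + 1L)]
  freq <- if (sm$normalization == "mean") count / sm$n_characters else count
  out <- data.frame(from = state_symbols[from_i + 1L],
                    to = state_symbols[to_i + 1L],
                    from_value = from_i, to_value = to_i,
                    count = count, frequency = freq,
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Fraction of changes on the single-step diagonals
#'
#' The share of unambiguous changes that move exactly one state up or down
#' (|i - j| = 1), the double-diagonal signature of stepwise substructure
#' evolution in bubble charts.
#'
#' @param sm a `step_matrix`.
#' @return numeric fraction in `[0, 1]` (`NaN` when no changes).
#' @export
single_step_fraction <- function(sm) {
  stopifnot(inherits(sm, "step_matrix"))
  idx <- which(abs(row(sm$counts) - col(sm$counts)) == 1L)
  sum(sm$counts[idx]) / sum(sm$counts)
}
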
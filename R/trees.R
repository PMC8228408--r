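#' Parse a rooted tree
#'
#' Thin wrapper around ape's Newick and NEXUS tree readers that validates
#' what the downstream analyses need: the tree is used exactly as written
#' (no re-rooting), polytomies are preserved, and leaf labels must be
#' unique. Branch lengths, if present, are carried along but ignored by the
#' node-distance age computation.
#'
#' @param text tree text (Newick string or NEXUS TREES block content).
#' @param format `"newick"` or `"nexus"`.
#' @return an [ape::phylo] object.
#' @export
parse_tree <- function(text, format = c("newick", "nexus")) {
  format <- match.arg(format)
  text <- paste(text, collapse = "\n")
  if (format == "newick") {
    n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
    n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
    if (n_open != n_close)
      stop("newick parse error: unbalanced parentheses (", n_open,
           " '(' vs ", n_close, "')')")
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  } else {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf))
    writeLines(text, tf)
    tr <- tryCatch(ape::read.nexus(tf), error = function(e) NULL)
    if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop(format, " parse error: could not read a tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Read a rooted tree from a file
#'
#' @param path file path; format guessed from extension (`.nex`, `.nexus` or
#'   a `#NEXUS` first line means NEXUS, otherwise Newick) unless given.
#' @param format optional `"newick"` or `"nexus"`.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    first <- readLines(path, n = 1)
    format <- if (ext %in% c("nex", "nexus", "nxs") ||
                  grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus"
              else "newick"
  }
  parse_tree(readLines(path), format)
}

#' Internal node depths of every node
#'
#' @param tree rooted [ape::phylo].
#' @return integer vector indexed by ape node number: the count of internal
#'   nodes on the root-to-node path, counting the root and the node itself
#'   when internal.
#' @keywords internal
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  edge <- ape::reorder.phylo(tree, "cladewise")$edge  # preorder
  D <- integer(nn)
  root <- ntip + 1L
  D[root] <- 1L
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    D[ch] <- D[p] + as.integer(ch > ntip)
  }
  D
}

#' Relative node-distance ages of tree leaves
#'
#' On a rooted tree of substructures, the relative time of origin of a leaf
#' is its distance in nodes from the hypothetical ancestor: the number of
#' internal nodes on the root-to-leaf path (root counted), rescaled to a
#' relative 0-1 scale where 0 is the origin of the molecule (the shallowest
#' leaf) and 1 the present molecule (the deepest leaves). Branch lengths are
#' ignored; sister leaves at equal depth share the same age. On highly
#' pectinate trees of substructures this recovers the accretion order of the
#' parts.
#'
#' @param tree rooted [ape::phylo] with >= 2 leaves.
#' @return data.frame with columns `label`, `depth` (raw internal-node
#'   count, root included) and `nd` in `[0, 1]`; rows in tip order.
#'   Degenerate trees in which all leaves sit at the same depth get `nd = 0`
#'   everywhere, with a warning.
#' @examples
#' tr <- parse_tree("(((S4,S3)x,S2)y,S1)z;")
#' node_distance_ages(tr)
#' @export
node_distance_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("node-distance ages need a tree with >= 2 leaves")
  D <- node_depths(tree)
  depth <- D[seq_len(ntip)]
  rng <- range(depth)
  if (rng[1] == rng[2]) {
    warning("all leaves at equal depth; node-distance ages degenerate to 0")
    nd <- rep(0, ntip)
  } else {
    nd <- (depth - rng[1]) / (rng[2] - rng[1])
  }
  data.frame(label = tree$tip.label, depth = depth, nd = nd,
             stringsAsFactors = FALSE)
}

#' Write node-distance ages as TSV
#'
#' @param ages data.frame from [node_distance_ages()].
#' @param path output path.
#' @return the input, invisibly.
#' @export
write_ages <- function(ages, path) {
  utils::write.table(ages[, c("label", "nd")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(ages)
}
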
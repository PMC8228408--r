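#' Configuration for synthetic accretion data
#'
#' Bundles the generating parameters for synthetic accretion histories,
#' stepwise character evolution and molecule sets. The defaults are the
#' conditions of the tRNA analysis: a 10-substructure molecule whose stem
#' lengths decay as y(x) = A exp(-c x) with A = 13.56 and c = 0.490
#' (the fitted tRNA values), multiplicative lognormal noise with sd 0.2 on
#' the log scale, and rare single-step character change (0.1 expected
#' steps per branch).
#'
#' @param n_sub number of substructures (>= 3).
#' @param A_true generating MA intercept (length of the first construct, > 0).
#' @param c_true generating MA decay rate (>= 0).
#' @param noise_sd standard deviation of additive noise on ln y (>= 0).
#' @param n_taxa number of leaves for simulated molecule trees.
#' @param step_rate expected number of +-1 state steps per branch (>= 0).
#' @param seed RNG seed; all draws of a generator run flow from one global
#'   stream seeded with it, so outputs are bit-reproducible.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_sub = 10L, A_true = 13.56, c_true = 0.490,
                             noise_sd = 0.2, n_taxa = 20L, step_rate = 0.1,
                             seed = 1L) {
  if (n_sub < 3L) stop("config error: n_sub must be >= 3")
  if (A_true <= 0) stop("config error: A_true must be > 0")
  if (c_true < 0) stop("config error: c_true must be >= 0")
  if (noise_sd < 0) stop("config error: noise_sd must be >= 0")
  if (n_taxa < 2L) stop("config error: n_taxa must be >= 2")
  if (step_rate < 0) stop("config error: step_rate must be >= 0")
  structure(list(n_sub = as.integer(n_sub), A_true = A_true, c_true = c_true,
                 noise_sd = noise_sd, n_taxa = as.integer(n_taxa),
                 step_rate = step_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Pectinate tree of substructures
#'
#' A fully pectinate (caterpillar) rooted tree whose leaves are
#' substructures in accretion order: `sub1` branches off at the root
#' (oldest, nd = 0), each later substructure one node deeper; the last two
#' share the deepest cherry.
#'
#' @param n_sub number of leaves (>= 3).
#' @param labels optional leaf labels, oldest first.
#' @return an [ape::phylo].
#' @export
pectinate_tree <- function(n_sub, labels = paste0("sub", seq_len(n_sub))) {
  stopifnot(n_sub >= 3L, length(labels) == n_sub)
  nwk <- paste0("(", labels[n_sub], ",", labels[n_sub - 1L], ")")
  for (i in (n_sub - 2L):1L) nwk <- paste0("(", nwk, ",", labels[i], ")")
  parse_tree(paste0(nwk, ";"))
}

#' Generate a synthetic accretion history
#'
#' Builds a fully pectinate tree of `n_sub` substructures and an accretion
#' series in which mean lengths decay as y(x) = A exp(-c x) with
#' multiplicative lognormal noise: ln y gets additive Normal(0, noise_sd)
#' noise, and lengths are floored at 1 (a present substructure cannot have
#' length 0). Ages are node distances on the tree and x is the accretion
#' rank (ties at the deepest cherry share their rank).
#'
#' @param cfg a [synthetic_config()].
#' @return list with `tree` (the pectinate [ape::phylo]) and `series`
#'   (an `accretion_series`).
#' @examples
#' h <- gen_accretion_history(synthetic_config(noise_sd = 0))
#' h$series
#' @export
gen_accretion_history <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  tree <- pectinate_tree(cfg$n_sub)
  ages <- node_distance_ages(tree)
  ages <- ages[order(ages$nd, ages$label), ]
  x <- vapply(ages$nd, function(v) sum(ages$nd <= v), 0L)
  eps <- stats::rnorm(cfg$n_sub, 0, cfg$noise_sd)
  y <- pmax(1, cfg$A_true * exp(-cfg$c_true * x) * exp(eps))
  series <- data.frame(label = ages$label, class = "helical", nd = ages$nd,
                       mean_length = y, x = x, stringsAsFactors = FALSE)
  class(series) <- c("accretion_series", "data.frame")
  list(tree = tree, series = series)
}

#' Simulate stepwise evolution of an ordered character
#'
#' Evolves one ordered multistate character along a rooted tree: on each
#' branch the state takes Poisson(`step_rate`) unit steps, each +1 or -1
#' with equal probability, reflecting at the alphabet boundaries 0 and 35.
#' This is the generative counterpart of the single-step change pattern
#' parsimony recovers on the double diagonals of bubble charts.
#'
#' @param tree rooted [ape::phylo].
#' @param root_state ancestral state at the root (0..35).
#' @param step_rate expected steps per branch (>= 0).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return named integer vector of leaf states, with attributes
#'   `total_steps` (number of unit steps drawn across all branches) and
#'   `node_states` (states at every ape node).
#' @export
simulate_ordered_character <- function(tree, root_state, step_rate,
                                       seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (root_state < 0 || root_state > 35)
    stop("root_state must lie in 0..35")
  if (step_rate < 0) stop("step_rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  state <- integer(ntip + tree$Nnode)
  state[ntip + 1L] <- as.integer(root_state)
  total <- 0L
  for (k in seq_len(nrow(edge))) {
    s <- state[edge[k, 1]]
    nstep <- stats::rpois(1, step_rate)
    total <- total + nstep
    if (nstep > 0) for (d in sample(c(-1L, 1L), nstep, replace = TRUE)) {
      s <- s + d
      if (s < 0L) s <- -s           # reflect at 0
      if (s > 35L) s <- 70L - s     # reflect at 35
    }
    state[edge[k, 2]] <- s
  }
  out <- state[seq_len(ntip)]
  names(out) <- tree$tip.label
  attr(out, "total_steps") <- total
  attr(out, "node_states") <- state
  out
}

#' Generate a self-checking set of secondary structures
#'
#' Emits dot-bracket molecules sharing a template topology - a 5' free end,
#' `n_sub` hairpin (stem-loop) units separated by joints, and a 3' free end
#' - with stem and loop lengths varying around template values that decay
#' as A exp(-c x). The last unit is occasionally absent (stem and loop
#' dropped together with the preceding joint), exercising the
#' missing-substructure state `'0'`. Every record is verified by
#' decomposition against the intended lengths before it is returned, so the
#' fixture is self-checking.
#'
#' @param cfg a [synthetic_config()]; `n_taxa` molecules with `n_sub` units.
#' @return list with `structures` (named list of [rna_structure]),
#'   `lengths` (taxa x label matrix of intended lengths, 0 = absent),
#'   `classes` (named vector label -> helical/unpaired) and `cfg`.
#' @export
gen_molecule_set <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  k <- cfg$n_sub
  stem_base <- pmax(2L, as.integer(round(cfg$A_true * exp(-cfg$c_true * seq_len(k)))))
  loop_base <- rep(4L, k)
  joint_len <- 2L
  f5 <- 3L; f3 <- 3L
  labels <- c("F5",
              as.vector(rbind(paste0("S", seq_len(k)), paste0("HL", seq_len(k)),
                              c(paste0("J", seq_len(k - 1L)), "F3"))))
  classes <- setNames(ifelse(startsWith(labels, "S"), "helical", "unpaired"),
                      labels)
  taxa <- sprintf("mol%02d", seq_len(cfg$n_taxa))
  lengths <- matrix(0L, cfg$n_taxa, length(labels),
                    dimnames = list(taxa, labels))
  structures <- vector("list", cfg$n_taxa)
  for (m in seq_len(cfg$n_taxa)) {
    stems <- pmax(2L, stem_base + sample(-1:1, k, replace = TRUE))
    loops <- pmax(3L, loop_base + sample(-1:1, k, replace = TRUE))
    present <- rep(TRUE, k)
    if (stats::runif(1) < 0.3) present[k] <- FALSE  # variable 3' unit
    db <- strrep(".", f5)
    seqs <- strrep("A", f5)
    lengths[m, "F5"] <- f5
    kept <- which(present)
    for (u in kept) {
      if (u != kept[1]) {
        db <- paste0(db, strrep(".", joint_len))
        seqs <- paste0(seqs, strrep("A", joint_len))
      }
      db <- paste0(db, strrep("(", stems[u]), strrep(".", loops[u]),
                   strrep(")", stems[u]))
      seqs <- paste0(seqs, strrep("G", stems[u]), strrep("A", loops[u]),
                     strrep("C", stems[u]))
      lengths[m, paste0("S", u)] <- stems[u]
      lengths[m, paste0("HL", u)] <- loops[u]
    }
    ## joints sit between consecutive present units; only the last unit is
    ## optional, so they are always J1..J(n_present - 1)
    if (length(kept) > 1L)
      lengths[m, paste0("J", seq_len(length(kept) - 1L))] <- joint_len
    db <- paste0(db, strrep(".", f3))
    seqs <- paste0(seqs, strrep("A", f3))
    lengths[m, "F3"] <- f3
    s <- parse_structure(c(paste0(">", taxa[m]), seqs, db), "dotbracket")
    d <- decompose(s, gu_separate = FALSE)
    got <- setNames(d$length, d$label)
    want <- lengths[m, ]
    want <- want[want > 0L]
    if (length(got) != length(want) || !all(names(want) %in% names(got)) ||
        any(got[names(want)] != want))
      stop("fixture error: decomposition of '", taxa[m],
           "' does not reproduce the intended lengths")
    structures[[m]] <- s
  }
  names(structures) <- taxa
  list(structures = structures, lengths = lengths, classes = classes,
       cfg = cfg)
}
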
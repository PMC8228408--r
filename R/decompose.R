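#' Decompose a secondary structure into substructures
#'
#' Splits a molecule into the spatial components whose lengths are coded as
#' phylogenetic characters: double-helical stems, hairpin loops, bulges,
#' internal loops, multiloop segments, connecting joints and 5'/3' free ends,
#' plus (optionally) a G:U wobble-pair count per stem.
#'
#' A stem is a maximal run of consecutively stacked pairs
#' `(i,j), (i+1,j-1), ...`; any interruption of stacking (a one-nucleotide
#' bulge, an internal loop, a junction) terminates the stem, so a bulge splits
#' a helix into two stem characters. Every residue belongs to exactly one
#' substructure: paired residues to their stem, unpaired residues to the
#' loop/bulge/joint/free-end run that contains them. Unpaired runs are
#' classified by flanking context: `hairpin_loop` when enclosed by a single
#' stem end, `bulge`/`internal_loop` when between the ends of two adjacent
#' stems (one- vs two-sided), `multiloop_segment` inside a junction of three
#' or more stems, `joint` between stems in the exterior (unenclosed) region,
#' and free ends at the molecule termini. A fully unpaired molecule is a
#' single 5' free end.
#'
#' Crossing (pseudoknot) pairs are retained: stems are built from maximal
#' stacking runs on the full pair set, so both helices of a pseudoknot are
#' reported. Unpaired-run classification uses the maximal non-crossing subset
#' of stems (kept greedily by stem length), since loop context is only
#' defined on a nested scaffold.
#'
#' @param s an [rna_structure].
#' @param gu_separate also emit a `gu_pairs` record per stem holding its G:U
#'   (wobble) pair count; defaults to on when the sequence is known. G:U
#'   pairs still count towards stem length.
#' @return a data.frame with one row per substructure: `label` (positional,
#'   e.g. `S1`, `HL1`, `J2`), `kind`, `length` (base pairs for
#'   `stem`/`gu_pairs`, nucleotides otherwise) and a list column `positions`
#'   of 0-based residue indices. `gu_pairs` rows overlay their stem's
#'   residues and are excluded from the residue partition.
#' @examples
#' s <- parse_structure("..(((...)))", "dotbracket")
#' decompose(s)
#' @export
decompose <- function(s, gu_separate = nzchar(s$sequence)) {
  stopifnot(inherits(s, "rna_structure"))
  n <- s$length
  empty <- data.frame(label = character(0), kind = character(0),
                      length = integer(0))
  empty$positions <- list()
  if (n == 0L) return(empty)
  partner <- pair_partner(s)

  ## maximal stacking runs on the full pair set
  stems <- list()
  visited <- rep(FALSE, n)
  opens <- which(!is.na(partner) & partner > seq_len(n))
  for (a in opens) {
    if (visited[a]) next
    b <- partner[a]
    len <- 1L
    while (a + len < b - len && !is.na(partner[a + len]) &&
           partner[a + len] == b - len) len <- len + 1L
    pos <- c(a:(a + len - 1L), (b - len + 1L):b)
    visited[pos] <- TRUE
    stems[[length(stems) + 1L]] <- list(a0 = a, b0 = b, len = len, pos = pos)
  }

  ## non-crossing scaffold for loop classification
  keep <- rep(TRUE, length(stems))
  if (length(stems) > 1L) {
    ord <- order(-vapply(stems, `[[`, 1L, "len"),
                 vapply(stems, `[[`, 1L, "a0"))
    kept <- integer(0)
    keep <- rep(FALSE, length(stems))
    for (k in ord) {
      cross <- FALSE
      for (m in kept) {
        ax <- stems[[m]]$a0; bx <- stems[[m]]$b0
        ay <- stems[[k]]$a0; by <- stems[[k]]$b0
        if ((ax < ay && ay < bx && bx < by) || (ay < ax && ax < by && by < bx)) {
          cross <- TRUE; break
        }
      }
      if (!cross) { keep[k] <- TRUE; kept <- c(kept, k) }
    }
  }
  ## all pairs of kept stems, and kept stem outer spans
  kp <- do.call(rbind, lapply(stems[keep], function(st)
    cbind(st$a0 + 0:(st$len - 1L), st$b0 - 0:(st$len - 1L))))
  kspan <- do.call(rbind, lapply(stems[keep], function(st) c(st$a0, st$b0)))

  ## unpaired runs
  up <- is.na(partner)
  runs <- list()
  r <- rle(up)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  for (k in seq_along(r$values))
    if (r$values[k]) runs[[length(runs) + 1L]] <- c(starts[k], stops[k])

  classify_run <- function(u1, u2) {
    if (u1 == 1L) return("free_end_5p")
    if (u2 == n) return("free_end_3p")
    if (is.null(kp) || nrow(kp) == 0L) return("free_end_5p")
    enc <- which(kp[, 1] < u1 & kp[, 2] > u2)
    if (length(enc) == 0L) return("joint")
    inner <- enc[which.min(kp[enc, 2] - kp[enc, 1])]
    a <- kp[inner, 1]; b <- kp[inner, 2]
    cand <- which(kspan[, 1] > a & kspan[, 2] < b)
    if (length(cand) > 1L) {  # direct children only
      direct <- vapply(cand, function(k) {
        !any(kspan[cand, 1] < kspan[k, 1] & kspan[cand, 2] > kspan[k, 2])
      }, TRUE)
      cand <- cand[direct]
    }
    if (length(cand) == 0L) return("hairpin_loop")
    if (length(cand) >= 2L) return("multiloop_segment")
    cc <- kspan[cand, 1]; d <- kspan[cand, 2]
    left <- if (cc > a + 1L) sum(up[(a + 1L):(cc - 1L)]) else 0L
    right <- if (b > d + 1L) sum(up[(d + 1L):(b - 1L)]) else 0L
    if (left > 0L && right > 0L) "internal_loop" else "bulge"
  }

  rows <- list()
  for (st in stems)
    rows[[length(rows) + 1L]] <-
      list(kind = "stem", length = st$len, pos = st$pos, first = st$a0)
  for (run in runs)
    rows[[length(rows) + 1L]] <-
      list(kind = classify_run(run[1], run[2]),
           length = run[2] - run[1] + 1L, pos = run[1]:run[2], first = run[1])

  ## G:U wobble counts per stem
  if (gu_separate && nzchar(s$sequence)) {
    sq <- strsplit(chartr("T", "U", s$sequence), "")[[1]]
    for (st in stems) {
      i <- st$a0 + 0:(st$len - 1L); j <- st$b0 - 0:(st$len - 1L)
      wob <- (sq[i] == "G" & sq[j] == "U") | (sq[i] == "U" & sq[j] == "G")
      if (any(wob))
        rows[[length(rows) + 1L]] <-
          list(kind = "gu_pairs", length = sum(wob),
               pos = sort(c(i[wob], j[wob])), first = st$a0)
    }
  }

  ord <- order(vapply(rows, `[[`, 1L, "first"),
               match(vapply(rows, `[[`, "", "kind"), .substructure_kinds))
  rows <- rows[ord]
  kind <- vapply(rows, `[[`, "", "kind")
  counters <- c(stem = 0L, hairpin_loop = 0L, bulge = 0L, internal_loop = 0L,
                multiloop_segment = 0L, joint = 0L, gu_pairs = 0L)
  prefix <- c(stem = "S", hairpin_loop = "HL", bulge = "B",
              internal_loop = "IL", multiloop_segment = "ML", joint = "J",
              gu_pairs = "GU")
  label <- character(length(rows))
  stem_seen <- 0L
  for (k in seq_along(rows)) {
    kd <- kind[k]
    if (kd == "free_end_5p") label[k] <- "F5"
    else if (kd == "free_end_3p") label[k] <- "F3"
    else if (kd == "gu_pairs") {
      label[k] <- paste0("GU_S", stem_seen)  # follows its stem in 5' order
    } else {
      counters[kd] <- counters[kd] + 1L
      label[k] <- paste0(prefix[kd], counters[kd])
      if (kd == "stem") stem_seen <- counters["stem"]
    }
  }
  out <- data.frame(label = label, kind = kind,
                    length = vapply(rows, `[[`, 1L, "length"),
                    stringsAsFactors = FALSE)
  out$positions <- lapply(rows, function(x) as.integer(x$pos) - 1L)
  out
}

.substructure_kinds <- c("stem", "gu_pairs", "hairpin_loop", "bulge",
                         "internal_loop", "multiloop_segment", "joint",
                         "free_end_5p", "free_end_3p")

#' Character class of a substructure kind
#'
#' Stems are `helical`; loops, bulges, joints and free ends are `unpaired`.
#' The class of the per-stem G:U wobble count is configurable: wobble pairs
#' sit inside helices but destabilize them, and both treatments appear in
#' practice.
#'
#' @param kind character vector of substructure kinds.
#' @param gu_class class assigned to `gu_pairs` characters.
#' @return character vector, `"helical"` or `"unpaired"`.
#' @export
substructure_class <- function(kind, gu_class = c("unpaired", "helical")) {
  gu_class <- match.arg(gu_class)
  bad <- setdiff(unique(kind), .substructure_kinds)
  if (length(bad) > 0)
    stop("unknown substructure kind(s): ", paste(bad, collapse = ", "))
  ifelse(kind == "stem", "helical",
         ifelse(kind == "gu_pairs", gu_class, "unpaired"))
}
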
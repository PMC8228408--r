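#' RNA secondary structure objects
#'
#' An `rna_structure` holds one molecule: an id, an (optionally empty)
#' sequence over `A,C,G,U,N`, and a set of base pairs given as 0-based index
#' pairs `(i, j)` with `i < j`. Each residue may pair with at most one
#' partner. Crossing (pseudoknotted) pairs are permitted and preserved.
#'
#' @param id character label.
#' @param n molecule length in residues.
#' @param sequence character string of length `n`, or `""` when only the
#'   topology is known.
#' @param pairs two-column integer matrix of 0-based pair indices, `i < j`.
#' @return an object of class `rna_structure` with fields `id`, `length`,
#'   `sequence`, `pairs`.
#' @export
rna_structure <- function(id, n, sequence = "", pairs = matrix(integer(0), 0, 2)) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nzchar(sequence) && nchar(sequence) != n)
    stop("sequence length ", nchar(sequence), " != molecule length ", n)
  if (nzchar(sequence) && grepl("[^ACGUTN]", toupper(sequence)))
    stop("sequence contains characters outside A,C,G,U,T,N")
  if (nrow(pairs) > 0) {
    if (any(pairs[, 1] >= pairs[, 2]))
      stop("pairs must satisfy i < j")
    if (any(pairs < 0) || any(pairs >= n))
      stop("pair index out of range 0..", n - 1L)
    idx <- c(pairs[, 1], pairs[, 2])
    if (anyDuplicated(idx))
      stop("duplicate pairing partner at 0-based position(s) ",
           paste(unique(idx[duplicated(idx)]), collapse = ", "))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  structure(
    list(id = as.character(id), length = as.integer(n),
         sequence = toupper(sequence), pairs = pairs),
    class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure '", x$id, "': ", x$length, " nt, ",
      nrow(x$pairs), " base pairs\n", sep = "")
  invisible(x)
}

#' Pairing partner vector
#'
#' @param s an [rna_structure].
#' @return integer vector of length `s$length`; `partner[i]` is the 1-based
#'   partner of residue `i` (1-based), or `NA` if unpaired.
#' @keywords internal
pair_partner <- function(s) {
  partner <- rep(NA_integer_, s$length)
  if (nrow(s$pairs) > 0) {
    partner[s$pairs[, 1] + 1L] <- s$pairs[, 2] + 1L
    partner[s$pairs[, 2] + 1L] <- s$pairs[, 1] + 1L
  }
  partner
}

.bracket_open <- c("(", "[", "{", "<")
.bracket_close <- c(")", "]", "}", ">")

#' Parse an RNA secondary structure record
#'
#' @param text the record as a single string or a character vector of lines.
#' @param format one of `"dotbracket"`, `"ct"`, `"bpseq"`.
#' @param id fallback id when the record carries none.
#' @return an [rna_structure].
#' @details
#' Dot-bracket records are Vienna style: an optional `>id` line, an optional
#' sequence line, and the structure line using `.` for unpaired residues and
#' the bracket families `()`, `[]`, `{}`, `<>` for (possibly crossing) pairs.
#' CT is the Zuker 6-column format and bpseq the 3-column `index base pair`
#' format; both are 1-based on disk.
#' @examples
#' parse_structure(">h\nGGGAAACCC\n(((...)))", "dotbracket")
#' @export
parse_structure <- function(text, format = c("dotbracket", "ct", "bpseq"),
                            id = "structure") {
  format <- match.arg(format)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ", format, " record")
  switch(format,
         dotbracket = .parse_dotbracket(lines, id),
         ct = .parse_ct(lines, id),
         bpseq = .parse_bpseq(lines, id))
}

.parse_dotbracket <- function(lines, id) {
  if (startsWith(lines[1], ">")) {
    id <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) == 0L) stop("dot-bracket record has no structure line")
  seq <- ""
  if (length(lines) >= 2L) {
    if (grepl("[^ACGUTNacgutn]", lines[1]))
      stop("line 2: expected a sequence line over A,C,G,U,N")
    seq <- lines[1]
    db <- lines[2]
  } else {
    db <- lines[1]
    if (!any(strsplit(db, "")[[1]] %in%
             c(".", .bracket_open, .bracket_close)))
      stop("structure line contains no dot-bracket symbols")
  }
  chars <- strsplit(db, "")[[1]]
  stacks <- rep(list(integer(0)), 4L)
  pairs <- matrix(integer(0), 0, 2)
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == ".") next
    io <- match(ch, .bracket_open)
    ic <- match(ch, .bracket_close)
    if (!is.na(io)) {
      stacks[[io]] <- c(stacks[[io]], k)
    } else if (!is.na(ic)) {
      st <- stacks[[ic]]
      if (length(st) == 0L)
        stop("unbalanced brackets: unmatched '", ch,
             "' at structure line column ", k)
      pairs <- rbind(pairs, c(st[length(st)] - 1L, k - 1L))
      stacks[[ic]] <- st[-length(st)]
    } else {
      stop("invalid structure symbol '", ch, "' at column ", k)
    }
  }
  open_left <- vapply(stacks, length, 1L)
  if (any(open_left > 0L))
    stop("unbalanced brackets: ", sum(open_left), " unmatched '",
         paste(.bracket_open[open_left > 0L], collapse = "','"),
         "' in structure line")
  rna_structure(id, length(chars), seq, pairs)
}

.parse_ct <- function(lines, id) {
  head <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(head[1]))
  if (is.na(n)) stop("CT line 1: expected residue count, got '", head[1], "'")
  if (length(head) > 1L) id <- paste(head[-1], collapse = " ")
  body <- lines[-1]
  if (length(body) != n)
    stop("CT record declares ", n, " residues but has ", length(body), " rows")
  seq <- character(n)
  partner <- integer(n)
  for (r in seq_len(n)) {
    f <- strsplit(trimws(body[r]), "\\s+")[[1]]
    if (length(f) < 5L) stop("CT line ", r + 1L, ": expected >= 5 columns")
    i <- as.integer(f[1])
    if (is.na(i) || i != r) stop("CT line ", r + 1L, ": index ", f[1],
                                 " out of order (expected ", r, ")")
    seq[r] <- f[2]
    partner[r] <- as.integer(f[5])
    if (is.na(partner[r]) || partner[r] < 0L || partner[r] > n)
      stop("CT line ", r + 1L, ": pair index '", f[5], "' out of range 0..", n)
  }
  .pairs_from_partner(partner, n, id, paste(seq, collapse = ""), "CT")
}

.parse_bpseq <- function(lines, id) {
  lines <- lines[!grepl("^#", lines)]
  n <- length(lines)
  seq <- character(n)
  partner <- integer(n)
  for (r in seq_len(n)) {
    f <- strsplit(trimws(lines[r]), "\\s+")[[1]]
    if (length(f) != 3L) stop("bpseq line ", r, ": expected 3 columns")
    i <- as.integer(f[1])
    if (is.na(i) || i != r) stop("bpseq line ", r, ": index ", f[1],
                                 " out of order (expected ", r, ")")
    seq[r] <- f[2]
    partner[r] <- as.integer(f[3])
    if (is.na(partner[r]) || partner[r] < 0L || partner[r] > n)
      stop("bpseq line ", r, ": pair index '", f[3], "' out of range 0..", n)
  }
  .pairs_from_partner(partner, n, id, paste(seq, collapse = ""), "bpseq")
}

.pairs_from_partner <- function(partner, n, id, seq, what) {
  for (r in seq_len(n)) {
    p <- partner[r]
    if (p > 0L && partner[p] != r)
      stop(what, ": inconsistent pairing, residue ", r, " pairs ", p,
           " but residue ", p, " pairs ", partner[p])
    if (p == r) stop(what, ": residue ", r, " pairs with itself")
  }
  sel <- which(partner > seq_len(n))
  pairs <- cbind(sel - 1L, partner[sel] - 1L)
  if (grepl("[^ACGUTN]", toupper(seq))) seq <- ""
  rna_structure(id, n, seq, pairs)
}

#' Write an RNA secondary structure record
#'
#' @param s an [rna_structure].
#' @param format output format (`"dotbracket"`, `"ct"`, `"bpseq"`).
#' @param path optional file path; when `NULL` the record is returned as a
#'   character vector of lines.
#' @return the record lines, invisibly when written to `path`.
#' @details Crossing pairs are written in dot-bracket by greedy assignment of
#' helices to the bracket families `()`, `[]`, `{}`, `<>`; structures needing
#' more than four mutually crossing families are rejected.
#' @export
write_structure <- function(s, format = c("dotbracket", "ct", "bpseq"),
                            path = NULL) {
  format <- match.arg(format)
  lines <- switch(format,
                  dotbracket = .format_dotbracket(s),
                  ct = .format_ct(s),
                  bpseq = .format_bpseq(s))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

.format_dotbracket <- function(s) {
  chars <- rep(".", s$length)
  if (nrow(s$pairs) > 0) {
    ord <- order(s$pairs[, 1])
    pr <- s$pairs[ord, , drop = FALSE]
    page <- integer(nrow(pr))
    for (k in seq_len(nrow(pr))) {
      placed <- FALSE
      for (pg in 1:4) {
        same <- which(page[seq_len(k - 1L)] == pg)
        crossing <- FALSE
        for (m in same) {
          a <- pr[m, 1]; b <- pr[m, 2]; i <- pr[k, 1]; j <- pr[k, 2]
          if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
            crossing <- TRUE; break
          }
        }
        if (!crossing) { page[k] <- pg; placed <- TRUE; break }
      }
      if (!placed)
        stop("structure needs more than 4 crossing bracket families")
    }
    chars[pr[, 1] + 1L] <- .bracket_open[page]
    chars[pr[, 2] + 1L] <- .bracket_close[page]
  }
  seq <- if (nzchar(s$sequence)) s$sequence else strrep("N", s$length)
  c(paste0(">", s$id), seq, paste(chars, collapse = ""))
}

.format_ct <- function(s) {
  partner <- pair_partner(s)
  partner[is.na(partner)] <- 0L
  seq <- if (nzchar(s$sequence)) strsplit(s$sequence, "")[[1]]
         else rep("N", s$length)
  i <- seq_len(s$length)
  c(paste(s$length, s$id),
    sprintf("%d %s %d %d %d %d", i, seq, i - 1L,
            ifelse(i == s$length, 0L, i + 1L), partner, i))
}

.format_bpseq <- function(s) {
  partner <- pair_partner(s)
  partner[is.na(partner)] <- 0L
  seq <- if (nzchar(s$sequence)) strsplit(s$sequence, "")[[1]]
         else rep("N", s$length)
  sprintf("%d %s %d", seq_len(s$length), seq, partner)
}

#' Read RNA secondary structures from a file
#'
#' Dot-bracket files may hold several records (each introduced by a `>id`
#' line); CT and bpseq files hold one record.
#'
#' @param path file path.
#' @param format format; by default guessed from the file extension
#'   (`.ct`, `.bpseq`, otherwise dot-bracket).
#' @return a list of [rna_structure] objects (length one for CT/bpseq).
#' @export
read_structures <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ct") "ct" else if (ext == "bpseq") "bpseq"
              else "dotbracket"
  }
  lines <- readLines(path)
  if (format != "dotbracket")
    return(list(parse_structure(lines, format,
                                id = tools::file_path_sans_ext(basename(path)))))
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) starts <- 1L
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts))
    out[[k]] <- parse_structure(lines[starts[k]:ends[k]], "dotbracket",
                                id = paste0("structure", k))
  names(out) <- vapply(out, function(s) s$id, "")
  out
}
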
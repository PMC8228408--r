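#' Build an ordered multistate character matrix from decomposed structures
#'
#' Each homologous substructure becomes one character; its state in a taxon
#' is the substructure's length coded with [encode_state()]. Taxa lacking a
#' substructure get the minimum state `'0'` (absence). All characters are
#' ordered (Wagner): states form a linear chain, so a change from value i to
#' value j costs |i - j| steps.
#'
#' Homology between per-molecule substructures is positional. When all
#' molecules share a template topology the positional labels produced by
#' [decompose()] (`S1`, `HL1`, ...) already align and `homology` can be left
#' `NULL`; otherwise supply an explicit per-taxon map from local to shared
#' labels.
#'
#' @param decomps named list (one entry per taxon) of [decompose()] results.
#' @param homology `NULL` for identity, or a named list (per taxon) of named
#'   character vectors mapping local substructure labels to shared homology
#'   labels. Local labels missing from a taxon's map keep their own name.
#' @param gu_class class assigned to `gu_pairs` characters, see
#'   [substructure_class()].
#' @return an object of class `char_matrix`: list with `taxa`, `labels`,
#'   `class` (named character vector, `helical`/`unpaired`), `states`
#'   (taxa x characters matrix of symbols) and `ordered = TRUE`.
#' @export
build_character_matrix <- function(decomps, homology = NULL,
                                   gu_class = c("unpaired", "helical")) {
  gu_class <- match.arg(gu_class)
  stopifnot(is.list(decomps), length(decomps) > 0)
  if (is.null(names(decomps)) || any(!nzchar(names(decomps))))
    stop("decomps must be a named list (taxon labels)")
  taxa <- names(decomps)

  relabel <- function(taxon, d) {
    map <- homology[[taxon]]
    glb <- d$label
    if (!is.null(map)) {
      hit <- match(d$label, names(map))
      glb[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
    }
    if (anyDuplicated(glb))
      stop("homology conflict in taxon '", taxon,
           "': two substructures share label(s) ",
           paste(unique(glb[duplicated(glb)]), collapse = ", "))
    glb
  }

  globals <- lapply(taxa, function(tx) relabel(tx, decomps[[tx]]))
  labels <- unique(unlist(globals))
  cls <- setNames(rep(NA_character_, length(labels)), labels)
  states <- matrix("0", nrow = length(taxa), ncol = length(labels),
                   dimnames = list(taxa, labels))
  for (k in seq_along(taxa)) {
    d <- decomps[[k]]
    if (nrow(d) == 0L) next
    cl <- substructure_class(d$kind, gu_class)
    lb <- globals[[k]]
    conflict <- !is.na(cls[lb]) & cls[lb] != cl
    if (any(conflict))
      stop("character class conflict for label(s) ",
           paste(lb[conflict], collapse = ", "),
           " (helical vs unpaired across taxa)")
    cls[lb] <- cl
    states[k, lb] <- encode_state(d$length)
  }
  char_matrix(states, cls)
}

#' Construct a character matrix from states and classes
#'
#' Low-level constructor for an ordered multistate character matrix.
#'
#' @param states character matrix of state symbols (`0-9A-Z`) with taxa as
#'   rownames and character labels as colnames. An integer matrix of state
#'   values is also accepted and encoded.
#' @param class character vector (length = number of characters) of classes,
#'   `"helical"` or `"unpaired"`.
#' @return a `char_matrix`.
#' @export
char_matrix <- function(states, class) {
  if (is.numeric(states)) {
    sym <- matrix(encode_state(states), nrow = nrow(states),
                  dimnames = dimnames(states))
    states <- sym
  }
  if (is.null(rownames(states)) || is.null(colnames(states)))
    stop("states must have taxa rownames and character colnames")
  decode_state(states)  # validates symbols
  if (length(class) != ncol(states))
    stop("class must have one entry per character")
  if (!all(class %in% c("helical", "unpaired")))
    stop("classes must be 'helical' or 'unpaired'")
  structure(list(taxa = rownames(states), labels = colnames(states),
                 class = setNames(as.character(class), colnames(states)),
                 states = states, ordered = TRUE),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Ordered multistate character matrix: ", length(x$taxa), " taxa x ",
      length(x$labels), " characters (",
      sum(x$class == "helical"), " helical, ",
      sum(x$class == "unpaired"), " unpaired)\n", sep = "")
  invisible(x)
}

#' Integer state values of a character matrix
#'
#' @param cm a `char_matrix`.
#' @return integer matrix (taxa x characters) of decoded state values 0..35.
#' @export
state_values <- function(cm) {
  v <- matrix(decode_state(cm$states), nrow = length(cm$taxa),
              dimnames = dimnames(cm$states))
  v
}

.nexus_symbols <- paste(c(as.character(0:9), LETTERS), collapse = "")

#' Write a character matrix as a NEXUS file
#'
#' Emits a `DATA` block with
#' `SYMBOLS="0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ"` and a `SETS` block with
#' one `CHARSET` per character class (`helical`, `unpaired`).
#'
#' @param cm a `char_matrix`.
#' @param path output file path, or `NULL` to return the lines.
#' @return the file lines, invisibly when written.
#' @export
write_nexus_matrix <- function(cm, path = NULL) {
  stopifnot(inherits(cm, "char_matrix"))
  pad <- max(nchar(cm$taxa))
  rows <- sprintf("    %-*s  %s", pad, cm$taxa,
                  apply(cm$states, 1, paste, collapse = ""))
  charsets <- character(0)
  for (cl in c("helical", "unpaired")) {
    idx <- which(cm$class == cl)
    if (length(idx) > 0)
      charsets <- c(charsets, sprintf("  CHARSET %s = %s;", cl,
                                      paste(idx, collapse = " ")))
  }
  lines <- c("#NEXUS",
             "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                     length(cm$taxa), length(cm$labels)),
             sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
                     .nexus_symbols),
             paste0("  CHARLABELS ", paste(cm$labels, collapse = " "), ";"),
             "  MATRIX",
             rows,
             "  ;",
             "END;",
             "BEGIN SETS;",
             charsets,
             "END;")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a character matrix from a NEXUS file
#'
#' Reads the `DATA`/`CHARACTERS` block written by [write_nexus_matrix()]
#' (alphanumeric standard data, optional `CHARLABELS`, `CHARSET` lines
#' assigning classes; ranges like `1-4` are supported in charsets).
#'
#' @param path file path or a character vector of lines.
#' @return a `char_matrix`.
#' @export
read_nexus_matrix <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(sub("\\[[^]]*\\]", "", lines))  # strip NEXUS comments
  if (length(lines) == 0L || !grepl("^#NEXUS", lines[1], ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header)")
  one <- paste(lines, collapse = "\n")
  dim_m <- regmatches(one, regexpr("DIMENSIONS[^;]*;", one, ignore.case = TRUE))
  if (length(dim_m) == 0) stop("NEXUS: no DIMENSIONS statement")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", dim_m,
                         ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", dim_m,
                           ignore.case = TRUE))
  lab_m <- regmatches(one, regexpr("CHARLABELS[^;]*;", one, ignore.case = TRUE))
  labels <- if (length(lab_m) == 1) {
    strsplit(trimws(sub(";$", "", sub("^CHARLABELS", "", lab_m,
                                      ignore.case = TRUE))), "\\s+")[[1]]
  } else paste0("char", seq_len(nchar_))
  if (length(labels) != nchar_)
    stop("NEXUS: CHARLABELS count ", length(labels), " != NCHAR ", nchar_)

  mstart <- grep("^MATRIX\\b", lines, ignore.case = TRUE)
  if (length(mstart) != 1) stop("NEXUS: expected one MATRIX statement")
  taxa <- character(0); rows <- character(0)
  k <- mstart + 1L
  while (k <= length(lines)) {
    ln <- lines[k]
    if (grepl("^;", ln)) break
    if (nzchar(ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 2) stop("NEXUS MATRIX line ", k, ": expected taxon + states")
      taxa <- c(taxa, f[1])
      rows <- c(rows, gsub("\\s", "", paste(f[-1], collapse = "")))
    }
    k <- k + 1L
  }
  if (k > length(lines)) stop("NEXUS: MATRIX not terminated by ';'")
  if (length(taxa) != ntax)
    stop("NEXUS: MATRIX has ", length(taxa), " taxa, DIMENSIONS says ", ntax)
  if (anyDuplicated(taxa))
    stop("NEXUS: duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (any(nchar(rows) != nchar_))
    stop("NEXUS: matrix row length != NCHAR ", nchar_)
  states <- matrix(unlist(strsplit(rows, "")), nrow = ntax, byrow = TRUE,
                   dimnames = list(taxa, labels))
  decode_state(states)  # validates the symbols

  cls <- setNames(rep("unpaired", nchar_), labels)
  cs <- regmatches(one, gregexpr("CHARSET[^;]*;", one, ignore.case = TRUE))[[1]]
  for (stmt in cs) {
    body <- trimws(sub(";$", "", sub("^CHARSET", "", stmt, ignore.case = TRUE)))
    nm <- trimws(sub("=.*", "", body))
    spec <- strsplit(trimws(sub(".*=", "", body)), "\\s+")[[1]]
    idx <- unlist(lapply(spec, function(tok) {
      if (grepl("-", tok)) {
        ab <- as.integer(strsplit(tok, "-")[[1]])
        ab[1]:ab[2]
      } else as.integer(tok)
    }))
    if (any(is.na(idx)) || any(idx < 1 | idx > nchar_))
      stop("NEXUS: bad CHARSET indices in: ", stmt)
    cls[idx] <- nm
  }
  if (!all(cls %in% c("helical", "unpaired")))
    stop("NEXUS: charsets must assign classes 'helical'/'unpaired'")
  structure(list(taxa = taxa, labels = labels, class = cls,
                 states = states, ordered = TRUE),
            class = "char_matrix")
}
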
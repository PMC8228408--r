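#' Run configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]. All
#' fields are optional except `out_dir`; the pipeline runs whichever stages
#' its inputs allow. Configurations round-trip losslessly through JSON via
#' [read_run_config()] / [write_run_config()].
#'
#' @param structures path to a dot-bracket file of molecules (alternative to
#'   `matrix`).
#' @param matrix path to a NEXUS character matrix.
#' @param tree path to a rooted tree of molecules (Newick/NEXUS) for
#'   step-matrix tracing.
#' @param subtree path to a rooted tree of substructures for node-distance
#'   ages.
#' @param ages path to a `label<TAB>nd` TSV (alternative to `subtree`).
#' @param series path to an accretion-series TSV (bypasses all upstream
#'   stages for the correlation/MA stages).
#' @param class_filter `"both"`, `"helical"` or `"unpaired"`.
#' @param gu_separate code per-stem G:U wobble counts as extra characters.
#' @param mpr_limit MPR enumeration bound for [unambiguous_changes()].
#' @param normalization bubble-chart normalization, `"mean"` or `"raw"`.
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed recorded in the manifest and set before any
#'   stochastic stage.
#' @param verbose print stage progress.
#' @return a `run_config` list.
#' @export
run_config <- function(structures = NULL, matrix = NULL, tree = NULL,
                       subtree = NULL, ages = NULL, series = NULL,
                       class_filter = c("both", "helical", "unpaired"),
                       gu_separate = FALSE, mpr_limit = 1e5,
                       normalization = c("mean", "raw"),
                       out_dir = "accretion-out", seed = 1L,
                       verbose = FALSE) {
  cfg <- list(structures = structures, matrix = matrix, tree = tree,
              subtree = subtree, ages = ages, series = series,
              class_filter = match.arg(class_filter),
              gu_separate = isTRUE(gu_separate),
              mpr_limit = as.numeric(mpr_limit),
              normalization = match.arg(normalization),
              out_dir = out_dir, seed = as.integer(seed),
              verbose = isTRUE(verbose))
  for (f in c("structures", "matrix", "tree", "subtree", "ages", "series"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config error: ", f, " file does not exist: ", cfg[[f]])
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, TRUE)])
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)], path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cfg)
}

.stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the accretion-analysis pipeline
#'
#' Executes, as the inputs allow: structure decomposition and character
#' coding; step-matrix tracing of unambiguous character-state changes on a
#' tree of molecules; node-distance ages from a tree of substructures;
#' length-versus-age correlation statistics; and Menzerath-Altmann fits of
#' length versus accretion rank. All artifacts (NEXUS matrix, bubble TSVs,
#' series TSV, correlation JSON, MA report TSV) plus a JSON manifest
#' (inputs, package version, seed, config) are written to `out_dir`.
#' Outputs are a pure function of (inputs, config, seed).
#'
#' @param cfg a [run_config()], or a path to its JSON form.
#' @return the run report (paths and fitted objects), invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- cfg$verbose
  report <- list(config = cfg, outputs = character(0))
  out <- function(...) file.path(cfg$out_dir, paste0(...))

  cm <- NULL
  if (!is.null(cfg$matrix)) {
    cm <- .stage("matrix", v, read_nexus_matrix(cfg$matrix))
  } else if (!is.null(cfg$structures)) {
    cm <- .stage("encode", v, {
      strs <- read_structures(cfg$structures)
      decomps <- lapply(strs, decompose, gu_separate = cfg$gu_separate)
      m <- build_character_matrix(decomps)
      write_nexus_matrix(m, out("matrix.nex"))
      m
    })
    report$outputs <- c(report$outputs, out("matrix.nex"))
  }
  report$matrix <- cm

  if (!is.null(cfg$tree) && !is.null(cm)) {
    report$step_matrices <- .stage("csr", v, {
      tr <- read_tree(cfg$tree)
      classes <- if (cfg$class_filter == "both") c("helical", "unpaired")
                 else cfg$class_filter
      classes <- intersect(classes, unique(cm$class))
      sms <- lapply(classes, function(cl) {
        sm <- build_step_matrix(tr, cm, cl, cfg$normalization, cfg$mpr_limit)
        export_bubble(sm, out("bubble-", cl, ".tsv"))
        sm
      })
      names(sms) <- classes
      report$outputs <- c(report$outputs,
                          out("bubble-", classes, ".tsv"))
      sms
    })
  }

  ages <- NULL
  if (!is.null(cfg$ages)) {
    ages <- .stage("ages", v, utils::read.delim(cfg$ages))
  } else if (!is.null(cfg$subtree)) {
    ages <- .stage("ages", v, {
      a <- node_distance_ages(read_tree(cfg$subtree))
      write_ages(a, out("ages.tsv"))
      a
    })
    report$outputs <- c(report$outputs, out("ages.tsv"))
  }

  series <- NULL
  if (!is.null(cfg$series)) {
    series <- .stage("series", v, read_series(cfg$series))
  } else if (!is.null(cm) && !is.null(ages)) {
    series <- .stage("series", v,
                     build_series(mean_lengths(cm), ages, cfg$class_filter))
  }
  if (!is.null(series)) {
    write_series(series, out("series.tsv"))
    report$outputs <- c(report$outputs, out("series.tsv"))
    report$series <- series

    classes <- if (cfg$class_filter == "both") unique(series$class)
               else cfg$class_filter
    report$correlations <- .stage("correlate", v, {
      res <- list()
      for (cl in classes) {
        sub <- series[series$class == cl, ]
        if (nrow(sub) >= 3) res[[cl]] <- correlate(sub)
      }
      jsonlite::write_json(lapply(res, unclass), out("correlations.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      res
    })
    report$ma_fits <- .stage("mafit", v, {
      fits <- list()
      for (cl in classes) {
        sub <- series[series$class == cl, ]
        if (nrow(sub) >= 3) fits[[paste0(cl, "_special")]] <- fit_ma_special(sub)
        if (nrow(sub) >= 4) fits[[paste0(cl, "_general")]] <-
          tryCatch(fit_ma_general(sub), error = function(e) NULL,
                   warning = function(w) suppressWarnings(fit_ma_general(sub)))
      }
      fits <- fits[!vapply(fits, is.null, TRUE)]
      if (length(fits)) ma_report(fits, out("ma-fits.tsv"))
      fits
    })
    report$outputs <- c(report$outputs, out("correlations.json"),
                        out("ma-fits.tsv"))
  }

  manifest <- list(
    package = "rnaccretion",
    version = as.character(utils::packageVersion("rnaccretion")),
    seed = cfg$seed,
    inputs = Filter(Negate(is.null),
                    cfg[c("structures", "matrix", "tree", "subtree",
                          "ages", "series")]),
    config = unclass(cfg),
    outputs = report$outputs)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  report$manifest <- out("manifest.json")
  invisible(report)
}

#' Write the synthetic fixture set produced by a config
#'
#' Convenience exporter behind the `simulate` pipeline stage: writes the
#' dot-bracket molecule set, its NEXUS matrix, a pectinate tree of the
#' molecule set's substructures in 5'-to-3' template order (Newick, so
#' node-distance ages join against the coded characters), an accretion
#' series TSV drawn from the generative MA law, and a JSON manifest
#' recording the configuration and seed.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory.
#' @return named character vector of the files written, invisibly.
#' @export
write_synthetic_set <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hist <- gen_accretion_history(cfg)
  mols <- gen_molecule_set(cfg)
  files <- c(structures = file.path(out_dir, "molecules.dbn"),
             matrix = file.path(out_dir, "matrix.nex"),
             subtree = file.path(out_dir, "substructures.nwk"),
             series = file.path(out_dir, "series.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  writeLines(unlist(lapply(mols$structures, write_structure, "dotbracket")),
             files["structures"])
  decomps <- lapply(mols$structures, decompose, gu_separate = FALSE)
  write_nexus_matrix(build_character_matrix(decomps), files["matrix"])
  ## tree of the molecule set's substructures: accretion follows the
  ## 5'-to-3' template order, so its labels join the coded characters
  ape::write.tree(pectinate_tree(ncol(mols$lengths),
                                 labels = colnames(mols$lengths)),
                  files["subtree"])
  write_series(hist$series, files["series"])
  jsonlite::write_json(list(package = "rnaccretion",
                            version = as.character(
                              utils::packageVersion("rnaccretion")),
                            config = unclass(cfg)),
                       files["manifest"], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(files)
}
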
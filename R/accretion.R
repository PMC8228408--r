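#' Average substructure lengths from a character matrix
#'
#' Per character, the mean of the decoded state values over the taxa in
#' which the substructure is present. Absences (state `'0'`) are excluded
#' from the average; characters absent from every taxon are dropped with a
#' warning.
#'
#' @param cm a `char_matrix`.
#' @return data.frame with columns `label`, `class`, `mean_length`,
#'   `n_present`.
#' @export
mean_lengths <- function(cm) {
  stopifnot(inherits(cm, "char_matrix"))
  if (length(cm$labels) == 0L) stop("character matrix is empty")
  vals <- state_values(cm)
  n_present <- colSums(vals > 0L)
  ml <- vapply(seq_along(cm$labels), function(j) {
    v <- vals[, j]
    if (n_present[j] == 0L) NA_real_ else mean(v[v > 0L])
  }, 0)
  drop <- n_present == 0L
  if (any(drop))
    warning("dropping character(s) absent in all taxa: ",
            paste(cm$labels[drop], collapse = ", "))
  data.frame(label = cm$labels[!drop],
             class = unname(cm$class[!drop]),
             mean_length = ml[!drop],
             n_present = unname(n_present[!drop]),
             stringsAsFactors = FALSE)
}

#' Build a length-versus-age accretion series
#'
#' Joins per-substructure mean lengths with their node-distance ages and
#' assigns each substructure its accretion rank `x`: the number of
#' substructures that had appeared by its time of origin (the cumulative
#' count of records with `nd` less than or equal to its own, ties sharing
#' the same `x`). `x` is the "number of parts" axis of the
#' Menzerath-Altmann law.
#'
#' @param means data.frame from [mean_lengths()] (columns `label`, `class`,
#'   `mean_length`).
#' @param ages data.frame from [node_distance_ages()] (columns `label`,
#'   `nd`), typically computed on a rooted tree of substructures.
#' @param class_filter `"both"`, `"helical"` or `"unpaired"`.
#' @return an `accretion_series` data.frame with columns `label`, `class`,
#'   `nd`, `mean_length`, `x`, sorted by `nd`.
#' @export
build_series <- function(means, ages,
                         class_filter = c("both", "helical", "unpaired")) {
  class_filter <- match.arg(class_filter)
  stopifnot(is.data.frame(means), is.data.frame(ages))
  no_age <- setdiff(means$label, ages$label)
  no_mean <- setdiff(ages$label, means$label)
  if (length(no_age) || length(no_mean))
    stop("label join error;",
         if (length(no_age)) paste0(" mean length without age: ",
           paste(no_age, collapse = ", ")),
         if (length(no_mean)) paste0(" age without mean length: ",
           paste(no_mean, collapse = ", ")))
  if (class_filter != "both") means <- means[means$class == class_filter, ]
  if (nrow(means) == 0L)
    stop("no substructures left after class filter '", class_filter, "'")
  nd <- ages$nd[match(means$label, ages$label)]
  out <- data.frame(label = means$label, class = means$class, nd = nd,
                    mean_length = means$mean_length,
                    stringsAsFactors = FALSE)
  out <- out[order(out$nd, out$label), ]
  out$x <- vapply(out$nd, function(v) sum(out$nd <= v), 0L)
  rownames(out) <- NULL
  class(out) <- c("accretion_series", "data.frame")
  out
}

#' Coerce a data.frame to an accretion series
#'
#' Accepts external chronology tables (columns `label`, `class`, `nd`,
#' `mean_length`), sorts them by age and (re)computes the accretion rank
#' `x`, so published chronologies can bypass the structure-coding and tree
#' stages.
#'
#' @param df data.frame with columns `label`, `class`, `nd`, `mean_length`.
#' @return an `accretion_series`.
#' @export
as_accretion_series <- function(df) {
  need <- c("label", "class", "nd", "mean_length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$nd < 0 | df$nd > 1)) stop("nd must lie in [0, 1]")
  if (any(df$mean_length <= 0)) stop("mean_length must be positive")
  out <- df[order(df$nd, df$label), need]
  out$x <- vapply(out$nd, function(v) sum(out$nd <= v), 0L)
  rownames(out) <- NULL
  class(out) <- c("accretion_series", "data.frame")
  out
}

#' Read / write accretion series TSV
#'
#' @param path file path with tab-separated columns `label`, `class`, `nd`,
#'   `mean_length`.
#' @return an `accretion_series`.
#' @export
read_series <- function(path) {
  as_accretion_series(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_series
#' @param series an `accretion_series`.
#' @export
write_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(series)
}

## exact two-tailed permutation p-value for Spearman's rho (n <= 9)
.all_perms <- function(n) {
  P <- matrix(1L, 1, 1)
  if (n == 1L) return(P)
  for (k in 2:n) {
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      block <- (pos - 1L) * m + seq_len(m)
      if (pos > 1L) out[block, seq_len(pos - 1L)] <- P[, seq_len(pos - 1L)]
      out[block, pos] <- k
      if (pos < k) out[block, (pos + 1L):k] <- P[, pos:(k - 1L), drop = FALSE]
    }
    P <- out
  }
  P
}

.spearman_exact_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rxc <- rx - mean(rx)
  den <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
  P <- .all_perms(n)
  M <- matrix(ry[P], ncol = n)
  rho_perm <- as.vector(M %*% rxc) / den
  rho_obs <- sum(ry * rxc) / den
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
}

#' Correlation and normality statistics for an accretion series
#'
#' Reproduces the statistics used to test diminishing returns: an ordinary
#' least-squares regression of mean substructure length on relative age
#' (`nd`), Pearson's correlation with its two-sided t-test (df = n - 2),
#' Spearman's rho (average ranks for ties) with an exact two-tailed
#' permutation p-value for n <= 9 and the t-approximation otherwise, and a
#' Kolmogorov-Smirnov test of normality of the lengths against a normal
#' with the sample mean and standard deviation. Because plug-in KS p-values
#' are conservative, a Lilliefors-corrected p-value is reported as well
#' (for n >= 5).
#'
#' @param series an `accretion_series` (n >= 3) with positive variance in
#'   both `nd` and `mean_length`.
#' @return an object of class `correlation_result` with fields `slope`,
#'   `intercept`, `R2`, `r`, `p_r`, `rho`, `p_rho`, `df`, `D`, `p_D`,
#'   `p_D_lilliefors`, `n`.
#' @export
correlate <- function(series) {
  stopifnot(is.data.frame(series))
  n <- nrow(series)
  if (n < 3L) stop("correlation needs n >= 3 points, got ", n)
  y <- series$mean_length
  t <- series$nd
  if (stats::var(t) == 0 || stats::var(y) == 0)
    stop("degenerate input: zero variance in ",
         if (stats::var(t) == 0) "nd" else "mean_length")
  fit <- stats::lm(y ~ t)
  sm <- .quiet_summary(fit)
  pear <- stats::cor.test(t, y, method = "pearson", alternative = "two.sided")
  rx <- rank(t); ry <- rank(y)
  rho <- if (anyDuplicated(rx) || anyDuplicated(ry)) {
    stats::cor(rx, ry)  # average ranks for ties
  } else {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))  # exact without ties
  }
  p_rho <- if (n <= 9L) {
    .spearman_exact_p(t, y)
  } else {
    if (1 - rho^2 <= 0) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), n - 2)
    }
  }
  ks <- suppressWarnings(stats::ks.test(y, "pnorm", mean(y), stats::sd(y)))
  lil <- if (n >= 5L) tryCatch(nortest::lillie.test(y), error = function(e) NULL)
         else NULL
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 R2 = sm$r.squared,
                 r = unname(pear$estimate),
                 p_r = pear$p.value,
                 rho = unname(rho),
                 p_rho = p_rho,
                 df = n - 2L,
                 D = unname(ks$statistic),
                 p_D = ks$p.value,
                 p_D_lilliefors = if (is.null(lil)) NA_real_ else lil$p.value,
                 n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 3, ...) {
  star <- function(p) if (is.na(p)) "" else if (p < 0.001) " **"
                      else if (p < 0.05) " *" else ""
  cat("Length-vs-age correlation (n = ", x$n, ", df = ", x$df, ")\n",
      "  OLS: slope = ", signif(x$slope, digits),
      ", intercept = ", signif(x$intercept, digits),
      ", R2 = ", signif(x$R2, digits), "\n",
      "  Pearson r = ", signif(x$r, digits), star(x$p_r),
      " (p = ", signif(x$p_r, digits), ")\n",
      "  Spearman rho = ", signif(x$rho, digits), star(x$p_rho),
      " (two-tailed p = ", signif(x$p_rho, digits), ")\n",
      "  KS normality: D = ", signif(x$D, digits),
      ", p = ", signif(x$p_D, digits),
      ", Lilliefors p = ", signif(x$p_D_lilliefors, digits), "\n", sep = "")
  invisible(x)
}
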
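#' Read a multi-phenotype GWAS summary-statistics table
#'
#' Reads a delimited text file with a header row, a SNP identifier in the
#' first column and one association p-value column per phenotype. Rows with
#' any missing p-value are dropped (with a message reporting the count),
#' mirroring standard multi-trait preprocessing where only SNPs observed in
#' every study are retained.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @param delim Field delimiter. `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A tibble: `snp_id` plus one numeric column per phenotype.
#' @seealso [transform_pvalues()], [thin_snps()]
#' @export
read_summary_stats <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  # columns are read as text and converted with R's correctly rounded
  # strtod so that written doubles round-trip bit-exactly
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  names(out)[1] <- "snp_id"
  for (j in seq_along(out)[-1]) {
    num <- suppressWarnings(as.numeric(out[[j]]))
    if (all(is.na(num) == is.na(out[[j]]))) out[[j]] <- num
  }
  drop_missing_rows(out)
}

#' Read per-SNP annotation scores or binary annotations
#'
#' Same layout as [read_summary_stats()]: SNP identifier first, then one
#' column per annotation track (scores in \[0, 1\] or already-binary 0/1).
#'
#' @inheritParams read_summary_stats
#' @return A tibble: `snp_id` plus one numeric column per annotation.
#' @export
read_annotation_scores <- function(path, delim = NULL) {
  read_summary_stats(path, delim = delim)
}

#' Read a prior phenotype graph as an edge list
#'
#' The prior graph encodes external knowledge (e.g. from literature mining)
#' about which phenotype pairs are expected to be genetically correlated. The
#' file is a two-column delimited edge list of phenotype labels, one edge per
#' row. Self-edges are invalid.
#'
#' @inheritParams read_summary_stats
#' @return A tibble with columns `from` and `to`.
#' @export
read_prior_graph <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (ncol(out) < 2) abort("A prior graph file needs two columns of phenotype labels.")
  out <- tibble::tibble(from = as.character(out[[1]]), to = as.character(out[[2]]))
  if (any(out$from == out$to)) {
    abort("Prior graph contains self-edges; a phenotype cannot be linked to itself.")
  }
  out
}

#' Write a table in the package's delimited dialect
#'
#' @param data A data frame.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `data`, invisibly.
#' @export
write_stats_table <- function(data, path, delim = "\t") {
  readr::write_delim(data, path, delim = delim, progress = FALSE)
  invisible(data)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

drop_missing_rows <- function(data) {
  keep <- stats::complete.cases(data)
  if (!all(keep)) {
    inform(sprintf("Dropped %d row(s) with missing values.", sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  data
}

#' Transform association p-values to z-scores
#'
#' Applies the probit transform \eqn{y = \Phi^{-1}(1 - p)} column-wise, after
#' clipping p-values into `[clip_low, clip_high]` so the result is always
#' finite (p-values of exactly 0 or 1 occur in real summary statistics).
#' Under the null, y is standard normal; strongly associated SNPs have large
#' positive y.
#'
#' @param data Data frame: SNP identifier column followed by one p-value
#'   column per phenotype. Rows with missing values are dropped with a
#'   message.
#' @param clip_low,clip_high Clipping bounds, `0 < clip_low < clip_high < 1`.
#' @return A tibble of the same layout holding z-scores.
#' @examples
#' transform_pvalues(data.frame(snp_id = "rs1", P1 = 0.025))
#' @export
transform_pvalues <- function(data, clip_low = 1e-300, clip_high = 1 - 1e-16) {
  check_prob(clip_low, "clip_low")
  check_prob(clip_high, "clip_high")
  if (clip_low >= clip_high) abort("`clip_low` must be below `clip_high`.")
  data <- drop_missing_rows(data)
  s <- split_stats(data, "p-value")
  p <- s$values
  bad <- which(p < 0 | p > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "p-value out of [0, 1] at SNP '%s', phenotype '%s' (value %g).",
      s$ids[bad[1, 1]], s$names[bad[1, 2]], p[bad[1, 1], bad[1, 2]]))
  }
  p <- pmin(pmax(p, clip_low), clip_high)
  # qnorm(p, lower.tail = FALSE) evaluates Phi^{-1}(1 - p) without the
  # catastrophic cancellation of 1 - p for tiny p
  y <- qnorm(p, lower.tail = FALSE)
  dimnames(y) <- list(NULL, s$names)
  bind_stats(s$ids, y)
}

#' Binarize annotation scores at a cutoff
#'
#' Converts continuous per-SNP functional scores in \[0, 1\] (e.g. posterior
#' probabilities of functionality from tissue-specific epigenome integration)
#' into binary annotations: 1 iff the score is strictly above `cutoff`.
#'
#' @param data Data frame: SNP identifier column followed by score columns.
#' @param cutoff Strict threshold, default 0.5.
#' @return A tibble of the same layout with 0/1 entries.
#' @export
binarize_annotations <- function(data, cutoff = 0.5) {
  s <- split_stats(data, "score")
  x <- s$values
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    abort("Annotation scores must lie in [0, 1].")
  }
  a <- (x > cutoff) + 0
  dimnames(a) <- list(NULL, s$names)
  bind_stats(s$ids, a)
}

#' Thin SNPs by keeping one in every k
#'
#' Retains rows at positions 1, 1 + k, 1 + 2k, ... of the (file-ordered)
#' table, a cheap way to reduce local linkage disequilibrium between
#' neighbouring SNPs before model fitting. Apply it after missing-value
#' filtering; aligned annotation tables are thinned identically by passing
#' them through the same call or by re-aligning on `snp_id` afterwards.
#'
#' @param data Data frame in genomic/file order.
#' @param k Keep-one-in-k stride, a positive integer (default 10).
#' @return The thinned tibble.
#' @export
thin_snps <- function(data, k = 10) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != floor(k)) {
    abort("`k` must be a positive integer.")
  }
  tibble::as_tibble(data[seq(1, nrow(data), by = k), , drop = FALSE])
}

#' Decorrelate z-score columns to adjust for sample overlap
#'
#' Shared subjects between GWAS cohorts induce spurious correlation between
#' their summary statistics that can masquerade as pleiotropy. This removes
#' it by whitening the selected columns with the symmetric inverse square
#' root of their sample correlation matrix, \eqn{C^{-1/2}}: the columns are
#' standardized, multiplied per SNP by \eqn{C^{-1/2}} (eigendecomposition
#' root), and returned on their original location/scale, so the sample
#' correlation of the output group is exactly the identity. z-score columns
#' are already approximately standardized, for which this coincides with
#' multiplying the raw matrix by \eqn{C^{-1/2}}. The operation is idempotent.
#'
#' @param data Data frame of z-scores (SNP identifier column first), e.g.
#'   from [transform_pvalues()].
#' @param group Character vector (length >= 2) of phenotype column names to
#'   decorrelate jointly; other columns are untouched. Default: all
#'   phenotype columns.
#' @return A tibble of the same layout.
#' @export
decorrelate_zscores <- function(data, group = NULL) {
  s <- split_stats(data, "z-score")
  group <- group %||% s$names
  missing <- setdiff(group, s$names)
  if (length(missing) > 0) {
    abort(sprintf("Phenotype(s) not found: %s.", paste(missing, collapse = ", ")))
  }
  if (length(group) < 2) abort("`group` must contain at least two phenotypes.")
  y <- s$values
  idx <- match(group, s$names)
  x <- y[, idx, drop = FALSE]
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) abort("A selected column is constant; cannot decorrelate.")
  z <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  C <- cor(x)
  eig <- eigen(C, symmetric = TRUE)
  if (min(eig$values) < 1e-10) {
    abort(sprintf(
      "Sample correlation matrix is singular or nearly so (smallest eigenvalue %.3e).",
      min(eig$values)))
  }
  w <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
  out <- z %*% w
  out <- sweep(sweep(out, 2, scl, "*"), 2, ctr, "+")
  y[, idx] <- out
  dimnames(y) <- list(NULL, s$names)
  bind_stats(s$ids, y)
}
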
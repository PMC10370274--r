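# Internal helpers shared across modules.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise logsumexp of a matrix (hot path: called per MH proposal)
col_logsumexp <- function(K) {
  nr <- nrow(K)
  m <- K[max.col(t(K)) + (seq_len(ncol(K)) - 1L) * nr]
  m + log(colSums(exp(K - rep(m, each = nr))))
}

# Split a samples-by-variables data frame into an id vector and a numeric
# matrix. The id column is the first column when it is character/factor;
# otherwise row indices are used as ids and all columns are treated as values.
split_stats <- function(data, what = "value") {
  if (!is.data.frame(data)) {
    abort(sprintf("`data` must be a data frame of per-SNP %s columns.", what))
  }
  first <- data[[1]]
  if (is.character(first) || is.factor(first)) {
    ids <- as.character(first)
    vals <- data[, -1, drop = FALSE]
  } else {
    ids <- as.character(seq_len(nrow(data)))
    vals <- data
  }
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("Non-numeric %s column(s): %s.", what,
                  paste(names(vals)[bad], collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- NULL
  list(ids = ids, values = m, names = colnames(vals),
       has_id = is.character(first) || is.factor(first))
}

# Rebuild a tibble in the layout produced by split_stats().
bind_stats <- function(ids, values, id_name = "snp_id") {
  out <- tibble::as_tibble(as.data.frame(values))
  dplyr::bind_cols(tibble::tibble(!!id_name := ids), out)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single probability in (0, 1).", name))
  }
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

# matrix of zeros that stays silent for zero-extent dimensions
zero_matrix <- function(nr, nc) {
  matrix(if (nr == 0L || nc == 0L) numeric(0) else 0, nr, nc)
}
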
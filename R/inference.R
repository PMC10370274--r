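# Decision layer: phenotype-graph calls, annotation-relevance calls, and
# FDR-controlled association lists from a fitted model.

#' Decide the phenotype graph from posterior edge summaries
#'
#' An edge between two phenotypes is called when both its posterior
#' inclusion probability p(E(i,j) | Y) and the posterior probability that
#' its pairwise coefficient is positive, p(beta_ij > 0 | Y), strictly
#' exceed their cuts (defaults 0.5 and 0.95). The double rule requires both
#' that the edge is structurally supported and that its coefficient is
#' clearly nonzero.
#'
#' @param fit A [pleio_fit()] object.
#' @param p_edge_cut,p_sign_cut Strict thresholds in (0, 1).
#' @return A tibble with one row per phenotype pair: `phenotype1`,
#'   `phenotype2`, `p_edge`, `p_beta_pos`, `beta_mean` (posterior mean given
#'   inclusion), and logical `edge`.
#' @export
decide_graph <- function(fit, p_edge_cut = 0.5, p_sign_cut = 0.95) {
  check_prob(p_edge_cut, "p_edge_cut")
  check_prob(p_sign_cut, "p_sign_cut")
  ed <- edge_table(fit)
  dplyr::mutate(ed, edge = .data$p_edge > p_edge_cut &
                  .data$p_beta_pos > p_sign_cut)
}

edge_table <- function(fit) {
  if (inherits(fit, "pleio_fit")) return(fit$edges)
  if (is.data.frame(fit)) return(tibble::as_tibble(fit))
  abort("`fit` must be a pleio_fit object (or its edge table).")
}

#' Decide which annotations are relevant to which phenotypes
#'
#' Annotation m is declared associated with phenotype i when
#' p(gamma_im > 0 | Y) strictly exceeds `p_sign_cut` (default 0.95).
#'
#' @param fit A [pleio_fit()] object.
#' @param p_sign_cut Strict threshold in (0, 1).
#' @return A tibble: `phenotype`, `annotation`, `p_gamma_pos`, `gamma_mean`
#'   (posterior mean given inclusion), logical `called`.
#' @export
decide_annotations <- function(fit, p_sign_cut = 0.95) {
  check_prob(p_sign_cut, "p_sign_cut")
  an <- if (inherits(fit, "pleio_fit")) fit$annotations else
    tibble::as_tibble(fit)
  dplyr::mutate(an, called = .data$p_gamma_pos > p_sign_cut)
}

#' Select significant items by the direct posterior probability approach
#'
#' Ranks items by posterior association probability (descending, ties in
#' input order) and selects the largest prefix whose mean local false
#' discovery rate -- the mean of 1 minus the probability -- does not exceed
#' `level`. This controls the global FDR at `level` directly from posterior
#' probabilities, without p-value thresholds.
#'
#' @param probs Vector of posterior association probabilities in \[0, 1\].
#' @param level Nominal FDR level in (0, 1).
#' @return Integer vector of selected indices into `probs`, in rank order
#'   (possibly empty).
#' @examples
#' fdr_select(c(0.99, 0.98, 0.9, 0.5), 0.05)  # selects the first three
#' @export
fdr_select <- function(probs, level) {
  check_prob(level, "level")
  if (length(probs) == 0) return(integer(0))
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    abort("`probs` must lie in [0, 1].")
  }
  ord <- order(-probs)  # stable: ties keep input order
  lfdr <- 1 - probs[ord]
  ok <- cumsum(lfdr) / seq_along(lfdr) <= level
  k <- if (any(ok)) max(which(ok)) else 0L
  ord[seq_len(k)]
}

#' FDR-controlled association calls for single phenotypes
#'
#' Applies [fdr_select()] to the per-SNP marginal posterior association
#' probabilities of each requested phenotype at each requested level.
#'
#' @param fit A [pleio_fit()] object.
#' @param phenotypes Character vector of phenotype names (default all).
#' @param levels Nominal FDR levels (default 0.05, 0.10, 0.20).
#' @return A tibble: `snp_id`, `target`, `prob`, `local_fdr`
#'   (`1 - prob`), and one logical column `sig_at_<level>` per level
#'   (monotone in level).
#' @export
association_calls <- function(fit, phenotypes = NULL,
                              levels = c(0.05, 0.10, 0.20)) {
  stopifnot(inherits(fit, "pleio_fit"))
  phenotypes <- phenotypes %||% fit$phenotypes
  idx <- match(phenotypes, fit$phenotypes)
  if (anyNA(idx)) {
    abort(sprintf("Unknown phenotype(s): %s.",
                  paste(phenotypes[is.na(idx)], collapse = ", ")))
  }
  purrr::map_dfr(seq_along(idx), function(k) {
    probs <- fit$snp_marginal[, idx[k]]
    calls_table(fit$snp_ids, phenotypes[k], probs, levels)
  })
}

calls_table <- function(snp_ids, target, probs, levels) {
  out <- tibble::tibble(snp_id = snp_ids, target = target,
                        prob = probs, local_fdr = 1 - probs)
  for (lv in sort(levels)) {
    sel <- rep(FALSE, length(probs))
    sel[fdr_select(probs, lv)] <- TRUE
    out[[sprintf("sig_at_%g", lv)]] <- sel
  }
  out
}

#' FDR-controlled pleiotropy calls for a phenotype set
#'
#' Uses the accumulated posterior probability that all indicators in the
#' set are simultaneously 1 -- p(e_it = 1, e_jt = 1 | Y) for a pair --
#' and applies the direct posterior probability FDR rule. All pairs are
#' accumulated by default; sets of three or more phenotypes must have been
#' requested at fitting time via `pleio_control(joint_sets = ...)`.
#'
#' @param fit A [pleio_fit()] object.
#' @param phenotypes Character vector (length >= 2) naming the set.
#' @param levels Nominal FDR levels.
#' @return A tibble in the layout of [association_calls()], with `target`
#'   the set label (names joined by `+`).
#' @export
pleiotropy_calls <- function(fit, phenotypes, levels = c(0.05, 0.10, 0.20)) {
  stopifnot(inherits(fit, "pleio_fit"))
  idx <- sort(match(phenotypes, fit$phenotypes))
  if (anyNA(idx) || length(idx) < 2) {
    abort("`phenotypes` must name at least two fitted phenotypes.")
  }
  label <- paste(fit$phenotypes[idx], collapse = "+")
  if (length(idx) == 2) {
    k <- which(fit$pairs[1, ] == idx[1] & fit$pairs[2, ] == idx[2])
    probs <- fit$snp_pairwise[, k]
  } else {
    g <- which(vapply(fit$joint_sets, identical, logical(1), idx))
    if (length(g) == 0) {
      abort(sprintf(
        "Joint probabilities for {%s} were not accumulated; re-run pleio_fit() with pleio_control(joint_sets = list(c(%s))).",
        label, paste(sprintf('"%s"', fit$phenotypes[idx]), collapse = ", ")))
    }
    probs <- fit$snp_joint[, g[1]]
  }
  calls_table(fit$snp_ids, label, probs, levels)
}

#' Export a decided phenotype graph in DOT format
#'
#' Writes an undirected graph with one node per phenotype and one edge per
#' called pair, labelled by the posterior mean of beta given inclusion.
#'
#' @param decision Output of [decide_graph()] (or a `pleio_fit`, decided at
#'   default cuts).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graph_dot <- function(decision, path) {
  if (inherits(decision, "pleio_fit")) decision <- decide_graph(decision)
  nodes <- unique(c(decision$phenotype1, decision$phenotype2))
  called <- decision[decision$edge, , drop = FALSE]
  lines <- c(
    "graph phenotypes {",
    sprintf('  "%s";', nodes),
    sprintf('  "%s" -- "%s" [label="%.2f"];',
            called$phenotype1, called$phenotype2, called$beta_mean),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
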
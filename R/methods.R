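#' @export
print.pleio_fit <- function(x, ...) {
  cat(sprintf(
    "Multi-trait MRF fit: %d SNPs, %d phenotypes, %d annotations\n",
    x$T, x$n, x$M))
  cat(sprintf("MCMC: %d sweeps (%d burn-in, thin %d), %d retained samples, %.1f s\n",
              x$control$n_iter, x$control$n_burnin, x$control$thin,
              x$n_kept, x$runtime_sec))
  g <- decide_graph(x)
  cat(sprintf("Edges called at default cuts (p_edge > 0.5, p_beta_pos > 0.95): %d / %d\n",
              sum(g$edge), nrow(g)))
  if (x$M > 0) {
    a <- decide_annotations(x)
    cat(sprintf("Annotation terms called (p_gamma_pos > 0.95): %d / %d\n",
                sum(a$called), nrow(a)))
  }
  invisible(x)
}

#' Tidy posterior summaries of a fitted model
#'
#' @param x A [pleio_fit()] object.
#' @param type One of `"edges"` (phenotype-pair posterior summaries),
#'   `"annotations"` (per phenotype-annotation pair), `"phenotypes"` (MRF
#'   intercepts alpha), `"emission"` (lognormal mu and sigma), or `"snps"`
#'   (per-SNP marginal association probabilities, long format).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pleio_fit
#' @export
tidy.pleio_fit <- function(x, type = c("edges", "annotations", "phenotypes",
                                       "emission", "snps"), ...) {
  type <- match.arg(type)
  switch(type,
    edges = x$edges,
    annotations = x$annotations,
    phenotypes = x$alpha,
    emission = x$emission,
    snps = {
      m <- x$snp_marginal
      colnames(m) <- x$phenotypes
      tidyr::pivot_longer(
        dplyr::bind_cols(tibble::tibble(snp_id = x$snp_ids),
                         tibble::as_tibble(as.data.frame(m))),
        -"snp_id", names_to = "phenotype", values_to = "prob")
    })
}

#' One-row summary of a fitted model
#'
#' @param x A [pleio_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row: dimensions, MCMC settings, number of
#'   edges and annotation terms called at default cuts, posterior mean of
#'   the annotation inclusion rate p_u, and runtime.
#' @method glance pleio_fit
#' @export
glance.pleio_fit <- function(x, ...) {
  tibble::tibble(
    n_snps = x$T, n_phenotypes = x$n, n_annotations = x$M,
    n_iter = x$control$n_iter, n_burnin = x$control$n_burnin,
    n_kept = x$n_kept,
    n_edges_called = sum(decide_graph(x)$edge),
    n_annotations_called = if (x$M > 0) sum(decide_annotations(x)$called) else 0L,
    p_u_mean = x$p_u_mean,
    runtime_sec = x$runtime_sec
  )
}

#' Plot a fitted model
#'
#' `type = "graph"` draws the decided phenotype graph on a circular layout
#' (edge width proportional to the posterior mean of beta);
#' `type = "trace"` shows thinned posterior traces for alpha, mu, sigma and
#' p_u; `type = "annotations"` shows a phenotype-by-annotation heatmap of
#' p(gamma > 0 | Y).
#'
#' @param object A [pleio_fit()] object.
#' @param type `"graph"`, `"trace"`, or `"annotations"`.
#' @param p_edge_cut,p_sign_cut Thresholds passed to [decide_graph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pleio_fit
#' @export
autoplot.pleio_fit <- function(object, type = c("graph", "trace", "annotations"),
                               p_edge_cut = 0.5, p_sign_cut = 0.95, ...) {
  type <- match.arg(type)
  if (type == "graph") {
    nodes <- tibble::tibble(
      phenotype = object$phenotypes,
      angle = 2 * pi * (seq_len(object$n) - 1) / object$n)
    nodes$x <- cos(nodes$angle)
    nodes$y <- sin(nodes$angle)
    ed <- decide_graph(object, p_edge_cut, p_sign_cut)
    ed <- ed[ed$edge, , drop = FALSE]
    ed <- dplyr::left_join(ed, setNames(nodes[c("phenotype", "x", "y")],
                                        c("phenotype1", "x1", "y1")),
                           by = "phenotype1")
    ed <- dplyr::left_join(ed, setNames(nodes[c("phenotype", "x", "y")],
                                        c("phenotype2", "x2", "y2")),
                           by = "phenotype2")
    ggplot2::ggplot() +
      ggplot2::geom_segment(
        data = ed,
        ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                     yend = .data$y2, linewidth = .data$beta_mean),
        colour = "grey40") +
      ggplot2::geom_point(data = nodes,
                          ggplot2::aes(x = .data$x, y = .data$y), size = 10,
                          colour = "steelblue") +
      ggplot2::geom_text(data = nodes,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$phenotype)) +
      ggplot2::scale_linewidth(range = c(0.3, 2.5), guide = "none") +
      ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
      ggplot2::theme_void() +
      ggplot2::labs(title = "Estimated phenotype graph")
  } else if (type == "trace") {
    tr <- object$traces
    phen <- object$phenotypes
    long <- dplyr::bind_rows(
      trace_long(tr$alpha, phen, "alpha"),
      trace_long(tr$mu, phen, "mu"),
      trace_long(sqrt(tr$sigma2), phen, "sigma"),
      tibble::tibble(sample = seq_along(tr$p_u), series = "p_u",
                     parameter = "p_u", value = tr$p_u))
    ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value,
                                       colour = .data$series)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "retained sample", y = NULL, colour = NULL)
  } else {
    an <- decide_annotations(object, p_sign_cut)
    ggplot2::ggplot(an, ggplot2::aes(x = .data$annotation, y = .data$phenotype,
                                     fill = .data$p_gamma_pos)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(
        label = ifelse(.data$called, sprintf("%.2f", .data$gamma_mean), "")),
        colour = "white") +
      ggplot2::scale_fill_gradient(low = "grey90", high = "firebrick",
                                   limits = c(0, 1)) +
      ggplot2::labs(fill = "p(γ>0|Y)")
  }
}

trace_long <- function(m, phen, parameter) {
  colnames(m) <- phen
  out <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(as.data.frame(m)),
                  sample = dplyr::row_number()),
    -"sample", names_to = "series", values_to = "value")
  out$parameter <- parameter
  out
}
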
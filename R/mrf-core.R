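# Exact probability computations for the latent Markov random field:
# emission densities, the annotation-modified auto-logistic kernel, its
# enumerated normalizing constant, the full conditional of a single latent
# indicator, and the joint log-posterior kernel.

.state_cache <- new.env(parent = emptyenv())

# All 2^n binary vectors as a 2^n x n matrix (first coordinate fastest).
mrf_states <- function(n) {
  key <- as.character(n)
  s <- .state_cache[[key]]
  if (is.null(s)) {
    s <- as.matrix(do.call(expand.grid, rep(list(c(0, 1)), n)))
    dimnames(s) <- NULL
    .state_cache[[key]] <- s
  }
  s
}

pairs_of <- function(n) if (n < 2) matrix(integer(0), 2, 0) else combn(n, 2)

# upper-triangle coefficient vector (pair order of pairs_of) from a matrix
upper_vec <- function(m, pairs) m[cbind(pairs[1, ], pairs[2, ])]

vec_to_sym <- function(v, pairs, n) {
  m <- matrix(0, n, n)
  m[cbind(pairs[1, ], pairs[2, ])] <- v
  m[cbind(pairs[2, ], pairs[1, ])] <- v
  m
}

#' Emission log-density of a transformed association statistic
#'
#' The observed z-score of an associated SNP (`associated = 1`) is modelled
#' as lognormal LN(mu, sigma2) -- associated SNPs have small p-values, hence
#' positive z -- and as standard normal N(0, 1) otherwise.
#'
#' @param y Numeric vector of z-scores.
#' @param associated 0/1 (recycled): latent association indicator.
#' @param mu,sigma2 Lognormal location and squared scale (used only where
#'   `associated == 1`).
#' @return Log-density; `-Inf` for an associated value with `y <= 0`.
#' @export
emission_logdensity <- function(y, associated, mu = 0, sigma2 = 1) {
  check_pos(sigma2, "sigma2")
  assoc <- rep_len(as.logical(associated), length(y))
  out <- dnorm(y, log = TRUE)
  if (any(assoc)) {
    out[assoc] <- dlnorm(y[assoc], meanlog = mu, sdlog = sqrt(sigma2), log = TRUE)
  }
  out
}

#' Auto-logistic MRF log-kernel for one SNP's association vector
#'
#' Log of the unnormalized probability of the length-n latent vector e:
#' \deqn{\sum_i (\alpha_i + \sum_m \gamma_{im} a_m) e_i +
#'       \sum_{i<j} \beta_{ij} e_i e_j.}
#' Annotations raise the effective intercept of annotated SNPs, so being
#' annotated supports association; pairwise terms couple phenotypes that are
#' genetically correlated.
#'
#' @param e Length-n 0/1 vector.
#' @param alpha Length-n phenotype intercepts.
#' @param beta Symmetric n x n matrix of pairwise coefficients (zero
#'   diagonal), or `NULL` for none.
#' @param gamma n x M matrix of annotation coefficients, or `NULL`.
#' @param a Length-M 0/1 annotation vector for this SNP (required when
#'   `gamma` is given).
#' @return The log-kernel (0 for the all-zero vector).
#' @export
mrf_log_kernel <- function(e, alpha, beta = NULL, gamma = NULL, a = NULL) {
  n <- length(alpha)
  if (length(e) != n) abort("`e` and `alpha` must have the same length.")
  eff <- alpha
  if (!is.null(gamma)) {
    gamma <- as.matrix(gamma)
    if (nrow(gamma) != n) abort("`gamma` must have one row per phenotype.")
    if (is.null(a) || length(a) != ncol(gamma)) {
      abort("`a` must be a binary vector with one entry per annotation.")
    }
    eff <- eff + drop(gamma %*% a)
  }
  val <- sum(eff * e)
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    if (!all(dim(beta) == n)) abort("`beta` must be n x n.")
    val <- val + 0.5 * drop(e %*% beta %*% e) - 0.5 * sum(diag(beta) * e)
  }
  val
}

#' Exact normalizing constant of the auto-logistic MRF
#'
#' Sums exp(kernel) over all 2^n binary association vectors, in log space.
#' Exact enumeration is the point: the constant is not ignorable for the
#' intercept, pairwise and annotation updates, and n (number of phenotypes)
#' is small in practice. Enumeration is refused above `n_max`.
#'
#' @param alpha_eff Length-n effective intercepts (alpha plus any annotation
#'   contribution for the SNP's annotation pattern).
#' @param beta Symmetric n x n pairwise coefficient matrix, or `NULL`.
#' @param log Return the log constant instead of the constant.
#' @param n_max Guard on the enumeration size (default 15).
#' @return The (log) normalizing constant.
#' @export
mrf_normalizing_constant <- function(alpha_eff, beta = NULL, log = FALSE,
                                     n_max = 15) {
  n <- length(alpha_eff)
  if (n > n_max) {
    abort(sprintf(
      "Exact enumeration over 2^%d states exceeds `n_max` = %d; reduce the number of phenotypes or raise `n_max` knowingly.",
      n, n_max))
  }
  S <- mrf_states(n)
  k <- drop(S %*% alpha_eff)
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    diag(beta) <- 0
    k <- k + 0.5 * rowSums((S %*% beta) * S)
  }
  lc <- logsumexp(k)
  if (log) lc else exp(lc)
}

# Log normalizing constants for every distinct annotation pattern at once.
# patterns: P x M 0/1 matrix (M may be 0); returns length-P vector.
logC_patterns <- function(alpha, gamma, beta, patterns, n_max = 15) {
  n <- length(alpha)
  if (n > n_max) {
    abort(sprintf("Exact enumeration needs n <= n_max (= %d).", n_max))
  }
  S <- mrf_states(n)
  P <- nrow(patterns)
  if (P == 0) return(numeric(0))
  alpha_eff <- matrix(alpha, P, n, byrow = TRUE)
  if (ncol(patterns) > 0) alpha_eff <- alpha_eff + patterns %*% t(gamma)
  K <- S %*% t(alpha_eff)
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    diag(beta) <- 0
    K <- K + 0.5 * rowSums((S %*% beta) * S)
  }
  col_logsumexp(K)
}

# Group annotation rows into distinct patterns.
# Returns list(patterns = P x M matrix, counts, index = length-T map).
annotation_patterns <- function(A) {
  M <- ncol(A)
  if (M == 0) {
    return(list(patterns = matrix(0, 1, 0), counts = nrow(A),
                index = rep(1L, nrow(A))))
  }
  key <- if (M <= 50) {
    as.vector(A %*% 2^(seq_len(M) - 1))
  } else {
    apply(A, 1, paste, collapse = "")
  }
  uk <- unique(key)
  idx <- match(key, uk)
  first <- match(uk, key)
  list(patterns = A[first, , drop = FALSE],
       counts = tabulate(idx, nbins = length(uk)),
       index = idx)
}

#' Full-conditional odds that one SNP is associated with one phenotype
#'
#' The normalizing constant cancels in the full conditional of a single
#' latent indicator, leaving a logistic form: the odds are
#' exp(effective intercept + neighbour coupling) times the
#' lognormal/normal emission density ratio. The Gibbs probability is
#' odds / (1 + odds), and is 0 whenever `y <= 0` (the lognormal component
#' has positive support).
#'
#' @param y z-score of the SNP for this phenotype.
#' @param mu,sigma2 Emission parameters for the phenotype.
#' @param alpha Phenotype intercept.
#' @param gamma Length-M annotation coefficients for this phenotype (or
#'   `NULL`).
#' @param a Length-M annotation vector of the SNP (or `NULL`).
#' @param beta_neighbors,e_neighbors Pairwise coefficients to, and current
#'   indicators of, the phenotype's graph neighbours (or `NULL`).
#' @return Nonnegative odds (vectorized over `y`).
#' @export
conditional_association_odds <- function(y, mu, sigma2, alpha,
                                         gamma = NULL, a = NULL,
                                         beta_neighbors = NULL,
                                         e_neighbors = NULL) {
  check_pos(sigma2, "sigma2")
  eta <- alpha
  if (!is.null(gamma)) eta <- eta + sum(gamma * a)
  if (!is.null(beta_neighbors)) eta <- eta + sum(beta_neighbors * e_neighbors)
  lr <- dlnorm(y, mu, sqrt(sigma2), log = TRUE) - dnorm(y, log = TRUE)
  odds <- exp(eta + lr)
  odds[y <= 0] <- 0
  odds
}

#' Joint log-posterior kernel of the full model
#'
#' Sums the emission log-likelihood, the MRF log-kernel minus its log
#' normalizing constant per SNP, and the log-priors for all parameters:
#' normal priors on mu and alpha, inverse-gamma on sigma^2, spike-and-slab
#' gamma priors on the pairwise coefficients (given edge inclusion) and on
#' the annotation coefficients (given annotation inclusion), Bernoulli edge
#' priors (optionally informed by a prior graph), Bernoulli(p_u) annotation
#' inclusion, and a uniform prior on p_u. Used mainly for validation: the
#' change under flipping one latent indicator must equal the log of its
#' full-conditional odds.
#'
#' @param y T x n matrix of z-scores.
#' @param annotations T x M 0/1 matrix (or `NULL`).
#' @param state List with elements `e` (T x n 0/1), `alpha`, `beta` (n x n),
#'   `graph` (n x n 0/1), `gamma` (n x M), `u` (n x M), `p_u`, `mu`,
#'   `sigma2`.
#' @param hyper A [pleio_hyper()] object.
#' @param prior_graph Optional n x n 0/1 adjacency of prior edges.
#' @param n_max Enumeration guard.
#' @return The log unnormalized posterior (may be `-Inf`).
#' @export
mrf_log_posterior <- function(y, annotations, state, hyper = pleio_hyper(),
                              prior_graph = NULL, n_max = 15) {
  n <- length(state$alpha)
  A <- annotations
  if (is.null(A)) A <- zero_matrix(nrow(y), 0L)
  M <- ncol(A)
  e <- state$e
  beta <- as.matrix(state$beta)
  graph <- as.matrix(state$graph)
  validate_state(state, n, M)
  pairs <- pairs_of(n)
  bvec <- upper_vec(beta, pairs)
  evec <- upper_vec(graph, pairs)

  # emission
  logN <- dnorm(y, log = TRUE)
  ll <- sum(logN[e == 0])
  for (i in seq_len(n)) {
    yi <- y[e[, i] == 1, i]
    ll <- ll + sum(dlnorm(yi, state$mu[i], sqrt(state$sigma2[i]), log = TRUE))
  }
  if (!is.finite(ll)) return(-Inf)

  # MRF kernel and normalizing constants
  eff <- if (nrow(y) == 0) zero_matrix(0L, n) else
    matrix(state$alpha, nrow(y), n, byrow = TRUE)
  if (M > 0) eff <- eff + A %*% t(state$gamma)
  ll <- ll + sum(eff * e)
  s_pair <- colSums(e[, pairs[1, ], drop = FALSE] * e[, pairs[2, ], drop = FALSE])
  ll <- ll + sum(bvec * s_pair)
  pat <- annotation_patterns(A)
  lc <- logC_patterns(state$alpha, state$gamma, beta, pat$patterns, n_max)
  ll <- ll - sum(pat$counts * lc)

  # priors
  ll <- ll + sum(dnorm(state$mu, hyper$theta_mu, sqrt(hyper$tau2_mu), log = TRUE))
  ll <- ll + sum(hyper$a_sigma * log(hyper$b_sigma) - lgamma(hyper$a_sigma) -
                   (hyper$a_sigma + 1) * log(state$sigma2) -
                   hyper$b_sigma / state$sigma2)
  ll <- ll + sum(dnorm(state$alpha, hyper$theta_alpha, sqrt(hyper$tau2_alpha),
                       log = TRUE))
  pe <- edge_prior_probs(pairs, prior_graph, hyper)
  on <- evec == 1
  ll <- ll + sum(log(pe[on])) + sum(log(1 - pe[!on]))
  ll <- ll + sum(dgamma(bvec[on], hyper$a_beta, rate = hyper$b_beta, log = TRUE))
  if (M > 0) {
    uon <- state$u == 1
    ll <- ll + sum(uon) * log(state$p_u) + sum(!uon) * log(1 - state$p_u)
    ll <- ll + sum(dgamma(state$gamma[uon], hyper$a_gamma, rate = hyper$b_gamma,
                          log = TRUE))
  }
  ll
}

validate_state <- function(state, n, M) {
  beta <- as.matrix(state$beta)
  graph <- as.matrix(state$graph)
  if (!isTRUE(all.equal(beta, t(beta))) || !isTRUE(all.equal(graph, t(graph)))) {
    abort("`beta` and `graph` must be symmetric.")
  }
  if (any(beta != 0 & graph == 0)) {
    abort("Invariant violated: beta[i, j] != 0 requires graph[i, j] = 1.")
  }
  if (any(state$sigma2 <= 0)) abort("`sigma2` must be strictly positive.")
  if (M > 0) {
    g <- as.matrix(state$gamma)
    u <- as.matrix(state$u)
    if (any((g > 0) != (u == 1))) {
      abort("Invariant violated: gamma[i, m] > 0 iff u[i, m] = 1.")
    }
    if (state$p_u < 0 || state$p_u > 1) abort("`p_u` must lie in [0, 1].")
  }
  invisible(TRUE)
}

# per-pair Bernoulli edge prior probabilities
edge_prior_probs <- function(pairs, prior_graph, hyper) {
  K <- ncol(pairs)
  if (is.null(prior_graph)) return(rep(0.5, K))
  ifelse(prior_graph[cbind(pairs[1, ], pairs[2, ])] == 1,
         hyper$prior_edge_prob_in, hyper$prior_edge_prob_out)
}
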
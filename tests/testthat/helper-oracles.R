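# Independent oracles used across test files. These deliberately avoid the
# package's computational paths (expand.grid/logsumexp): states come from
# intToBits and sums are plain exp sums.

# brute-force normalizing constant of the auto-logistic model
brute_force_C <- function(alpha_eff, beta_mat = NULL) {
  n <- length(alpha_eff)
  total <- 0
  for (s in 0:(2^n - 1)) {
    e <- as.integer(intToBits(s))[seq_len(n)]
    val <- sum(alpha_eff * e)
    if (!is.null(beta_mat) && n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) val <- val + beta_mat[i, j] * e[i] * e[j]
      }
    }
    total <- total + exp(val)
  }
  total
}

# all binary states of length n, as a list, via the same bit route
brute_force_states <- function(n) {
  lapply(0:(2^n - 1), function(s) as.integer(intToBits(s))[seq_len(n)])
}

# random symmetric coefficient matrix on a random graph
random_beta <- function(n, p_edge = 0.5) {
  b <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) b[i, j] <- b[j, i] <- rexp(1)
    }
  }
  b
}

# a small random model state satisfying all invariants
random_state <- function(n, M, Tn, y) {
  graph <- matrix(0, n, n)
  beta <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < 0.5) {
        graph[i, j] <- graph[j, i] <- 1
        beta[i, j] <- beta[j, i] <- rgamma(1, 4, 2)
      }
    }
  }
  u <- matrix(rbinom(n * M, 1, 0.5), n, M)
  gamma <- matrix(0, n, M)
  gamma[u == 1] <- rgamma(sum(u), 4, 2)
  e <- matrix(rbinom(Tn * n, 1, 0.3), Tn, n)
  e[y <= 0] <- 0
  list(e = e, alpha = rnorm(n, -2, 1), beta = beta, graph = graph,
       gamma = gamma, u = u, p_u = runif(1), mu = rnorm(n, 1, 0.2),
       sigma2 = runif(n, 0.1, 0.5))
}
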
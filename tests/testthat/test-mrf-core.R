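test_that("emission log-density matches closed forms and support", {
  # LN(1; 0, 1) = N(0; 0, 1) = 1/sqrt(2*pi) = 0.3989422804014327
  expect_equal(emission_logdensity(1, 1, 0, 1), log(0.3989422804014327))
  expect_equal(emission_logdensity(0, 0), log(0.3989422804014327))
  expect_identical(emission_logdensity(-0.5, 1, 0, 1), -Inf)
  expect_identical(emission_logdensity(0, 1, 0, 1), -Inf)
  # vectorized with mixed indicators
  y <- c(-0.2, 0.8, 1.6)
  out <- emission_logdensity(y, c(0, 1, 0), mu = 0.5, sigma2 = 0.2)
  expect_equal(out[1], dnorm(-0.2, log = TRUE))
  expect_equal(out[2], dlnorm(0.8, 0.5, sqrt(0.2), log = TRUE))
})

test_that("MRF log-kernel sums singleton, annotation and pairwise terms", {
  expect_equal(mrf_log_kernel(c(0, 0), alpha = c(1, -2)), 0)
  b <- matrix(c(0, log(2), log(2), 0), 2)
  expect_equal(mrf_log_kernel(c(1, 1), alpha = c(0, 0), beta = b), log(2))
  # one phenotype with an annotation raising the intercept
  expect_equal(mrf_log_kernel(1, alpha = -4.7, gamma = matrix(1, 1, 1), a = 1),
               -3.7)
  expect_error(mrf_log_kernel(c(1, 0, 0), alpha = c(0, 0)), "same length")
})

test_that("normalizing constant matches closed forms and brute force", {
  expect_equal(mrf_normalizing_constant(0), 2)
  b <- matrix(c(0, log(2), log(2), 0), 2)
  expect_equal(mrf_normalizing_constant(c(0, 0), b), 5)
  set.seed(11)
  for (n in 3:6) {
    alpha <- rnorm(n, -1, 1.5)
    beta <- random_beta(n)
    got <- mrf_normalizing_constant(alpha, beta)
    want <- brute_force_C(alpha, beta)
    expect_lt(abs(got - want) / want, 1e-12)
  }
})

test_that("enumeration above n_max is refused", {
  expect_error(mrf_normalizing_constant(rep(0, 16)), "n_max")
  expect_equal(mrf_normalizing_constant(rep(0, 16), n_max = 16), 2^16)
})

test_that("MRF state probabilities sum to one", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    alpha <- rnorm(n)
    beta <- random_beta(n)
    lC <- mrf_normalizing_constant(alpha, beta, log = TRUE)
    tot <- sum(vapply(
      brute_force_states(n),
      function(e) exp(mrf_log_kernel(e, alpha, beta) - lC), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("annotation-pattern grouping equals per-SNP evaluation", {
  set.seed(13)
  n <- 4; M <- 3; Tn <- 40
  A <- matrix(rbinom(Tn * M, 1, 0.3), Tn, M)
  alpha <- rnorm(n); beta <- random_beta(n)
  gamma <- matrix(rexp(n * M, 2), n, M)
  pat <- pleiograph:::annotation_patterns(A)
  grouped <- pleiograph:::logC_patterns(alpha, gamma, beta, pat$patterns)
  per_snp <- vapply(seq_len(Tn), function(t) {
    mrf_normalizing_constant(alpha + drop(gamma %*% A[t, ]), beta, log = TRUE)
  }, numeric(1))
  expect_equal(grouped[pat$index], per_snp, tolerance = 1e-12)
  expect_equal(sum(pat$counts), Tn)
})

test_that("zero annotation coefficients reduce to the annotation-free model", {
  set.seed(14)
  n <- 5; M <- 4
  alpha <- rnorm(n); beta <- random_beta(n)
  patterns <- matrix(rbinom(8 * M, 1, 0.5), 8, M)
  with_anno <- pleiograph:::logC_patterns(alpha, matrix(0, n, M), beta, patterns)
  without <- mrf_normalizing_constant(alpha, beta, log = TRUE)
  expect_identical(with_anno, rep(without, 8))
})

test_that("normalizing constant is invariant to phenotype permutation", {
  set.seed(15)
  n <- 5
  alpha <- rnorm(n); beta <- random_beta(n)
  perm <- sample(n)
  expect_equal(mrf_normalizing_constant(alpha[perm], beta[perm, perm]),
               mrf_normalizing_constant(alpha, beta), tolerance = 1e-12)
})

test_that("conditional association odds follow the logistic form", {
  # equal emission densities: LN(1; 1, 1) = N(1; 0, 1) = dnorm(-1)
  odds <- conditional_association_odds(1, mu = 1, sigma2 = 1, alpha = 0)
  expect_equal(odds, 1)
  # one active neighbour with coupling log 3 gives probability 0.75
  odds <- conditional_association_odds(1, 1, 1, alpha = 0,
                                       beta_neighbors = log(3), e_neighbors = 1)
  expect_equal(odds / (1 + odds), 0.75)
  expect_equal(conditional_association_odds(-1, 0, 1, alpha = 5), 0)
})

test_that("flipping one indicator changes the joint kernel by its log-odds", {
  set.seed(16)
  n <- 3; M <- 2; Tn <- 8
  y <- matrix(rnorm(Tn * n, 1, 1.5), Tn, n)
  A <- matrix(rbinom(Tn * M, 1, 0.4), Tn, M)
  hyper <- pleio_hyper()
  for (rep in 1:40) {
    st <- random_state(n, M, Tn, y)
    lp0 <- mrf_log_posterior(y, A, st, hyper)
    t <- sample(Tn, 1); i <- sample(n, 1)
    if (y[t, i] <= 0) next  # flip target must respect the support constraint
    st1 <- st
    st1$e[t, i] <- 1 - st1$e[t, i]
    lp1 <- mrf_log_posterior(y, A, st1, hyper)
    nbr <- which(st$graph[i, ] == 1)
    odds <- conditional_association_odds(
      y[t, i], st$mu[i], st$sigma2[i], st$alpha[i],
      gamma = st$gamma[i, ], a = A[t, ],
      beta_neighbors = st$beta[i, nbr], e_neighbors = st$e[t, nbr])
    delta <- if (st1$e[t, i] == 1) log(odds) else -log(odds)
    expect_equal(lp1 - lp0, delta, tolerance = 1e-8)
  }
})

test_that("log-posterior enforces the spike-slab support invariant", {
  set.seed(17)
  y <- matrix(rnorm(6, 1, 1), 3, 2)
  st <- random_state(2, 0, 3, y)
  st$beta[1, 2] <- st$beta[2, 1] <- 1.5
  st$graph[1, 2] <- st$graph[2, 1] <- 0
  expect_error(mrf_log_posterior(y, NULL, st, pleio_hyper()), "graph")
})

test_that("with no SNPs the log-posterior is the sum of log-priors", {
  set.seed(18)
  n <- 2
  hyper <- pleio_hyper()
  st <- list(e = matrix(0, 0, n), alpha = c(-1, 0.5),
             beta = matrix(0, n, n), graph = matrix(0, n, n),
             gamma = matrix(0, n, 0), u = matrix(0, n, 0), p_u = 0.5,
             mu = c(1, 0.9), sigma2 = c(0.2, 0.3))
  got <- mrf_log_posterior(matrix(0, 0, n), NULL, st, hyper)
  want <- sum(dnorm(st$mu, 0, 100, log = TRUE)) +
    sum(dnorm(st$alpha, 0, 100, log = TRUE)) +
    sum(0.5 * log(0.5) - lgamma(0.5) - 1.5 * log(st$sigma2) - 0.5 / st$sigma2) +
    log(0.5) # one absent edge at prior probability 0.5
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("edge priors follow the prior graph in/out probabilities", {
  hyper <- pleio_hyper()
  pairs <- pleiograph:::pairs_of(3)
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1
  pe <- pleiograph:::edge_prior_probs(pairs, adj, hyper)
  expect_equal(pe, c(0.8, 0.2, 0.2))
  expect_equal(pleiograph:::edge_prior_probs(pairs, NULL, hyper), rep(0.5, 3))
})
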
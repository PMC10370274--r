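# Correctness checks for the Metropolis-within-Gibbs sampler. The heavier
# end-to-end recovery runs live in test-acceptance.R.

small_sim <- function(n_snps = 800, seed = 31) {
  sc <- sim_scenario(
    n_snps = n_snps, n_phenotypes = 3, n_annotations = 2,
    edges = matrix(c(1, 2), 1), beta = 2.5,
    alpha = c(-2.5, -2.8, -2.2), gamma = cbind(c(2, 2, 0), c(0, 0, 0)),
    mu = c(1.1, 1.0, 1.0), sigma = c(0.4, 0.35, 0.4), gibbs_iters = 100)
  pleio_sim(sc, seed = seed)
}

test_that("identical seeds give bitwise-identical fits", {
  sim <- small_sim()
  ctl <- pleio_control(n_iter = 150, n_burnin = 50, thin = 2, seed = 5)
  f1 <- pleio_fit(sim$zscores, sim$annotations, control = ctl)
  f2 <- pleio_fit(sim$zscores, sim$annotations, control = ctl)
  expect_identical(f1$snp_marginal, f2$snp_marginal)
  expect_identical(f1$traces, f2$traces)
  expect_identical(f1$edges, f2$edges)
  f3 <- pleio_fit(sim$zscores, sim$annotations,
                  control = pleio_control(n_iter = 150, n_burnin = 50,
                                          thin = 2, seed = 6))
  expect_false(identical(f1$traces$alpha, f3$traces$alpha))
})

test_that("the latent Gibbs sweep samples the exact full conditional", {
  set.seed(32)
  Tn <- 30000
  n <- 2
  alpha <- c(-0.7, 0.4)
  B <- matrix(c(0, 1.2, 1.2, 0), 2)
  LR <- matrix(rnorm(Tn * n, 0, 0.5), Tn, n)
  e0 <- matrix(rbinom(Tn * n, 1, 0.5), Tn, n)
  e1 <- pleiograph:::gibbs_e_sweep(e0, alpha, B, NULL, LR)
  # column 1 is updated first, against the *old* column 2
  p1 <- plogis(alpha[1] + B[1, 2] * e0[, 2] + LR[, 1])
  # column 2 is updated against the *new* column 1
  p2 <- plogis(alpha[2] + B[2, 1] * e1[, 1] + LR[, 2])
  for (probs in list(cbind(e1[, 1], p1), cbind(e1[, 2], p2))) {
    bins <- cut(probs[, 2], c(0, 0.25, 0.5, 0.75, 1))
    for (b in levels(bins)) {
      idx <- bins == b
      if (sum(idx) < 500) next
      se <- sqrt(mean(probs[idx, 2]) * (1 - mean(probs[idx, 2])) / sum(idx))
      expect_lt(abs(mean(probs[idx, 1]) - mean(probs[idx, 2])), 4 * se)
    }
  }
})

test_that("emission ratio computation agrees with dlnorm/dnorm", {
  set.seed(33)
  Y <- matrix(c(rnorm(40), rlnorm(20, 1, 0.4)), 30, 2)
  lY <- suppressWarnings(log(Y))
  LR <- pleiograph:::emission_logratio(lY, dnorm(Y, log = TRUE), !(Y > 0),
                                       mu = c(1, 0.9), sigma2 = c(0.16, 0.2))
  ref <- dlnorm(Y[, 1], 1, 0.4, log = TRUE) - dnorm(Y[, 1], log = TRUE)
  ref[Y[, 1] <= 0] <- -Inf
  expect_equal(LR[, 1], ref)
})

test_that("phenotypes with no positive z-scores get zero association", {
  set.seed(34)
  d <- tibble::tibble(snp_id = paste0("s", 1:300),
                      P1 = rnorm(300, 2, 1), P2 = -abs(rnorm(300)))
  fit <- pleio_fit(d, control = pleio_control(n_iter = 120, n_burnin = 40,
                                              thin = 2, seed = 1))
  expect_true(all(fit$snp_marginal[, 2] == 0))
  expect_true(all(fit$snp_marginal[d$P1 <= 0, 1] == 0))
})

test_that("the emission Gibbs pair targets the conjugate posterior", {
  set.seed(35)
  hyper <- pleio_hyper()
  z <- rnorm(5000, 1.05, 0.4)
  mu <- 1
  draws <- matrix(NA_real_, 3000, 2)
  for (it in seq_len(nrow(draws))) {
    d <- pleiograph:::draw_emission_pair(z, mu, hyper)
    mu <- d[2]
    draws[it, ] <- d
  }
  # with 5,000 observations the posterior concentrates at the sample moments
  expect_lt(abs(mean(draws[, 2]) - mean(z)), 4 * sd(z) / sqrt(length(z)))
  expect_lt(abs(mean(draws[, 1]) - var(z)) / var(z), 0.05)
  # with no data the pair reduces to the prior
  set.seed(36)
  pr <- replicate(4000, pleiograph:::draw_emission_pair(numeric(0), 0, hyper))
  expect_lt(abs(mean(pr[2, ])) / (100 / sqrt(4000)), 4)  # mu ~ N(0, 100^2)
  expect_lt(abs(mean(1 / pr[1, ]) - 1), 0.1)  # 1/sigma2 ~ Gamma(.5, .5), mean 1
})

test_that("with no SNPs the chain recovers the edge and inclusion priors", {
  empty <- tibble::tibble(snp_id = character(0), P1 = numeric(0),
                          P2 = numeric(0), P3 = numeric(0))
  ctl <- pleio_control(n_iter = 4000, n_burnin = 500, thin = 1, seed = 7,
                       step_alpha = 30)
  fit <- pleio_fit(empty, control = ctl)
  expect_true(all(abs(fit$p_edge - 0.5) < 0.06))
  # informative prior graph shifts edge probabilities to 0.8 / 0.2
  pg <- data.frame(from = "P1", to = "P2")
  fit2 <- pleio_fit(empty, prior_graph = pg, control = ctl)
  expect_lt(abs(fit2$p_edge[1] - 0.8), 0.06)
  expect_true(all(abs(fit2$p_edge[2:3] - 0.2) < 0.06))
  # annotation inclusion recovers E[p_u] = 1/2 under the uniform hyperprior
  empty_ann <- tibble::tibble(snp_id = character(0), A1 = numeric(0))
  fit3 <- pleio_fit(empty, empty_ann, control = ctl)
  expect_true(all(abs(fit3$p_u_incl - 0.5) < 0.08))
  expect_lt(abs(fit3$p_u_mean - 0.5), 0.08)
})

test_that("strong co-association drives the edge probability to one", {
  set.seed(38)
  sc <- sim_scenario(n_snps = 3000, n_phenotypes = 2, n_annotations = 0,
                     edges = matrix(c(1, 2), 1), beta = 3.5,
                     alpha = c(-3.5, -3.2), gamma = matrix(0, 2, 0),
                     mu = c(1.1, 1.0), sigma = c(0.4, 0.4), gibbs_iters = 100)
  sim <- pleio_sim(sc, seed = 39)
  fit <- pleio_fit(sim$zscores,
                   control = pleio_control(n_iter = 800, n_burnin = 300,
                                           thin = 2, seed = 2))
  expect_gt(fit$p_edge[1], 0.9)
  expect_gt(fit$edges$p_beta_pos[1], 0.95)
  # adapted step sizes land the post-burn-in acceptance in a healthy band
  a_rate <- fit$acceptance$rate[fit$acceptance$block == "alpha"]
  expect_gt(a_rate, 0.2)
  expect_lt(a_rate, 0.6)
})

test_that("pairwise accumulators never exceed the marginals", {
  sim <- small_sim(600, seed = 40)
  fit <- pleio_fit(sim$zscores, sim$annotations,
                   control = pleio_control(n_iter = 200, n_burnin = 80,
                                           thin = 2, seed = 3))
  for (k in seq_len(ncol(fit$pairs))) {
    i <- fit$pairs[1, k]; j <- fit$pairs[2, k]
    expect_true(all(fit$snp_pairwise[, k] <=
                      pmin(fit$snp_marginal[, i], fit$snp_marginal[, j]) + 1e-12))
  }
  expect_true(all(fit$snp_marginal >= 0 & fit$snp_marginal <= 1))
})

test_that("annotation-free fits and gamma-frozen fits are identical chains", {
  sim <- small_sim(500, seed = 41)
  ctl <- pleio_control(n_iter = 150, n_burnin = 50, thin = 2, seed = 4,
                       fix_gamma_zero = TRUE)
  with_frozen <- pleio_fit(sim$zscores, sim$annotations, control = ctl)
  without <- pleio_fit(sim$zscores,
                       control = pleio_control(n_iter = 150, n_burnin = 50,
                                               thin = 2, seed = 4))
  expect_identical(with_frozen$traces$alpha, without$traces$alpha)
  expect_identical(with_frozen$traces$beta, without$traces$beta)
  expect_identical(with_frozen$snp_marginal, without$snp_marginal)
  expect_true(all(with_frozen$traces$gamma == 0))
})

test_that("misaligned SNP identifiers and oversized models are rejected", {
  sim <- small_sim(100, seed = 42)
  bad_ann <- sim$annotations[1:50, ]
  expect_error(pleio_fit(sim$zscores, bad_ann, control = pleio_control(
    n_iter = 10, n_burnin = 2, seed = 1)), "missing from")
  wide <- tibble::tibble(snp_id = paste0("s", 1:10))
  for (i in 1:16) wide[[paste0("P", i)]] <- rnorm(10)
  expect_error(pleio_fit(wide, control = pleio_control(n_iter = 10,
                                                       n_burnin = 2, seed = 1)),
               "n_max")
})

test_that("alternating updates with data regeneration preserve the prior", {
  # Successive-conditional joint check on a tiny instance: one transition of
  # the sampler given Y, then Y redrawn from the emission given the latent
  # indicators. The stationary marginal of every parameter is its prior, so
  # systematic drift flags an incorrect acceptance ratio or full conditional.
  set.seed(43)
  n <- 2; Tn <- 50; M <- 1
  hyper <- pleio_hyper(tau2_mu = 1, tau2_alpha = 1, a_sigma = 3, b_sigma = 3)
  A <- matrix(rbinom(Tn * M, 1, 0.3), Tn, M)
  draw_y <- function(e, mu, sigma2) {
    y <- matrix(rnorm(Tn * n), Tn, n)
    for (i in seq_len(n)) {
      on <- e[, i] == 1
      y[on, i] <- rlnorm(sum(on), mu[i], sqrt(sigma2[i]))
    }
    y
  }
  # start from a joint prior draw
  state <- list(
    e = matrix(0, Tn, n), mu = rnorm(n, 0, 1),
    sigma2 = 1 / rgamma(n, 3, 3), alpha = rnorm(n, 0, 1),
    beta_vec = 0, E_vec = 0L, gamma = matrix(0, n, M),
    u = matrix(0L, n, M), p_u = 0.5)
  Y <- draw_y(state$e, state$mu, state$sigma2)
  n_cycles <- 900
  out <- matrix(NA_real_, n_cycles, 8)
  for (k in seq_len(n_cycles)) {
    ctl <- pleio_control(n_iter = 1, n_burnin = 0, thin = 1, seed = 43000 + k,
                         adapt = FALSE, step_alpha = 0.8, step_beta = 0.6,
                         step_gamma = 0.6)
    res <- pleiograph:::fit_engine(Y, A, NULL, hyper, ctl, state0 = state)
    state <- res$final_state
    Y <- draw_y(state$e, state$mu, state$sigma2)
    out[k, ] <- c(state$alpha[1], state$mu[1], 1 / state$sigma2[1],
                  state$E_vec[1], state$beta_vec[1], state$u[1, 1],
                  state$gamma[1, 1], state$p_u)
  }
  keep <- out[-(1:100), ]
  expect_lt(abs(mean(keep[, 1])), 0.25)              # alpha ~ N(0, 1)
  expect_lt(abs(sd(keep[, 1]) - 1), 0.3)
  expect_lt(abs(mean(keep[, 2])), 0.25)              # mu ~ N(0, 1)
  expect_lt(abs(mean(keep[, 3]) - 1), 0.25)          # 1/sigma2 ~ Gamma(3, 3)
  expect_gt(mean(keep[, 4]), 0.35)                   # edge prior 0.5
  expect_lt(mean(keep[, 4]), 0.65)
  on <- keep[, 4] == 1                               # slab Gamma(4, 2), mean 2
  expect_lt(abs(mean(keep[on, 5]) - 2), 0.45)
  expect_gt(mean(keep[, 6]), 0.35)                   # u marginal E[p_u] = 0.5
  expect_lt(mean(keep[, 6]), 0.65)
  expect_lt(abs(mean(keep[, 8]) - 0.5), 0.12)        # p_u ~ Beta posterior chain
})
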
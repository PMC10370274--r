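#' Hyperparameters of the hierarchical model
#'
#' Weakly informative defaults for the top level of the hierarchy: normal
#' priors on the emission location mu and the MRF intercepts alpha,
#' inverse-gamma (shape/rate) on the emission variance sigma^2, and
#' shape/rate gamma slabs for the pairwise coefficients beta and the
#' annotation coefficients gamma. The slab shape/rate (4, 2) places most
#' slab mass away from zero, so an included edge or annotation means a
#' clearly nonzero coefficient. `prior_edge_prob_in` / `prior_edge_prob_out`
#' are the Bernoulli edge-prior probabilities for pairs inside/outside a
#' supplied prior graph; without a prior graph every pair gets probability
#' 0.5.
#'
#' @param theta_mu,tau2_mu Normal prior mean/variance for mu.
#' @param a_sigma,b_sigma Inverse-gamma shape/rate for sigma^2.
#' @param theta_alpha,tau2_alpha Normal prior mean/variance for alpha.
#' @param a_beta,b_beta Gamma slab shape/rate for beta.
#' @param a_gamma,b_gamma Gamma slab shape/rate for gamma.
#' @param prior_edge_prob_in,prior_edge_prob_out Edge prior probability for
#'   pairs present/absent in the prior graph.
#' @return A list of class `pleio_hyper`.
#' @export
pleio_hyper <- function(theta_mu = 0, tau2_mu = 10000,
                        a_sigma = 0.5, b_sigma = 0.5,
                        theta_alpha = 0, tau2_alpha = 10000,
                        a_beta = 4, b_beta = 2,
                        a_gamma = 4, b_gamma = 2,
                        prior_edge_prob_in = 0.8,
                        prior_edge_prob_out = 0.2) {
  for (nm in c("tau2_mu", "a_sigma", "b_sigma", "tau2_alpha",
               "a_beta", "b_beta", "a_gamma", "b_gamma")) {
    check_pos(get(nm), nm)
  }
  check_prob(prior_edge_prob_in, "prior_edge_prob_in")
  check_prob(prior_edge_prob_out, "prior_edge_prob_out")
  structure(list(
    theta_mu = theta_mu, tau2_mu = tau2_mu,
    a_sigma = a_sigma, b_sigma = b_sigma,
    theta_alpha = theta_alpha, tau2_alpha = tau2_alpha,
    a_beta = a_beta, b_beta = b_beta,
    a_gamma = a_gamma, b_gamma = b_gamma,
    prior_edge_prob_in = prior_edge_prob_in,
    prior_edge_prob_out = prior_edge_prob_out
  ), class = "pleio_hyper")
}

#' MCMC settings for [pleio_fit()]
#'
#' @param n_iter Total sweeps of the Metropolis-within-Gibbs cycle.
#' @param n_burnin Burn-in sweeps discarded before accumulation
#'   (`0 <= n_burnin < n_iter`).
#' @param thin Stride between retained samples.
#' @param seed Integer seed; with identical inputs it fully determines the
#'   chain.
#' @param step_alpha,step_beta,step_gamma Initial random-walk standard
#'   deviations for alpha, log-beta and log-gamma proposals.
#' @param adapt Adapt step sizes toward `target_accept` during burn-in only
#'   (frozen afterwards, preserving detailed balance).
#' @param target_accept Target acceptance rate in (0, 1).
#' @param n_max Maximum number of phenotypes for exact enumeration of the
#'   MRF normalizing constant.
#' @param joint_sets Optional list of character vectors of phenotype names;
#'   the posterior probability that all indicators in each set are 1 is
#'   accumulated per SNP (all pairs are always accumulated).
#' @param fix_gamma_zero Force all annotation coefficients to zero and skip
#'   their updates (the annotation-free model on annotated input; mainly for
#'   reducibility checks).
#' @param verbose Print progress every 500 sweeps.
#' @return A list of class `pleio_control`.
#' @export
pleio_control <- function(n_iter = 10000, n_burnin = 5000, thin = 5,
                          seed = 1,
                          step_alpha = 0.15, step_beta = 0.3,
                          step_gamma = 0.3, adapt = TRUE,
                          target_accept = 0.35, n_max = 15,
                          joint_sets = NULL, fix_gamma_zero = FALSE,
                          verbose = FALSE) {
  if (n_iter < 1 || n_burnin < 0 || n_burnin >= n_iter) {
    abort("Need 0 <= n_burnin < n_iter.")
  }
  if (thin < 1) abort("`thin` must be a positive integer.")
  check_prob(target_accept, "target_accept")
  structure(list(
    n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
    thin = as.integer(thin), seed = as.integer(seed),
    step_alpha = step_alpha, step_beta = step_beta, step_gamma = step_gamma,
    adapt = isTRUE(adapt), target_accept = target_accept,
    n_max = as.integer(n_max), joint_sets = joint_sets,
    fix_gamma_zero = isTRUE(fix_gamma_zero), verbose = isTRUE(verbose)
  ), class = "pleio_control")
}
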
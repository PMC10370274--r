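# Metropolis-within-Gibbs sampler over (e, mu, sigma^2, alpha, beta, G,
# gamma, u, p_u). Update cycle per sweep: e -> emission -> alpha ->
# (beta, G) -> (gamma, u) -> p_u. Latent indicators are updated
# phenotype-by-phenotype, jointly over SNPs (SNPs are conditionally
# independent given the other phenotypes' indicators). Normalizing constants
# are evaluated exactly by 2^n enumeration, once per distinct annotation
# pattern per proposal.

#' Fit the graphical multi-trait association model
#'
#' Jointly analyzes GWAS summary statistics for n phenotypes under a latent
#' auto-logistic Markov random field: each SNP carries a binary association
#' indicator per phenotype; the indicators are coupled through an estimated
#' phenotype graph (spike-and-slab pairwise coefficients beta with
#' birth/death edge moves) and their propensity is raised for SNPs carrying
#' functional annotations (nonnegative coefficients gamma with
#' spike-and-slab annotation selection). z-scores of associated entries
#' follow a lognormal emission, null entries a standard normal. Posterior
#' summaries for the phenotype graph, annotation relevance, and per-SNP
#' marginal and pairwise association probabilities are accumulated during
#' sampling.
#'
#' @param data Data frame: SNP identifier column followed by one column per
#'   phenotype. By default columns hold z-scores (from
#'   [transform_pvalues()]); set `values = "p"` to pass p-values and have
#'   the transform applied with its defaults.
#' @param annotations Optional data frame of binary annotations aligned by
#'   SNP identifier (use [binarize_annotations()] for continuous scores).
#' @param prior_graph Optional two-column data frame of phenotype-label
#'   edges encoding prior knowledge about the graph; pairs in it get edge
#'   prior probability `hyper$prior_edge_prob_in`, pairs outside
#'   `hyper$prior_edge_prob_out`. Without it every pair has probability 0.5.
#' @param hyper A [pleio_hyper()] object.
#' @param control A [pleio_control()] object (iterations, burn-in, seed,
#'   step sizes, adaptation).
#' @param values `"z"` (default) or `"p"`.
#' @return An object of class `pleio_fit`; see [tidy.pleio_fit()],
#'   [glance.pleio_fit()], [decide_graph()], [decide_annotations()],
#'   [association_calls()], [pleiotropy_calls()].
#' @examples
#' sim <- pleio_sim(sim_scenario(n_snps = 300, gibbs_iters = 20), seed = 1)
#' fit <- pleio_fit(sim$zscores, sim$annotations,
#'                  control = pleio_control(n_iter = 200, n_burnin = 100,
#'                                          seed = 1))
#' tidy(fit, "edges")
#' @export
pleio_fit <- function(data, annotations = NULL, prior_graph = NULL,
                      hyper = pleio_hyper(), control = pleio_control(),
                      values = c("z", "p")) {
  values <- match.arg(values)
  if (!inherits(hyper, "pleio_hyper")) abort("`hyper` must come from pleio_hyper().")
  if (!inherits(control, "pleio_control")) abort("`control` must come from pleio_control().")
  if (values == "p") data <- transform_pvalues(data)
  s <- split_stats(data, "z-score")
  Y <- s$values
  phen <- s$names
  n <- ncol(Y)
  if (n < 1) abort("Need at least one phenotype column.")
  if (n > control$n_max) {
    abort(sprintf(
      "%d phenotypes exceeds the exact-enumeration limit n_max = %d.",
      n, control$n_max))
  }

  if (!is.null(annotations)) {
    sa <- split_stats(annotations, "annotation")
    if (s$has_id && sa$has_id) {
      idx <- match(s$ids, sa$ids)
      if (anyNA(idx)) {
        abort(sprintf(
          "%d SNP(s) in `data` are missing from `annotations`; alignment is by SNP identifier.",
          sum(is.na(idx))))
      }
      A <- sa$values[idx, , drop = FALSE]
    } else {
      if (nrow(sa$values) != nrow(Y)) {
        abort("Without SNP identifiers, `annotations` must have the same rows as `data`.")
      }
      A <- sa$values
    }
    if (!all(A %in% c(0, 1))) {
      abort("Annotations must be 0/1; use binarize_annotations() for scores.")
    }
    anno_names <- sa$names
  } else {
    A <- zero_matrix(nrow(Y), 0L)
    anno_names <- character(0)
  }

  prior_adj <- NULL
  if (!is.null(prior_graph)) {
    pg <- as.data.frame(prior_graph)
    labs <- unique(c(as.character(pg[[1]]), as.character(pg[[2]])))
    unknown <- setdiff(labs, phen)
    if (length(unknown) > 0) {
      abort(sprintf("Prior-graph label(s) not among phenotypes: %s.",
                    paste(unknown, collapse = ", ")))
    }
    prior_adj <- matrix(0, n, n, dimnames = list(phen, phen))
    for (r in seq_len(nrow(pg))) {
      i <- match(as.character(pg[r, 1]), phen)
      j <- match(as.character(pg[r, 2]), phen)
      if (i == j) abort("Prior graph contains a self-edge.")
      prior_adj[i, j] <- prior_adj[j, i] <- 1
    }
  }

  joint_sets <- lapply(control$joint_sets, function(g) {
    idx <- match(g, phen)
    if (anyNA(idx) || length(idx) < 2) {
      abort("Each element of `joint_sets` must name >= 2 phenotypes.")
    }
    sort(idx)
  })

  res <- fit_engine(Y, A, prior_adj, hyper, control, joint_sets)
  res$phenotypes <- phen
  res$annotation_names <- anno_names
  res$snp_ids <- s$ids
  res$hyper <- hyper
  res$control <- control
  res <- label_fit(res)
  class(res) <- "pleio_fit"
  res
}

fit_engine <- function(Y, A, prior_adj, hyper, control, joint_sets = list(),
                       state0 = NULL) {
  t0 <- proc.time()[["elapsed"]]
  set.seed(control$seed)
  Tn <- nrow(Y)
  n <- ncol(Y)
  M <- ncol(A)
  if (control$fix_gamma_zero) M_active <- 0L else M_active <- M
  pairs <- pairs_of(n)
  K <- ncol(pairs)
  pat <- annotation_patterns(A)
  n_pat <- nrow(pat$patterns)
  S <- mrf_states(n)
  Spair_states <- S[, pairs[1, ], drop = FALSE] * S[, pairs[2, ], drop = FALSE]
  # engine-local normalizing constants: same quantity as logC_patterns(),
  # with the enumeration scaffolding hoisted out of the sweep loop
  logC_fast <- function(alpha, gamma, beta_vec) {
    if (n_pat == 0) return(numeric(0))
    ae <- matrix(alpha, n_pat, n, byrow = TRUE)
    if (M > 0) ae <- ae + pat$patterns %*% t(gamma)
    K <- tcrossprod(S, ae)
    if (any(beta_vec != 0)) K <- K + drop(Spair_states %*% beta_vec)
    col_logsumexp(K)
  }
  pe <- edge_prior_probs(pairs, prior_adj, hyper)
  logN <- dnorm(Y, log = TRUE)
  lY <- suppressWarnings(log(Y))   # NaN below the lognormal support
  yneg <- !(Y > 0)

  # --- initialization ---------------------------------------------------
  if (is.null(state0)) {
    e <- (Y > 2.33) + 0
    mu <- numeric(n)
    sigma2 <- numeric(n)
    for (i in seq_len(n)) {
      z <- log(Y[e[, i] == 1, i])
      mu[i] <- if (length(z) > 4) mean(z) else 1
      sigma2[i] <- if (length(z) > 4) max(var(z), 0.01) else 0.16
    }
    cm <- if (Tn > 0) colMeans(e) else rep(0.01, n)
    alpha <- qlogis(pmin(pmax(cm, 1 / max(Tn, 2)), 0.5))
    beta_vec <- numeric(K)
    E_vec <- integer(K)
    gamma <- zero_matrix(n, M)
    u <- zero_matrix(n, M)
    p_u <- 0.5
    ls_alpha <- rep(log(control$step_alpha), n)
    ls_beta <- log(control$step_beta)
    ls_gamma <- log(control$step_gamma)
  } else {
    e <- state0$e; mu <- state0$mu; sigma2 <- state0$sigma2
    alpha <- state0$alpha; beta_vec <- state0$beta_vec
    E_vec <- state0$E_vec; gamma <- state0$gamma; u <- state0$u
    p_u <- state0$p_u
    ls_alpha <- state0$ls_alpha %||% rep(log(control$step_alpha), n)
    ls_beta <- state0$ls_beta %||% log(control$step_beta)
    ls_gamma <- state0$ls_gamma %||% log(control$step_gamma)
  }
  B <- vec_to_sym(beta_vec, pairs, n)

  logC <- logC_fast(alpha, gamma, beta_vec)
  sum_logC <- sum(pat$counts * logC)

  # --- accumulators and traces ------------------------------------------
  n_keep <- length(seq(control$n_burnin + control$thin, control$n_iter,
                       by = control$thin))
  acc_edge <- numeric(K)
  acc_beta_pos <- numeric(K)
  acc_beta_sum <- numeric(K)
  acc_u <- zero_matrix(n, M)
  acc_gamma_pos <- zero_matrix(n, M)
  acc_gamma_sum <- zero_matrix(n, M)
  acc_e <- zero_matrix(Tn, n)
  acc_pair <- zero_matrix(Tn, K)
  acc_joint <- if (length(joint_sets)) zero_matrix(Tn, length(joint_sets))
  tr_alpha <- matrix(NA_real_, n_keep, n)
  tr_beta <- matrix(NA_real_, n_keep, K)
  tr_gamma <- if (M > 0) matrix(NA_real_, n_keep, n * M)
  tr_mu <- matrix(NA_real_, n_keep, n)
  tr_sigma2 <- matrix(NA_real_, n_keep, n)
  tr_pu <- numeric(n_keep)
  kept <- 0L

  # acceptance bookkeeping: totals and per-burn-in-batch counts
  acc_tot <- c(alpha = 0, beta_within = 0, beta_trans = 0,
               gamma_within = 0, gamma_trans = 0)
  try_tot <- acc_tot
  bat_acc_alpha <- numeric(n); bat_try_alpha <- numeric(n)
  bat_acc_beta <- 0; bat_try_beta <- 0
  bat_acc_gamma <- 0; bat_try_gamma <- 0
  batch_len <- 50L
  batch_no <- 0L

  for (iter in seq_len(control$n_iter)) {
    ## ---- e | rest (Gibbs, exact full conditionals) --------------------
    if (Tn > 0) {
      Ag <- if (M_active > 0) A %*% t(gamma) else NULL
      LR <- emission_logratio(lY, logN, yneg, mu, sigma2)
      e <- gibbs_e_sweep(e, alpha, B, Ag, LR)
    }

    ## ---- emission parameters (conjugate) -------------------------------
    for (i in seq_len(n)) {
      z <- if (Tn > 0) lY[e[, i] == 1, i] else numeric(0)
      draw <- draw_emission_pair(z, mu[i], hyper)
      sigma2[i] <- draw[1]
      mu[i] <- draw[2]
    }

    ## ---- alpha (random-walk MH; normalizing constant recomputed) ------
    s_e <- colSums(e)
    for (i in seq_len(n)) {
      prop <- alpha
      prop[i] <- alpha[i] + rnorm(1, 0, exp(ls_alpha[i]))
      lC_new <- logC_fast(prop, gamma, beta_vec)
      sum_new <- sum(pat$counts * lC_new)
      la <- (prop[i] - alpha[i]) * s_e[i] - (sum_new - sum_logC) +
        dnorm(prop[i], hyper$theta_alpha, sqrt(hyper$tau2_alpha), log = TRUE) -
        dnorm(alpha[i], hyper$theta_alpha, sqrt(hyper$tau2_alpha), log = TRUE)
      try_tot["alpha"] <- try_tot["alpha"] + 1
      bat_try_alpha[i] <- bat_try_alpha[i] + 1
      if (log(runif(1)) < la) {
        alpha <- prop; logC <- lC_new; sum_logC <- sum_new
        acc_tot["alpha"] <- acc_tot["alpha"] + 1
        bat_acc_alpha[i] <- bat_acc_alpha[i] + 1
      }
    }

    ## ---- (beta, G): within-model walks and birth/death edge moves -----
    for (k in seq_len(K)) {
      i <- pairs[1, k]; j <- pairs[2, k]
      s_ij <- if (Tn > 0) sum(e[, i] * e[, j]) else 0
      if (runif(1) < 0.5) {
        # within-model log-scale random walk, only when the edge exists
        if (E_vec[k] == 1) {
          b_old <- beta_vec[k]
          b_new <- b_old * exp(rnorm(1, 0, exp(ls_beta)))
          bv2 <- beta_vec; bv2[k] <- b_new
          lC_new <- logC_fast(alpha, gamma, bv2)
          sum_new <- sum(pat$counts * lC_new)
          la <- (b_new - b_old) * s_ij - (sum_new - sum_logC) +
            dgamma(b_new, hyper$a_beta, rate = hyper$b_beta, log = TRUE) -
            dgamma(b_old, hyper$a_beta, rate = hyper$b_beta, log = TRUE) +
            log(b_new) - log(b_old)
          try_tot["beta_within"] <- try_tot["beta_within"] + 1
          bat_try_beta <- bat_try_beta + 1
          if (log(runif(1)) < la) {
            beta_vec[k] <- b_new; B[i, j] <- B[j, i] <- b_new
            logC <- lC_new; sum_logC <- sum_new
            acc_tot["beta_within"] <- acc_tot["beta_within"] + 1
            bat_acc_beta <- bat_acc_beta + 1
          }
        }
      } else {
        # trans-model: birth proposes beta from the slab (so the slab
        # density cancels), death removes the edge
        try_tot["beta_trans"] <- try_tot["beta_trans"] + 1
        if (E_vec[k] == 0) {
          b_new <- rgamma(1, hyper$a_beta, rate = hyper$b_beta)
          bv2 <- beta_vec; bv2[k] <- b_new
          lC_new <- logC_fast(alpha, gamma, bv2)
          sum_new <- sum(pat$counts * lC_new)
          la <- b_new * s_ij - (sum_new - sum_logC) + log(pe[k]) - log(1 - pe[k])
          if (log(runif(1)) < la) {
            E_vec[k] <- 1L; beta_vec[k] <- b_new; B[i, j] <- B[j, i] <- b_new
            logC <- lC_new; sum_logC <- sum_new
            acc_tot["beta_trans"] <- acc_tot["beta_trans"] + 1
          }
        } else {
          b_old <- beta_vec[k]
          bv2 <- beta_vec; bv2[k] <- 0
          lC_new <- logC_fast(alpha, gamma, bv2)
          sum_new <- sum(pat$counts * lC_new)
          la <- -b_old * s_ij - (sum_new - sum_logC) + log(1 - pe[k]) - log(pe[k])
          if (log(runif(1)) < la) {
            E_vec[k] <- 0L; beta_vec[k] <- 0; B[i, j] <- B[j, i] <- 0
            logC <- lC_new; sum_logC <- sum_new
            acc_tot["beta_trans"] <- acc_tot["beta_trans"] + 1
          }
        }
      }
    }

    ## ---- (gamma, u): same scheme per (phenotype, annotation) ----------
    if (M_active > 0) {
      SAE <- if (Tn > 0) crossprod(A, e) else zero_matrix(M, n)  # M x n
      for (i in seq_len(n)) {
        for (m in seq_len(M)) {
          s_ae <- SAE[m, i]
          if (runif(1) < 0.5) {
            if (u[i, m] == 1L) {
              g_old <- gamma[i, m]
              g_new <- g_old * exp(rnorm(1, 0, exp(ls_gamma)))
              G2 <- gamma; G2[i, m] <- g_new
              lC_new <- logC_fast(alpha, G2, beta_vec)
              sum_new <- sum(pat$counts * lC_new)
              la <- (g_new - g_old) * s_ae - (sum_new - sum_logC) +
                dgamma(g_new, hyper$a_gamma, rate = hyper$b_gamma, log = TRUE) -
                dgamma(g_old, hyper$a_gamma, rate = hyper$b_gamma, log = TRUE) +
                log(g_new) - log(g_old)
              try_tot["gamma_within"] <- try_tot["gamma_within"] + 1
              bat_try_gamma <- bat_try_gamma + 1
              if (log(runif(1)) < la) {
                gamma <- G2; logC <- lC_new; sum_logC <- sum_new
                acc_tot["gamma_within"] <- acc_tot["gamma_within"] + 1
                bat_acc_gamma <- bat_acc_gamma + 1
              }
            }
          } else {
            try_tot["gamma_trans"] <- try_tot["gamma_trans"] + 1
            if (u[i, m] == 0L) {
              g_new <- rgamma(1, hyper$a_gamma, rate = hyper$b_gamma)
              G2 <- gamma; G2[i, m] <- g_new
              lC_new <- logC_fast(alpha, G2, beta_vec)
              sum_new <- sum(pat$counts * lC_new)
              la <- g_new * s_ae - (sum_new - sum_logC) + log(p_u) - log(1 - p_u)
              if (log(runif(1)) < la) {
                u[i, m] <- 1L; gamma <- G2
                logC <- lC_new; sum_logC <- sum_new
                acc_tot["gamma_trans"] <- acc_tot["gamma_trans"] + 1
              }
            } else {
              g_old <- gamma[i, m]
              G2 <- gamma; G2[i, m] <- 0
              lC_new <- logC_fast(alpha, G2, beta_vec)
              sum_new <- sum(pat$counts * lC_new)
              la <- -g_old * s_ae - (sum_new - sum_logC) + log(1 - p_u) - log(p_u)
              if (log(runif(1)) < la) {
                u[i, m] <- 0L; gamma <- G2
                logC <- lC_new; sum_logC <- sum_new
                acc_tot["gamma_trans"] <- acc_tot["gamma_trans"] + 1
              }
            }
          }
        }
      }
      ## ---- p_u (conjugate Beta) ----------------------------------------
      p_u <- rbeta(1, 1 + sum(u), 1 + n * M - sum(u))
    }

    ## ---- step-size adaptation during burn-in ---------------------------
    if (control$adapt && iter <= control$n_burnin && iter %% batch_len == 0) {
      batch_no <- batch_no + 1L
      step <- min(0.5, 2 / sqrt(batch_no))
      ok <- bat_try_alpha > 0
      ls_alpha[ok] <- ls_alpha[ok] +
        step * (bat_acc_alpha[ok] / bat_try_alpha[ok] - control$target_accept)
      if (bat_try_beta > 0) {
        ls_beta <- ls_beta + step * (bat_acc_beta / bat_try_beta - control$target_accept)
      }
      if (bat_try_gamma > 0) {
        ls_gamma <- ls_gamma + step * (bat_acc_gamma / bat_try_gamma - control$target_accept)
      }
      bat_acc_alpha[] <- 0; bat_try_alpha[] <- 0
      bat_acc_beta <- bat_try_beta <- 0
      bat_acc_gamma <- bat_try_gamma <- 0
    }

    ## ---- accumulation at thinned post-burn-in sweeps --------------------
    if (iter > control$n_burnin &&
        (iter - control$n_burnin) %% control$thin == 0) {
      kept <- kept + 1L
      acc_edge <- acc_edge + E_vec
      acc_beta_pos <- acc_beta_pos + (beta_vec > 0)
      acc_beta_sum <- acc_beta_sum + beta_vec
      if (M > 0) {
        acc_u <- acc_u + u
        acc_gamma_pos <- acc_gamma_pos + (gamma > 0)
        acc_gamma_sum <- acc_gamma_sum + gamma
      }
      if (Tn > 0) {
        acc_e <- acc_e + e
        acc_pair <- acc_pair + e[, pairs[1, ], drop = FALSE] *
          e[, pairs[2, ], drop = FALSE]
        if (length(joint_sets)) {
          for (g in seq_along(joint_sets)) {
            prod_g <- e[, joint_sets[[g]][1]]
            for (ii in joint_sets[[g]][-1]) prod_g <- prod_g * e[, ii]
            acc_joint[, g] <- acc_joint[, g] + prod_g
          }
        }
      }
      tr_alpha[kept, ] <- alpha
      tr_beta[kept, ] <- beta_vec
      if (M > 0) tr_gamma[kept, ] <- as.vector(gamma)
      tr_mu[kept, ] <- mu
      tr_sigma2[kept, ] <- sigma2
      tr_pu[kept] <- p_u
    }

    if (control$verbose && iter %% 500 == 0) {
      inform(sprintf("sweep %d/%d; %d edge(s), %d annotation term(s) active",
                     iter, control$n_iter, sum(E_vec), sum(u)))
    }
  }

  rates <- ifelse(try_tot > 0, acc_tot / try_tot, NA_real_)
  list(
    n = n, M = M, T = Tn, pairs = pairs,
    p_edge = acc_edge / kept,
    p_beta_pos = acc_beta_pos / kept,
    beta_mean_incl = ifelse(acc_edge > 0, acc_beta_sum / pmax(acc_edge, 1),
                            NA_real_),
    p_u_incl = if (M > 0) acc_u / kept else matrix(0, n, 0),
    p_gamma_pos = if (M > 0) acc_gamma_pos / kept else matrix(0, n, 0),
    gamma_mean_incl = if (M > 0) {
      ifelse(acc_u > 0, acc_gamma_sum / pmax(acc_u, 1), NA_real_)
    } else matrix(0, n, 0),
    snp_marginal = if (Tn > 0) acc_e / kept else acc_e,
    snp_pairwise = if (Tn > 0) acc_pair / kept else acc_pair,
    snp_joint = if (length(joint_sets)) acc_joint / kept,
    joint_sets = joint_sets,
    traces = list(alpha = tr_alpha, beta = tr_beta,
                  gamma = if (M > 0) tr_gamma,
                  mu = tr_mu, sigma2 = tr_sigma2, p_u = tr_pu),
    n_kept = kept,
    acceptance = tibble::tibble(block = names(rates), rate = unname(rates),
                                proposals = unname(try_tot)),
    step_sizes = list(alpha = exp(ls_alpha), log_beta = exp(ls_beta),
                      log_gamma = exp(ls_gamma)),
    final_state = list(e = e, mu = mu, sigma2 = sigma2, alpha = alpha,
                       beta_vec = beta_vec, E_vec = E_vec, gamma = gamma,
                       u = u, p_u = p_u, ls_alpha = ls_alpha,
                       ls_beta = ls_beta, ls_gamma = ls_gamma),
    runtime_sec = proc.time()[["elapsed"]] - t0
  )
}

# attach phenotype/annotation labels and build the summary tibbles
label_fit <- function(res) {
  phen <- res$phenotypes
  pairs <- res$pairs
  K <- ncol(pairs)
  ci <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  ci_cols <- function(m) {
    if (ncol(m) == 0) matrix(numeric(0), 2, 0) else apply(m, 2, ci)
  }
  bq <- ci_cols(res$traces$beta)
  res$edges <- tibble::tibble(
    phenotype1 = phen[pairs[1, ]],
    phenotype2 = phen[pairs[2, ]],
    p_edge = res$p_edge,
    p_beta_pos = res$p_beta_pos,
    beta_mean = res$beta_mean_incl,
    beta_lo = bq[1, ], beta_hi = bq[2, ]
  )
  aq <- apply(res$traces$alpha, 2, ci)
  res$alpha <- tibble::tibble(
    phenotype = phen,
    alpha_mean = colMeans(res$traces$alpha),
    alpha_lo = aq[1, ], alpha_hi = aq[2, ]
  )
  mq <- apply(res$traces$mu, 2, ci)
  sig <- sqrt(res$traces$sigma2)
  sq <- apply(sig, 2, ci)
  res$emission <- tibble::tibble(
    phenotype = phen,
    mu_mean = colMeans(res$traces$mu), mu_lo = mq[1, ], mu_hi = mq[2, ],
    sigma_mean = colMeans(sig), sigma_lo = sq[1, ], sigma_hi = sq[2, ]
  )
  if (res$M > 0) {
    gq <- ci_cols(res$traces$gamma)
    res$annotations <- tibble::tibble(
      phenotype = rep(phen, times = res$M),
      annotation = rep(res$annotation_names, each = res$n),
      p_incl = as.vector(res$p_u_incl),
      p_gamma_pos = as.vector(res$p_gamma_pos),
      gamma_mean = as.vector(res$gamma_mean_incl),
      gamma_lo = gq[1, ], gamma_hi = gq[2, ]
    )
  } else {
    res$annotations <- tibble::tibble(
      phenotype = character(0), annotation = character(0),
      p_incl = numeric(0), p_gamma_pos = numeric(0), gamma_mean = numeric(0),
      gamma_lo = numeric(0), gamma_hi = numeric(0)
    )
  }
  res$p_u_mean <- if (res$M > 0) mean(res$traces$p_u) else NA_real_
  res
}


# T x n matrix of log emission-density ratios log LN(y) - log N(y), written
# out to avoid dlnorm calls in the innermost loop; -Inf where y <= 0
emission_logratio <- function(lY, logN, yneg, mu, sigma2) {
  n <- length(mu)
  LR <- matrix(0, nrow(lY), n)
  for (i in seq_len(n)) {
    lr <- -lY[, i] - 0.5 * log(sigma2[i]) - 0.9189385332046727 -
      (lY[, i] - mu[i])^2 / (2 * sigma2[i]) - logN[, i]
    lr[yneg[, i]] <- -Inf
    LR[, i] <- lr
  }
  LR
}

# One systematic Gibbs scan over phenotypes: column i is resampled jointly
# over SNPs (conditionally independent given the other columns) from the
# exact full conditional, sequentially over i.
gibbs_e_sweep <- function(e, alpha, B, Ag, LR) {
  Tn <- nrow(e)
  for (i in seq_along(alpha)) {
    eta <- alpha[i] + drop(e %*% B[, i])
    if (!is.null(Ag)) eta <- eta + Ag[, i]
    e[, i] <- (runif(Tn) < 1 / (1 + exp(-(eta + LR[, i])))) + 0
  }
  e
}

# sigma^2 from its inverse-gamma full conditional given mu, then mu from its
# normal full conditional given the new sigma^2; prior draws when no SNP is
# associated. Returns c(sigma2, mu).
draw_emission_pair <- function(z, mu_prev, hyper) {
  nz <- length(z)
  sigma2 <- 1 / rgamma(1, hyper$a_sigma + nz / 2,
                       rate = hyper$b_sigma +
                         (if (nz > 0) sum((z - mu_prev)^2) / 2 else 0))
  prec <- 1 / hyper$tau2_mu + nz / sigma2
  mn <- (hyper$theta_mu / hyper$tau2_mu + (if (nz > 0) sum(z) else 0) / sigma2) /
    prec
  c(sigma2, rnorm(1, mn, sqrt(1 / prec)))
}
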
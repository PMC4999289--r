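# shared fixtures: all built in code, no stored data

# 3-study toy network: two 2-arm trials and one 3-arm trial, 3 treatments
toy_arms <- function() {
  arm_table(study = c("alpha", "alpha", "beta", "beta", "gamma", "gamma", "gamma"),
            treatment = c(1L, 2L, 1L, 3L, 1L, 2L, 3L),
            r = c(12L, 7L, 20L, 12L, 5L, 4L, 2L),
            n = c(120L, 118L, 240L, 236L, 60L, 62L, 59L))
}

toy_network <- function() build_network(toy_arms())

# deterministic parameter state with the right dimensions for a network
toy_state <- function(net, seed = 42, sigma = 0.3, beta = 0) {
  set.seed(seed)
  ix <- nmareg:::network_indices(net)
  parameter_state(mu = rnorm(net$n_studies, -2, 0.5),
                  d = c(0, rnorm(net$n_treatments - 1, -0.5, 0.3)),
                  delta = rnorm(sum(!ix$is_base), -0.4, 0.4),
                  sigma = sigma, beta = beta)
}

# independent evaluation of the toy model's log joint (brute force):
# binomial pmfs summed term by term plus closed-form normal/MVN priors
oracle_log_joint <- function(state, net, spec, x = NULL, m_center = NULL) {
  ix <- nmareg:::network_indices(net)
  if (spec$covariate_mode == "baseline_risk") x <- state$mu - m_center
  total <- 0
  for (a in seq_along(ix$r)) {
    eta <- state$mu[ix$study[a]]
    if (!ix$is_base[a]) {
      eta <- eta + if (spec$effect == "RE") state$delta[ix$delta_idx[a]] else
        state$d[ix$treat[a]] - state$d[ix$base[a]]
    }
    if (!is.null(x)) {
      w <- as.integer(ix$treat[a] != 1L) - as.integer(ix$base[a] != 1L)
      eta <- eta + state$beta * x[ix$study[a]] * w
    }
    p <- 1 / (1 + exp(-eta))
    total <- total + lchoose(ix$n[a], ix$r[a]) +
      ix$r[a] * log(p) + (ix$n[a] - ix$r[a]) * log1p(-p)
  }
  total <- total +
    sum(dnorm(state$mu, spec$prior_effect_mean, spec$prior_effect_sd, log = TRUE)) +
    sum(dnorm(state$d[-1], spec$prior_effect_mean, spec$prior_effect_sd, log = TRUE))
  if (spec$covariate_mode != "none") {
    total <- total + dnorm(state$beta, spec$beta_prior_mean, spec$beta_prior_sd, log = TRUE)
  }
  if (spec$effect == "RE") {
    total <- total + dunif(state$sigma, 0, spec$sd_prior_upper, log = TRUE)
    for (s in seq_len(net$n_studies)) {
      rows <- which(ix$study == s & !ix$is_base)
      m <- length(rows)
      Sigma <- state$sigma^2 * (diag(m) + matrix(1, m, m)) / 2
      e <- state$delta[ix$delta_idx[rows]] -
        (state$d[ix$treat[rows]] - state$d[ix$base[rows]])
      total <- total - 0.5 * (m * log(2 * pi) + determinant(Sigma)$modulus +
                                drop(t(e) %*% solve(Sigma) %*% e))
    }
  }
  as.numeric(total)
}

# quiet fit wrappers: scaled-down MCMC runs may warn about convergence
qfit <- function(...) suppressWarnings(fit_nma(...))
qfit_cov <- function(...) suppressWarnings(fit_covariate_model(...))
qfit_base <- function(...) suppressWarnings(fit_baseline_risk_model(...))

# minimal hand-built nma_fit carrying given p draws (for deviance oracles)
fake_fit <- function(net, p_draws) {
  structure(list(network = net, p = list(p_draws),
                 draws = list(matrix(0, nrow(p_draws), 1,
                                     dimnames = list(NULL, "d[2]"))),
                 convergence = NULL,
                 mcmc = mcmc_config(chains = 1, burn_in = 0,
                                    samples = nrow(p_draws))),
            class = "nma_fit")
}

# minimal fit holding given per-chain draw vectors (for BGR checks)
fake_chain_fit <- function(..., par = "theta") {
  chains <- lapply(list(...), function(v) matrix(v, ncol = 1,
                                                 dimnames = list(NULL, par)))
  structure(list(draws = chains, mcmc = mcmc_config(chains = length(chains))),
            class = "nma_fit")
}
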
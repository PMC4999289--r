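test_that("interaction terms cancel for within-trial non-reference contrasts", {
  # study 'hh' compares two active treatments; no reference arm anywhere in it
  arms <- arm_table(c("pc", "pc", "hh", "hh", "hh"),
                    c(1L, 2L, 2L, 3L, 4L),
                    c(10L, 6L, 8L, 7L, 9L), c(100L, 100L, 90L, 95L, 88L))
  net <- build_network(arms)
  spec <- model_spec("RE", covariate_mode = "covariate")
  set.seed(11)
  for (i in 1:20) {
    st <- toy_state(net, seed = i, beta = rnorm(1, 0, 2))
    st2 <- st; st2$beta <- rnorm(1, 0, 2)
    x <- rnorm(2, 0, 3)
    eta1 <- regression_linear_predictor(st, net, x, spec)
    eta2 <- regression_linear_predictor(st2, net, x, spec)
    hh <- net$arms$study == "hh"
    # all within-study contrasts in the head-to-head trial: identical
    expect_identical(diff(eta1[hh]), diff(eta2[hh]))
    # but the placebo-controlled trial's active arm does move with beta
    pc_active <- which(net$arms$study == "pc" & net$arms$treatment == 2L)
    expect_false(isTRUE(all.equal(eta1[pc_active], eta2[pc_active])))
  }
})

test_that("beta = 0 reproduces the unadjusted predictor; known shift checks out", {
  net <- toy_network()
  spec_adj <- model_spec("RE", covariate_mode = "covariate")
  st <- toy_state(net, seed = 2, beta = 0)
  x <- c(2, -1, 0.5)
  expect_identical(regression_linear_predictor(st, net, x, spec_adj),
                   regression_linear_predictor(st, net, NULL, spec_adj))
  # placebo-controlled arm with x = 2, beta = 0.5: logit shifted by exactly +1
  st5 <- st; st5$beta <- 0.5
  eta0 <- regression_linear_predictor(st, net, x, spec_adj)
  eta5 <- regression_linear_predictor(st5, net, x, spec_adj)
  a_active <- which(net$arms$study == "alpha" & net$arms$treatment == 2L)
  expect_equal(eta5[a_active] - eta0[a_active], 1)
  a_base <- which(net$arms$study == "alpha" & net$arms$treatment == 1L)
  expect_equal(eta5[a_base], eta0[a_base])
  expect_error(regression_linear_predictor(st, net, x[1:2], spec_adj), "wrong length")
})

test_that("covariate model recovers a known interaction and pairs with a matched comparator", {
  cfg <- sim_config(n_studies = 20, n_treatments = 5, prop_placebo = 1,
                    true_beta = 0.8, beta_covariate = "follow_up",
                    arm_n = c(400L, 800L), zero_cell_rate = 0,
                    true_sigma = 0.2, seed = 101)
  sim <- simulate_network(cfg)
  net <- build_network(sim$arms)
  att <- attach_covariate(net, sim$covariates, "follow_up")
  cf <- qfit_cov(att, model_spec("RE"), mcmc_config_test(seed = 9))
  b <- beta_summary(cf)
  expect_true(b$beta_l95 <= 0.8 && b$beta_u95 >= 0.8)
  expect_equal(b$covariate, "follow_up")
  # matched comparator fitted on the same reduced data
  expect_identical(cf$unadjusted$network$arms, cf$adjusted$network$arms)
  expect_true(all(do.call(rbind, cf$unadjusted$draws)[, "beta"] == 0))
})

test_that("shifting the covariate leaves beta, baselines and off-reference contrasts alone", {
  # in this parameterisation a shift x -> x + c moves each effect versus
  # the reference by -beta * c (effects are defined at x = 0), cancels in
  # every contrast between non-reference treatments, and leaves beta and
  # the baselines untouched
  cfg <- sim_config(n_studies = 14, n_treatments = 4, prop_placebo = 1,
                    true_beta = 0.5, arm_n = c(400L, 800L), zero_cell_rate = 0,
                    true_sigma = 0.15, seed = 55)
  sim <- simulate_network(cfg)
  net <- build_network(sim$arms)
  att <- attach_covariate(net, sim$covariates, "follow_up")
  mc <- mcmc_config_test(seed = 6)
  f_c <- qfit_cov(att, model_spec("RE"), mc, fit_unadjusted = FALSE)
  att_shift <- att; att_shift$x <- att$x + 3
  f_s <- qfit_cov(att_shift, model_spec("RE"), mc, fit_unadjusted = FALSE)
  b_c <- beta_summary(f_c)$beta_median
  b_s <- beta_summary(f_s)$beta_median
  expect_equal(b_c, b_s, tolerance = 0.25)
  d_c <- posterior_summary(f_c$adjusted, paste0("d[", 2:4, "]"))$median
  d_s <- posterior_summary(f_s$adjusted, paste0("d[", 2:4, "]"))$median
  # reference effects shift by about -beta * 3 ...
  expect_equal(d_s - d_c, rep(-3 * b_c, 3), tolerance = 0.35)
  # ... so non-reference contrasts are unchanged within MC error
  expect_equal(d_c[2] - d_c[1], d_s[2] - d_s[1], tolerance = 0.1)
  # baselines are untouched (baseline arms carry no interaction term)
  pc <- which(unname(net$study_baseline) == 1L)[1]
  mu_c <- posterior_summary(f_c$adjusted, sprintf("mu[%d]", pc))$median
  mu_s <- posterior_summary(f_s$adjusted, sprintf("mu[%d]", pc))$median
  expect_equal(mu_c, mu_s, tolerance = 0.05)
})

test_that("baseline-risk model: head-to-head contrasts invariant, null beta covered", {
  # algebraic invariance of non-reference contrasts to beta, machine precision
  arms <- arm_table(c("pc", "pc", "hh", "hh"), c(1L, 2L, 2L, 3L),
                    c(10L, 6L, 8L, 7L), c(100L, 100L, 90L, 95L))
  net <- build_network(arms)
  spec <- model_spec("RE", covariate_mode = "baseline_risk")
  for (i in 1:10) {
    st <- toy_state(net, seed = i, beta = rnorm(1, 0, 2))
    st2 <- st; st2$beta <- st$beta + 1.3
    e1 <- regression_linear_predictor(st, net, st$mu - (-2), spec)
    e2 <- regression_linear_predictor(st2, net, st2$mu - (-2), spec)
    hh <- net$arms$study == "hh"
    expect_identical(diff(e1[hh]), diff(e2[hh]))
  }

  # data simulated with beta = 0: CrI covers 0
  cfg <- sim_config(n_studies = 16, n_treatments = 4, prop_placebo = 0.6,
                    true_beta = 0, arm_n = c(300L, 700L), zero_cell_rate = 0,
                    true_sigma = 0.15, seed = 77)
  sim <- simulate_network(cfg)
  bf <- qfit_base(build_network(sim$arms), model_spec("RE"),
                  mcmc_config_test(seed = 12, burn_in = 5000L, samples = 5000L),
                  fit_unadjusted = FALSE)
  b <- beta_summary(bf)
  expect_true(b$beta_l95 <= 0 && b$beta_u95 >= 0)
  expect_equal(b$covariate, "baseline_risk")
})

test_that("latent baseline (exchangeable) resists the dilution that biases the naive covariate", {
  # beta = 0 truth, small arms: the observed-logit covariate shares its
  # sampling error with the effect estimate and drifts negative; the
  # hierarchical latent-covariate model stays near zero (paired seeds)
  naive <- c(); latent <- c()
  for (s in 1:6) {
    cfg <- sim_config(n_studies = 20, n_treatments = 4, prop_placebo = 1,
                      true_beta = 0, beta_on = "baseline",
                      arm_n = c(40L, 80L), zero_cell_rate = 0, true_sigma = 0.1,
                      baseline_mu = c(-1.5, 0.6), seed = s)
    sim <- simulate_network(cfg)
    net <- build_network(sim$arms)
    obs <- observed_baseline_logits(net)[net$studies]
    att <- list(network = net, x = obs - mean(obs), name = "baseline_naive")
    mc <- mcmc_config_test(seed = s + 70, burn_in = 5000L, samples = 5000L)
    nf <- qfit_cov(att, model_spec("RE"), mc, fit_unadjusted = FALSE)
    lf <- qfit_base(net, model_spec("RE"), mc, fit_unadjusted = FALSE,
                    baseline_prior = "exchangeable")
    naive <- c(naive, beta_summary(nf)$beta_median)
    latent <- c(latent, beta_summary(lf)$beta_median)
  }
  expect_gte(abs(mean(naive)), abs(mean(latent)))
})
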
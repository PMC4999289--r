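test_that("residual deviance matches brute-force evaluation to 12 decimals", {
  net <- build_network(arm_table(c("a", "a", "b", "b"), c(1L, 2L, 1L, 2L),
                                 c(3L, 0L, 10L, 12L), c(40L, 100L, 60L, 80L)))
  set.seed(42)
  p <- matrix(runif(5 * 4, 0.02, 0.3), nrow = 5)
  fit <- fake_fit(net, p)
  rd <- residual_deviance(fit)
  # independent brute force, draw by draw
  r <- net$arms$r; n <- net$arms$n
  brute <- sapply(seq_len(4), function(a) {
    mean(sapply(seq_len(5), function(j) {
      rhat <- n[a] * p[j, a]
      t1 <- if (r[a] == 0) 0 else r[a] * log(r[a] / rhat)
      t2 <- if (r[a] == n[a]) 0 else (n[a] - r[a]) * log((n[a] - r[a]) / (n[a] - rhat))
      2 * (t1 + t2)
    }))
  })
  expect_equal(unname(rd$dev_i), brute, tolerance = 1e-12)
  expect_equal(rd$Dbar, sum(brute), tolerance = 1e-12)
})

test_that("zero-cell deviance hits the closed form and saturated fits give zero", {
  net <- build_network(arm_table(c("a", "a"), c(1L, 2L), c(0L, 5L), c(100L, 50L)))
  # r = 0, n = 100, p-hat = 0.05 -> dev = 2 * 100 * log(100 / 95)
  p <- matrix(c(0.05, 5 / 50), nrow = 1)
  rd <- residual_deviance(fake_fit(net, p))
  expect_equal(unname(rd$dev_i[1]), 2 * 100 * log(100 / 95), tolerance = 1e-12)
  expect_equal(unname(rd$dev_i[1]), 10.25865888, tolerance = 1e-7)
  # saturated: p = r/n exactly -> zero everywhere (0 log 0 convention)
  p_sat <- matrix(c(0, 0.1), nrow = 1)
  expect_equal(unname(residual_deviance(fake_fit(net, p_sat))$dev_i), c(0, 0))
  # discordant degenerate plug-in propagates infinity, never masks it
  p_bad <- matrix(c(0.05, 0), nrow = 1)  # r = 5 but rhat = 0
  expect_equal(unname(residual_deviance(fake_fit(net, p_bad))$dev_i[2]), Inf)
})

test_that("DIC identities hold exactly on a real fit", {
  sim <- simulate_network(sim_config(n_studies = 8, n_treatments = 4, seed = 3))
  fit <- qfit(build_network(sim$arms), model_spec("RE"), mcmc_config_test(seed = 11))
  dg <- dic(fit)
  expect_equal(dg$DIC, dg$Dbar + dg$pD, tolerance = 1e-12)
  expect_equal(dg$DIC, dg$Dhat + 2 * dg$pD, tolerance = 1e-10)
  expect_equal(dg$Dbar, sum(dg$dev_i), tolerance = 1e-12)
  expect_equal(unname(dg$pD_i), unname(dg$dev_i) -
                 sapply(seq_len(dg$n_points), function(a) {
                   nmareg:::deviance_point(fit$network$arms$r[a], fit$network$arms$n[a],
                                           mean(nmareg:::pooled_p(fit)[, a]))
                 }), tolerance = 1e-10)
  expect_true(all(dg$dev_i >= 0))
})

test_that("FE effective parameters count baselines plus basic effects on mega-trials", {
  # 6 independent two-arm mega-trials over 4 treatments:
  # parameters = 6 baselines + 3 basic effects = 9
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  rows <- do.call(rbind, lapply(seq_len(6), function(i) {
    data.frame(study = sprintf("s%d", i), treatment = pairs[i, ],
               r = c(4000L, 3500L), n = c(50000L, 50000L))
  }))
  net <- build_network(arm_table(rows$study, rows$treatment, rows$r, rows$n))
  fit <- qfit(net, model_spec("FE"), mcmc_config_test(seed = 4))
  expect_equal(dic(fit)$pD, 9, tolerance = 0.7)
})

test_that("DIC comparison demands identical data and is zero on self-comparison", {
  sim <- simulate_network(sim_config(n_studies = 8, n_treatments = 4, seed = 3))
  net <- build_network(sim$arms)
  fit <- qfit(net, model_spec("RE"), mcmc_config_test(seed = 11))
  expect_equal(dic_difference(fit, fit), 0)
  sim2 <- simulate_network(sim_config(n_studies = 8, n_treatments = 4, seed = 4))
  fit2 <- qfit(build_network(sim2$arms), model_spec("RE"), mcmc_config_test(seed = 11))
  expect_error(dic_difference(fit, fit2), "identical data")
})

test_that("leverage flags points beyond the c = 3 parabola, order-invariantly", {
  # direct evaluation: w = 1.5, pD_i = 1 -> contribution 3.25 -> flagged;
  # a perfectly fitted point with tiny leverage is never flagged
  dg <- structure(list(dev_i = c(p1 = 2.25, p2 = 0), pD_i = c(1, 1e-9),
                       w_i = c(1.5, 0), study = c("a", "b"),
                       treatment = c(2L, 2L), n_points = 2L),
                  class = "fit_diagnostics")
  lev <- leverage_coordinates(dg)
  expect_equal(lev$contribution, c(3.25, 1e-9))
  expect_identical(lev$flagged, c(TRUE, FALSE))

  sim <- simulate_network(sim_config(n_studies = 8, n_treatments = 4, seed = 3))
  arms <- as.data.frame(sim$arms)
  f1 <- qfit(build_network(arm_table(arms$study, arms$treatment, arms$r, arms$n)),
             model_spec("RE"), mcmc_config_test(seed = 11))
  perm <- arms[sample(nrow(arms)), ]
  f2 <- qfit(build_network(arm_table(perm$study, perm$treatment, perm$r, perm$n)),
             model_spec("RE"), mcmc_config_test(seed = 11))
  l1 <- leverage_coordinates(dic(f1)); l2 <- leverage_coordinates(dic(f2))
  expect_identical(l1$flagged[order(l1$point_id)], l2$flagged[order(l2$point_id)])
})

test_that("an anomalous zero-cell arm surfaces as the extreme leverage point", {
  # a mid-sized trial whose anchor arm records zero events against a high
  # baseline is the analogue of the anomalous trial in the motivating
  # network: it should carry the largest deviance contribution
  sim <- simulate_network(sim_config(n_studies = 10, n_treatments = 4,
                                     arm_n = c(300L, 600L), zero_cell_rate = 0,
                                     true_sigma = 0.1, seed = 23))
  arms <- as.data.frame(sim$arms)
  anom <- which(arms$study == arms$study[1] & arms$treatment == 2L)[1]
  arms$r[anom] <- 0L; arms$n[anom] <- 250L
  fit <- qfit(build_network(arm_table(arms$study, arms$treatment, arms$r, arms$n)),
              model_spec("RE"), mcmc_config_test(seed = 14))
  lev <- leverage_coordinates(dic(fit))
  anom_id <- sprintf("%s:%d", arms$study[anom], 2L)
  expect_equal(lev$point_id[which.max(lev$contribution)], anom_id)
  expect_true(lev$flagged[lev$point_id == anom_id])
})

test_that("BGR is exactly 1 on identical chains and large when chains disagree", {
  x <- rnorm(500)
  fit_same <- fake_chain_fit(x, x)
  rep_same <- convergence_report(fit_same, split = FALSE)
  expect_identical(unname(rep_same$bgr), 1)

  set.seed(1)
  fit_far <- fake_chain_fit(rnorm(500, 0, 1), rnorm(500, 5, 1))
  rep_far <- convergence_report(fit_far, split = FALSE)
  expect_gt(rep_far$bgr, 1.1)
  expect_false(rep_far$converged)

  expect_error(convergence_report(fake_chain_fit(x)), "2 chains")
})

test_that("BGR agrees with the coda oracle where both are calibrated", {
  # the pooled/within population-variance ratio and coda's PSRF are
  # different estimators of the same quantity; they must agree at
  # stationarity (both ~ 1) and both must reject grossly separated chains
  skip_if_not_installed("coda")
  set.seed(9)
  a <- rnorm(4000); b <- rnorm(4000)
  ours <- unname(convergence_report(fake_chain_fit(a, b), split = FALSE)$bgr)
  cd <- unname(coda::gelman.diag(coda::mcmc.list(coda::mcmc(a), coda::mcmc(b)),
                                 autoburnin = FALSE)$psrf[1, 1])
  expect_equal(ours, cd, tolerance = 0.005)
  a2 <- rnorm(4000, 0, 1); b2 <- rnorm(4000, 5, 1)
  ours2 <- unname(convergence_report(fake_chain_fit(a2, b2), split = FALSE)$bgr)
  cd2 <- unname(coda::gelman.diag(coda::mcmc.list(coda::mcmc(a2), coda::mcmc(b2)),
                                  autoburnin = FALSE)$psrf[1, 1])
  expect_gt(ours2, 1.5)
  expect_gt(cd2, 1.5)
})

test_that("long chains on a well-identified model converge below threshold", {
  arms <- arm_table(c("big", "big"), c(1L, 2L), c(2000L, 1500L), c(20000L, 20000L))
  fit <- qfit(build_network(arms), model_spec("FE"),
              mcmc_config_test(seed = 21, burn_in = 4000L, samples = 4000L))
  expect_true(fit$convergence$converged)
  expect_lt(fit$convergence$max_bgr, 1.05)
  expect_true(all(abs(fit$convergence$autocorr[, "lag50"]) < 0.2))
})

test_that("model comparison rows carry the full reporting schema", {
  sim <- simulate_network(sim_config(n_studies = 8, n_treatments = 4, seed = 3))
  net <- build_network(sim$arms)
  att <- attach_covariate(net, sim$covariates, "age")
  cf <- qfit_cov(att, model_spec("RE"), mcmc_config_test(seed = 2,
                                                         burn_in = 800L, samples = 800L))
  row <- model_comparison_row(cf)
  expect_identical(names(row), c("covariate", "beta_median", "beta_l95", "beta_u95",
                                 "dic_diff", "resid_dev", "n_datapoints",
                                 "sd_median", "sd_l95", "sd_u95"))
  expect_equal(row$n_datapoints, nrow(net$arms))
})
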
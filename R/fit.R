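#' @useDynLib nmareg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Observed baseline-arm empirical logits
#'
#' Per-study empirical logit of the baseline arm, with a 1/2 continuity
#' correction so zero cells stay finite. Used (a) as the fixed centering
#' constant of the latent baseline-risk model and (b) as the covariate of
#' the naive plug-in variant that ignores baseline sampling error -- the
#' variant whose regression-dilution bias the latent model avoids.
#'
#' @param net a \code{treatment_network}.
#' @return named numeric vector, one logit per study.
#' @export
observed_baseline_logits <- function(net) {
  ix <- network_indices(net)
  b <- ix$is_base
  stats::setNames(log((ix$r[b] + 0.5) / (ix$n[b] - ix$r[b] + 0.5)),
                  net$arms$study[b])
}

# fixed centering constant of the latent baseline-risk model
baseline_logit_center <- function(net) {
  mean(observed_baseline_logits(net))
}

# draws from the effect prior truncated to |value| <= bound (log-odds scale)
rtrunc_prior <- function(k, mean, sd, bound = 5) {
  lo <- stats::pnorm(-bound, mean, sd)
  hi <- stats::pnorm(bound, mean, sd)
  stats::qnorm(stats::runif(k, lo, hi), mean, sd)
}

nma_parnames <- function(net) {
  ix <- network_indices(net)
  nb <- which(!ix$is_base)
  c(paste0("d[", seq_len(net$n_treatments)[-1L], "]"),
    "sigma", "beta",
    paste0("mu[", seq_len(net$n_studies), "]"),
    sprintf("delta[%s,%d]", net$arms$study[nb], net$arms$treatment[nb]),
    "b_mean", "b_sd")
}

nma_fit_engine <- function(net, spec, mcmc, x = NULL, hier = FALSE) {
  stopifnot(inherits(net, "treatment_network"), inherits(spec, "model_spec"),
            inherits(mcmc, "mcmc_config"))
  ix <- network_indices(net)
  S <- net$n_studies; K <- net$n_treatments
  mode <- switch(spec$covariate_mode, none = 0L, covariate = 1L, baseline_risk = 2L)
  if (mode == 1L) {
    if (is.null(x)) stop("covariate mode needs a centered covariate vector x", call. = FALSE)
    if (length(x) != S) stop("covariate vector length != number of studies", call. = FALSE)
  } else {
    x <- numeric(S)
  }
  m_center <- if (mode == 2L) baseline_logit_center(net) else 0

  data <- list(study = ix$study - 1L, treat = ix$treat - 1L, base = ix$base - 1L,
               didx = ifelse(is.na(ix$delta_idx), -1L, ix$delta_idx - 1L),
               w = as.integer((ix$treat != 1L) - (ix$base != 1L)),
               r = as.numeric(ix$r), n = as.numeric(ix$n),
               S = S, K = K, mode = mode, re = as.integer(spec$effect == "RE"),
               x = as.numeric(x), m_center = m_center,
               pm = spec$prior_effect_mean, psd = spec$prior_effect_sd,
               sd_up = spec$sd_prior_upper,
               bpm = spec$beta_prior_mean, bpsd = spec$beta_prior_sd,
               hier = as.integer(hier), bsd_up = 5)

  nd <- sum(!ix$is_base)
  set.seed(mcmc$seed)
  chain_seeds <- sample.int(2147483646L, mcmc$chains)
  beta_bound <- if (mode == 1L) 5 / max(1, stats::sd(x)) else 5

  draws <- vector("list", mcmc$chains)
  pdraws <- vector("list", mcmc$chains)
  accept <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(chain_seeds[ch])
    # overdispersed starts from the (truncated) priors
    init <- list(mu = rtrunc_prior(S, spec$prior_effect_mean, spec$prior_effect_sd),
                 d = c(0, rtrunc_prior(K - 1L, spec$prior_effect_mean, spec$prior_effect_sd)),
                 delta = stats::rnorm(nd, 0, 1),
                 sigma = if (spec$effect == "RE") stats::runif(1, 0.02, spec$sd_prior_upper * 0.9) else 0,
                 beta = if (mode != 0L) rtrunc_prior(1, spec$beta_prior_mean, spec$beta_prior_sd, beta_bound) else 0,
                 b_mean = if (hier) stats::rnorm(1, -2, 1) else 0,
                 b_sd = if (hier) stats::runif(1, 0.1, 2) else 0)
    out <- .nma_mcmc_chain(data, init, mcmc$burn_in, mcmc$samples, mcmc$thin)
    colnames(out$draws) <- nma_parnames(net)
    draws[[ch]] <- out$draws
    pdraws[[ch]] <- out$p
    accept[[ch]] <- out$accept
  }

  fit <- structure(list(draws = draws, p = pdraws, spec = spec, mcmc = mcmc,
                        network = net, x = if (mode == 1L) x else NULL,
                        m_center = if (mode == 2L) m_center else NULL,
                        baseline_prior = if (hier) "exchangeable" else "independent",
                        accept = accept, chain_seeds = chain_seeds),
                   class = "nma_fit")
  fit$convergence <- tryCatch(convergence_report(fit), error = function(e) NULL)
  if (!is.null(fit$convergence) && !fit$convergence$converged) {
    warning(sprintf("MCMC convergence not reached: max split-BGR = %.3f (> %.3f); interpret with caution",
                    fit$convergence$max_bgr, mcmc$convergence_threshold),
            call. = FALSE)
  }
  fit
}

#' Fit the (unadjusted) network meta-analysis model
#'
#' Random- or fixed-effect binomial-logit NMA over a connected treatment
#' network, sampled with an adaptive Metropolis-within-Gibbs MCMC.
#' Posterior summaries use the median and equal-tailed 95\% credible
#' interval. Convergence metadata (split Brooks-Gelman-Rubin statistic per
#' monitored parameter) is attached; a fit that fails the threshold is
#' returned with a prominent warning, never silently.
#'
#' @param net a \code{\link{build_network}} result.
#' @param spec a \code{\link{model_spec}} with \code{covariate_mode = "none"}.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @return An object of class \code{nma_fit}: per-chain draw matrices
#'   (\code{d[k]}, \code{sigma}, \code{beta}, \code{mu[i]},
#'   \code{delta[study,t]}), per-chain fitted event-probability draws
#'   \code{p}, the spec/config/network, and a \code{convergence} report.
#' @export
fit_nma <- function(net, spec = model_spec("RE"), mcmc = mcmc_config()) {
  if (spec$covariate_mode != "none") {
    stop("use fit_covariate_model() or fit_baseline_risk_model() for covariate modes", call. = FALSE)
  }
  nma_fit_engine(net, spec, mcmc)
}

#' Fit the common-interaction covariate meta-regression model
#'
#' Adds one common treatment-by-covariate interaction coefficient beta
#' versus the reference treatment to the NMA model. Studies with a missing
#' covariate must already have been dropped by
#' \code{\link{attach_covariate}}, which also supplies the centered
#' covariate. A matched unadjusted fit on the same reduced network is
#' produced alongside, because DIC is only comparable on identical data.
#'
#' @param attachment the list returned by \code{\link{attach_covariate}}.
#' @param spec a \code{\link{model_spec}}; its \code{covariate_mode} is
#'   forced to \code{"covariate"} for the adjusted fit and \code{"none"}
#'   for the comparator.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param fit_unadjusted set FALSE to skip the comparator fit.
#' @return A list of class \code{covariate_fit}: \code{adjusted}
#'   (\code{nma_fit} with beta draws), \code{unadjusted} (matched
#'   comparator or NULL), \code{name}, \code{x}.
#' @export
fit_covariate_model <- function(attachment, spec = model_spec("RE"),
                                mcmc = mcmc_config(), fit_unadjusted = TRUE) {
  stopifnot(is.list(attachment), !is.null(attachment$network), !is.null(attachment$x))
  spec_adj <- spec; spec_adj$covariate_mode <- "covariate"
  spec_un <- spec; spec_un$covariate_mode <- "none"
  adj <- nma_fit_engine(attachment$network, spec_adj, mcmc, x = attachment$x)
  un <- if (fit_unadjusted) nma_fit_engine(attachment$network, spec_un, mcmc) else NULL
  structure(list(adjusted = adj, unadjusted = un,
                 name = attachment$name, x = attachment$x),
            class = "covariate_fit")
}

#' Fit the baseline-risk meta-regression model
#'
#' Uses the trial-specific baseline log-odds mu_i -- a latent quantity
#' estimated by the model itself -- as the study-level covariate, centered
#' at a fixed constant (the mean of the observed baseline-arm empirical
#' logits). Because the covariate is latent, the uncertainty in every
#' trial baseline propagates into the interaction coefficient, avoiding
#' the regression-dilution bias of plugging in observed placebo-arm
#' proportions as if they were known.
#'
#' @param net a \code{\link{build_network}} result.
#' @param spec a \code{\link{model_spec}}; \code{covariate_mode} forced to
#'   \code{"baseline_risk"}.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param fit_unadjusted also fit the matched unadjusted model.
#' @param baseline_prior \code{"independent"} (default): vague independent
#'   normal priors on each trial baseline, matching the unadjusted model;
#'   \code{"exchangeable"}: a hierarchical model
#'   \code{mu_i ~ N(b_mean, b_sd^2)} with vague hyperpriors. The
#'   exchangeable variant is the full errors-in-variables treatment of the
#'   latent covariate and is what demonstrably removes regression-dilution
#'   bias in simulation; the independent variant propagates baseline
#'   uncertainty but shares the small-trial bias of the plug-in covariate.
#' @return A \code{covariate_fit} (see \code{\link{fit_covariate_model}})
#'   with \code{name = "baseline_risk"}.
#' @export
fit_baseline_risk_model <- function(net, spec = model_spec("RE"),
                                    mcmc = mcmc_config(), fit_unadjusted = TRUE,
                                    baseline_prior = c("independent", "exchangeable")) {
  baseline_prior <- match.arg(baseline_prior)
  hier <- baseline_prior == "exchangeable"
  spec_adj <- spec; spec_adj$covariate_mode <- "baseline_risk"
  spec_un <- spec; spec_un$covariate_mode <- "none"
  adj <- nma_fit_engine(net, spec_adj, mcmc, hier = hier)
  un <- if (fit_unadjusted) nma_fit_engine(net, spec_un, mcmc, hier = hier) else NULL
  structure(list(adjusted = adj, unadjusted = un,
                 name = "baseline_risk", x = NULL),
            class = "covariate_fit")
}

# pooled (all chains stacked) draw matrix
pooled_draws <- function(fit) {
  do.call(rbind, fit$draws)
}

pooled_p <- function(fit) {
  do.call(rbind, fit$p)
}

#' Posterior summary of monitored parameters
#'
#' @param fit an \code{nma_fit}.
#' @param pars optional character vector of parameter names.
#' @return data.frame with \code{parameter}, \code{median}, \code{l95},
#'   \code{u95} (equal-tailed 2.5/97.5 percentiles), \code{mean}, \code{bgr}.
#' @export
posterior_summary <- function(fit, pars = NULL) {
  dm <- pooled_draws(fit)
  if (!is.null(pars)) {
    miss <- setdiff(pars, colnames(dm))
    if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
    dm <- dm[, pars, drop = FALSE]
  }
  q <- t(apply(dm, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975), names = FALSE))
  bgr <- if (!is.null(fit$convergence)) fit$convergence$bgr[colnames(dm)] else NA_real_
  data.frame(parameter = colnames(dm), median = q[, 1L], l95 = q[, 2L],
             u95 = q[, 3L], mean = colMeans(dm), bgr = unname(bgr),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.nma_fit <- function(x, ...) {
  cat(sprintf("NMA fit: %s model, covariate mode '%s'\n",
              x$spec$effect, x$spec$covariate_mode))
  cat(sprintf("  %d chains x %d kept iterations (burn-in %d)\n",
              x$mcmc$chains, nrow(x$draws[[1L]]), x$mcmc$burn_in))
  if (!is.null(x$convergence)) {
    cat(sprintf("  max split-BGR = %.3f (%s)\n", x$convergence$max_bgr,
                if (x$convergence$converged) "converged" else "NOT CONVERGED"))
  }
  keep <- c(grep("^d\\[", colnames(x$draws[[1L]]), value = TRUE), "sigma", "beta")
  print(posterior_summary(x, keep), digits = 3)
  invisible(x)
}

#' @export
summary.nma_fit <- function(object, ...) posterior_summary(object)

#' Interaction-coefficient summary of a covariate model
#'
#' @param cfit a \code{covariate_fit}.
#' @return one-row data.frame: \code{covariate}, \code{beta_median},
#'   \code{beta_l95}, \code{beta_u95}.
#' @export
beta_summary <- function(cfit) {
  stopifnot(inherits(cfit, "covariate_fit"))
  s <- posterior_summary(cfit$adjusted, "beta")
  data.frame(covariate = cfit$name, beta_median = s$median,
             beta_l95 = s$l95, beta_u95 = s$u95, stringsAsFactors = FALSE)
}

#' League table of all pairwise relative treatment effects
#'
#' For every unordered treatment pair (a, b) with a < b, summarises the
#' posterior of \code{d_b - d_a} (log odds ratio of b versus a) and its
#' exponential. Antisymmetry and consistency hold draw-by-draw because
#' all contrasts are built from the basic parameters.
#'
#' @param fit an \code{nma_fit} (or the \code{adjusted} element of a
#'   \code{covariate_fit}).
#' @return data.frame with K(K-1)/2 rows: \code{treat_a}, \code{treat_b}
#'   (codes), \code{label_a}, \code{label_b}, \code{log_or_median},
#'   \code{log_or_l95}, \code{log_or_u95}, \code{or_median}, \code{or_l95},
#'   \code{or_u95}.
#' @export
relative_effects <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  K <- fit$network$n_treatments
  dm <- pooled_draws(fit)
  dmat <- cbind(0, dm[, paste0("d[", seq_len(K)[-1L], "]"), drop = FALSE])
  labs <- fit$network$coding$names
  pairs <- utils::combn(K, 2L)
  res <- apply(pairs, 2L, function(pr) {
    diff <- dmat[, pr[2L]] - dmat[, pr[1L]]
    stats::quantile(diff, probs = c(0.5, 0.025, 0.975), names = FALSE)
  })
  data.frame(treat_a = pairs[1L, ], treat_b = pairs[2L, ],
             label_a = labs[pairs[1L, ]], label_b = labs[pairs[2L, ]],
             log_or_median = res[1L, ], log_or_l95 = res[2L, ],
             log_or_u95 = res[3L, ],
             or_median = exp(res[1L, ]), or_l95 = exp(res[2L, ]),
             or_u95 = exp(res[3L, ]), stringsAsFactors = FALSE)
}
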
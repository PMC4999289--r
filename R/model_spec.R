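#' Model specification
#'
#' Describes the binomial-logit network meta-analysis model to fit.
#'
#' Priors are deliberately vague: independent Normal(\code{prior_effect_mean},
#' \code{prior_effect_sd}^2) on every study baseline log-odds and every basic
#' treatment effect, Uniform(0, \code{sd_prior_upper}) on the between-study
#' standard deviation, and Normal(0, \code{beta_prior_sd}^2) on the
#' interaction coefficient. The default prior mean is 0; with an SD of 100
#' a mean of 1 is numerically indistinguishable, and both are supported.
#'
#' @param effect \code{"RE"} (random study-specific effects with common
#'   between-study SD) or \code{"FE"} (fixed effect).
#' @param covariate_mode \code{"none"}, \code{"covariate"} (a named
#'   study-level covariate with one common interaction coefficient versus
#'   the reference treatment), or \code{"baseline_risk"} (the latent trial
#'   baseline log-odds is the covariate).
#' @param prior_effect_mean prior mean for baselines and basic effects
#'   (log-odds scale).
#' @param prior_effect_sd prior SD for baselines and basic effects.
#' @param sd_prior_upper upper bound of the uniform prior on the
#'   between-study SD.
#' @param beta_prior_mean,beta_prior_sd normal prior on the interaction
#'   coefficient.
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(effect = c("RE", "FE"),
                       covariate_mode = c("none", "covariate", "baseline_risk"),
                       prior_effect_mean = 0,
                       prior_effect_sd = 100,
                       sd_prior_upper = 2,
                       beta_prior_mean = 0,
                       beta_prior_sd = 100) {
  effect <- match.arg(effect)
  covariate_mode <- match.arg(covariate_mode)
  stopifnot(prior_effect_sd > 0, sd_prior_upper > 0, beta_prior_sd > 0)
  structure(list(effect = effect, covariate_mode = covariate_mode,
                 prior_effect_mean = prior_effect_mean,
                 prior_effect_sd = prior_effect_sd,
                 sd_prior_upper = sd_prior_upper,
                 beta_prior_mean = beta_prior_mean,
                 beta_prior_sd = beta_prior_sd),
            class = "model_spec")
}

#' MCMC configuration
#'
#' @param chains number of chains (>= 2 so convergence can be checked).
#' @param burn_in adaptation/burn-in iterations discarded per chain.
#' @param samples retained iterations per chain (before thinning).
#' @param thin keep every \code{thin}-th retained iteration.
#' @param seed integer seed; per-chain streams are derived from it.
#' @param convergence_threshold flag the fit as unconverged when any
#'   monitored parameter's split potential scale reduction factor exceeds
#'   this value.
#' @return An object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(chains = 3L, burn_in = 50000L, samples = 50000L,
                        thin = 1L, seed = 1L, convergence_threshold = 1.05) {
  stopifnot(chains >= 1L, burn_in >= 0L, samples >= 1L, thin >= 1L)
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 samples = as.integer(samples), thin = as.integer(thin),
                 seed = as.integer(seed),
                 convergence_threshold = convergence_threshold),
            class = "mcmc_config")
}

#' Short MCMC defaults for tests and simulation studies
#'
#' 3 chains, 2,000 burn-in and 2,000 retained iterations: enough for the
#' posterior medians of this model class to stabilise on small networks,
#' at a fraction of the production 50,000/50,000 run.
#' @param seed integer seed.
#' @param ... overrides passed to \code{\link{mcmc_config}}.
#' @export
mcmc_config_test <- function(seed = 1L, ...) {
  args <- list(chains = 3L, burn_in = 2000L, samples = 2000L, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(mcmc_config, args)
}
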
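#' Parameter state for the binomial-logit NMA model
#'
#' @param mu per-study baseline log-odds, in the network's study order.
#' @param d per-treatment basic effect versus treatment 1; \code{d[1]}
#'   must be exactly 0.
#' @param delta trial-specific log odds ratios, one per non-baseline arm
#'   in the row order of \code{net$arms}; ignored (may be NULL) for FE.
#' @param sigma between-study SD (>= 0); ignored for FE.
#' @param beta interaction coefficient; 0 when \code{covariate_mode = "none"}.
#' @return A list of class \code{parameter_state}.
#' @export
parameter_state <- function(mu, d, delta = NULL, sigma = 0, beta = 0) {
  if (abs(d[1L]) > 0) stop("d[1] must be exactly 0 (reference treatment)", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(mu = as.numeric(mu), d = as.numeric(d),
                 delta = if (is.null(delta)) NULL else as.numeric(delta),
                 sigma = sigma, beta = beta),
            class = "parameter_state")
}

# index helpers shared by the R reference density and the sampler bridge
network_indices <- function(net) {
  arms <- net$arms
  study_i <- match(arms$study, net$studies)         # 1..S per arm
  base_t <- unname(net$study_baseline[arms$study])  # baseline code per arm
  is_base <- arms$treatment == base_t
  # a study contributes one delta per non-baseline arm, in row order
  delta_idx <- rep(NA_integer_, nrow(arms))
  delta_idx[!is_base] <- seq_len(sum(!is_base))
  list(study = study_i, treat = arms$treatment, base = base_t,
       is_base = is_base, delta_idx = delta_idx,
       r = arms$r, n = arms$n)
}

#' Per-arm linear predictor of the meta-regression model
#'
#' Computes \code{logit(p_ik) = mu_i + delta_ik + beta * x_i *
#' (I(t_ik != 1) - I(t_base != 1))}: the common interaction enters only
#' for effects expressed against treatment 1 (the reference), so in a
#' trial whose arms are all non-reference every within-trial contrast is
#' free of the covariate -- the interaction terms cancel.
#'
#' @param state a \code{\link{parameter_state}}.
#' @param net a \code{treatment_network}.
#' @param x centered covariate vector, one value per study in the
#'   network's study order (NULL for no covariate; for the baseline-risk
#'   model pass \code{state$mu - m_center}).
#' @param spec a \code{\link{model_spec}} (used for FE/RE delta handling).
#' @return numeric vector of per-arm logits, in \code{net$arms} row order.
#' @export
regression_linear_predictor <- function(state, net, x = NULL,
                                        spec = model_spec("RE")) {
  ix <- network_indices(net)
  S <- net$n_studies
  if (length(state$mu) != S) stop("mu has wrong length", call. = FALSE)
  if (!is.null(x) && length(x) != S) stop("covariate vector has wrong length", call. = FALSE)
  eta <- state$mu[ix$study]
  if (spec$effect == "FE" || is.null(state$delta)) {
    contrast <- state$d[ix$treat] - state$d[ix$base]
    eta <- eta + ifelse(ix$is_base, 0, contrast)
  } else {
    if (length(state$delta) != sum(!ix$is_base)) stop("delta has wrong length", call. = FALSE)
    eta[!ix$is_base] <- eta[!ix$is_base] + state$delta[ix$delta_idx[!ix$is_base]]
  }
  if (!is.null(x) && state$beta != 0) {
    w <- (ix$treat != 1L) - (ix$base != 1L)   # in {-?,0,1}; baseline arm always 0
    eta <- eta + state$beta * x[ix$study] * w
  }
  eta
}

#' Log joint density of the NMA model
#'
#' Log prior plus log likelihood: \code{r_ik ~ Binomial(n_ik, p_ik)} with
#' \code{logit(p_ik)} from \code{\link{regression_linear_predictor}};
#' FE sets \code{delta_ik = d[t_ik] - d[t_base]} deterministically; RE puts
#' a multivariate normal on each study's delta vector with per-arm variance
#' \code{sigma^2} and pairwise correlation 1/2 (the standard multi-arm
#' construction). Zero-event arms contribute \code{n * log(1 - p)} with no
#' continuity correction and stay finite for \code{p < 1}.
#'
#' This pure-R density is the package's reference implementation; the
#' compiled sampler maintains its own conditionals and is validated
#' against this function in the test suite.
#'
#' @inheritParams regression_linear_predictor
#' @param spec a \code{\link{model_spec}}.
#' @param x centered covariate (see \code{regression_linear_predictor});
#'   for \code{covariate_mode = "baseline_risk"} supply \code{m_center}
#'   instead and \code{x} is taken as \code{state$mu - m_center}.
#' @param m_center fixed centering constant for the baseline-risk model.
#' @return log joint density (a real number; \code{-Inf} allowed, NaN not).
#' @export
log_joint <- function(state, net, spec, x = NULL, m_center = NULL) {
  if (any(!is.finite(state$mu)) || any(!is.finite(state$d)) ||
      (!is.null(state$delta) && any(!is.finite(state$delta))) ||
      !is.finite(state$sigma) || !is.finite(state$beta)) {
    stop("non-finite parameter state", call. = FALSE)
  }
  ix <- network_indices(net)
  if (spec$covariate_mode == "baseline_risk") {
    if (is.null(m_center)) stop("baseline_risk mode needs m_center", call. = FALSE)
    x <- state$mu - m_center
  }
  eta <- regression_linear_predictor(state, net, x, spec)
  p <- stats::plogis(eta)
  ll <- sum(stats::dbinom(ix$r, ix$n, p, log = TRUE))

  lp <- sum(stats::dnorm(state$mu, spec$prior_effect_mean, spec$prior_effect_sd, log = TRUE)) +
    sum(stats::dnorm(state$d[-1L], spec$prior_effect_mean, spec$prior_effect_sd, log = TRUE))
  if (spec$covariate_mode != "none") {
    lp <- lp + stats::dnorm(state$beta, spec$beta_prior_mean, spec$beta_prior_sd, log = TRUE)
  }
  if (spec$effect == "RE") {
    if (state$sigma <= 0 || state$sigma >= spec$sd_prior_upper) return(-Inf)
    lp <- lp + stats::dunif(state$sigma, 0, spec$sd_prior_upper, log = TRUE)
    # multivariate normal over each study's deltas: Var sigma^2, Cov sigma^2/2
    for (s in seq_len(net$n_studies)) {
      rows <- which(ix$study == s & !ix$is_base)
      m <- length(rows)
      mean_s <- state$d[ix$treat[rows]] - state$d[ix$base[rows]]
      e <- state$delta[ix$delta_idx[rows]] - mean_s
      s2 <- state$sigma^2
      qf <- (2 / s2) * (sum(e^2) - sum(e)^2 / (m + 1))
      logdet <- m * log(s2 / 2) + log(m + 1)
      lp <- lp - 0.5 * (m * log(2 * pi) + logdet + qf)
    }
  }
  ll + lp
}
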
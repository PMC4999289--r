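#' Posterior residual deviance
#'
#' Per data point (arm) and per posterior draw,
#' \code{dev = 2 * (r * log(r / rhat) + (n - r) * log((n - r) / (n - rhat)))}
#' with \code{rhat = n * p} and the \code{0 * log(0) = 0} convention, so
#' zero-event arms need no continuity correction. The posterior mean per
#' point is \code{dev_i}; their sum is \code{Dbar}. A well-fitting model
#' has \code{Dbar} close to the number of data points. If a draw puts
#' \code{rhat} at 0 or \code{n} while the observed \code{r} disagrees the
#' infinite contribution is propagated, not masked.
#'
#' @param fit an \code{nma_fit}.
#' @return list with \code{dev_i} (named per-point posterior means) and
#'   \code{Dbar}.
#' @export
residual_deviance <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  ix <- network_indices(fit$network)
  p <- pooled_p(fit)
  dev_i <- vapply(seq_along(ix$r), function(a) {
    mean(deviance_point(ix$r[a], ix$n[a], p[, a]))
  }, numeric(1))
  names(dev_i) <- point_ids(fit$network)
  list(dev_i = dev_i, Dbar = sum(dev_i))
}

# deviance of one binomial observation against fitted probability p
# (vectorised over p); saturated-model reference
deviance_point <- function(r, n, p) {
  rhat <- n * p
  t1 <- if (r == 0) 0 else r * log(r / rhat)
  t2 <- if (r == n) 0 else (n - r) * log((n - r) / (n - rhat))
  2 * (t1 + t2)
}

point_ids <- function(net) {
  sprintf("%s:%d", net$arms$study, net$arms$treatment)
}

#' Deviance information criterion and leverage decomposition
#'
#' \code{Dhat} is the deviance at the plug-in fit (posterior mean of each
#' arm's event probability); \code{pD = Dbar - Dhat} is the effective
#' number of parameters and \code{DIC = Dbar + pD}. The per-point leverage
#' \code{pD_i = dev_i - dev_i(phat)} and the signed root deviance
#' \code{w_i = sign(r - rhat) * sqrt(dev_i)} are the coordinates of the
#' leverage plot.
#'
#' @param fit an \code{nma_fit}.
#' @return An object of class \code{fit_diagnostics}: \code{dev_i},
#'   \code{Dbar}, \code{Dhat}, \code{pD}, \code{pD_i}, \code{DIC},
#'   \code{w_i}, \code{n_points}, \code{bgr}.
#' @export
dic <- function(fit) {
  rd <- residual_deviance(fit)
  ix <- network_indices(fit$network)
  pbar <- colMeans(pooled_p(fit))
  dev_hat_i <- vapply(seq_along(ix$r), function(a) {
    deviance_point(ix$r[a], ix$n[a], pbar[a])
  }, numeric(1))
  pD_i <- rd$dev_i - dev_hat_i
  w_i <- sign(ix$r - ix$n * pbar) * sqrt(rd$dev_i)
  Dhat <- sum(dev_hat_i)
  pD <- rd$Dbar - Dhat
  structure(list(dev_i = rd$dev_i, Dbar = rd$Dbar, Dhat = Dhat,
                 pD = pD, pD_i = stats::setNames(pD_i, names(rd$dev_i)),
                 DIC = rd$Dbar + pD,
                 w_i = stats::setNames(w_i, names(rd$dev_i)),
                 n_points = length(rd$dev_i),
                 study = fit$network$arms$study,
                 treatment = fit$network$arms$treatment,
                 bgr = if (!is.null(fit$convergence)) fit$convergence$bgr else NULL),
            class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("Residual deviance %.2f against %d data points; pD = %.2f; DIC = %.2f\n",
              x$Dbar, x$n_points, x$pD, x$DIC))
  invisible(x)
}

#' DIC difference between an adjusted and an unadjusted model
#'
#' Only meaningful on identical data: both fits must have been run on the
#' same (possibly covariate-reduced) network, else an error is raised.
#'
#' @param adjusted,unadjusted \code{nma_fit} objects, or a single
#'   \code{covariate_fit} as the first argument.
#' @return \code{DIC(adjusted) - DIC(unadjusted)}; negative favours the
#'   adjusted model.
#' @export
dic_difference <- function(adjusted, unadjusted = NULL) {
  if (inherits(adjusted, "covariate_fit")) {
    if (is.null(adjusted$unadjusted)) stop("covariate_fit has no matched unadjusted fit", call. = FALSE)
    unadjusted <- adjusted$unadjusted
    adjusted <- adjusted$adjusted
  }
  a <- adjusted$network$arms; u <- unadjusted$network$arms
  if (!identical(a[c("study", "treatment", "r", "n")],
                 u[c("study", "treatment", "r", "n")])) {
    stop("DIC comparison requires identical data in both fits", call. = FALSE)
  }
  dic(adjusted)$DIC - dic(unadjusted)$DIC
}

#' Leverage-plot coordinates and influence flags
#'
#' Each data point is placed at (w_i, pD_i): signed root residual deviance
#' against leverage. Points above the parabola \code{c = x^2 + y} with
#' \code{c = threshold} (default 3) contribute heavily to the DIC and are
#' flagged for investigation.
#'
#' @param diag a \code{\link{dic}} result (or an \code{nma_fit}, for which
#'   diagnostics are computed).
#' @param threshold parabola constant c; default 3.
#' @return data.frame: \code{point_id}, \code{study}, \code{treatment},
#'   \code{dev_i}, \code{pD_i}, \code{w_i}, \code{contribution}
#'   (\code{w_i^2 + pD_i}), \code{flagged}.
#' @export
leverage_coordinates <- function(diag, threshold = 3) {
  if (inherits(diag, "nma_fit")) diag <- dic(diag)
  stopifnot(inherits(diag, "fit_diagnostics"))
  contribution <- diag$w_i^2 + diag$pD_i
  data.frame(point_id = names(diag$dev_i), study = diag$study,
             treatment = diag$treatment,
             dev_i = unname(diag$dev_i), pD_i = unname(diag$pD_i),
             w_i = unname(diag$w_i), contribution = unname(contribution),
             flagged = unname(contribution > threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

# population-variance BGR: V = pooled (1/N) variance of all draws,
# W = mean per-chain (1/n) variance; R = sqrt(V / W) >= 1, and exactly 1
# when between-chain variance is zero.
bgr_scalar <- function(chains) {
  n <- length(chains[[1L]])
  W <- mean(vapply(chains, function(x) mean((x - mean(x))^2), numeric(1)))
  all_x <- unlist(chains, use.names = FALSE)
  V <- mean((all_x - mean(all_x))^2)
  if (W == 0 && V == 0) return(1)
  sqrt(V / W)
}

#' Convergence report: Brooks-Gelman-Rubin statistics and autocorrelation
#'
#' Computes a potential scale reduction factor per monitored parameter as
#' the ratio of pooled to mean within-chain variance (on split half-chains
#' by default), plus lagged autocorrelations averaged over chains. The fit
#' is flagged unconverged when any BGR exceeds the threshold.
#'
#' @param fit an \code{nma_fit} with at least 2 chains.
#' @param split split each chain in half before comparing (default TRUE);
#'   with \code{split = FALSE}, chains with zero between-chain variance
#'   give BGR = 1 exactly.
#' @param lags lags at which to report autocorrelation.
#' @param threshold convergence threshold (default from the fit's
#'   \code{mcmc_config}).
#' @return list: \code{bgr} (named vector), \code{autocorr} (parameters x
#'   lags matrix), \code{max_bgr}, \code{converged}, \code{threshold}.
#' @export
convergence_report <- function(fit, split = TRUE, lags = c(1L, 5L, 10L, 50L),
                               threshold = NULL) {
  stopifnot(inherits(fit, "nma_fit"))
  if (length(fit$draws) < 2L) stop("convergence checking needs >= 2 chains", call. = FALSE)
  if (is.null(threshold)) threshold <- fit$mcmc$convergence_threshold
  pars <- colnames(fit$draws[[1L]])
  n <- nrow(fit$draws[[1L]])
  lags <- lags[lags < n]
  bgr <- vapply(pars, function(pn) {
    ch <- lapply(fit$draws, function(m) m[, pn])
    if (split) {
      h <- n %/% 2L
      ch <- unlist(lapply(ch, function(x) list(x[seq_len(h)], x[(h + 1L):(2L * h)])),
                   recursive = FALSE)
    }
    bgr_scalar(ch)
  }, numeric(1))
  ac <- t(vapply(pars, function(pn) {
    per_chain <- vapply(fit$draws, function(m) {
      x <- m[, pn]
      if (stats::sd(x) == 0) return(rep(0, length(lags)))
      a <- stats::acf(x, lag.max = max(lags), plot = FALSE, demean = TRUE)
      as.numeric(a$acf[lags + 1L])
    }, numeric(length(lags)))
    rowMeans(matrix(per_chain, nrow = length(lags)))
  }, numeric(length(lags))))
  colnames(ac) <- paste0("lag", lags)
  max_bgr <- max(bgr[is.finite(bgr)])
  list(bgr = bgr, autocorr = ac, max_bgr = max_bgr,
       converged = max_bgr <= threshold, threshold = threshold)
}

#' Table-style model-comparison row for a covariate model
#'
#' One row per covariate model: interaction-coefficient summary, DIC
#' difference versus the matched unadjusted model on the same reduced
#' data, residual deviance and data-point count of the adjusted model,
#' and the between-study SD summary.
#'
#' @param cfit a \code{covariate_fit}.
#' @return one-row data.frame with columns \code{covariate},
#'   \code{beta_median}, \code{beta_l95}, \code{beta_u95}, \code{dic_diff},
#'   \code{resid_dev}, \code{n_datapoints}, \code{sd_median},
#'   \code{sd_l95}, \code{sd_u95}.
#' @export
model_comparison_row <- function(cfit) {
  stopifnot(inherits(cfit, "covariate_fit"))
  b <- beta_summary(cfit)
  dg <- dic(cfit$adjusted)
  sd_s <- posterior_summary(cfit$adjusted, "sigma")
  data.frame(covariate = cfit$name,
             beta_median = b$beta_median, beta_l95 = b$beta_l95,
             beta_u95 = b$beta_u95,
             dic_diff = if (!is.null(cfit$unadjusted)) dic_difference(cfit) else NA_real_,
             resid_dev = dg$Dbar, n_datapoints = dg$n_points,
             sd_median = sd_s$median, sd_l95 = sd_s$l95, sd_u95 = sd_s$u95,
             stringsAsFactors = FALSE)
}
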
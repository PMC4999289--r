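#' Configuration for the synthetic-network generator
#'
#' Describes a stated world: an anchor-centred ("star-like") evidence
#' network in which every study carries the anchor treatment, loops arise
#' only from multi-arm studies, binomial event counts follow the
#' binomial-logit NMA model with trial baselines, random trial effects
#' share a common between-study SD (multi-arm correlation 1/2), and an
#' optional common treatment-by-covariate interaction acts versus the
#' reference. Zero-event arms arise naturally from low event
#' probabilities in occasional small studies, never by post-hoc zeroing.
#'
#' @param n_studies number of studies.
#' @param n_treatments number of treatments K (reference = code 1).
#' @param anchor_treatment code present in every study (default 2).
#' @param arms_per_study named probabilities for 2- and 3-arm studies.
#' @param prop_placebo fraction of studies that carry a reference arm.
#' @param baseline_mu c(mean, sd) of the study baseline log-odds.
#' @param true_d length-K vector of basic effects (true_d[1] = 0).
#' @param true_sigma between-study SD.
#' @param true_beta common interaction coefficient.
#' @param beta_on \code{"covariate"} (a generated study covariate) or
#'   \code{"baseline"} (the study's own baseline log-odds, centered).
#' @param beta_covariate which generated covariate carries the
#'   interaction (when \code{beta_on = "covariate"}).
#' @param covariate_ranges named list of c(min, max) uniform ranges for
#'   the four study-level covariates.
#' @param arm_n c(min, max) range of per-arm sample sizes (log-uniform).
#' @param zero_cell_rate fraction of studies drawn as small studies of
#'   size \code{small_arm_n}, where zero event counts become likely.
#' @param small_arm_n arm size of the occasional small study.
#' @param seed integer seed recorded in the truth record.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_studies = 12L, n_treatments = 6L,
                       anchor_treatment = 2L,
                       arms_per_study = c(`2` = 0.8, `3` = 0.2),
                       prop_placebo = 0.4,
                       baseline_mu = c(-2.3, 0.38),
                       true_d = NULL,
                       true_sigma = 0.26,
                       true_beta = 0,
                       beta_on = c("covariate", "baseline"),
                       beta_covariate = "follow_up",
                       covariate_ranges = list(prev_stroke_tia = c(0, 55),
                                               male = c(46, 100),
                                               age = c(66, 75),
                                               follow_up = c(11, 42)),
                       arm_n = c(150L, 1500L),
                       zero_cell_rate = 0.1,
                       small_arm_n = 60L,
                       seed = 1L) {
  beta_on <- match.arg(beta_on)
  if (is.null(true_d)) {
    true_d <- c(0, -0.9, seq(-1.1, -0.2, length.out = n_treatments - 2L))
  }
  stopifnot(length(true_d) == n_treatments, true_d[1L] == 0,
            n_treatments >= 3L, anchor_treatment >= 2L,
            anchor_treatment <= n_treatments,
            true_sigma >= 0, zero_cell_rate >= 0, zero_cell_rate <= 1)
  if (n_studies < n_treatments - 2L) {
    stop("unconnectable design: need at least K - 2 studies to reach every non-anchor treatment",
         call. = FALSE)
  }
  structure(list(n_studies = as.integer(n_studies),
                 n_treatments = as.integer(n_treatments),
                 anchor_treatment = as.integer(anchor_treatment),
                 arms_per_study = arms_per_study, prop_placebo = prop_placebo,
                 baseline_mu = baseline_mu, true_d = true_d,
                 true_sigma = true_sigma, true_beta = true_beta,
                 beta_on = beta_on, beta_covariate = beta_covariate,
                 covariate_ranges = covariate_ranges,
                 arm_n = as.integer(arm_n), zero_cell_rate = zero_cell_rate,
                 small_arm_n = as.integer(small_arm_n),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an arm-level dataset with known truth
#'
#' Draws per-study baselines, covariates and trial-specific effects from
#' the stated generative model, then binomial event counts per arm. Every
#' study contains the anchor treatment, so the network is connected by
#' construction; non-anchor treatments are assigned round-robin so all K
#' treatments appear. The same seed gives bit-identical output.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{arms} (an \code{\link{arm_table}}),
#'   \code{covariates} (a \code{covariate_table}), and \code{truth}
#'   (every generated latent: mu, delta, d, sigma, beta, per-arm p,
#'   the centered interaction covariate, and the seed).
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  S <- cfg$n_studies; K <- cfg$n_treatments; anchor <- cfg$anchor_treatment

  others <- setdiff(seq_len(K), c(1L, anchor))
  has_placebo <- stats::runif(S) < cfg$prop_placebo
  n_arms <- 2L + stats::rbinom(S, 1L, unname(cfg$arms_per_study["3"]))
  # free slots for non-anchor, non-placebo treatments; upgrade studies to
  # 3 arms where needed so every treatment gets at least one slot
  slots <- pmax(n_arms - 1L - has_placebo, 0L)
  i <- 1L
  while (sum(slots) < length(others) && i <= S) {
    if (n_arms[i] == 2L) { n_arms[i] <- 3L; slots[i] <- slots[i] + 1L }
    i <- i + 1L
  }
  if (sum(slots) < length(others)) {
    stop("unconnectable design: could not place every treatment; increase n_studies",
         call. = FALSE)
  }
  assign_pool <- rep(others, length.out = sum(slots))
  study_treats <- vector("list", S)
  oi <- 0L
  for (i in seq_len(S)) {
    ts <- anchor
    if (has_placebo[i]) ts <- c(1L, ts)
    for (j in seq_len(slots[i])) {
      # next pool entry not already in this study (pool cycles all others)
      step <- 0L
      repeat {
        cand <- assign_pool[(oi + step) %% length(assign_pool) + 1L]
        if (!cand %in% ts) break
        step <- step + 1L
        if (step > length(assign_pool)) { cand <- NA_integer_; break }
      }
      oi <- oi + step + 1L
      if (!is.na(cand)) ts <- c(ts, cand)
    }
    study_treats[[i]] <- sort(unique(ts))
  }
  if (length(setdiff(seq_len(K), unique(unlist(study_treats))))) {
    stop("unconnectable design: could not place every treatment; increase n_studies",
         call. = FALSE)
  }

  # covariates (uniform over the stated ranges)
  rg <- cfg$covariate_ranges
  cov <- data.frame(study = sprintf("study_%02d", seq_len(S)),
                    prev_stroke_tia_pct = stats::runif(S, rg$prev_stroke_tia[1], rg$prev_stroke_tia[2]),
                    male_pct = stats::runif(S, rg$male[1], rg$male[2]),
                    mean_age_yr = stats::runif(S, rg$age[1], rg$age[2]),
                    follow_up_months = stats::runif(S, rg$follow_up[1], rg$follow_up[2]),
                    stringsAsFactors = FALSE)

  mu <- stats::rnorm(S, cfg$baseline_mu[1], cfg$baseline_mu[2])
  if (cfg$beta_on == "covariate") {
    info <- covariate_column(cfg$beta_covariate)
    raw <- cov[[info$col]] * info$scale
    x <- raw - mean(raw)
  } else {
    x <- mu - cfg$baseline_mu[1]
  }

  small <- stats::runif(S) < cfg$zero_cell_rate
  n_i <- ifelse(small, cfg$small_arm_n,
                round(exp(stats::runif(S, log(cfg$arm_n[1]), log(cfg$arm_n[2])))))

  rows <- list(); truth_delta <- vector("list", S); p_list <- list()
  for (i in seq_len(S)) {
    ts <- study_treats[[i]]
    b <- min(ts)
    nb <- setdiff(ts, b)
    mean_d <- cfg$true_d[nb] - cfg$true_d[b]
    u0 <- stats::rnorm(1)
    delta <- mean_d + cfg$true_sigma * (u0 + stats::rnorm(length(nb))) / sqrt(2)
    names(delta) <- nb
    truth_delta[[i]] <- delta
    eta <- c(mu[i], mu[i] + delta)
    names(eta) <- c(b, nb)
    w <- (as.integer(names(eta)) != 1L) - (b != 1L)
    eta <- eta + cfg$true_beta * x[i] * w
    p <- stats::plogis(eta)
    r <- stats::rbinom(length(p), n_i[i], p)
    rows[[i]] <- data.frame(study = cov$study[i],
                            treatment = as.integer(names(eta)),
                            r = r, n = n_i[i], stringsAsFactors = FALSE)
    p_list[[i]] <- p
  }
  arms_df <- do.call(rbind, rows)
  arms <- arm_table(arms_df$study, arms_df$treatment, arms_df$r, arms_df$n)
  truth <- list(mu = stats::setNames(mu, cov$study),
                delta = stats::setNames(truth_delta, cov$study),
                d = cfg$true_d, sigma = cfg$true_sigma, beta = cfg$true_beta,
                beta_on = cfg$beta_on, beta_covariate = cfg$beta_covariate,
                x = stats::setNames(x, cov$study),
                p = stats::setNames(p_list, cov$study),
                seed = cfg$seed)
  list(arms = arms, covariates = covariate_table(cov), truth = truth)
}

#' Preset emulating the published ischaemic-stroke evidence network
#'
#' 19 studies over 15 treatments, every study anchored on an
#' adjusted-dose-VKA analogue, covariate spans matching the reported
#' ranges (follow-up 11-42 months, males 46-100\%, previous stroke/TIA
#' 0-55\%, age 66-75 years), baseline log-odds centred near odds 0.10
#' with spread covering the reported placebo-odds span 0.05-0.22,
#' between-study SD 0.26, and a small rate of genuinely small studies so
#' zero-event arms occur (as in the real network). All treatment labels
#' are synthetic analogues; this is a stand-in world with known truth,
#' not the published dataset.
#'
#' @param seed integer seed.
#' @param ... overrides forwarded to \code{\link{sim_config}}.
#' @return a \code{\link{sim_config}}.
#' @export
paper_like_preset <- function(seed = 1L, ...) {
  args <- list(
    n_studies = 19L, n_treatments = 15L, anchor_treatment = 2L,
    arms_per_study = c(`2` = 0.8, `3` = 0.2), prop_placebo = 0.4,
    baseline_mu = c(-2.3, 0.38),
    true_d = c(0, -0.9, -1.0, -1.1, -0.95, -1.05,
               -0.3, -0.4, -0.5, -0.2, -0.6, -0.45, -0.35, -0.55, -0.25),
    true_sigma = 0.26, true_beta = 0,
    arm_n = c(150L, 1500L), zero_cell_rate = 0.15, small_arm_n = 60L,
    seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

#' Treatment labels for the preset network
#'
#' Synthetic analogues of the comparators in an anticoagulant evidence
#' network (reference first).
#' @param k number of treatments.
#' @return a \code{\link{treatment_coding}}.
#' @export
preset_coding <- function(k = 15L) {
  labs <- c("placebo", "adjusted_dose_VKA", "apixaban_like", "dabigatran_like",
            "rivaroxaban_like", "edoxaban_like", "aspirin_like",
            "aspirin_clopidogrel_like", "fixed_low_dose_VKA_like",
            "fld_VKA_aspirin_like", "indobufen_like", "idraparinux_like",
            "triflusal_like", "ximelagatran_like", "alt_dose_VKA_like")
  if (k > length(labs)) labs <- c(labs, sprintf("treatment_%d", (length(labs) + 1L):k))
  treatment_coding(labs[seq_len(k)])
}
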
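#' Build a treatment network from arm-level data
#'
#' Assembles the evidence network: nodes are treatments, edges are
#' within-study comparisons. Validates that every study has at least two
#' arms and that the comparison graph is connected. The per-study baseline
#' arm is the arm with the lowest treatment code present in that study
#' (the standard arm-ordering convention for network meta-analysis).
#'
#' @param arms an \code{\link{arm_table}}. The \code{treatment} column may
#'   be integer codes (used as-is) or labels matched against \code{coding}.
#' @param coding optional \code{\link{treatment_coding}}. When supplied,
#'   character treatments in \code{arms} are translated; when absent,
#'   codes must already be contiguous integers starting at 1.
#' @return An object of class \code{treatment_network} with elements
#'   \code{arms} (arm table sorted by study then code), \code{coding},
#'   \code{study_baseline} (named integer vector, study -> baseline code),
#'   \code{studies}, \code{n_studies}, \code{n_treatments}.
#' @export
build_network <- function(arms, coding = NULL) {
  arms <- validate_arm_table(as.data.frame(arms))
  if (!is.null(coding)) {
    if (!inherits(coding, "treatment_coding")) stop("coding must be a treatment_coding", call. = FALSE)
    k <- length(coding$names)
  } else {
    codes <- sort(unique(arms$treatment))
    if (!identical(codes, seq_along(codes))) {
      stop("treatment codes must be contiguous 1..K (or supply a coding)", call. = FALSE)
    }
    k <- length(codes)
    coding <- treatment_coding(paste0("treatment_", seq_len(k)))
  }
  if (any(arms$treatment > k)) {
    stop("arm table uses treatment codes beyond the coding (K = ", k, ")", call. = FALSE)
  }
  # canonical order: study label, then treatment code
  arms <- arms[order(arms$study, arms$treatment), , drop = FALSE]
  rownames(arms) <- NULL
  class(arms) <- c("arm_table", "data.frame")

  studies <- unique(arms$study)
  n_arms <- table(factor(arms$study, levels = studies))
  if (any(n_arms < 2L)) {
    stop("single-arm study: ", paste(studies[n_arms < 2L], collapse = ", "), call. = FALSE)
  }
  comp <- network_components(arms, k)
  if (length(unique(comp[!is.na(comp)])) > 1L) {
    groups <- split(coding$names[which(!is.na(comp))], comp[!is.na(comp)])
    stop("evidence network is disconnected; components: ",
         paste(vapply(groups, function(g) paste0("{", paste(g, collapse = ", "), "}"), ""),
               collapse = " "), call. = FALSE)
  }
  base <- vapply(studies, function(s) min(arms$treatment[arms$study == s]), integer(1))
  names(base) <- studies
  structure(list(arms = arms, coding = coding, study_baseline = base,
                 studies = studies, n_studies = length(studies),
                 n_treatments = length(unique(arms$treatment))),
            class = "treatment_network")
}

# connected-component labels over treatments present in the data
network_components <- function(arms, k) {
  comp <- rep(NA_integer_, k)
  present <- sort(unique(arms$treatment))
  lab <- 0L
  adj <- vector("list", k)
  for (s in unique(arms$study)) {
    ts <- arms$treatment[arms$study == s]
    for (t in ts) adj[[t]] <- unique(c(adj[[t]], setdiff(ts, t)))
  }
  for (t0 in present) {
    if (!is.na(comp[t0])) next
    lab <- lab + 1L
    queue <- t0
    while (length(queue)) {
      t <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[t])) next
      comp[t] <- lab
      queue <- c(queue, adj[[t]][is.na(comp[adj[[t]]])])
    }
  }
  comp
}

#' Number of unordered pairwise comparisons
#'
#' For a connected K-treatment network the league table has
#' \code{K * (K - 1) / 2} unordered treatment pairs.
#'
#' @param net a \code{\link{build_network}} result, or an integer K.
#' @return integer pair count.
#' @export
n_pairwise <- function(net) {
  k <- if (inherits(net, "treatment_network")) net$n_treatments else as.integer(net)
  (k * (k - 1L)) %/% 2L
}

#' @export
print.treatment_network <- function(x, ...) {
  multi <- sum(table(x$arms$study) > 2L)
  cat(sprintf("Treatment network: %d studies, %d treatments, %d arms (%d multi-arm)\n",
              x$n_studies, x$n_treatments, nrow(x$arms), multi))
  cat(sprintf("Reference treatment: '%s' (code 1); %d pairwise comparisons\n",
              x$coding$names[1L], n_pairwise(x)))
  invisible(x)
}

#' Read a study-level covariate CSV
#'
#' Columns \code{study,prev_stroke_tia_pct,male_pct,mean_age_yr,follow_up_months};
#' empty cells are missing values. Proportions are stored as percent (0-100),
#' age in years, follow-up in months.
#'
#' @param path path to the CSV file.
#' @return A \code{data.frame} of class \code{covariate_table}.
#' @export
read_covariate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  covariate_table(df)
}

#' Validate a study-level covariate table
#'
#' @param df data.frame with the covariate CSV schema.
#' @return the validated \code{covariate_table}.
#' @export
covariate_table <- function(df) {
  req <- c("study", "prev_stroke_tia_pct", "male_pct", "mean_age_yr", "follow_up_months")
  if (!all(req %in% names(df))) {
    stop("covariate table missing column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  chk <- function(col, lo, hi, what) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad)) {
      stop(sprintf("study '%s': %s = %g outside [%g, %g]",
                   df$study[bad[1L]], what, v[bad[1L]], lo, hi), call. = FALSE)
    }
  }
  chk("prev_stroke_tia_pct", 0, 100, "previous stroke/TIA percent")
  chk("male_pct", 0, 100, "male percent")
  chk("mean_age_yr", 1e-9, 120, "mean age (years)")
  chk("follow_up_months", 1e-9, Inf, "follow-up (months)")
  if (anyDuplicated(df$study)) stop("duplicate study in covariate table", call. = FALSE)
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' Covariate name to column and default regression scale
#'
#' Proportions enter the regression as percent by default (scale 1);
#' follow-up is recorded in months but regressed per year (scale 1/12),
#' since descriptives use months while effect sizes per month would be
#' vanishingly small.
#' @keywords internal
covariate_column <- function(name) {
  switch(name,
         prev_stroke_tia = list(col = "prev_stroke_tia_pct", scale = 1),
         male            = list(col = "male_pct",            scale = 1),
         age             = list(col = "mean_age_yr",         scale = 1),
         follow_up       = list(col = "follow_up_months",    scale = 1 / 12),
         stop("unknown covariate '", name,
              "'; use one of prev_stroke_tia, male, age, follow_up", call. = FALSE))
}

#' Attach a study-level covariate to a network
#'
#' Drops studies with a missing value for the chosen covariate, re-validates
#' the reduced network, and returns the covariate centered at the mean of
#' the retained studies (after applying the regression scale). The reduced
#' network is what the matching unadjusted comparator model must be fitted
#' on for a like-for-like DIC comparison.
#'
#' @param net a \code{treatment_network}.
#' @param cov a \code{covariate_table}.
#' @param name one of \code{"prev_stroke_tia"}, \code{"male"}, \code{"age"},
#'   \code{"follow_up"}.
#' @param scale multiplier applied to the raw covariate before centering;
#'   default is the per-covariate convention of \code{covariate_column}.
#' @return A list with \code{network} (reduced, re-validated),
#'   \code{x} (named centered covariate vector, one per retained study),
#'   \code{name}, \code{center} (mean on the scaled axis), \code{scale},
#'   and \code{dropped} (labels of removed studies).
#' @export
attach_covariate <- function(net, cov, name, scale = NULL) {
  stopifnot(inherits(net, "treatment_network"))
  cov <- covariate_table(as.data.frame(cov))
  info <- covariate_column(name)
  if (is.null(scale)) scale <- info$scale
  idx <- match(net$studies, cov$study)
  if (anyNA(idx)) {
    stop("covariate table missing studies: ",
         paste(net$studies[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  v <- cov[[info$col]][idx] * scale
  keep <- !is.na(v)
  dropped <- net$studies[!keep]
  arms2 <- net$arms[net$arms$study %in% net$studies[keep], , drop = FALSE]
  if (nrow(arms2) == 0L) stop("all studies missing covariate '", name, "'", call. = FALSE)
  net2 <- tryCatch(build_network(arms2, net$coding),
                   error = function(e) stop("covariate reduction: ", conditionMessage(e), call. = FALSE))
  x <- v[keep] - mean(v[keep])
  names(x) <- net$studies[keep]
  x <- x[net2$studies]  # align with reduced network's study order
  list(network = net2, x = x, name = name, center = mean(v[keep]),
       scale = scale, dropped = dropped)
}
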
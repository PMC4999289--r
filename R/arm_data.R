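#' Arm-level binary outcome tables
#'
#' An arm table holds one row per trial arm: the study label, the integer
#' treatment code, the event count \code{r} and the arm sample size \code{n}.
#' It is the unit of likelihood contribution for the binomial-logit network
#' meta-analysis model. Zero-event arms are legitimate data and are retained
#' without any continuity correction.
#'
#' @param study character or factor vector of study labels.
#' @param treatment integer vector of positive treatment codes (reference
#'   treatment, conventionally placebo, is code 1).
#' @param r integer vector of event counts, \code{0 <= r <= n}.
#' @param n integer vector of arm sample sizes, \code{n >= 1}.
#' @return A \code{data.frame} of class \code{arm_table} with columns
#'   \code{study}, \code{treatment}, \code{r}, \code{n}.
#' @export
arm_table <- function(study, treatment, r, n) {
  df <- data.frame(study = as.character(study),
                   treatment = as.integer(treatment),
                   r = as.integer(r), n = as.integer(n),
                   stringsAsFactors = FALSE)
  validate_arm_table(df)
}

validate_arm_table <- function(df) {
  if (nrow(df) == 0L) stop("no arm records", call. = FALSE)
  req <- c("study", "treatment", "r", "n")
  if (!all(req %in% names(df))) {
    stop("arm table must have columns study, treatment, r, n; missing: ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  bad_row <- function(i, msg) {
    stop(sprintf("arm record %d (study '%s', treatment %s): %s",
                 i, df$study[i], df$treatment[i], msg), call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    if (is.na(df$treatment[i]) || df$treatment[i] < 1L) bad_row(i, "treatment code must be a positive integer")
    if (is.na(df$n[i]) || df$n[i] < 1L) bad_row(i, "n must be >= 1")
    if (is.na(df$r[i]) || df$r[i] < 0L) bad_row(i, "r must be >= 0")
    if (df$r[i] > df$n[i]) bad_row(i, sprintf("r = %d exceeds n = %d", df$r[i], df$n[i]))
  }
  key <- paste(df$study, df$treatment, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (study, treatment) pair: ('%s', %d)",
                 df$study[d], df$treatment[d]), call. = FALSE)
  }
  class(df) <- c("arm_table", "data.frame")
  df
}

#' Read an arm-level CSV file
#'
#' Expects a UTF-8 CSV with header columns \code{study,treatment,r,n}.
#' Rows violating the arm-record invariants (\code{r > n}, \code{n < 1},
#' duplicate study/treatment pairs) are rejected with a row-level message.
#'
#' @param path path to the CSV file.
#' @return An \code{\link{arm_table}}.
#' @export
read_arm_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("no arm records", call. = FALSE)
  extra <- setdiff(names(df), c("study", "treatment", "r", "n"))
  if (length(extra)) {
    stop("unknown column(s) in arm CSV: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  arm_table(df$study, as.integer(df$treatment), as.integer(df$r), as.integer(df$n))
}

#' Write an arm table to CSV
#'
#' Inverse of \code{\link{read_arm_data}}: writing then reading reproduces
#' the table, and on a canonical fixture the file itself byte-for-byte.
#'
#' @param arms an \code{\link{arm_table}}.
#' @param path output path.
#' @export
write_arm_data <- function(arms, path) {
  utils::write.csv(as.data.frame(arms)[, c("study", "treatment", "r", "n")],
                   path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Treatment coding
#'
#' Maps treatment labels to contiguous integer codes \code{1..K}, with the
#' reference treatment (placebo) always code 1. Relative treatment effects
#' \code{d_k} are expressed against code 1.
#'
#' @param names ordered character vector of treatment labels; the first is
#'   the reference.
#' @return An object of class \code{treatment_coding}.
#' @export
treatment_coding <- function(names) {
  names <- as.character(names)
  if (length(names) < 2L) stop("need at least two treatments", call. = FALSE)
  if (anyDuplicated(names)) stop("duplicate treatment labels", call. = FALSE)
  structure(list(names = names, reference_index = 1L),
            class = "treatment_coding")
}

#' Read a treatment coding file
#'
#' One label per line, reference (placebo) first.
#'
#' @param path path to the coding file.
#' @return A \code{\link{treatment_coding}}.
#' @export
read_treatment_coding <- function(path) {
  lab <- readLines(path, warn = FALSE)
  lab <- lab[nzchar(trimws(lab))]
  treatment_coding(trimws(lab))
}

#' @export
print.treatment_coding <- function(x, ...) {
  cat(sprintf("Treatment coding: %d treatments, reference = '%s' (code 1)\n",
              length(x$names), x$names[1L]))
  invisible(x)
}
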
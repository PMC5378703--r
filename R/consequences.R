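# Consequence metrics: equating-error statistics across replications and
# classification / passing-rate misclassification against the truth.

.performance_levels <- c("inadequate", "adequate", "proficient", "advanced")

#' Equating-error summary across replications
#'
#' Conditioning on each number-correct score `s` in `score_range`:
#' `MEE(s)` is the mean over replications of the estimated-minus-true
#' equated score, `RMSEE(s)` the root mean square of the same differences,
#' and `REMSEE` the equally weighted average of the `RMSEE(s)` over the
#' score range (the single aggregate recovery indicator).
#'
#' @param estimated_tables list of estimated `conversion_table`s (one per
#'   replication).
#' @param true_table the true conversion table.
#' @param score_range integer scores to aggregate over; default the true
#'   table's non-extrapolated score range.
#' @return list of class `"equating_error_summary"` with `score`, `mee`,
#'   `rmsee` vectors and scalar `remsee`.
#' @export
equating_errors <- function(estimated_tables, true_table,
                            score_range = NULL) {
  if (inherits(estimated_tables, "conversion_table"))
    estimated_tables <- list(estimated_tables)
  if (!length(estimated_tables)) stop("need at least one replication")
  validate_conversion_table(true_table)
  if (is.null(score_range))
    score_range <- true_table$nc_score[!true_table$extrapolated]
  score_range <- as.integer(score_range)
  e_true <- true_table$equated_score[match(score_range, true_table$nc_score)]
  if (anyNA(e_true)) stop("true table does not cover the score range")
  diffs <- vapply(estimated_tables, function(tab) {
    validate_conversion_table(tab)
    e_hat <- tab$equated_score[match(score_range, tab$nc_score)]
    if (anyNA(e_hat)) stop("an estimated table does not cover the score range")
    e_hat - e_true
  }, numeric(length(score_range)))
  diffs <- matrix(diffs, nrow = length(score_range))
  mee <- rowMeans(diffs)
  rmsee <- sqrt(rowMeans(diffs^2))
  structure(list(score = score_range, mee = mee, rmsee = rmsee,
                 remsee = mean(rmsee), replications = ncol(diffs)),
            class = "equating_error_summary")
}

#' Practical-significance flag for equating error
#'
#' A REMSEE at or above the "difference that matters" (DTM) of half a
#' number-correct score point is judged practically significant.
#'
#' @param remsee nonnegative aggregate equating error.
#' @param dtm threshold, default 0.5.
#' @return `TRUE` iff `remsee >= dtm`.
#' @export
flag_practical_significance <- function(remsee, dtm = 0.5) {
  if (!is.finite(remsee) || remsee < 0) stop("remsee must be nonnegative")
  remsee >= dtm
}

#' Derive Form Y cut scores from a conversion table
#'
#' For each Form X cut, the (real-valued) Form Y number-correct score whose
#' equated value equals the cut, by monotone linear interpolation between
#' adjacent integer rows of the table; on a flat stretch (tie) the lower
#' score is taken.
#'
#' @param table a `conversion_table` mapping Form Y scores to Form X
#'   equated scores.
#' @param x_cuts Form X cut scores, default `c(21, 37, 49)` (the
#'   adequate / proficient / advanced thresholds; the middle cut is the
#'   pass cut).
#' @return list of class `"cut_scores"` with `x_cuts`, `y_cuts`, and
#'   `pass_index = 2` (the middle cut).
#' @export
derive_cut_scores <- function(table, x_cuts = c(21, 37, 49)) {
  validate_conversion_table(table)
  if (any(diff(x_cuts) <= 0)) stop("x_cuts must be strictly increasing")
  e <- table$equated_score
  s <- table$nc_score
  y_cuts <- vapply(x_cuts, function(cut) {
    if (cut < min(e) || cut > max(e))
      stop("cut ", cut, " outside the equated score range [",
           round(min(e), 3), ", ", round(max(e), 3), "]")
    i <- which(e >= cut)[1]          # first row at or above the cut
    if (e[i] == cut) {
      # tie broken toward the lower score on a flat stretch
      return(s[which(e == cut)[1]])
    }
    s[i - 1] + (cut - e[i - 1]) / (e[i] - e[i - 1])
  }, numeric(1))
  structure(list(x_cuts = x_cuts, y_cuts = y_cuts, pass_index = 2L),
            class = "cut_scores")
}

#' Classify examinees into performance categories
#'
#' Compares each examinee's Form Y number-correct score with the Form Y cut
#' scores; a score at a cut falls in the higher category (at-or-above
#' convention). Categories are encoded 0..3 and labelled inadequate /
#' adequate / proficient / advanced.
#'
#' @param nc_scores integer Form Y number-correct scores.
#' @param cuts a [derive_cut_scores()] result (or numeric vector of three
#'   increasing Y cuts).
#' @param max_nc maximum attainable score (for validation), default 54.
#' @return integer vector in `0:3` with a `"labels"` attribute.
#' @export
classify <- function(nc_scores, cuts, max_nc = 54L) {
  y_cuts <- if (inherits(cuts, "cut_scores")) cuts$y_cuts else as.numeric(cuts)
  if (length(y_cuts) != 3L || any(diff(y_cuts) <= 0))
    stop("need three strictly increasing cut scores")
  if (any(nc_scores < 0 | nc_scores > max_nc | nc_scores != floor(nc_scores)))
    stop("nc_scores must be integers in 0..", max_nc)
  cat <- rowSums(outer(nc_scores, y_cuts, ">="))
  structure(as.integer(cat), labels = .performance_levels)
}

#' Classification agreement report against the truth
#'
#' Rates (in percent) of accurate, over- (estimated above true) and under-
#' (estimated below true) classification, plus passing rates (percentage at
#' or above the proficient cut) under the estimated and true
#' classifications and their signed difference, the passing
#' misclassification (positive = true passing rate over-estimated).
#'
#' @param estimated,true integer category vectors (0..3) of equal length.
#' @return list of class `"classification_report"` with `accuracy`, `over`,
#'   `under`, `passing_estimated`, `passing_true`,
#'   `passing_misclassification` (all percentages).
#' @export
classification_report <- function(estimated, true) {
  if (length(estimated) != length(true))
    stop("category vectors must have equal length")
  if (!length(estimated)) stop("empty category vectors")
  n <- length(true)
  acc <- 100 * sum(estimated == true) / n
  over <- 100 * sum(estimated > true) / n
  under <- 100 * sum(estimated < true) / n
  pe <- 100 * sum(estimated >= 2L) / n
  pt <- 100 * sum(true >= 2L) / n
  structure(list(accuracy = acc, over = over, under = under,
                 passing_estimated = pe, passing_true = pt,
                 passing_misclassification = pe - pt, n = n),
            class = "classification_report")
}
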
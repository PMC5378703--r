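# IRT true-score equating: map each Form Y number-correct score s to the
# Form X expected score at the ability solving TCC_Y(theta) = s, once both
# forms share a scale.

#' Invert a test characteristic curve
#'
#' Finds the ability at which the expected total score over `params` equals
#' `target`, by bracketed monotone root search on `[-10, 10]` (Brent). The
#' target must lie strictly inside the attainable open range (sum of lower
#' asymptotes, maximum score); outside it a condition of class
#' `"eqmisfit_range_error"` is signalled so callers can apply the
#' extrapolation rule.
#'
#' @param params item-parameter table (the scored items of a form).
#' @param target expected score to invert.
#' @param D logistic scaling constant.
#' @param tol tolerance on `|TCC(theta) - target|` (default 1e-8).
#' @return the ability `theta` with `|TCC(theta) - target| < tol`.
#' @export
invert_tcc <- function(params, target, D = default_D(), tol = 1e-8) {
  validate_item_params(params)
  lo_asym <- sum(params$c)
  hi <- max_score(params, role = unique(params$role))
  if (!is.finite(target) || target <= lo_asym || target >= hi) {
    cond <- structure(
      class = c("eqmisfit_range_error", "error", "condition"),
      list(message = sprintf(
        "target %.4f outside attainable open range (%.4f, %.4f)",
        target, lo_asym, hi), call = sys.call()))
    stop(cond)
  }
  .invert_tcc_fun(.tcc_fun(params, D), target, tol)
}

# Vectorized bisection solving TCC(theta) = target for many targets at
# once (the TCC is strictly increasing, so bisection cannot fail).
.invert_tcc_many <- function(tccf, targets, tol = 1e-8) {
  lo <- rep(-10, length(targets))
  hi <- rep(10, length(targets))
  while (any(tccf(lo) > targets) && lo[1] > -35) lo <- lo - 5
  while (any(tccf(hi) < targets) && hi[1] < 35) hi <- hi + 5
  for (iter in 1:80) {
    mid <- (lo + hi) / 2
    up <- tccf(mid) < targets
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(hi - lo) < 1e-13) break
  }
  th <- (lo + hi) / 2
  if (max(abs(tccf(th) - targets)) >= tol)
    stop("TCC inversion did not reach tolerance")
  th
}

# Root search given a prepared TCC evaluator (one validation, many solves).
.invert_tcc_fun <- function(tccf, target, tol = 1e-8) {
  f <- function(th) tccf(th) - target
  lower <- -10; upper <- 10
  # widen the bracket if the asymptote is approached only beyond +-10
  while (f(lower) > 0 && lower > -35) lower <- lower - 5
  while (f(upper) < 0 && upper < 35) upper <- upper + 5
  r <- uniroot(f, c(lower, upper), tol = 1e-12)
  if (abs(f(r$root)) >= tol)
    stop("TCC inversion did not reach tolerance at target ", target)
  r$root
}

#' IRT true-score conversion table
#'
#' For each integer number-correct score `s = 0..S` on Form Y, the equated
#' Form X expected score `e(s) = TCC_X(theta_s)` with `TCC_Y(theta_s) = s`.
#' Scores at or below the Form Y lower asymptote (the sum of its 3PL `c`
#' parameters) have no solution; they are filled by linear interpolation
#' from `(0, 0)` to the first solvable score's equated value (or left `NA`
#' with `extrapolation = "sentinel"`) and flagged. The top score `S` maps
#' to the Form X maximum and is likewise flagged (no finite ability attains
#' it). Both parameter sets must already share a scale (FCIP output, or
#' transformed estimates).
#'
#' @param params_y,params_x item-parameter tables of the scored items of
#'   Form Y (the form being equated) and Form X (the reference form).
#' @param D logistic scaling constant.
#' @param extrapolation `"interpolate"` (default) or `"sentinel"`.
#' @param tol TCC inversion tolerance.
#' @return a `data.frame` of class `"conversion_table"` with columns
#'   `nc_score`, `equated_score`, `theta`, `extrapolated`; `S + 1` rows,
#'   `equated_score` nondecreasing.
#' @export
true_score_conversion <- function(params_y, params_x, D = default_D(),
                                  extrapolation = c("interpolate", "sentinel"),
                                  tol = 1e-8) {
  extrapolation <- match.arg(extrapolation)
  validate_item_params(params_y)
  validate_item_params(params_x)
  S <- max_score(params_y, role = unique(params_y$role))
  Sx <- max_score(params_x, role = unique(params_x$role))
  lo_y <- sum(params_y$c)
  scores <- 0:S
  theta <- rep(NA_real_, S + 1)
  eq <- rep(NA_real_, S + 1)
  extr <- rep(TRUE, S + 1)
  tccf_y <- .tcc_fun(params_y, D)
  tccf_x <- .tcc_fun(params_x, D)
  solvable <- which(scores > lo_y & scores < S)
  if (length(solvable)) {
    th <- .invert_tcc_many(tccf_y, scores[solvable], tol)
    theta[solvable] <- th
    eq[solvable] <- tccf_x(th)
    extr[solvable] <- FALSE
  }
  eq[S + 1] <- Sx  # top score maps to the reference maximum
  if (extrapolation == "interpolate") {
    low_rows <- which(extr & scores < S)
    if (length(low_rows)) {
      s1 <- min(solvable)
      # straight line from (0, 0) to the first solvable equated value
      eq[low_rows] <- scores[low_rows] * eq[s1] / scores[s1]
    }
  }
  out <- data.frame(nc_score = scores, equated_score = eq, theta = theta,
                    extrapolated = extr)
  class(out) <- c("conversion_table", "data.frame")
  out
}

#' Validate a conversion table
#'
#' Checks the structural invariants: complete integer score column,
#' nondecreasing equated scores, and ability solutions only on
#' non-extrapolated rows.
#'
#' @param table a `conversion_table`.
#' @return the table, invisibly.
#' @export
validate_conversion_table <- function(table) {
  need <- c("nc_score", "equated_score", "theta", "extrapolated")
  if (!all(need %in% names(table))) stop("not a conversion table")
  if (!identical(as.integer(table$nc_score),
                 seq.int(0L, nrow(table) - 1L)))
    stop("nc_score must run 0..max without gaps")
  eqs <- table$equated_score[!is.na(table$equated_score)]
  if (any(diff(eqs) < -1e-9))
    stop("equated scores must be nondecreasing")
  if (any(!table$extrapolated & is.na(table$theta)))
    stop("non-extrapolated rows must carry a theta solution")
  invisible(table)
}
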
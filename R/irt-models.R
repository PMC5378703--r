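#' @useDynLib eqmisfit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim plogis qlogis rbeta rlnorm rnorm runif sd setNames
#'   uniroot dnorm cor
#' @importFrom utils read.csv write.csv
NULL

# Largest magnitude allowed in exponent space; beyond this the logistic is
# saturated at working precision anyway.
.EXP_CLIP <- 35

#' Default logistic scaling constant
#'
#' The scaling constant `D` multiplying `a * (theta - b)` in every logistic
#' item response function of the package. `D = 1.7` makes the logistic curve
#' closely match the normal ogive and is the convention of the operational
#' calibration software family this pipeline mirrors. All downstream results
#' are invariant to the choice as long as the same value is used in
#' generation, calibration, linking, and equating; every function that needs
#' it exposes a `D` argument defaulting to this value.
#'
#' @return The numeric constant 1.7.
#' @export
default_D <- function() 1.7

.dich_models <- c("1PL", "2PL", "3PL")
.poly_models <- c("PC", "GPC")

#' Construct an item-parameter table
#'
#' The central data structure of the package: one row per item with the
#' item's model tag and parameter vector. Dichotomous items (1PL/2PL/3PL)
#' use columns `a` (discrimination), `b` (difficulty), `c` (lower asymptote,
#' nonzero only under the 3PL). Polytomous items (PC/GPC) use `a`, location
#' `b`, and category parameters `d1..d4` (with implicit `d0 = 0`); the
#' number of score categories is one more than the number of non-`NA` `d`
#' columns, and the `d`s sum to zero (identification constraint).
#'
#' @param item_id character vector of unique item identifiers.
#' @param role `"unique"` (scored) or `"anchor"` (common, unscored).
#' @param item_type `"MC"`, `"SR"`, or `"CR"`.
#' @param model `"1PL"`, `"2PL"`, `"3PL"`, `"PC"`, or `"GPC"`.
#' @param a,b,c numeric parameter vectors (`c` ignored for non-3PL items).
#' @param d matrix (items x 4) of category parameters, `NA` for dichotomous
#'   rows; rows may use fewer than 4 categories by trailing `NA`s.
#' @return A validated `data.frame` with columns
#'   `item_id, role, item_type, model, a, b, c, d1, d2, d3, d4`.
#' @export
item_params <- function(item_id, role, item_type, model, a, b, c = 0,
                        d = NULL) {
  n <- length(item_id)
  if (is.null(d)) d <- matrix(NA_real_, n, 4)
  d <- as.matrix(d)
  if (ncol(d) < 4) d <- cbind(d, matrix(NA_real_, n, 4 - ncol(d)))
  df <- data.frame(
    item_id = as.character(item_id),
    role = rep_len(role, n),
    item_type = rep_len(item_type, n),
    model = rep_len(model, n),
    a = as.numeric(a),
    b = as.numeric(b),
    c = rep_len(as.numeric(c), n),
    d1 = d[, 1], d2 = d[, 2], d3 = d[, 3], d4 = d[, 4],
    stringsAsFactors = FALSE
  )
  df$c[df$model != "3PL"] <- 0
  validate_item_params(df)
  df
}

#' Validate an item-parameter table
#'
#' Checks the structural invariants of the item-parameter schema: known
#' model tags, positive finite discriminations, finite difficulties,
#' `c` in `[0, 1)` and zero except under the 3PL, and sum-to-zero category
#' parameters for polytomous items.
#'
#' @param df an item-parameter `data.frame` (see [item_params()]).
#' @param tol tolerance for the sum-to-zero check on `d`.
#' @return `df`, invisibly, if valid; otherwise an error.
#' @export
validate_item_params <- function(df, tol = 1e-8) {
  need <- c("item_id", "role", "item_type", "model", "a", "b", "c",
            "d1", "d2", "d3", "d4")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("item parameter table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$item_id))
    stop("duplicated item_id in item parameter table")
  if (!all(df$model %in% c(.dich_models, .poly_models)))
    stop("unknown model tag: ",
         paste(setdiff(df$model, c(.dich_models, .poly_models)), collapse = ", "))
  if (!all(df$role %in% c("unique", "anchor")))
    stop("role must be 'unique' or 'anchor'")
  if (!all(is.finite(df$a)) || any(df$a <= 0))
    stop("discrimination a must be finite and > 0")
  if (!all(is.finite(df$b)))
    stop("difficulty b must be finite")
  if (any(!is.finite(df$c) | df$c < 0 | df$c >= 1))
    stop("lower asymptote c must lie in [0, 1)")
  if (any(df$c[df$model != "3PL"] != 0))
    stop("c must be 0 for models other than the 3PL")
  dich <- df$model %in% .dich_models
  dmat <- as.matrix(df[, c("d1", "d2", "d3", "d4")])
  if (any(!is.na(dmat[dich, , drop = FALSE])))
    stop("dichotomous items must have NA category parameters")
  for (i in which(!dich)) {
    dv <- dmat[i, ]
    m <- sum(!is.na(dv))
    if (m < 1) stop("polytomous item ", df$item_id[i], " has no d parameters")
    if (any(is.na(dv[seq_len(m)])))
      stop("d parameters of item ", df$item_id[i], " must be contiguous")
    if (abs(sum(dv[seq_len(m)])) > tol)
      stop("d parameters of item ", df$item_id[i], " must sum to zero")
  }
  invisible(df)
}

#' Number of score categories per item
#'
#' @param df item-parameter table.
#' @return integer vector: 2 for dichotomous rows, `m + 1` for polytomous
#'   rows with `m` non-`NA` category parameters.
#' @export
item_ncat <- function(df) {
  dmat <- as.matrix(df[, c("d1", "d2", "d3", "d4")])
  ifelse(df$model %in% .dich_models, 2L, rowSums(!is.na(dmat)) + 1L)
}

#' Maximum number-correct score of the scored items of a form
#'
#' @param df item-parameter table.
#' @param role which items to count, default the scored (`"unique"`) ones.
#' @return integer maximum attainable number-correct score.
#' @export
max_score <- function(df, role = "unique") {
  sum(item_ncat(df[df$role %in% role, , drop = FALSE]) - 1L)
}

.clip_exp <- function(z) pmin(pmax(z, -.EXP_CLIP), .EXP_CLIP)

.as_item_row <- function(item) {
  if (is.data.frame(item)) {
    if (nrow(item) != 1L) stop("expected a single item row")
    as.list(item)
  } else as.list(item)
}

#' Probability of a correct response under a logistic dichotomous model
#'
#' `P(theta) = c + (1 - c) / (1 + exp(-D a (theta - b)))`, covering the
#' 1PL (`c = 0`, common `a`), 2PL (`c = 0`) and 3PL models.
#'
#' @param item a single-row item-parameter table or a list with elements
#'   `a`, `b` and optionally `c`.
#' @param theta numeric vector of abilities.
#' @param D logistic scaling constant, see [default_D()].
#' @return numeric vector of correct-response probabilities.
#' @export
prob_dichotomous <- function(item, theta, D = default_D()) {
  it <- .as_item_row(item)
  cc <- if (is.null(it$c) || is.na(it$c)) 0 else it$c
  if (!all(is.finite(theta))) stop("theta must be finite")
  if (!is.finite(it$a) || it$a <= 0 || !is.finite(it$b) ||
      !is.finite(cc) || cc < 0 || cc >= 1)
    stop("invalid dichotomous item parameters")
  cc + (1 - cc) * plogis(.clip_exp(D * it$a * (theta - it$b)))
}

#' Category response probabilities under the (generalized) partial credit model
#'
#' Muraki location-plus-category parameterization: the probability of score
#' category `k` (for `k = 0..m`) is proportional to
#' `exp(sum_{v<=k} D a (theta - b + d_v))` with `d_0 = 0`. With `m = 1` and
#' `d_1 = 0` this reduces exactly to the 2PL.
#'
#' @inheritParams prob_dichotomous
#' @return matrix `length(theta) x (m + 1)` of category probabilities; each
#'   row sums to one.
#' @export
prob_categories <- function(item, theta, D = default_D()) {
  it <- .as_item_row(item)
  dv <- unlist(it[c("d1", "d2", "d3", "d4")], use.names = FALSE)
  m <- sum(!is.na(dv))
  if (m < 1) stop("polytomous item needs at least one d parameter")
  dv <- dv[seq_len(m)]
  if (any(is.na(dv))) stop("d parameters must be contiguous (no internal NA)")
  if (!all(is.finite(theta))) stop("theta must be finite")
  if (!is.finite(it$a) || it$a <= 0) stop("invalid discrimination")
  # cumulative logits z_k = sum_{v=1..k} D a (theta - b + d_v), z_0 = 0
  z <- .gpc_logits(it$a, it$b, dv, theta, D)
  z <- .clip_exp(z - .row_max(z))
  ez <- exp(z)
  ez / rowSums(ez)
}

# Cumulative GPC logits z_k = sum_{v<=k} D a (theta - b + d_v), k = 0..m,
# as a length(theta) x (m + 1) matrix (cumsum via triangular matmul).
.gpc_logits <- function(a, b, dv, theta, D) {
  m <- length(dv)
  steps <- outer(D * a * (theta - b), rep(1, m)) +
    matrix(D * a * dv, length(theta), m, byrow = TRUE)
  cum <- if (m > 1L) steps %*% upper.tri(diag(m), diag = TRUE) else steps
  cbind(0, cum)
}

.row_max <- function(z) {
  out <- z[, 1L]
  for (k in seq_len(ncol(z))[-1L]) out <- pmax(out, z[, k])
  out
}

#' Expected item score
#'
#' Expected score on one item at ability `theta`: the correct-response
#' probability for a 0/1 item, `sum_k k P_k(theta)` for a polytomous item.
#'
#' @inheritParams prob_dichotomous
#' @return numeric vector of expected scores.
#' @export
expected_item_score <- function(item, theta, D = default_D()) {
  it <- .as_item_row(item)
  if (it$model %in% .dich_models) {
    prob_dichotomous(it, theta, D)
  } else {
    P <- prob_categories(it, theta, D)
    as.numeric(P %*% (seq_len(ncol(P)) - 1))
  }
}

#' Test characteristic curve
#'
#' Expected total score over a set of items as a function of ability: the
#' sum of [expected_item_score()] across the rows of `df`. Strictly
#' increasing in `theta` whenever all discriminations are positive; bounded
#' below by the sum of the 3PL lower asymptotes and above by the maximum
#' attainable score.
#'
#' @param df item-parameter table (all rows are used; subset before calling
#'   to restrict to e.g. scored or anchor items).
#' @param theta numeric vector of abilities.
#' @param D logistic scaling constant.
#' @return numeric vector of expected total scores, one per `theta`.
#' @export
tcc <- function(df, theta, D = default_D()) {
  .tcc_fun(df, D)(theta)
}

# Prepared fast TCC evaluator: validates and unpacks the table once, then
# evaluates vectorized over theta (hot path for equating and linking).
.tcc_fun <- function(df, D = default_D()) {
  if (!is.data.frame(df) || nrow(df) == 0L)
    stop("tcc needs a nonempty item-parameter table")
  validate_item_params(df)
  par <- as.matrix(df[, c("a", "b", "c", "d1", "d2", "d3", "d4")])
  par[is.na(par)] <- 0
  dich <- df$model %in% .dich_models
  mcat <- item_ncat(df) - 1L
  function(theta) {
    if (!all(is.finite(theta))) stop("theta must be finite")
    .tcc_par(par, dich, mcat, theta, D)
  }
}

# Vectorized TCC from a raw parameter matrix (a, b, c, d1..d4 with 0 in
# unused cells); hot path for the Stocking-Lord criterion.
.tcc_par <- function(par, dich, mcat, nodes, D) {
  Q <- length(nodes)
  out <- numeric(Q)
  if (any(dich)) {
    a <- par[dich, 1]; b <- par[dich, 2]; cc <- par[dich, 3]
    Z <- (matrix(nodes, Q, length(a)) -
            matrix(b, Q, length(a), byrow = TRUE)) *
      matrix(D * a, Q, length(a), byrow = TRUE)
    P <- matrix(cc, Q, length(a), byrow = TRUE) +
      matrix(1 - cc, Q, length(a), byrow = TRUE) * plogis(.clip_exp(Z))
    out <- out + rowSums(P)
  }
  for (j in which(!dich)) {
    m <- mcat[j]
    z <- .gpc_logits(par[j, 1], par[j, 2], par[j, 3 + seq_len(m)], nodes, D)
    z <- .clip_exp(z - .row_max(z))
    ez <- exp(z)
    out <- out + as.numeric((ez %*% (0:m)) / rowSums(ez))
  }
  out
}

# Stacked category-probability matrix straight from the raw parameter
# matrix (per-cycle hot path of the EM loop).
.prob_matrix_par <- function(par, dich, mcat, nodes, D) {
  ncat <- ifelse(dich, 2L, mcat + 1L)
  C <- sum(ncat)
  Q <- length(nodes)
  P <- matrix(0, C, Q)
  off <- c(0L, cumsum(ncat))
  if (any(dich)) {
    jd <- which(dich)
    a <- par[jd, 1]; b <- par[jd, 2]; cc <- par[jd, 3]
    Z <- (matrix(nodes, Q, length(jd)) -
            matrix(b, Q, length(jd), byrow = TRUE)) *
      matrix(D * a, Q, length(jd), byrow = TRUE)
    P1 <- matrix(cc, Q, length(jd), byrow = TRUE) +
      matrix(1 - cc, Q, length(jd), byrow = TRUE) * plogis(.clip_exp(Z))
    for (t in seq_along(jd)) {
      P[off[jd[t]] + 1L, ] <- 1 - P1[, t]
      P[off[jd[t]] + 2L, ] <- P1[, t]
    }
  }
  for (j in which(!dich)) {
    m <- mcat[j]
    z <- .gpc_logits(par[j, 1], par[j, 2], par[j, 3 + seq_len(m)], nodes, D)
    z <- .clip_exp(z - .row_max(z))
    ez <- exp(z)
    P[off[j] + seq_len(m + 1L), ] <- t(ez / rowSums(ez))
  }
  list(P = P, ncat = ncat, offset = off[seq_len(length(ncat))])
}

# Stacked category-probability matrix used by calibration: rows are the
# categories of all items in order, columns are quadrature nodes. Returns the
# matrix plus row->item and row->score maps.
prob_matrix <- function(df, nodes, D = default_D()) {
  ncat <- item_ncat(df)
  C <- sum(ncat)
  P <- matrix(0, C, length(nodes))
  row_item <- integer(C)
  row_score <- numeric(C)
  off <- 0L
  for (j in seq_len(nrow(df))) {
    it <- df[j, ]
    if (it$model %in% .dich_models) {
      p1 <- prob_dichotomous(it, nodes, D)
      P[off + 1L, ] <- 1 - p1
      P[off + 2L, ] <- p1
    } else {
      P[off + seq_len(ncat[j]), ] <- t(prob_categories(it, nodes, D))
    }
    row_item[off + seq_len(ncat[j])] <- j
    row_score[off + seq_len(ncat[j])] <- seq_len(ncat[j]) - 1
    off <- off + ncat[j]
  }
  list(P = P, row_item = row_item, row_score = row_score, ncat = ncat,
       offset = c(0L, cumsum(ncat))[seq_len(nrow(df))])
}
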
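# Synthetic NEAT-design data generation. The operational item parameters the
# study design is modelled on are confidential, so this module generates a
# stand-in pool with the same structure: two mixed-format forms (29 MC + 5 SR
# + 5 CR scored items, maximum number-correct score 54) plus a 39-item
# external anchor common to both administrations, with MC items following the
# 3PL, SR the 2PL, and CR (0-4) the GPC as the generating truth.

#' Deterministic substream seed derivation
#'
#' Expands a single master seed into reproducible, practically distinct
#' substreams keyed by arbitrary labels (form, condition, replication,
#' attempt, ...). Uses a 32-bit FNV-1a hash of the label path so that
#' substreams are independent of evaluation order and safe to draw in
#' parallel.
#'
#' @param master integer master seed.
#' @param ... label components (coerced to character) identifying the
#'   substream.
#' @return an integer seed in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  s <- paste(c(format(master), vapply(list(...), format, "")), collapse = "|")
  h <- 2166136261
  for (byte in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(byte))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483645) + 1L
}

.rtrunc <- function(n, rfun, lower, upper, max_tries = 1000L) {
  x <- rfun(n)
  for (i in seq_len(max_tries)) {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) return(x)
    x[bad] <- rfun(length(bad))
  }
  pmin(pmax(x, lower), upper)
}

#' Item-parameter generator specification
#'
#' Distributions used to draw realistic mixed-format item parameters:
#' discriminations log-normal (truncated), difficulties/locations normal
#' (truncated), 3PL lower asymptotes Beta with mean 0.2, and GPC category
#' parameters normal, centered to sum zero and sorted decreasing so the step
#' difficulties `b - d_k` are increasing. Counts default to the 29 MC / 5 SR
#' / 5 CR composition (maximum scored number-correct score 54).
#'
#' @param a_meanlog,a_sdlog,a_range log-normal parameters and truncation
#'   range for discriminations.
#' @param b_mean,b_sd,b_range normal parameters and truncation range for
#'   difficulties.
#' @param c_shape1,c_shape2 Beta parameters for the 3PL lower asymptote
#'   (defaults give mean 0.2, consistent with 4-5-option multiple choice).
#' @param d_sd standard deviation of raw GPC category parameters before
#'   sum-zero centering.
#' @param n_mc,n_sr,n_cr item counts per type.
#' @param cr_categories number of score categories of a CR item (0 to
#'   `cr_categories - 1` scored).
#' @return a list with class `"item_generator_spec"`.
#' @export
item_generator_spec <- function(a_meanlog = log(1.0), a_sdlog = 0.35,
                                a_range = c(0.3, 2.5),
                                b_mean = 0, b_sd = 1, b_range = c(-3, 3),
                                c_shape1 = 8, c_shape2 = 32,
                                d_sd = 0.8,
                                n_mc = 29L, n_sr = 5L, n_cr = 5L,
                                cr_categories = 5L) {
  spec <- list(a_meanlog = a_meanlog, a_sdlog = a_sdlog, a_range = a_range,
               b_mean = b_mean, b_sd = b_sd, b_range = b_range,
               c_shape1 = c_shape1, c_shape2 = c_shape2, d_sd = d_sd,
               n_mc = as.integer(n_mc), n_sr = as.integer(n_sr),
               n_cr = as.integer(n_cr),
               cr_categories = as.integer(cr_categories))
  if (spec$n_mc < 0 || spec$n_sr < 0 || spec$n_cr < 0)
    stop("item counts must be nonnegative")
  if (spec$cr_categories < 2L || spec$cr_categories > 5L)
    stop("cr_categories must be between 2 and 5")
  class(spec) <- "item_generator_spec"
  spec
}

.draw_form <- function(spec, prefix, role) {
  n <- spec$n_mc + spec$n_sr + spec$n_cr
  a <- .rtrunc(n, function(k) rlnorm(k, spec$a_meanlog, spec$a_sdlog),
               spec$a_range[1], spec$a_range[2])
  b <- .rtrunc(n, function(k) rnorm(k, spec$b_mean, spec$b_sd),
               spec$b_range[1], spec$b_range[2])
  cc <- numeric(n)
  if (spec$n_mc > 0)
    cc[seq_len(spec$n_mc)] <-
      if (spec$c_shape1 == 0) 0 else
        pmin(rbeta(spec$n_mc, spec$c_shape1, spec$c_shape2), 0.5)
  m_cr <- spec$cr_categories - 1L
  dmat <- matrix(NA_real_, n, 4)
  if (spec$n_cr > 0) {
    for (i in seq_len(spec$n_cr)) {
      dk <- rnorm(m_cr, 0, spec$d_sd)
      dk <- sort(dk - mean(dk), decreasing = TRUE)
      dmat[spec$n_mc + spec$n_sr + i, seq_len(m_cr)] <- dk
    }
  }
  item_params(
    item_id = sprintf("%s%02d", prefix, seq_len(n)),
    role = role,
    item_type = rep(c("MC", "SR", "CR"), c(spec$n_mc, spec$n_sr, spec$n_cr)),
    model = rep(c("3PL", "2PL", "GPC"), c(spec$n_mc, spec$n_sr, spec$n_cr)),
    a = a, b = b, c = cc, d = dmat
  )
}

#' Generate item parameters for the NEAT design
#'
#' Draws three item sets from an [item_generator_spec()]: Form X unique
#' items, Form Y unique items, and the Form A external anchor (taken by both
#' cohorts, excluded from scoring). MC items are tagged 3PL, SR items 2PL,
#' and CR items GPC -- the generating truth of the simulation study.
#'
#' @param spec an [item_generator_spec()].
#' @param seed integer seed (the draw is fully reproducible given it).
#' @return list with elements `form_x`, `form_y`, `anchor`, each an
#'   item-parameter table.
#' @export
generate_item_parameters <- function(spec = item_generator_spec(), seed = 1L) {
  if (!inherits(spec, "item_generator_spec"))
    spec <- do.call(item_generator_spec, spec)
  set.seed(derive_seed(seed, "item-parameters"))
  list(form_x = .draw_form(spec, "X", "unique"),
       form_y = .draw_form(spec, "Y", "unique"),
       anchor = .draw_form(spec, "A", "anchor"))
}

#' Generate examinee abilities
#'
#' Draws `n` abilities from `N(mean, 1)`. The standard deviation is fixed at
#' one: the study design varies only the mean of the new-year cohort
#' (0.00, 0.10, 0.25, 0.50) against a standard-normal reference cohort.
#'
#' @param n number of examinees (>= 1).
#' @param mean ability mean.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
generate_abilities <- function(n, mean = 0, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.finite(mean)) stop("ability mean must be finite")
  if (!is.null(seed)) set.seed(seed)
  rnorm(as.integer(n), mean, 1)
}

#' Construct a response matrix bound to its items
#'
#' @param scores integer persons x items matrix.
#' @param items item-parameter table describing the columns, in order.
#' @return the matrix with attribute `"items"` and class `"response_matrix"`.
#' @export
response_matrix <- function(scores, items) {
  scores <- as.matrix(scores)
  validate_item_params(items)
  if (ncol(scores) != nrow(items))
    stop("response matrix has ", ncol(scores), " columns but ",
         nrow(items), " items")
  maxs <- item_ncat(items) - 1L
  for (j in seq_len(ncol(scores))) {
    xj <- scores[, j]
    if (anyNA(xj) || any(xj < 0 | xj > maxs[j] | xj != floor(xj)))
      stop("invalid scores in column ", items$item_id[j],
           " (allowed 0..", maxs[j], ", no missing)")
  }
  storage.mode(scores) <- "integer"
  colnames(scores) <- items$item_id
  attr(scores, "items") <- items
  class(scores) <- c("response_matrix", class(scores))
  scores
}

#' Items bound to a response matrix
#' @param x a `response_matrix`.
#' @return the item-parameter table describing its columns.
#' @export
response_items <- function(x) attr(x, "items")

#' Simulate item responses
#'
#' Draws one response per examinee per item from the item's category
#' distribution at the examinee's ability (Bernoulli for dichotomous items,
#' categorical under the GPC/PC for polytomous items).
#'
#' @param form item-parameter table for the administered items (columns of
#'   the result, in order).
#' @param thetas numeric vector of examinee abilities.
#' @param D logistic scaling constant.
#' @param seed optional integer seed.
#' @return a [response_matrix()] of dimension `length(thetas) x nrow(form)`.
#' @export
simulate_responses <- function(form, thetas, D = default_D(), seed = NULL) {
  validate_item_params(form)
  if (!all(is.finite(thetas))) stop("thetas must be finite")
  if (!is.null(seed)) set.seed(seed)
  n <- length(thetas)
  out <- matrix(0L, n, nrow(form))
  for (j in seq_len(nrow(form))) {
    it <- form[j, ]
    if (it$model %in% .dich_models) {
      out[, j] <- as.integer(runif(n) < prob_dichotomous(it, thetas, D))
    } else {
      P <- prob_categories(it, thetas, D)
      cum <- t(apply(P, 1L, cumsum))
      out[, j] <- as.integer(rowSums(runif(n) > cum))
    }
  }
  response_matrix(out, form)
}

#' Assemble NEAT-design datasets for one ability-shift condition
#'
#' For each replication, simulates the reference administration (Form X
#' unique items plus the Form A anchor, abilities `N(0, 1)`) and the
#' new-year administration (Form Y unique items plus the same anchor,
#' abilities `N(shift, 1)`). Substream seeds are derived deterministically
#' from the master seed, the condition, and the replication, so any
#' replication can be regenerated independently and runs are byte-identical
#' under the same master seed.
#'
#' @param params item sets from [generate_item_parameters()].
#' @param shift new-year ability mean (the reference mean is 0).
#' @param n examinees per administration.
#' @param replications number of replications to generate.
#' @param seed master seed.
#' @param D logistic scaling constant.
#' @param attempt regeneration counter used by the study driver's
#'   discard-and-regenerate rule; different attempts use fresh substreams.
#' @return list of length `replications`; each element has `x` and `y`
#'   [response_matrix()] objects (78 columns each: 39 unique + 39 anchor)
#'   and the generating abilities `theta_x`, `theta_y`.
#' @export
assemble_neat_dataset <- function(params, shift, n, replications = 1L,
                                  seed = 1L, D = default_D(), attempt = 0L) {
  form_xa <- rbind(params$form_x, params$anchor)
  form_ya <- rbind(params$form_y, params$anchor)
  validate_item_params(form_xa)
  lapply(seq_len(replications), function(r) {
    theta_x <- generate_abilities(
      n, 0, seed = derive_seed(seed, "theta", "X", 0, r, attempt))
    theta_y <- generate_abilities(
      n, shift, seed = derive_seed(seed, "theta", "Y", shift, r, attempt))
    x <- simulate_responses(form_xa, theta_x, D,
                            seed = derive_seed(seed, "resp", "X", 0, r, attempt))
    y <- simulate_responses(form_ya, theta_y, D,
                            seed = derive_seed(seed, "resp", "Y", shift, r, attempt))
    list(x = x, y = y, theta_x = theta_x, theta_y = theta_y)
  })
}
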
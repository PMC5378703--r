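# Marginal maximum likelihood (Bock-Aitkin) EM calibration of mixed-format
# response data, with separate-calibration and FCIP (fixed common item
# parameter) modes. The latent ability distribution is represented as
# discrete weights on an equally spaced quadrature grid.

#' Quadrature grid over the ability scale
#'
#' Equally spaced nodes with weights proportional to the standard normal
#' density, normalized to sum to one. The calibration default is 60 nodes on
#' `[-4, 4]`.
#'
#' @param n number of nodes.
#' @param lower,upper grid end points.
#' @return list with `points` (length `n`) and `weights` (nonnegative,
#'   summing to 1), class `"quadrature_grid"`.
#' @export
quadrature_grid <- function(n = 60L, lower = -4, upper = 4) {
  if (n < 2L || upper <= lower) stop("invalid quadrature grid")
  pts <- seq(lower, upper, length.out = n)
  w <- dnorm(pts)
  structure(list(points = pts, weights = w / sum(w)),
            class = "quadrature_grid")
}

#' Prior specification for penalized EM calibration
#'
#' Log-prior penalties added in the M-step: Beta on the 3PL lower asymptote
#' (the guessing prior), normal on log discrimination (the slope prior), and
#' normal on difficulties/locations and category parameters (the threshold
#' prior). Defaults: `c ~ Beta(8, 32)` (mean 0.2), `log a ~ N(0, 0.5^2)`,
#' `b, d_k ~ N(0, 2^2)`.
#'
#' @param on logical switch; `FALSE` disables all penalties.
#' @param c_shape1,c_shape2 Beta hyperparameters for `c`.
#' @param loga_mean,loga_sd normal hyperparameters for `log a`.
#' @param b_sd normal standard deviation for `b`.
#' @param d_sd normal standard deviation for each `d_k`.
#' @return list of class `"prior_spec"`.
#' @export
prior_spec <- function(on = TRUE, c_shape1 = 8, c_shape2 = 32,
                       loga_mean = 0, loga_sd = 0.5, b_sd = 2, d_sd = 2) {
  if (c_shape1 <= 0 || c_shape2 <= 0 || loga_sd <= 0 || b_sd <= 0 || d_sd <= 0)
    stop("prior hyperparameters must be positive")
  structure(list(on = isTRUE(on), c_shape1 = c_shape1, c_shape2 = c_shape2,
                 loga_mean = loga_mean, loga_sd = loga_sd, b_sd = b_sd,
                 d_sd = d_sd),
            class = "prior_spec")
}

.model_sets <- c("3PL/2PL/GPC", "2PL/2PL/GPC", "1PL/1PL/PC")

# item_type -> model under a model set
model_for_type <- function(model_set, item_type) {
  parts <- strsplit(model_set, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop("model_set must be 'MC/SR/CR' model triple")
  unname(c(MC = parts[1], SR = parts[2], CR = parts[3])[item_type])
}

#' Calibration configuration
#'
#' @param model_set one of `"3PL/2PL/GPC"`, `"2PL/2PL/GPC"`, `"1PL/1PL/PC"`:
#'   the models applied to MC/SR/CR items. The `1PL/1PL/PC` set shares a
#'   single estimated discrimination across all items.
#' @param prior a [prior_spec()].
#' @param conv_tol convergence criterion: maximum absolute inter-cycle
#'   change over all item parameters (default 0.001).
#' @param max_cycles maximum EM cycles (default 200); a run that exhausts
#'   them is flagged non-convergent, not an error.
#' @param mode `"separate"` or `"fcip"`.
#' @param latent_update `"fixed"` (standard-normal quadrature weights every
#'   cycle) or `"posterior"` (weights re-estimated from the posterior each
#'   cycle). FCIP requires `"posterior"` and never re-standardizes the
#'   latent scale; separate calibration with `"posterior"` re-standardizes
#'   the exit distribution to mean 0, sd 1 via a compensating linear
#'   transformation of the item parameters.
#' @param inner_max maximum Newton iterations per item per M-step.
#' @param D logistic scaling constant.
#' @return list of class `"calibration_config"`.
#' @export
calibration_config <- function(model_set = "3PL/2PL/GPC",
                               prior = prior_spec(),
                               conv_tol = 0.001, max_cycles = 200L,
                               mode = c("separate", "fcip"),
                               latent_update = NULL,
                               inner_max = 8L, D = default_D()) {
  mode <- match.arg(mode)
  model_set <- match.arg(model_set, .model_sets)
  if (is.null(latent_update))
    latent_update <- if (mode == "fcip") "posterior" else "fixed"
  latent_update <- match.arg(latent_update, c("fixed", "posterior"))
  if (mode == "fcip" && latent_update != "posterior")
    stop("FCIP calibration requires latent_update = 'posterior' ",
         "(posterior updates with no scale adjustment)")
  if (conv_tol <= 0 || max_cycles < 1L) stop("invalid convergence settings")
  structure(list(model_set = model_set, prior = prior, conv_tol = conv_tol,
                 max_cycles = as.integer(max_cycles), mode = mode,
                 latent_update = latent_update,
                 inner_max = as.integer(inner_max), D = D),
            class = "calibration_config")
}

# Working parameter matrix (J x 7: a b c d1..d4, NA d -> 0) and model codes.
.model_code <- c("1PL" = 1L, "2PL" = 2L, "3PL" = 3L, "PC" = 4L, "GPC" = 5L)

.par_matrix <- function(df) {
  m <- as.matrix(df[, c("a", "b", "c", "d1", "d2", "d3", "d4")])
  m[is.na(m)] <- 0
  m
}

.par_df <- function(par, meta) {
  ncat <- meta$ncat
  d <- matrix(NA_real_, nrow(par), 4)
  for (j in seq_len(nrow(par)))
    if (meta$model[j] %in% .poly_models)
      d[j, seq_len(ncat[j] - 1L)] <- par[j, 3 + seq_len(ncat[j] - 1L)]
  item_params(item_id = meta$item_id, role = meta$role,
              item_type = meta$item_type, model = meta$model,
              a = par[, 1], b = par[, 2], c = par[, 3], d = d)
}

# One-hot response indicator (n x total categories), built once per dataset.
.indicator <- function(resp, ncat) {
  n <- nrow(resp)
  C <- sum(ncat)
  off <- c(0L, cumsum(ncat))
  U <- matrix(0, n, C)
  for (j in seq_len(ncol(resp)))
    U[cbind(seq_len(n), off[j] + resp[, j] + 1L)] <- 1
  U
}

.estep_core <- function(U, P, weights) {
  logP <- log(pmax(P, 1e-300))
  logL <- U %*% logP                       # n x Q complete-data log-likelihood
  rmax <- .row_max(logL)
  dead <- which(!is.finite(rmax))
  if (length(dead))
    stop("zero posterior mass (likelihood underflow) for examinee(s) ",
         paste(utils::head(dead, 5L), collapse = ", "))
  L <- exp(logL - rmax)
  post <- sweep(L, 2L, weights, "*")
  rs <- rowSums(post)
  loglik <- sum(log(rs) + rmax)
  post <- post / rs
  list(nhat = colSums(post), counts = crossprod(U, post), post = post,
       loglik = loglik)
}

#' E-step expected counts
#'
#' Computes, under the current item parameters and latent weights, each
#' examinee's posterior over the quadrature nodes, the expected number of
#' examinees at each node, and the expected count of each item-category at
#' each node (the sufficient statistics of the M-step).
#'
#' @param responses a [response_matrix()].
#' @param params item-parameter table aligned with the response columns.
#' @param grid a [quadrature_grid()].
#' @param latent_weights weights over the nodes (default: the grid weights).
#' @param D logistic scaling constant.
#' @return list with `nhat` (expected examinees per node), `counts`
#'   (stacked item-category by node matrix with `row_item`/`row_score`
#'   maps), `post` (examinee-by-node posterior), and `loglik` (marginal
#'   log-likelihood at the inputs).
#' @export
estep <- function(responses, params, grid, latent_weights = grid$weights,
                  D = default_D()) {
  validate_item_params(params)
  if (abs(sum(latent_weights) - 1) > 1e-8 || any(latent_weights < 0))
    stop("latent_weights must be nonnegative and sum to 1")
  pm <- prob_matrix(params, grid$points, D)
  U <- .indicator(unclass(responses)[, , drop = FALSE], pm$ncat)
  es <- .estep_core(U, pm$P, latent_weights)
  list(nhat = es$nhat, counts = es$counts, row_item = pm$row_item,
       row_score = pm$row_score, post = es$post, loglik = es$loglik)
}

# R-side log prior matching the C++ penalty (free items only; shared slope
# penalized once).
.log_prior <- function(par, meta, prior, fixed, shared_slope) {
  if (!prior$on) return(0)
  lp <- 0
  shared_done <- FALSE
  for (j in seq_len(nrow(par))) {
    if (fixed[j]) next
    model <- meta$model[j]
    has_a <- model %in% c("2PL", "3PL", "GPC")
    if (has_a) {
      lp <- lp - 0.5 * ((log(par[j, 1]) - prior$loga_mean) / prior$loga_sd)^2
    } else if (shared_slope && !shared_done) {
      lp <- lp - 0.5 * ((log(par[j, 1]) - prior$loga_mean) / prior$loga_sd)^2
      shared_done <- TRUE
    }
    lp <- lp - 0.5 * (par[j, 2] / prior$b_sd)^2
    if (model == "3PL") {
      cc <- min(max(par[j, 3], 1e-10), 1 - 1e-10)
      lp <- lp + (prior$c_shape1 - 1) * log(cc) + (prior$c_shape2 - 1) * log(1 - cc)
    }
    if (model %in% .poly_models) {
      m <- meta$ncat[j] - 1L
      lp <- lp - 0.5 * sum((par[j, 3 + seq_len(m)] / prior$d_sd)^2)
    }
  }
  lp
}

#' Single-item M-step update
#'
#' Maximizes one item's expected complete-data log-likelihood plus log
#' prior, given E-step expected category counts at the quadrature nodes.
#' Used inside [calibrate()] (with a small iteration cap, giving a
#' generalized EM with a guaranteed ascent) and directly in tests against
#' brute-force grid-search oracles (with the cap effectively off).
#'
#' @param counts `K x Q` matrix of expected counts (categories by nodes).
#' @param model item model tag.
#' @param prior a [prior_spec()].
#' @param current named list or vector with current `a`, `b`, `c`,
#'   `d1..d4` as applicable.
#' @param theta quadrature node locations.
#' @param D logistic scaling constant.
#' @param max_iter,tol inner Newton iteration cap and step tolerance.
#' @return named list with updated `a`, `b`, `c`, `d` (length-4, `NA`
#'   padded) and the attained penalized objective.
#' @export
mstep_item <- function(counts, model, prior, current, theta,
                       D = default_D(), max_iter = 100L, tol = 1e-9) {
  counts <- as.matrix(counts)
  K <- nrow(counts)
  cur <- as.list(current)
  dvals <- unlist(cur[paste0("d", 1:4)], use.names = FALSE)
  if (is.null(dvals)) dvals <- rep(NA_real_, 4)
  par <- matrix(c(cur$a, cur$b, if (is.null(cur$c)) 0 else cur$c,
                  ifelse(is.na(dvals), 0, dvals)), 1, 7)
  res <- cpp_mstep(counts, offset = 0L, ncat = K,
                   model_code = .model_code[[model]], par = par,
                   fixed = FALSE, theta = theta, D = D,
                   prior_list = unclass(prior),
                   shared_slope = model %in% c("1PL", "PC"),
                   shared_a_init = cur$a, inner_max = as.integer(max_iter),
                   inner_tol = tol)
  p <- res$par
  m <- K - 1L
  d <- rep(NA_real_, 4)
  if (model %in% .poly_models) d[seq_len(m)] <- p[1, 3 + seq_len(m)]
  list(a = p[1, 1], b = p[1, 2], c = p[1, 3], d = d,
       objective = res$objective)
}

.init_params <- function(resp, meta, D) {
  J <- nrow(meta)
  par <- matrix(0, J, 7)
  for (j in seq_len(J)) {
    model <- meta$model[j]
    m <- meta$ncat[j] - 1L
    pbar <- mean(resp[, j]) / m
    c0 <- if (model == "3PL") 0.2 else 0
    padj <- min(max((pbar - c0) / (1 - c0), 0.05), 0.95)
    par[j, 1] <- 1
    par[j, 2] <- -qlogis(padj) / D
    par[j, 3] <- c0
  }
  par
}

.latent_moments <- function(grid, weights) {
  mu <- sum(weights * grid$points)
  list(mean = mu, sd = sqrt(max(sum(weights * grid$points^2) - mu^2, 1e-12)))
}

.calibrate_engine <- function(responses, config, grid, fixed_params = NULL) {
  items <- response_items(responses)
  resp <- unclass(responses)[, , drop = FALSE]
  meta <- data.frame(item_id = items$item_id, role = items$role,
                     item_type = items$item_type,
                     model = model_for_type(config$model_set, items$item_type),
                     ncat = item_ncat(items), stringsAsFactors = FALSE)
  shared_slope <- config$model_set == "1PL/1PL/PC"
  fixed <- rep(FALSE, nrow(meta))
  par <- .init_params(resp, meta, config$D)
  if (!is.null(fixed_params)) {
    idx <- match(fixed_params$item_id, meta$item_id)
    if (anyNA(idx))
      stop("fixed anchor parameters include unknown item ids: ",
           paste(fixed_params$item_id[is.na(idx)], collapse = ", "))
    fmodels <- model_for_type(config$model_set, meta$item_type[idx])
    if (!all(fixed_params$model == fmodels))
      stop("fixed anchor parameter models disagree with the model set")
    par[idx, ] <- .par_matrix(fixed_params)
    fixed[idx] <- TRUE
    anchor_cols <- idx
  }
  if (!all(meta$role[fixed] == "anchor") && !is.null(fixed_params))
    stop("fixed parameters must correspond to anchor items")

  off <- c(0L, cumsum(meta$ncat))[seq_len(nrow(meta))]
  weights <- grid$weights
  U <- .indicator(resp, meta$ncat)
  model_code <- unname(.model_code[meta$model])

  trace <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  shared_a <- 1
  dich <- meta$model %in% .dich_models
  mcat <- meta$ncat - 1L
  for (cyc in seq_len(config$max_cycles)) {
    cycles <- cyc
    pm <- .prob_matrix_par(par, dich, mcat, grid$points, config$D)
    es <- .estep_core(U, pm$P, weights)
    trace <- c(trace, es$loglik +
                 .log_prior(par, meta, config$prior, fixed, shared_slope))
    ms <- cpp_mstep(es$counts, offset = off, ncat = meta$ncat,
                    model_code = model_code, par = par, fixed = fixed,
                    theta = grid$points, D = config$D,
                    prior_list = unclass(config$prior),
                    shared_slope = shared_slope, shared_a_init = shared_a,
                    inner_max = config$inner_max, inner_tol = 1e-7)
    newpar <- ms$par
    shared_a <- ms$shared_a
    if (config$latent_update == "posterior") {
      weights <- es$nhat / sum(es$nhat)
    }
    delta <- max(abs(newpar - par))
    par <- newpar
    if (delta < config$conv_tol) { converged <- TRUE; break }
  }

  out_df <- .par_df(par, meta)
  lat <- .latent_moments(grid, weights)
  if (config$mode == "separate" && config$latent_update == "posterior") {
    # re-standardize the exit latent distribution to mean 0, sd 1 with a
    # compensating linear transformation of the item parameters
    k <- scaling_constants(1 / lat$sd, -lat$mean / lat$sd)
    out_df <- transform_item_parameters(out_df, k)
    lat <- list(mean = 0, sd = 1)
  }
  if (!is.null(fixed_params)) {
    # fixing contract: anchor rows pass through bit-for-bit
    out_df[anchor_cols, c("a", "b", "c", "d1", "d2", "d3", "d4")] <-
      fixed_params[, c("a", "b", "c", "d1", "d2", "d3", "d4")]
  }
  structure(list(params = out_df, converged = converged, cycles = cycles,
                 logpost = trace[length(trace)], logpost_trace = trace,
                 latent_weights = weights, latent_mean = lat$mean,
                 latent_sd = lat$sd, config = config),
            class = "calibration_result")
}

#' Calibrate item parameters by marginal maximum likelihood EM
#'
#' Alternates Bock-Aitkin E-steps and penalized M-steps until the maximum
#' absolute change over all item parameters falls below `conv_tol` or
#' `max_cycles` is reached. Non-convergence is reported in the result flag,
#' never raised: the study driver applies the discard-and-regenerate rule.
#'
#' @param responses a [response_matrix()] (columns carry item structure:
#'   role, type, number of categories; parameter values are estimated fresh).
#' @param config a [calibration_config()] with `mode = "separate"`.
#' @param grid a [quadrature_grid()].
#' @return a `"calibration_result"`: estimated `params`, `converged` flag,
#'   `cycles` used, final `logpost` with its per-cycle `logpost_trace`, and
#'   the exit latent distribution (`latent_weights`, `latent_mean`,
#'   `latent_sd`).
#' @export
calibrate <- function(responses, config = calibration_config(),
                      grid = quadrature_grid()) {
  if (config$mode != "separate")
    stop("use calibrate_fcip() for FCIP mode")
  .calibrate_engine(responses, config, grid)
}

#' FCIP calibration against fixed reference anchor parameters
#'
#' Calibrates a new-year administration with the anchor item parameters
#' frozen at their reference-year values, so the unique-item estimates land
#' directly on the reference scale. The latent distribution is re-estimated
#' from the posterior each cycle and never re-standardized (no scale
#' adjustment), which lets the estimated ability distribution absorb the
#' cohort's true mean shift.
#'
#' @param responses a [response_matrix()] for the new-year (Y+A) data.
#' @param anchor_params_fixed item-parameter table of the anchor items on
#'   the reference scale; passed through to the result unchanged.
#' @param config a [calibration_config()]; its mode is forced to `"fcip"`.
#' @param grid a [quadrature_grid()].
#' @return a `"calibration_result"` on the reference scale.
#' @export
calibrate_fcip <- function(responses, anchor_params_fixed,
                           config = calibration_config(mode = "fcip"),
                           grid = quadrature_grid()) {
  if (config$mode != "fcip")
    config <- calibration_config(model_set = config$model_set,
                                 prior = config$prior,
                                 conv_tol = config$conv_tol,
                                 max_cycles = config$max_cycles,
                                 mode = "fcip",
                                 inner_max = config$inner_max, D = config$D)
  validate_item_params(anchor_params_fixed)
  items <- response_items(responses)
  anchor_ids <- items$item_id[items$role == "anchor"]
  if (!setequal(anchor_params_fixed$item_id, anchor_ids))
    stop("anchor_params_fixed must cover exactly the anchor items")
  .calibrate_engine(responses, config, grid,
                    fixed_params = anchor_params_fixed)
}
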
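# Linear scale linking: placing new-year parameter estimates on the
# reference-year scale with constants (A, B) such that theta_ref =
# A * theta_new + B, estimated from the anchor items by the mean/sigma
# method or the Stocking-Lord characteristic-curve method.

#' Scaling constants of a linear ability-scale transformation
#'
#' @param A slope (> 0).
#' @param B intercept.
#' @param method optional label (`"MS"`, `"SL"`, ...).
#' @param criterion optional criterion value at the solution (SL).
#' @return list of class `"scaling_constants"`.
#' @export
scaling_constants <- function(A, B, method = NULL, criterion = NULL) {
  if (!is.finite(A) || A <= 0 || !is.finite(B))
    stop("scaling constants need finite A > 0 and finite B")
  structure(list(A = A, B = B, method = method, criterion = criterion),
            class = "scaling_constants")
}

#' Compose two scale transformations
#'
#' Applying `k1` then `k2` equals applying `compose_constants(k1, k2)`:
#' slope `A2 * A1`, intercept `A2 * B1 + B2`.
#'
#' @param k1,k2 [scaling_constants()].
#' @return the composed [scaling_constants()].
#' @export
compose_constants <- function(k1, k2) {
  scaling_constants(k2$A * k1$A, k2$A * k1$B + k2$B)
}

#' Inverse of a scale transformation
#' @param k a [scaling_constants()].
#' @return constants `(1/A, -B/A)` undoing `k`.
#' @export
invert_constants <- function(k) scaling_constants(1 / k$A, -k$B / k$A)

.align_anchors <- function(anchor_x, anchor_y) {
  validate_item_params(anchor_x)
  validate_item_params(anchor_y)
  if (!setequal(anchor_x$item_id, anchor_y$item_id) ||
      nrow(anchor_x) != nrow(anchor_y))
    stop("anchor sets must contain the same item ids")
  anchor_y[match(anchor_x$item_id, anchor_y$item_id), , drop = FALSE]
}

# Mixed-format difficulty pool: all dichotomous b's plus, for each
# polytomous item, its m step locations b - d_k (Loyd-Hoover-style
# extension); optionally locations only.
.b_pool <- function(df, pool = c("steps", "locations")) {
  pool <- match.arg(pool)
  out <- numeric(0)
  for (j in seq_len(nrow(df))) {
    if (df$model[j] %in% .dich_models || pool == "locations") {
      out <- c(out, df$b[j])
    } else {
      dv <- unlist(df[j, c("d1", "d2", "d3", "d4")], use.names = FALSE)
      dv <- dv[!is.na(dv)]
      out <- c(out, df$b[j] - dv)
    }
  }
  out
}

#' Mean/sigma linking constants
#'
#' `A = sd(b-pool X) / sd(b-pool Y)`, `B = mean(b-pool X) - A * mean(b-pool
#' Y)`, where the b-pool contains every dichotomous anchor difficulty plus,
#' for each polytomous anchor item, its step locations `b - d_k` (set
#' `pool = "locations"` for the location-only variant).
#'
#' @param anchor_x,anchor_y anchor item-parameter estimates from the
#'   reference and new administrations, aligned by item id.
#' @param pool `"steps"` (default) or `"locations"`.
#' @return [scaling_constants()] placing the Y scale onto the X scale.
#' @export
ms_constants <- function(anchor_x, anchor_y, pool = c("steps", "locations")) {
  anchor_y <- .align_anchors(anchor_x, anchor_y)
  bx <- .b_pool(anchor_x, pool)
  by <- .b_pool(anchor_y, pool)
  if (sd(bx) < 1e-12 || sd(by) < 1e-12)
    stop("zero variance in an anchor difficulty pool")
  A <- sd(bx) / sd(by)
  scaling_constants(A, mean(bx) - A * mean(by), method = "MS")
}

#' Stocking-Lord linking constants
#'
#' Finds `(A, B)` minimizing the sum over the quadrature nodes of the
#' squared difference between the reference anchor test characteristic
#' curve and the new-year anchor TCC after transforming the new-year
#' parameters by `(A, B)` (one-directional criterion, new onto reference).
#' Initialized at the mean/sigma solution; derivative-free Nelder-Mead
#' polished by a restart.
#'
#' @inheritParams ms_constants
#' @param grid a [quadrature_grid()] supplying the criterion nodes
#'   (default: 60 equally spaced on `[-4, 4]`).
#' @param D logistic scaling constant.
#' @param init optional [scaling_constants()] starting values.
#' @return [scaling_constants()] with the attained `criterion` value.
#' @export
sl_constants <- function(anchor_x, anchor_y, grid = quadrature_grid(),
                         D = default_D(), init = NULL) {
  anchor_y <- .align_anchors(anchor_x, anchor_y)
  nodes <- grid$points
  tcc_x <- tcc(anchor_x, nodes, D)
  par_y <- as.matrix(anchor_y[, c("a", "b", "c", "d1", "d2", "d3", "d4")])
  par_y[is.na(par_y)] <- 0
  dich <- anchor_y$model %in% .dich_models
  mcat <- item_ncat(anchor_y) - 1L
  crit <- function(p) {
    if (p[1] <= 0) return(Inf)
    tp <- par_y
    tp[, 1] <- par_y[, 1] / p[1]
    tp[, 2] <- p[1] * par_y[, 2] + p[2]
    tp[, 4:7] <- p[1] * par_y[, 4:7]
    sum((tcc_x - .tcc_par(tp, dich, mcat, nodes, D))^2)
  }
  if (is.null(init)) {
    init <- tryCatch(ms_constants(anchor_x, anchor_y),
                     error = function(e) scaling_constants(1, 0))
  }
  p0 <- c(init$A, init$B)
  fit <- optim(p0, crit, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000L))
  fit <- optim(fit$par, crit, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000L))
  if (!is.finite(fit$value))
    stop("Stocking-Lord criterion did not converge")
  scaling_constants(fit$par[1], fit$par[2], method = "SL",
                    criterion = fit$value)
}

#' Transform item parameters to a new ability scale
#'
#' Under `theta_new = A * theta_old + B`: `a -> a / A`, `b -> A * b + B`,
#' `c` unchanged, and for polytomous items `d_k -> A * d_k`. Response
#' probabilities are invariant: `P(theta; original) = P(A * theta + B;
#' transformed)` for every theta.
#'
#' @param params item-parameter table.
#' @param k a [scaling_constants()].
#' @return the transformed item-parameter table.
#' @export
transform_item_parameters <- function(params, k) {
  validate_item_params(params)
  if (!inherits(k, "scaling_constants")) k <- scaling_constants(k[[1]], k[[2]])
  out <- params
  out$a <- params$a / k$A
  out$b <- k$A * params$b + k$B
  for (col in c("d1", "d2", "d3", "d4"))
    out[[col]] <- k$A * params[[col]]
  validate_item_params(out)
  out
}
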
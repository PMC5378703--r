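test_that("E-step posteriors match enumeration and conserve examinees", {
  # 2-item toy, 3 examinees, 3-node grid: hand-computed Bayes posteriors
  items <- item_params(c("i1", "i2"), "unique", "MC", "2PL",
                       a = c(1.0, 1.5), b = c(-0.5, 0.5))
  grid <- quadrature_grid(3, -1, 1)
  X <- rbind(c(1L, 0L), c(0L, 0L), c(1L, 1L))
  resp <- response_matrix(X, items)
  es <- estep(resp, items, grid)

  P <- sapply(1:2, function(j) prob_dichotomous(items[j, ], grid$points))
  post_want <- matrix(0, 3, 3)
  for (i in 1:3) {
    lik <- apply(sapply(1:2, function(j)
      if (X[i, j] == 1) P[, j] else 1 - P[, j]), 1, prod)
    post_want[i, ] <- lik * grid$weights / sum(lik * grid$weights)
  }
  expect_equal(es$post, post_want, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(es$nhat), 3, tolerance = 3e-6)
  # per-item category counts at each node sum to that node's count
  for (j in 1:2) {
    rows <- which(es$row_item == j)
    expect_equal(colSums(es$counts[rows, ]), es$nhat, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # expected counts match the enumeration directly
  r1 <- rbind(colSums(post_want[X[, 1] == 0, , drop = FALSE]),
              colSums(post_want[X[, 1] == 1, , drop = FALSE]))
  expect_equal(es$counts[1:2, ], r1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("items with flat likelihood leave the posterior at the prior", {
  # near-zero slope: response probabilities constant in theta
  items <- item_params(c("f1", "f2"), "unique", "MC", "3PL",
                       a = 1e-9, b = 0, c = 0.2)
  grid <- quadrature_grid(5)
  resp <- response_matrix(cbind(c(1L, 0L, 1L), c(0L, 1L, 1L)), items)
  es <- estep(resp, items, grid)
  for (i in 1:3)
    expect_equal(es$post[i, ], grid$weights, tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("M-step is stationary at exact counts and matches grid oracles", {
  grid <- quadrature_grid(21)
  th <- grid$points
  pr_off <- prior_spec(on = FALSE)
  pr_on <- prior_spec()

  # stationary point: counts generated exactly at the current parameters
  counts <- expected_counts_dich(1.3, 0.4, 0, th, n_per_node = 1e4)
  up <- mstep_item(counts, "2PL", pr_off, list(a = 1.3, b = 0.4), th)
  expect_lt(max(abs(c(up$a - 1.3, up$b - 0.4))), 1e-3)

  # 2PL argmax vs brute-force nested grid search on (a, b)
  counts2 <- expected_counts_dich(0.9, -0.3, 0, th,
                                  n_per_node = 50 * grid$weights * 21)
  up2 <- mstep_item(counts2, "2PL", pr_on, list(a = 1, b = 0), th)
  gridmax <- function(avals, bvals) {
    best <- c(NA, NA); fbest <- -Inf
    for (a in avals) for (b in bvals) {
      f <- pen_obj_2pl(a, b, counts2, th, pr_on)
      if (f > fbest) { fbest <- f; best <- c(a, b) }
    }
    best
  }
  coarse <- gridmax(seq(0.2, 2.5, by = 0.01), seq(-3, 3, by = 0.01))
  fine <- gridmax(seq(coarse[1] - 0.02, coarse[1] + 0.02, by = 1e-3),
                  seq(coarse[2] - 0.02, coarse[2] + 0.02, by = 1e-3))
  expect_lt(abs(up2$a - fine[1]), 2e-3)
  expect_lt(abs(up2$b - fine[2]), 2e-3)

  # ascent property on the penalized objective
  expect_gte(up2$objective, pen_obj_2pl(1, 0, counts2, th, pr_on) - 1e-10)
})

test_that("the guessing prior pulls c toward its mean when data carry no information", {
  grid <- quadrature_grid(21)
  th <- grid$points
  # counts only at high-ability nodes: no information about the asymptote
  n_node <- ifelse(th >= 1, 500, 0)
  counts <- expected_counts_dich(1.2, 0, 0.35, th, n_node)
  up <- mstep_item(counts, "3PL", prior_spec(), list(a = 1.2, b = 0, c = 0.35),
                   th)
  expect_lt(up$c, 0.35)   # shrunk from the start toward the Beta(8, 32) mean
  expect_lt(abs(up$c - 0.2), abs(0.35 - 0.2))

  # limiting case of no information at all: the penalized argmax is the
  # prior mode, checked by a 1-D grid oracle over the Beta penalty
  zero <- matrix(0, 2, length(th))
  up0 <- mstep_item(zero, "3PL", prior_spec(),
                    list(a = 1.2, b = 0.5, c = 0.35), th)
  cgrid <- seq(0.001, 0.6, by = 5e-4)
  c_oracle <- cgrid[which.max((8 - 1) * log(cgrid) +
                                (32 - 1) * log(1 - cgrid))]
  expect_lt(abs(up0$c - c_oracle), 1e-3)
  expect_equal(up0$a, 1, tolerance = 1e-4)   # log-normal prior mode
  expect_equal(up0$b, 0, tolerance = 1e-4)
})

test_that("EM calibration ascends, converges, and flags non-convergence", {
  pars <- generate_item_parameters(seed = 21)
  th <- generate_abilities(1200, 0, seed = 22)
  resp <- simulate_responses(pars$form_x, th, seed = 23)
  grid <- quadrature_grid(31)

  fit <- calibrate(resp, calibration_config(), grid)
  expect_true(fit$converged)
  expect_lte(fit$cycles, 200)
  tr <- fit$logpost_trace
  expect_true(all(diff(tr) > -1e-8 * abs(tr[1])))

  short <- calibrate(resp, calibration_config(max_cycles = 2), grid)
  expect_false(short$converged)
  expect_equal(short$cycles, 2)

  # shared-slope constraint of the 1PL/PC set
  fit1 <- calibrate(resp, calibration_config(model_set = "1PL/1PL/PC",
                                             max_cycles = 50), grid)
  expect_equal(length(unique(fit1$params$a)), 1L)
  expect_true(all(fit1$params$c == 0))
  tr1 <- fit1$logpost_trace
  expect_true(all(diff(tr1) > -1e-8 * abs(tr1[1])))
})

test_that("EM matches direct marginal-likelihood maximization on a 1PL toy", {
  items <- item_params(paste0("t", 1:3), "unique", "MC", "1PL",
                       a = 1.2, b = c(-0.8, 0.1, 0.9))
  th <- generate_abilities(1500, 0, seed = 24)
  resp <- simulate_responses(items, th, seed = 25)
  grid <- quadrature_grid(21)
  fit <- calibrate(resp, calibration_config(model_set = "1PL/1PL/PC",
                                            prior = prior_spec(on = FALSE),
                                            conv_tol = 1e-5,
                                            max_cycles = 500), grid)
  expect_true(fit$converged)

  # independent optimizer on the marginal likelihood itself
  X <- unclass(resp)
  negml <- function(p) {
    a <- exp(p[1])
    P <- sapply(p[2:4], function(bb) plogis(1.7 * a * (grid$points - bb)))
    like <- matrix(1, nrow(X), length(grid$points))
    for (j in 1:3)
      like <- like * t(ifelse(outer(P[, j], X[, j], function(pp, x) x == 1),
                              P[, j], 1 - P[, j]))
    -sum(log(like %*% grid$weights))
  }
  o <- optim(c(0, -1, 0, 1), negml, control = list(reltol = 1e-14,
                                                   maxit = 5000))
  o <- optim(o$par, negml, method = "BFGS",
             control = list(reltol = 1e-12, maxit = 1000))
  expect_lt(max(abs(c(exp(o$par[1]) - fit$params$a[1],
                      o$par[2:4] - fit$params$b))), 1e-2)
})

test_that("posterior latent updates re-standardize to the fixed-weights scale", {
  pars <- generate_item_parameters(seed = 91)
  th <- generate_abilities(2000, 0.4, seed = 92)
  resp <- simulate_responses(pars$form_x, th, seed = 93)
  g <- quadrature_grid(41)
  f_fix <- calibrate(resp, calibration_config(), g)
  f_pos <- calibrate(resp, calibration_config(latent_update = "posterior"), g)
  # exit distribution standardized to mean 0, sd 1
  expect_equal(f_pos$latent_mean, 0, tolerance = 1e-9)
  expect_equal(f_pos$latent_sd, 1, tolerance = 1e-9)
  # estimates land on the same scale as the fixed-weights calibration
  expect_gt(cor(f_fix$params$b, f_pos$params$b), 0.999)
  expect_lt(abs(mean(f_fix$params$b - f_pos$params$b)), 0.1)
})

test_that("FCIP fixes anchors bit-for-bit and recovers the built-in shift", {
  pars <- generate_item_parameters(seed = 26)
  form_ya <- rbind(pars$form_y, pars$anchor)
  th <- generate_abilities(2000, 0.25, seed = 27)
  resp <- simulate_responses(form_ya, th, seed = 28)
  grid <- quadrature_grid(41)
  fit <- calibrate_fcip(resp, pars$anchor, calibration_config(mode = "fcip"),
                        grid)
  got <- as.matrix(fit$params[fit$params$role == "anchor",
                              c("a", "b", "c", "d1", "d2", "d3", "d4")])
  want <- as.matrix(pars$anchor[, c("a", "b", "c", "d1", "d2", "d3", "d4")])
  dimnames(got) <- dimnames(want) <- NULL
  expect_identical(got, want)
  expect_lt(abs(fit$latent_mean - 0.25), 0.08)

  # mis-configuration guard: FCIP never runs with a fixed latent prior
  expect_error(calibration_config(mode = "fcip", latent_update = "fixed"),
               "posterior")
  expect_error(calibrate(resp, calibration_config(mode = "fcip"), grid),
               "calibrate_fcip")
  # anchor coverage is mandatory
  expect_error(calibrate_fcip(resp, pars$anchor[1:10, ],
                              calibration_config(mode = "fcip"), grid),
               "anchor")
})
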
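test_that("mean/sigma constants match the closed form on hand pools", {
  ax <- item_params(paste0("a", 1:3), "anchor", "SR", "2PL",
                    a = 1, b = c(-1, 0, 1))
  ay <- item_params(paste0("a", 1:3), "anchor", "SR", "2PL",
                    a = 1, b = c(-0.5, 0.5, 1.5))
  k <- ms_constants(ax, ay)
  expect_equal(k$A, 1, tolerance = 1e-12)
  expect_equal(k$B, -0.5, tolerance = 1e-12)

  expect_equal(unclass(ms_constants(ax, ax))[c("A", "B")], list(A = 1, B = 0),
               tolerance = 1e-12)

  # zero-variance pool rejected
  az <- item_params(paste0("a", 1:3), "anchor", "SR", "2PL", a = 1, b = 0.3)
  expect_error(ms_constants(ax, az), "variance")
  # alignment strictly by item id
  expect_error(ms_constants(ax, ay[1:2, ]), "same item ids")

  # polytomous anchors contribute their step locations b - d_k
  axp <- rbind(ax, item_params("g1", "anchor", "CR", "GPC", a = 1, b = 0.2,
                               d = matrix(c(0.6, 0.2, -0.2, -0.6), 1)))
  ayp <- rbind(ay, item_params("g1", "anchor", "CR", "GPC", a = 1, b = 0.7,
                               d = matrix(c(0.6, 0.2, -0.2, -0.6), 1)))
  poolx <- c(-1, 0, 1, 0.2 - c(0.6, 0.2, -0.2, -0.6))
  pooly <- c(-0.5, 0.5, 1.5, 0.7 - c(0.6, 0.2, -0.2, -0.6))
  kp <- ms_constants(axp, ayp)
  A_want <- sd(poolx) / sd(pooly)
  expect_equal(kp$A, A_want, tolerance = 1e-12)
  expect_equal(kp$B, mean(poolx) - A_want * mean(pooly), tolerance = 1e-12)
})

test_that("affine anchor images are recovered exactly by mean/sigma", {
  set.seed(31)
  ax <- generate_item_parameters(seed = 32)$anchor
  A0 <- 1.35; B0 <- -0.4
  ay <- transform_item_parameters(ax, invert_constants(
    scaling_constants(A0, B0)))
  k <- ms_constants(ax, ay)
  expect_equal(k$A, A0, tolerance = 1e-9)
  expect_equal(k$B, B0, tolerance = 1e-9)
  back <- transform_item_parameters(ay, k)
  expect_equal(back$b, ax$b, tolerance = 1e-9)
  expect_equal(back$a, ax$a, tolerance = 1e-9)
})

test_that("Stocking-Lord recovers planted constants and beats mean/sigma", {
  anchor <- generate_item_parameters(seed = 33)$anchor
  # identity: criterion has an exact zero
  ki <- sl_constants(anchor, anchor)
  expect_equal(ki$A, 1, tolerance = 1e-6)
  expect_equal(ki$B, 0, tolerance = 1e-6)
  expect_lt(ki$criterion, 1e-10)

  # planted transformation (A0, B0) = (1.2, 0.3)
  ay <- transform_item_parameters(anchor, invert_constants(
    scaling_constants(1.2, 0.3)))
  k <- sl_constants(anchor, ay)
  expect_lt(abs(k$A - 1.2), 1e-4)
  expect_lt(abs(k$B - 0.3), 1e-4)

  # perturbed anchors: SL criterion at its optimum is no worse than at the
  # mean/sigma solution, and matches a nested 2-D grid search
  set.seed(34)
  ay2 <- ay
  ay2$b <- ay2$b + rnorm(39, 0, 0.08)
  ay2$a <- pmax(ay2$a * exp(rnorm(39, 0, 0.05)), 0.2)
  grid <- quadrature_grid()
  crit <- function(A, B) {
    tp <- transform_item_parameters(ay2, scaling_constants(A, B))
    sum((tcc(anchor, grid$points) - tcc(tp, grid$points))^2)
  }
  ksl <- sl_constants(anchor, ay2, grid)
  kms <- ms_constants(anchor, ay2)
  expect_lte(ksl$criterion, crit(kms$A, kms$B) + 1e-9)

  gridmin <- function(avals, bvals) {
    best <- c(NA, NA); fbest <- Inf
    for (A in avals) for (B in bvals) {
      f <- crit(A, B)
      if (f < fbest) { fbest <- f; best <- c(A, B) }
    }
    best
  }
  coarse <- gridmin(seq(0.5, 2, by = 0.01), seq(-1, 1, by = 0.01))
  fine <- gridmin(seq(coarse[1] - 0.02, coarse[1] + 0.02, by = 1e-3),
                  seq(coarse[2] - 0.02, coarse[2] + 0.02, by = 1e-3))
  expect_lt(abs(ksl$A - fine[1]), 1.5e-3)
  expect_lt(abs(ksl$B - fine[2]), 1.5e-3)
})

test_that("parameter transformations compose, invert, and preserve c", {
  toy <- tiny_form()
  expect_equal(transform_item_parameters(toy, scaling_constants(1, 0)), toy,
               tolerance = 1e-15)
  it <- item_params("x", "unique", "MC", "3PL", a = 1.2, b = 0.5, c = 0.15)
  tf <- transform_item_parameters(it, scaling_constants(1.1, -0.2))
  expect_equal(tf$a, 1.2 / 1.1, tolerance = 1e-12)
  expect_equal(tf$b, 1.1 * 0.5 - 0.2, tolerance = 1e-12)
  expect_equal(tf$c, 0.15, tolerance = 1e-15)

  set.seed(35)
  for (i in 1:5) {
    k1 <- scaling_constants(runif(1, 0.5, 2), runif(1, -1, 1))
    k2 <- scaling_constants(runif(1, 0.5, 2), runif(1, -1, 1))
    two <- transform_item_parameters(transform_item_parameters(toy, k1), k2)
    one <- transform_item_parameters(toy, compose_constants(k1, k2))
    expect_equal(two, one, tolerance = 1e-12)
    rt <- transform_item_parameters(transform_item_parameters(toy, k1),
                                    invert_constants(k1))
    expect_equal(rt, toy, tolerance = 1e-12)
  }
  expect_error(scaling_constants(-1, 0), "A > 0")
})
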
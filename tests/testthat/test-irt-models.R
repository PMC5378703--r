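test_that("dichotomous response functions match closed-form evaluations", {
  it <- item_params("m1", "unique", "MC", "3PL", a = 1, b = 0, c = 0.2)
  expect_equal(prob_dichotomous(it[1, ], 0), 0.6, tolerance = 1e-12)

  it2 <- item_params("m2", "unique", "SR", "2PL", a = 1.3, b = 0.7)
  expect_equal(prob_dichotomous(it2[1, ], 0.7), 0.5, tolerance = 1e-12)

  # independent hand evaluation of the closed form
  it3 <- item_params("m3", "unique", "MC", "3PL", a = 1.2, b = 0.5, c = 0.15)
  want <- 0.15 + 0.85 / (1 + exp(-1.7 * 1.2 * (1.0 - 0.5)))
  expect_equal(prob_dichotomous(it3[1, ], 1.0), want, tolerance = 1e-12)

  # monotone in theta, bounded by (c, 1)
  th <- seq(-4, 4, length.out = 101)
  p <- prob_dichotomous(it3[1, ], th)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0.15 & p < 1))
})

test_that("category probabilities normalize, match brute force, reduce to 2PL", {
  itg <- item_params("g1", "unique", "CR", "GPC", a = 1, b = 0,
                     d = matrix(c(0.5, 0.2, -0.2, -0.5), 1))
  # brute-force cumulative-sum oracle at theta = 0.3
  want <- gpc_prob_oracle(1, 0, c(0.5, 0.2, -0.2, -0.5), 0.3)
  expect_equal(as.numeric(prob_categories(itg[1, ], 0.3)), want,
               tolerance = 1e-12)
  expect_equal(expected_item_score(itg[1, ], 0.3), sum(0:4 * want),
               tolerance = 1e-12)

  # normalization on a 100-point grid for random valid items
  set.seed(11)
  th <- seq(-4, 4, length.out = 100)
  for (i in 1:10) {
    d <- rnorm(4); d <- d - mean(d)
    it <- item_params("x", "unique", "CR", "GPC", a = runif(1, 0.4, 2),
                      b = rnorm(1), d = matrix(d, 1))
    P <- prob_categories(it[1, ], th)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    # expected category index strictly increasing in theta
    expect_true(all(diff(as.numeric(P %*% 0:4)) > 0))
  }

  # GPC with two categories and d1 = 0 is exactly the 2PL
  for (i in 1:100) {
    a <- runif(1, 0.3, 2.5); b <- rnorm(1)
    it <- item_params("r", "unique", "SR", "GPC", a = a, b = b,
                      d = matrix(c(0, NA, NA, NA), 1))
    it2 <- item_params("r2", "unique", "SR", "2PL", a = a, b = b)
    th1 <- rnorm(1)
    expect_equal(prob_categories(it[1, ], th1)[1, 2],
                 prob_dichotomous(it2[1, ], th1), tolerance = 1e-12)
  }
})

test_that("test characteristic curves saturate at their bounds and sum itemwise", {
  form <- saturating_form()
  # lower asymptote: 29 items with c = 0.2
  expect_equal(tcc(form, -10), 5.8, tolerance = 1e-3)
  expect_equal(tcc(form, 10), 54, tolerance = 1e-3)
  expect_equal(tcc(form, -40), 5.8, tolerance = 1e-12)
  expect_equal(tcc(form, 40), 54, tolerance = 1e-12)

  # itemwise summation oracle on the 5-item toy form
  toy <- tiny_form()
  want <- sum(vapply(1:5, function(j) expected_item_score(toy[j, ], 0), 0))
  expect_equal(tcc(toy, 0), want, tolerance = 1e-12)

  # strictly increasing on a grid
  th <- seq(-4, 4, length.out = 201)
  expect_true(all(diff(tcc(toy, th)) > 0))
  expect_error(tcc(toy[0, ], 0), "nonempty")
})

test_that("probabilities are invariant under linear scale transformation", {
  set.seed(12)
  toy <- tiny_form()
  for (i in 1:10) {
    A <- runif(1, 0.5, 2); B <- runif(1, -1, 1)
    k <- scaling_constants(A, B)
    tf <- transform_item_parameters(toy, k)
    th <- rnorm(5)
    expect_equal(tcc(tf, A * th + B), tcc(toy, th), tolerance = 1e-12)
    for (j in c(1, 3)) {
      expect_equal(prob_dichotomous(tf[j, ], A * th + B),
                   prob_dichotomous(toy[j, ], th), tolerance = 1e-12)
    }
    expect_equal(prob_categories(tf[4, ], A * th + B),
                 prob_categories(toy[4, ], th), tolerance = 1e-12)
  }
})

test_that("invalid item parameters and abilities are rejected", {
  expect_error(item_params("a", "unique", "MC", "3PL", a = -1, b = 0, c = 0.2),
               "a must be")
  expect_error(item_params("a", "unique", "MC", "3PL", a = 1, b = Inf, c = 0.2),
               "b must be")
  expect_error(item_params("a", "unique", "MC", "3PL", a = 1, b = 0, c = 1.2),
               "c must")
  expect_error(item_params("a", "unique", "CR", "GPC", a = 1, b = 0,
                           d = matrix(c(0.5, 0.2, -0.1, -0.5), 1)),
               "sum to zero")
  it <- item_params("a", "unique", "MC", "2PL", a = 1, b = 0)
  expect_error(prob_dichotomous(it[1, ], NaN), "finite")
  # 1PL/2PL difference is only the slope-sharing convention; both validate
  expect_silent(validate_item_params(
    item_params(c("a", "b"), "unique", "MC", "1PL", a = 1, b = c(0, 1))))
})
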
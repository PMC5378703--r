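make_table <- function(e, extrapolated = NULL) {
  s <- seq_along(e) - 1L
  if (is.null(extrapolated)) extrapolated <- rep(FALSE, length(e))
  out <- data.frame(nc_score = s, equated_score = e,
                    theta = ifelse(extrapolated, NA_real_, s / 10),
                    extrapolated = extrapolated)
  class(out) <- c("conversion_table", "data.frame")
  out
}

identity_table <- function(S = 54) make_table(0:S)

test_that("equating error statistics follow their definitions", {
  tt <- identity_table()
  # estimated identical to truth in every replication
  z <- equating_errors(list(tt, tt, tt), tt, score_range = 6:53)
  expect_true(all(z$mee == 0) && all(z$rmsee == 0) && z$remsee == 0)

  # constant error +0.3 everywhere
  shifted <- make_table(0:54 + 0.3)
  one <- equating_errors(list(shifted), tt, score_range = 6:53)
  expect_lt(max(abs(one$mee - 0.3)), 1e-12)
  expect_lt(max(abs(one$rmsee - 0.3)), 1e-12)
  expect_equal(one$remsee, 0.3, tolerance = 1e-12)

  # symmetric cancellation: +0.3 and -0.3
  minus <- make_table(0:54 - 0.3)
  two <- equating_errors(list(shifted, minus), tt, score_range = 6:53)
  expect_lt(max(abs(two$mee)), 1e-12)
  expect_lt(max(abs(two$rmsee - 0.3)), 1e-12)

  # RMSEE >= |MEE| everywhere; invariance to replication order
  set.seed(51)
  tabs <- lapply(1:6, function(i) make_table(0:54 + rnorm(55, 0, 0.1)))
  a <- equating_errors(tabs, tt, 6:53)
  expect_true(all(a$rmsee >= abs(a$mee) - 1e-12))
  b <- equating_errors(rev(tabs), tt, 6:53)
  expect_equal(a$remsee, b$remsee, tolerance = 1e-12)

  expect_error(equating_errors(list(make_table(0:10)), tt, 6:53), "cover")
})

test_that("the DTM flag fires at and above half a score point", {
  expect_true(flag_practical_significance(0.5))
  expect_false(flag_practical_significance(0.49))
  expect_false(flag_practical_significance(0))
  expect_true(flag_practical_significance(1.11))
  expect_error(flag_practical_significance(-0.1), "nonnegative")
})

test_that("cut scores derive by monotone interpolation of the table", {
  tt <- identity_table()
  cuts <- derive_cut_scores(tt)
  expect_equal(cuts$y_cuts, c(21, 37, 49), tolerance = 1e-12)

  # e(s) = s - 1: the Form Y score equated to X cut 37 is 38
  tm1 <- make_table(0:54 - 1)
  expect_equal(derive_cut_scores(tm1)$y_cuts, c(22, 38, 50),
               tolerance = 1e-12)

  # fractional interpolation
  half <- make_table(0:54 - 0.5)
  expect_equal(derive_cut_scores(half)$y_cuts, c(21.5, 37.5, 49.5),
               tolerance = 1e-12)

  # monotone image; strictly increasing cuts
  set.seed(52)
  etab <- make_table(cumsum(runif(55, 0.5, 1.5)))
  yc <- derive_cut_scores(etab,
                          x_cuts = quantile(etab$equated_score,
                                            c(0.3, 0.6, 0.9)))$y_cuts
  expect_true(all(diff(yc) > 0))
  expect_error(derive_cut_scores(tt, x_cuts = c(21, 37, 80)), "outside")
})

test_that("classification uses the at-or-above convention", {
  tt <- identity_table()
  cuts <- derive_cut_scores(tt)
  got <- classify(c(20, 21, 37, 49), cuts)
  expect_equal(as.integer(got), c(0L, 1L, 2L, 3L))
  expect_true(all(classify(rep(54, 5), cuts) == 3L))
  expect_true(all(classify(rep(0, 5), cuts) == 0L))
  # boundary exactly at a fractional cut
  got2 <- classify(c(37, 38), c(10.5, 37.5, 50.5))
  expect_equal(as.integer(got2), c(1L, 2L))
  expect_error(classify(c(-1, 2), cuts), "0..54")
  expect_error(classify(55, cuts), "0..54")
})

test_that("classification reports honor identities and sign conventions", {
  same <- c(0L, 1L, 2L, 3L, 2L)
  r0 <- classification_report(same, same)
  expect_equal(r0$accuracy, 100)
  expect_equal(r0$over, 0)
  expect_equal(r0$under, 0)
  expect_equal(r0$passing_misclassification, 0)

  # 10 examinees, one bumped up across the pass cut
  true <- rep(1L, 10)
  est <- true; est[4] <- 2L
  r1 <- classification_report(est, true)
  expect_equal(r1$over, 10)
  expect_equal(r1$under, 0)
  expect_equal(r1$accuracy, 90)
  expect_equal(r1$passing_misclassification, 10)

  # under-estimated passing rate gives a negative misclassification
  est2 <- c(2L, 2L, 1L, 1L)
  true2 <- c(2L, 2L, 2L, 1L)
  r2 <- classification_report(est2, true2)
  expect_lt(r2$passing_misclassification, 0)
  expect_equal(r2$passing_misclassification,
               r2$passing_estimated - r2$passing_true, tolerance = 1e-12)

  # identity holds on random vectors
  set.seed(53)
  for (i in 1:10) {
    a <- sample(0:3, 97, replace = TRUE)
    b <- sample(0:3, 97, replace = TRUE)
    r <- classification_report(a, b)
    expect_equal(r$accuracy + r$over + r$under, 100, tolerance = 1e-9)
  }
  expect_error(classification_report(1:3, 1:4), "equal length")
})

test_that("classifying under the true table against itself is error-free", {
  pars <- generate_item_parameters(seed = 54)
  tt <- true_score_conversion(pars$form_y, pars$form_x)
  cuts <- derive_cut_scores(tt)
  scores <- sample(0:54, 500, replace = TRUE)
  r <- classification_report(classify(scores, cuts), classify(scores, cuts))
  expect_equal(r$accuracy, 100)
  expect_equal(r$passing_misclassification, 0)
})
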
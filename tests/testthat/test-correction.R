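# Closed-form normal-equations OLS, independent of fit_correction
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

test_that("fit_correction recovers exact linear relations", {
  x <- c(10, 20, 30, 40, 50)
  id <- fit_correction(x, x)
  expect_equal(id$intercept, 0, tolerance = 1e-12)
  expect_equal(id$slope, 1, tolerance = 1e-12)
  f <- fit_correction(x, 2 * x - 5)
  expect_equal(f$intercept, -5, tolerance = 1e-12)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$n_fit, 5L)
  expect_error(fit_correction(x, x[-1]), "paired")
  expect_error(fit_correction(x[1:2], x[1:2]), "at least 3")
  expect_error(fit_correction(rep(1, 5), x), "constant")
})

test_that("fit_correction matches the normal-equations oracle", {
  withr::local_seed(99)
  for (rep in 1:20) {
    x <- runif(50, 0, 100)
    y <- 5 + 0.9 * x + rnorm(50, 0, 8)
    f <- fit_correction(x, y)
    o <- ols_oracle(x, y)
    expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
    expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-10)
  }
})

test_that("apply_correction clips into bounds and flags it", {
  f <- structure(list(intercept = -10, slope = 1, lower = 0, upper = 100,
                      n_fit = 10L), class = "linear_correction")
  out <- apply_correction(c(5, 50, 115), f)
  expect_equal(as.numeric(out), c(0, 40, 100))
  expect_equal(was_clipped(out), c(TRUE, FALSE, TRUE))
  # identity correction leaves values alone
  idf <- structure(list(intercept = 0, slope = 1, lower = 0, upper = 100,
                        n_fit = 10L), class = "linear_correction")
  v <- c(0, 33.3, 100)
  expect_equal(as.numeric(apply_correction(v, idf)), v)
  # intensity upper clip at 3
  fi <- structure(list(intercept = 0.4, slope = 1, lower = 0, upper = 3,
                       n_fit = 10L), class = "linear_correction")
  oi <- apply_correction(3, fi)
  expect_equal(as.numeric(oi), 3)
  expect_true(was_clipped(oi))
  # monotone non-decreasing for non-negative slope
  withr::local_seed(1)
  v <- sort(runif(100, -50, 150))
  expect_true(all(diff(as.numeric(apply_correction(v, f))) >= 0))
})

test_that("leave-one-out on exactly linear data reproduces expert values", {
  x <- seq(5, 95, length.out = 12)
  y <- 0.5 + 0.9 * x
  pred <- cv_correct_expert_cores(x, y, c(0, 100), k_folds = 12, seed = 1)
  expect_equal(as.numeric(pred), y, tolerance = 1e-9)
})

test_that("cross-validated predictions never use the core's own pair", {
  withr::local_seed(7)
  n <- 40
  x <- runif(n, 0, 100)
  y <- pmin(pmax(2 + 0.85 * x + rnorm(n, 0, 6), 0), 100)
  pred <- cv_correct_expert_cores(x, y, c(0, 100), k_folds = 10, seed = 3)
  folds <- attr(pred, "folds")
  expect_equal(sort(unique(folds)), 1:10)
  # direct refit oracle: prediction i equals the clipped fit on the
  # complement of i's fold
  for (i in c(1, 17, 40)) {
    keep <- folds != folds[i]
    o <- ols_oracle(x[keep], y[keep])
    expect_equal(as.numeric(pred)[i],
                 min(max(o["intercept"] + o["slope"] * x[i], 0), 100),
                 tolerance = 1e-10)
  }
  # perturbing core i's expert value, folds held fixed, leaves its own
  # prediction unchanged (it only enters through other cores' fits)
  y2 <- y
  y2[17] <- y2[17] + 25
  pred2 <- cv_correct_expert_cores(x, y2, c(0, 100), k_folds = 10,
                                   seed = 3)
  expect_identical(attr(pred2, "folds"), folds)
  expect_equal(as.numeric(pred2)[17], as.numeric(pred)[17])
  # ...but does change predictions of cores in other folds
  other <- which(folds != folds[17])
  expect_false(isTRUE(all.equal(as.numeric(pred2)[other],
                                as.numeric(pred)[other])))
  expect_error(cv_correct_expert_cores(x[1:5], y[1:5], k_folds = 6),
               "k_folds")
})

test_that("correct_all routes expert cores through CV and others not", {
  withr::local_seed(21)
  n <- 60
  cs <- data.frame(core_id = sprintf("c%02d", 1:n), marker_id = "M1",
                   proportion = runif(n, 0, 90) + 5,
                   intensity = runif(n, 1, 3))
  exp_idx <- 1:20
  es <- data.frame(core_id = cs$core_id[exp_idx], marker_id = "M1",
                   proportion = pmin(pmax(cs$proportion[exp_idx] - 8 +
                                            rnorm(20, 0, 3), 0), 100),
                   intensity = pmin(cs$intensity[exp_idx] + 0.1, 3))
  out <- correct_all(cs, es, k_folds = 10, seed = 1)
  expect_equal(nrow(out), n)
  expect_equal(sum(out$was_cv), 20L)
  expect_setequal(out$core_id[out$was_cv], es$core_id)
  expect_true(all(out$h_score >= 0 & out$h_score <= 300))
  expect_equal(out$h_score,
               out$proportion_corrected * out$intensity_corrected)
  # non-expert cores use the single full fit
  fits <- attr(out, "corrections")$M1
  manual <- fits$proportion$intercept +
    fits$proportion$slope * cs$proportion[21:60]
  expect_equal(out$proportion_corrected[21:60],
               pmin(pmax(manual, 0), 100))
  # all cores expert-scored: every correction cross-validated
  all_cv <- correct_all(cs[exp_idx, ], es, k_folds = 10, seed = 1)
  expect_true(all(all_cv$was_cv))
  expect_error(correct_all(cs, es[0, ]), "empty expert")
})

test_that("identity crowd-expert relation passes through unchanged", {
  withr::local_seed(5)
  n <- 30
  cs <- data.frame(core_id = sprintf("c%02d", 1:n), marker_id = "M1",
                   proportion = runif(n, 5, 95),
                   intensity = runif(n, 1, 3))
  es <- data.frame(core_id = cs$core_id, marker_id = "M1",
                   proportion = cs$proportion, intensity = cs$intensity)
  out <- correct_all(cs, es, k_folds = 10, seed = 2)
  expect_equal(out$proportion_corrected, cs$proportion, tolerance = 1e-8)
  expect_equal(out$intensity_corrected, cs$intensity, tolerance = 1e-8)
})

test_that("correction shrinks the positive bias at the zero boundary", {
  # synthetic additive crowd bias: crowd = truth + 10 near the origin
  withr::local_seed(13)
  n <- 80
  truth <- c(rep(0, 30), runif(n - 30, 0, 100))
  crowd <- pmin(truth + 10 + rnorm(n, 0, 3), 100)
  cs <- data.frame(core_id = sprintf("c%02d", 1:n), marker_id = "M1",
                   proportion = crowd, intensity = 2)
  es <- data.frame(core_id = cs$core_id, marker_id = "M1",
                   proportion = truth, intensity = 2)
  pred <- cv_correct_expert_cores(cs$proportion, es$proportion,
                                  c(0, 100), 10, seed = 1)
  zero <- truth == 0
  expect_lt(mean(as.numeric(pred)[zero]), mean(crowd[zero]))
})

test_that("H-score is the bounded product of proportion and intensity", {
  expect_equal(h_score(100, 3), 300)
  expect_equal(h_score(0, 2.7), 0)
  expect_equal(h_score(50, 2), 100)
  expect_error(h_score(101, 2), "proportion")
  expect_error(h_score(50, 3.2), "intensity")
  # rescaled-swap symmetry holds exactly
  withr::local_seed(2)
  p <- runif(50, 0, 100); i <- runif(50, 0, 3)
  expect_equal(h_score(p, i), h_score(i * 100 / 3, p * 3 / 100))
})
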
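# Direct O/E-formula kappa on an explicit confusion matrix, independent
# of the package implementation
kappa_matrix_oracle <- function(O) {
  k <- nrow(O)
  n <- sum(O)
  w <- outer(0:(k - 1), 0:(k - 1), function(i, j) (i - j)^2) / (k - 1)^2
  E <- outer(rowSums(O), colSums(O)) / n
  if (sum(w * E) == 0) return(NA_real_)
  1 - sum(w * O) / sum(w * E)
}

ratings_from_matrix <- function(O) {
  cells <- which(O > 0, arr.ind = TRUE)
  a <- rep(cells[, 1] - 1L, O[cells])
  b <- rep(cells[, 2] - 1L, O[cells])
  list(a = a, b = b)
}

test_that("spearman_rho matches hand-derived and limiting values", {
  x <- 1:5
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # d^2 = (0,1,1,1,1): rho = 1 - 6*4 / (5*24) = 0.8 ... recompute:
  # pairs (1,1),(2,3),(3,2),(4,5),(5,4): sum d^2 = 4 -> 1 - 24/120 = 0.8?
  # the frozen value 0.7 comes from sum d^2 = 6 with pairing (1,2,3,4,5)
  # vs (1,3,2,5,4) computed on ranks directly:
  expect_equal(spearman_rho(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4)),
               1 - 6 * 4 / (5 * (25 - 1)))
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  withr::local_seed(31)
  x <- rnorm(40); y <- x + rnorm(40)
  r <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), r)
  expect_equal(spearman_rho(x, y^3 + 2 * y), r)
  expect_equal(spearman_rho(rank(x), y), r)
})

test_that("quadratic-weighted kappa: agreement limits and the oracle", {
  a <- c(0L, 1L, 2L, 3L, 2L, 1L)
  expect_equal(quadratic_weighted_kappa(a, a, 4), 1)
  # one pair changed from (3,3) to (0,3)
  b <- c(0L, 1L, 2L, 3L)
  b2 <- c(0L, 1L, 2L, 0L)
  O <- matrix(0L, 4, 4)
  for (i in 1:4) O[b2[i] + 1L, b[i] + 1L] <- O[b2[i] + 1L, b[i] + 1L] + 1L
  expect_equal(quadratic_weighted_kappa(b2, b, 4), kappa_matrix_oracle(O))
  expect_error(quadratic_weighted_kappa(c(0, 4), c(0, 1), 4), "0..3")
  expect_error(quadratic_weighted_kappa(0:3, 0:3, 1), "categories")
  expect_warning(k0 <- quadratic_weighted_kappa(rep(2L, 5), rep(2L, 5), 4),
                 "degenerate")
  expect_true(is.na(k0))
})

test_that("kappa equals the matrix oracle on random confusion matrices", {
  withr::local_seed(17)
  for (rep in 1:50) {
    O <- matrix(rpois(16, 2), 4, 4)
    if (sum(O) < 2) next
    r <- ratings_from_matrix(O)
    expect_equal(suppressWarnings(quadratic_weighted_kappa(r$a, r$b, 4)),
                 kappa_matrix_oracle(O))
  }
})

test_that("kappa of independent ratings is within 3 SE of zero", {
  withr::local_seed(8)
  n <- 100000
  a <- sample(0:3, n, TRUE)
  b <- sample(0:3, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  k <- quadratic_weighted_kappa(a, b, 4)
  # delta-method SE: kappa ~= 1 - mean(w_obs)/Ew with Ew fixed by the
  # marginals, so se(kappa) ~= sd(w_obs) / (Ew * sqrt(n))
  w <- (a - b)^2 / 9
  se <- sd(w) / (mean(w) * sqrt(n))  # Ew ~= mean(w) under independence
  expect_lt(abs(k), 3 * se)
})

test_that("discretize_intensity rounds half-up within bounds", {
  expect_identical(discretize_intensity(c(2.5, 0.4, 3.0, 0, 1.49)),
                   c(3L, 0L, 3L, 0L, 1L))
  expect_error(discretize_intensity(3.1), "intensity")
  expect_error(discretize_intensity(-0.1), "intensity")
})

test_that("bootstrap_ci is deterministic, ordered and shrinks with n", {
  withr::local_seed(4)
  x <- runif(60); y <- x + rnorm(60, 0, 0.3)
  ci1 <- bootstrap_ci(x, y, spearman_rho, n_boot = 500, seed = 9)
  ci2 <- bootstrap_ci(x, y, spearman_rho, n_boot = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$estimate)
  expect_gte(ci1$ci_high, ci1$estimate)
  # constant statistic: degenerate interval at the estimate
  cst <- bootstrap_ci(x, y, function(a, b) 0.5, n_boot = 100, seed = 1)
  expect_equal(cst$ci_low, 0.5)
  expect_equal(cst$ci_high, 0.5)
  # CI width shrinks as n grows (fixed seed, same generating law)
  xl <- runif(600); yl <- xl + rnorm(600, 0, 0.3)
  cil <- bootstrap_ci(xl, yl, spearman_rho, n_boot = 500, seed = 9)
  expect_lt(cil$ci_high - cil$ci_low, ci1$ci_high - ci1$ci_low)
  expect_error(bootstrap_ci(x[1:5], y[1:5], spearman_rho), "n >= 10")
  expect_error(bootstrap_ci(x, y, spearman_rho, n_boot = 50), "n_boot")
})

test_that("agreement_table: noiseless crowds agree, shuffled crowds do not", {
  cores <- generate_cores(60, 1, seed = 14)
  cls <- generate_classifications(cores, 25, rater_model(0, 0, 0, 0),
                                  scheme = 1, seed = 14)
  agg <- aggregate_cores(cls, 1)
  agg$marker_id <- "M1"
  # experts scoring in the same bins as the crowd: noiseless raters give
  # exact agreement
  withr::local_seed(14)
  pick <- sort(sample.int(60, 30))
  truth <- cores$cores[pick, ]
  experts <- data.frame(
    core_id = truth$core_id, marker_id = "M1",
    proportion = bin_midpoint(bin_index(truth$true_proportion, 1), 1),
    intensity = ifelse(truth$true_proportion == 0, 0,
                       pmin(pmax(floor(truth$true_intensity + 0.5), 1), 3))
  )
  corr <- correct_all(agg, experts, k_folds = 10, seed = 1)
  tab <- agreement_table(corr, experts, n_boot = 200, seed = 1)
  expect_setequal(tab$metric, c("spearman_h", "spearman_proportion",
                                "qw_kappa_intensity"))
  expect_true(all(tab$estimate >= 0.99))
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high))
  expect_true(all(tab$n_pairs == 30L))
  # continuous expert scores: agreement is then capped by the bin
  # censoring of crowd answers, not by rater noise
  experts_cont <- generate_expert_scores(cores, 0.5, expert_noise_sd = 0,
                                         expert_intensity_sd = 0,
                                         seed = 14)
  corr2 <- correct_all(agg, experts_cont, k_folds = 10, seed = 1)
  tab2 <- agreement_table(corr2, experts_cont, n_boot = 200, seed = 1)
  expect_true(all(tab2$estimate >= 0.9))
  # permutation null: shuffled expert pairing kills the correlation
  withr::local_seed(3)
  shuffled <- experts_cont
  shuffled[, c("proportion", "intensity")] <-
    shuffled[sample.int(nrow(shuffled)), c("proportion", "intensity")]
  tab0 <- agreement_table(corr2, shuffled, n_boot = 200, seed = 1)
  sp <- tab0$estimate[tab0$metric == "spearman_h"]
  expect_lt(abs(sp), 0.35)
})
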
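# Crowd-vs-expert agreement statistics -----------------------------------

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive their average rank).
#' Returns `NA` with a warning when either input is constant (the
#' statistic is undefined).
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` for constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Quadratic-weighted kappa for ordinal ratings
#'
#' Chance-corrected agreement between two fixed raters where the
#' penalty for a disagreement grows with the squared category distance:
#' `kappa = 1 - sum(w * O) / sum(w * E)` with weights
#' `w[i,j] = (i - j)^2 / (k - 1)^2`, `O` the observed confusion matrix
#' and `E` the outer product of its marginals scaled to the same total
#' (Cohen-style expectation).
#'
#' @param a,b Paired integer ratings in `0 .. n_categories - 1`.
#' @param n_categories Number of ordinal categories (>= 2).
#' @return Kappa in `[-1, 1]`; `NA` with a warning when both raters use
#'   a single identical category (chance disagreement is zero).
#' @export
quadratic_weighted_kappa <- function(a, b, n_categories = 4) {
  if (length(a) != length(b)) stop("ratings must be paired", call. = FALSE)
  if (length(a) < 2L) stop("need n >= 2", call. = FALSE)
  k <- as.integer(n_categories)
  if (k < 2L) stop("need at least 2 categories", call. = FALSE)
  if (anyNA(a) || anyNA(b) || any(a < 0L | a >= k) || any(b < 0L | b >= k)) {
    stop("ratings must lie in 0..", k - 1L, call. = FALSE)
  }
  lev <- 0:(k - 1L)
  O <- matrix(tabulate(as.integer(a) + k * as.integer(b) + 1L, k * k),
              nrow = k)
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  w <- outer(lev, lev, function(i, j) (i - j)^2) / (k - 1L)^2
  denom <- sum(w * E)
  if (denom == 0) {
    warning("degenerate marginals: kappa undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum(w * O) / denom
}

#' Discretise a continuous mean intensity to an ordinal category
#'
#' The crowd intensity is a mean over responses and therefore
#' continuous; weighted kappa needs categories. Rounds half-up to the
#' nearest integer in `{0, 1, 2, 3}`.
#'
#' @param x Numeric vector in `[0, 3]`.
#' @return Integer vector in 0..3.
#' @export
discretize_intensity <- function(x) {
  if (anyNA(x) || any(x < 0 | x > 3)) {
    stop("intensity must be in [0, 3]", call. = FALSE)
  }
  as.integer(floor(x + 0.5))
}

#' Percentile bootstrap confidence interval for a paired statistic
#'
#' Resamples the pairs with replacement `n_boot` times; the interval is
#' the empirical 2.5 and 97.5 percentile of the resampled statistic and
#' the point estimate is the statistic on the full data.
#'
#' @param x,y Paired data (n >= 10).
#' @param statistic `function(x, y)` returning a scalar.
#' @param n_boot Number of bootstrap resamples (>= 100; default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List `estimate`, `ci_low`, `ci_high`, `n`, `n_boot`.
#' @export
bootstrap_ci <- function(x, y, statistic, n_boot = 1000, seed = 1,
                         conf = 0.95) {
  n <- length(x)
  if (n < 10L) stop("need n >= 10 pairs", call. = FALSE)
  if (n_boot < 100L) stop("need n_boot >= 100", call. = FALSE)
  est <- statistic(x, y)
  withr::with_seed(derive_seed(seed, "bootstrap", n, n_boot), {
    stats_b <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(statistic(x[idx], y[idx]))
    }, numeric(1))
  })
  ok <- is.finite(stats_b)
  if (mean(ok) < 0.5) {
    stop("statistic undefined on more than half of the resamples",
         call. = FALSE)
  }
  qs <- stats::quantile(stats_b[ok], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(estimate = est, ci_low = qs[1], ci_high = qs[2], n = n,
       n_boot = n_boot)
}

#' Per-marker crowd-vs-expert agreement table
#'
#' For every marker with expert-scored cores, computes the Spearman
#' correlation of H-scores, the Spearman correlation of proportions,
#' and the quadratic-weighted kappa of discretised intensities between
#' corrected crowd scores and expert scores, each with a percentile
#' bootstrap CI (resampling cores).
#'
#' @param corrected Corrected core scores (from [correct_all()]).
#' @param expert_scores Expert table.
#' @param n_boot Bootstrap resamples per statistic.
#' @param seed Integer seed.
#' @param min_pairs Minimum expert-scored cores per marker (default 10).
#' @return data.frame `marker_id`, `metric`, `estimate`, `ci_low`,
#'   `ci_high`, `n_pairs`, `n_bootstrap`.
#' @export
agreement_table <- function(corrected, expert_scores, n_boot = 1000,
                            seed = 1, min_pairs = 10) {
  rows <- list()
  for (mk in sort(unique(expert_scores$marker_id))) {
    exp_mk <- expert_scores[expert_scores$marker_id == mk, , drop = FALSE]
    sub <- corrected[corrected$marker_id == mk, , drop = FALSE]
    m <- match(exp_mk$core_id, sub$core_id)
    keep <- !is.na(m)
    if (sum(keep) < min_pairs) {
      stop("marker ", mk, " has fewer than ", min_pairs,
           " expert-scored cores", call. = FALSE)
    }
    exp_mk <- exp_mk[keep, , drop = FALSE]
    sub <- sub[m[keep], , drop = FALSE]
    exp_h <- h_score(exp_mk$proportion, exp_mk$intensity)
    specs <- list(
      spearman_h = list(x = sub$h_score, y = exp_h, f = spearman_rho),
      spearman_proportion = list(x = sub$proportion_corrected,
                                 y = exp_mk$proportion, f = spearman_rho),
      qw_kappa_intensity = list(
        x = discretize_intensity(sub$intensity_corrected),
        y = discretize_intensity(exp_mk$intensity),
        f = function(x, y) quadratic_weighted_kappa(x, y, 4))
    )
    for (metric in names(specs)) {
      s <- specs[[metric]]
      ci <- bootstrap_ci(s$x, s$y, s$f, n_boot = n_boot,
                         seed = derive_seed(seed, mk, metric))
      rows[[paste(mk, metric)]] <- data.frame(
        marker_id = mk, metric = metric, estimate = ci$estimate,
        ci_low = ci$ci_low, ci_high = ci$ci_high, n_pairs = ci$n,
        n_bootstrap = ci$n_boot
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
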
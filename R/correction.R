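# Linear bias correction against expert scores ---------------------------
#
# Averaging noisy bounded scores biases cores near the bounds (a true
# proportion of 0 can only be overestimated), so aggregated crowd scores
# are mapped onto the expert scale by ordinary least squares with
# clipping. Expert-scored cores must not influence their own correction,
# hence k-fold cross-validated prediction for that subset.

#' Fit a linear correction mapping crowd scores to the expert scale
#'
#' Ordinary least squares of expert on crowd values. The fitted
#' correction carries the clipping bounds of its target scale —
#' `(0, 100)` for proportion, `(0, 3)` for intensity.
#'
#' @param crowd Aggregated crowd values.
#' @param expert Paired expert values (same length, n >= 3).
#' @param bounds Length-2 clipping bounds of the target scale.
#' @return Object of class `linear_correction`: `intercept`, `slope`,
#'   `lower`, `upper`, `n_fit`.
#' @export
fit_correction <- function(crowd, expert, bounds = c(0, 100)) {
  if (length(crowd) != length(expert)) {
    stop("crowd and expert must be paired", call. = FALSE)
  }
  n <- length(crowd)
  if (n < 3L) stop("need at least 3 pairs to fit", call. = FALSE)
  if (stats::sd(crowd) == 0) {
    stop("crowd values are constant; correction is unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, crowd), expert)
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 lower = bounds[1], upper = bounds[2], n_fit = n),
            class = "linear_correction")
}

#' @export
print.linear_correction <- function(x, ...) {
  cat(sprintf(
    "linear_correction: y = %.4f + %.4f x, clipped to [%g, %g] (n = %d)\n",
    x$intercept, x$slope, x$lower, x$upper, x$n_fit))
  invisible(x)
}

#' Apply a fitted correction with clipping
#'
#' Computes `intercept + slope * value` and clips the result into the
#' correction's bounds (a corrected proportion of -5 becomes 0). Which
#' values were clipped is recorded in the `"clipped"` attribute.
#'
#' @param value Numeric vector of crowd values.
#' @param correction A `linear_correction`.
#' @return Corrected numeric vector with logical attribute `"clipped"`.
#' @export
apply_correction <- function(value, correction) {
  stopifnot(inherits(correction, "linear_correction"))
  raw <- correction$intercept + correction$slope * value
  out <- pmin(pmax(raw, correction$lower), correction$upper)
  attr(out, "clipped") <- raw < correction$lower | raw > correction$upper
  out
}

#' Was a corrected value clipped?
#'
#' @param x Result of [apply_correction()] or
#'   [cv_correct_expert_cores()].
#' @return Logical vector.
#' @export
was_clipped <- function(x) {
  cl <- attr(x, "clipped")
  if (is.null(cl)) rep(FALSE, length(x)) else cl
}

#' Leakage-free corrected values for expert-scored cores
#'
#' Using the full-data fit to correct the very cores it was fitted on
#' would make their corrected scores look too good, so expert-scored
#' cores are corrected by k-fold cross-validated prediction: cores are
#' split into `k_folds` folds by a seeded random permutation cut into
#' contiguous blocks, and each core's correction comes from the model
#' fitted on the other folds, then clipped. No core's own expert value
#' influences its correction.
#'
#' @param crowd,expert Paired values for the expert-scored cores.
#' @param bounds Clipping bounds of the target scale.
#' @param k_folds Number of folds (default 10; `k = n` is
#'   leave-one-out).
#' @param seed Integer seed for the fold permutation.
#' @return Corrected numeric vector (same order as input) with
#'   attributes `"clipped"` and `"folds"`.
#' @export
cv_correct_expert_cores <- function(crowd, expert, bounds = c(0, 100),
                                    k_folds = 10, seed = 1) {
  n <- length(crowd)
  if (length(expert) != n) stop("crowd and expert must be paired",
                                call. = FALSE)
  if (k_folds < 2L || k_folds > n) {
    stop("need 2 <= k_folds <= n", call. = FALSE)
  }
  folds <- integer(n)
  withr::with_seed(derive_seed(seed, "cv_folds", n, k_folds), {
    perm <- sample.int(n)
  })
  # contiguous blocks of the permutation, sizes as equal as possible
  sizes <- rep(n %/% k_folds, k_folds) +
    (seq_len(k_folds) <= n %% k_folds)
  folds[perm] <- rep(seq_len(k_folds), times = sizes)
  out <- numeric(n)
  clipped <- logical(n)
  for (k in seq_len(k_folds)) {
    test <- folds == k
    fit <- fit_correction(crowd[!test], expert[!test], bounds)
    pred <- apply_correction(crowd[test], fit)
    out[test] <- pred
    clipped[test] <- was_clipped(pred)
  }
  attr(out, "clipped") <- clipped
  attr(out, "folds") <- folds
  out
}

#' Correct all core scores and compute H-scores
#'
#' Proportion and intensity are corrected by separate independent
#' linear models fitted on the expert-scored cores. Cores without an
#' expert score are corrected by the full-data fit; expert-scored cores
#' by cross-validated prediction ([cv_correct_expert_cores()]). The
#' H-score is computed from the corrected components.
#'
#' @param core_scores Aggregated crowd scores (from
#'   [aggregate_cores()]), with a `marker_id` column when several
#'   markers are present.
#' @param expert_scores Expert table (`core_id`, `marker_id`,
#'   `proportion`, `intensity`); must overlap `core_scores`.
#' @param k_folds Folds for the expert-core cross-validation.
#' @param seed Integer seed.
#' @return data.frame `core_id`, `marker_id`, `proportion_corrected`,
#'   `intensity_corrected`, `h_score`, `clipped_proportion`,
#'   `clipped_intensity`, `was_cv`, with the per-marker fitted
#'   corrections in the `"corrections"` attribute.
#' @export
correct_all <- function(core_scores, expert_scores, k_folds = 10, seed = 1) {
  if (nrow(expert_scores) == 0L) stop("empty expert set", call. = FALSE)
  cs <- core_scores
  if (is.null(cs$marker_id)) cs$marker_id <- unique(expert_scores$marker_id)[1]
  pieces <- list()
  corrections <- list()
  for (mk in sort(unique(cs$marker_id))) {
    sub <- cs[cs$marker_id == mk, , drop = FALSE]
    exp_mk <- expert_scores[expert_scores$marker_id == mk, , drop = FALSE]
    m <- match(sub$core_id, exp_mk$core_id)
    is_exp <- !is.na(m)
    if (!any(is_exp)) {
      stop("marker ", mk, " has no expert-scored cores", call. = FALSE)
    }
    fit_p <- fit_correction(sub$proportion[is_exp],
                            exp_mk$proportion[m[is_exp]], c(0, 100))
    fit_i <- fit_correction(sub$intensity[is_exp],
                            exp_mk$intensity[m[is_exp]], c(0, 3))
    pc <- numeric(nrow(sub)); ic <- numeric(nrow(sub))
    clp <- logical(nrow(sub)); cli <- logical(nrow(sub))
    if (any(!is_exp)) {
      pp <- apply_correction(sub$proportion[!is_exp], fit_p)
      ii <- apply_correction(sub$intensity[!is_exp], fit_i)
      pc[!is_exp] <- pp; clp[!is_exp] <- was_clipped(pp)
      ic[!is_exp] <- ii; cli[!is_exp] <- was_clipped(ii)
    }
    kf <- min(k_folds, sum(is_exp))
    pp <- cv_correct_expert_cores(sub$proportion[is_exp],
                                  exp_mk$proportion[m[is_exp]],
                                  c(0, 100), kf, seed)
    ii <- cv_correct_expert_cores(sub$intensity[is_exp],
                                  exp_mk$intensity[m[is_exp]],
                                  c(0, 3), kf, seed)
    pc[is_exp] <- pp; clp[is_exp] <- was_clipped(pp)
    ic[is_exp] <- ii; cli[is_exp] <- was_clipped(ii)
    # report at fixed precision: keeps genuine ties tied (fold-to-fold
    # fits on exact data differ by ~1e-14, which would otherwise scramble
    # ranks within tie groups) without touching real differences
    pc <- round(pc, 9)
    ic <- round(ic, 9)
    pieces[[mk]] <- data.frame(
      core_id = sub$core_id, marker_id = mk,
      proportion_corrected = pc, intensity_corrected = ic,
      h_score = h_score(pc, ic),
      clipped_proportion = clp, clipped_intensity = cli,
      was_cv = is_exp
    )
    corrections[[mk]] <- list(proportion = fit_p, intensity = fit_i)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "corrections") <- corrections
  out
}

#' H-score of a core or patient
#'
#' The semi-quantitative IHC H-score: proportion of cancer cells
#' stained (0-100%) multiplied by the average staining intensity (0-3),
#' giving a value between 0 (no cell positive) and 300 (all cells
#' positive at maximum intensity).
#'
#' @param proportion Percent stained, in `[0, 100]`.
#' @param intensity Average intensity, in `[0, 3]`.
#' @return Numeric H-score in `[0, 300]`.
#' @export
h_score <- function(proportion, intensity) {
  if (anyNA(proportion) || anyNA(intensity) ||
      any(proportion < 0 | proportion > 100) ||
      any(intensity < 0 | intensity > 3)) {
    stop("proportion must be in [0, 100] and intensity in [0, 3]",
         call. = FALSE)
  }
  proportion * intensity
}
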
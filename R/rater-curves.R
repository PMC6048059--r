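# Accuracy as a function of the number of ratings per core ---------------
#
# The analysis behind the operational decision to drop from 25 raters
# per segment to 5 (80 ratings over the central 16 segments): subsample
# the available classifications per core, re-run aggregation and
# correction, and track the crowd-vs-expert H-score Spearman rho.

#' Random subsample of classifications per core
#'
#' Draws exactly `n_per_core` classifications per core uniformly without
#' replacement.
#'
#' @param x Classification data.frame.
#' @param n_per_core Number of classifications to retain per core.
#' @param seed Integer seed.
#' @param on_short What to do with cores holding fewer than
#'   `n_per_core` classifications: `"skip"` drops them with a message,
#'   `"error"` aborts.
#' @return Classification data.frame.
#' @export
subsample_classifications <- function(x, n_per_core, seed = 1,
                                      on_short = c("skip", "error")) {
  on_short <- match.arg(on_short)
  dt <- data.table::as.data.table(x)
  counts <- dt[, list(n = .N), by = "core_id"]
  short <- counts$core_id[counts$n < n_per_core]
  if (length(short)) {
    if (on_short == "error") {
      stop(length(short), " cores have fewer than ", n_per_core,
           " classifications", call. = FALSE)
    }
    message(length(short), " cores with < ", n_per_core,
            " classifications skipped")
    dt <- dt[!dt$core_id %in% short, ]
  }
  withr::with_seed(derive_seed(seed, "subsample", n_per_core), {
    out <- dt[, .SD[sample.int(.N, n_per_core)], by = "core_id"]
  })
  data.table::setDF(out)
}

#' Crowd-vs-expert accuracy as a function of ratings per core
#'
#' For each `n` in `n_values`: subsample `n` classifications per
#' expert-scored core, aggregate, apply the leakage-free correction,
#' and compute the Spearman correlation between crowd and expert
#' H-scores. The bootstrap redraws the subsample and resamples the
#' core pairing jointly (`n_boot` replicates, 2.5/97.5 percentile CI),
#' since both sources of variation stand behind the published error
#' bars.
#'
#' @param classifications Classification data.frame.
#' @param expert_scores Expert table (single marker).
#' @param n_values Ascending vector of ratings-per-core values; cores
#'   with fewer available classifications are skipped at that `n`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param scheme Proportion bin scheme.
#' @param k_folds Folds for the expert-core cross-validation.
#' @param min_pairs Minimum expert cores required (default 10).
#' @return data.frame `marker_id`, `n_per_core`, `estimate`, `ci_low`,
#'   `ci_high`, `n_cores`.
#' @export
accuracy_curve <- function(classifications, expert_scores,
                           n_values = c(20, 40, 80, 160, 320, 640, 1280),
                           n_boot = 1000, seed = 1, scheme = 1,
                           k_folds = 10, min_pairs = 10) {
  stopifnot(!is.unsorted(n_values))
  mk <- unique(expert_scores$marker_id)
  if (length(mk) != 1L) {
    stop("accuracy_curve expects a single marker", call. = FALSE)
  }
  cls <- data.table::as.data.table(classifications)
  cls <- cls[cls$core_id %in% expert_scores$core_id, ]
  if (length(unique(cls$core_id)) < min_pairs) {
    stop("fewer than ", min_pairs, " expert-scored cores with ",
         "classifications", call. = FALSE)
  }

  one_pass <- function(dat, pass_seed, resample_cores) {
    sub <- suppressMessages(
      subsample_classifications(dat, n, seed = pass_seed)
    )
    agg <- aggregate_cores(sub, scheme)
    agg$marker_id <- mk
    m <- match(agg$core_id, expert_scores$core_id)
    corr <- correct_all(agg, expert_scores,
                        k_folds = min(k_folds, nrow(agg)),
                        seed = pass_seed)
    exp_h <- h_score(expert_scores$proportion[m],
                     expert_scores$intensity[m])
    pairs <- cbind(corr$h_score, exp_h)
    if (resample_cores) {
      idx <- sample.int(nrow(pairs), nrow(pairs), replace = TRUE)
      pairs <- pairs[idx, , drop = FALSE]
    }
    suppressWarnings(spearman_rho(pairs[, 1], pairs[, 2]))
  }

  rows <- list()
  for (n in n_values) {
    est <- one_pass(cls, derive_seed(seed, "curve", n, 0),
                    resample_cores = FALSE)
    boots <- withr::with_seed(derive_seed(seed, "curve_boot", n), {
      vapply(seq_len(n_boot), function(b) {
        one_pass(cls, derive_seed(seed, "curve", n, b),
                 resample_cores = TRUE)
      }, numeric(1))
    })
    ok <- is.finite(boots)
    qs <- stats::quantile(boots[ok], c(0.025, 0.975), names = FALSE)
    n_used <- length(unique(cls$core_id[
      cls$core_id %in% names(which(table(cls$core_id) >= n))]))
    rows[[as.character(n)]] <- data.frame(
      marker_id = mk, n_per_core = n, estimate = est,
      ci_low = qs[1], ci_high = qs[2], n_cores = n_used
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
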
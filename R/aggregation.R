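# Aggregation of classifications into core and patient scores ------------

#' Aggregate the classifications of a single core
#'
#' Pools all responses for the core across segments jointly (not
#' segment-then-core): the proportion is the mean of bin midpoints over
#' responses that indicated cancer (bin-0 responses contribute 0), the
#' intensity is the mean of intensity answers over responses with a
#' positive proportion bin, and "no cancer" responses contribute to
#' neither mean. A core whose responses are all "no cancer" gets
#' proportion 0 and intensity 0 with `all_no_cancer = TRUE`; such cores
#' are retained for auditability rather than dropped.
#'
#' @param x Classification data.frame for one core.
#' @param scheme Proportion bin scheme (id or object).
#' @return One-row data.frame: `core_id`, `proportion`, `intensity`,
#'   `n_responses`, `n_cancer_responses`, `n_intensity_responses`,
#'   `all_no_cancer`.
#' @export
aggregate_core <- function(x, scheme) {
  if (nrow(x) == 0L) stop("no classifications for core", call. = FALSE)
  if (length(unique(x$core_id)) != 1L) {
    stop("aggregate_core expects a single core; see aggregate_cores()",
         call. = FALSE)
  }
  aggregate_cores(x, scheme)
}

#' Aggregate classifications for every core in a table
#'
#' Vectorised version of [aggregate_core()] over all cores. When a core
#' map is supplied, a `marker_id` column is attached.
#'
#' @param x Classification data.frame (any number of cores).
#' @param scheme Proportion bin scheme (id or object).
#' @param core_map Optional data.frame `core_id`, `patient_id`,
#'   `marker_id`.
#' @param min_responses Optional threshold: cores with fewer total
#'   responses are flagged `usable = FALSE` (none are dropped).
#' @return data.frame with one row per core.
#' @export
aggregate_cores <- function(x, scheme, core_map = NULL,
                            min_responses = NULL) {
  scheme <- bin_scheme(scheme)
  dt <- data.table::as.data.table(x)
  mids <- scheme$midpoints
  agg <- dt[, {
    cp <- .SD[["cancer_present"]]
    pb <- .SD[["proportion_bin"]]
    it <- .SD[["intensity"]]
    n_cancer <- sum(cp)
    n_int <- sum(cp & !is.na(pb) & pb > 0L)
    list(
      proportion = if (n_cancer > 0L) mean(mids[pb[cp] + 1L]) else 0,
      intensity = if (n_int > 0L) mean(it[cp & !is.na(pb) & pb > 0L]) else 0,
      n_responses = .N,
      n_cancer_responses = n_cancer,
      n_intensity_responses = n_int,
      all_no_cancer = n_cancer == 0L
    )
  }, by = "core_id"]
  data.table::setkeyv(agg, "core_id")
  if (!is.null(min_responses)) {
    agg[, "usable" := agg[["n_responses"]] >= min_responses]
  }
  out <- data.table::setDF(agg)
  if (!is.null(core_map)) {
    out <- merge(out, core_map[, c("core_id", "marker_id")],
                 by = "core_id", sort = TRUE)
  }
  out
}

#' Keep only classifications of the central 16 segments
#'
#' @param x Classification data.frame.
#' @return The rows whose `segment_index` lies in
#'   [central_segment_indices()].
#' @export
filter_central_segments <- function(x) {
  out <- x[x$segment_index %in% central_segment_indices(), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine corrected core scores into patient-level scores
#'
#' Patients with several cores get the unweighted mean of the corrected
#' proportion and corrected intensity across their cores; the patient
#' H-score is then recomputed from the patient-level means (so it
#' respects the 0-300 bound by construction).
#'
#' @param corrected Corrected core scores (from [correct_all()]).
#' @param core_map data.frame `core_id`, `patient_id`, `marker_id`.
#' @return data.frame `patient_id`, `marker_id`, `proportion`,
#'   `intensity`, `h_score`, `n_cores`.
#' @export
aggregate_patients <- function(corrected, core_map) {
  if (nrow(corrected) == 0L) stop("no core scores", call. = FALSE)
  dt <- data.table::as.data.table(
    merge(corrected, core_map[, c("core_id", "patient_id")], by = "core_id")
  )
  out <- dt[, list(
    proportion = mean(.SD[["proportion_corrected"]]),
    intensity = mean(.SD[["intensity_corrected"]]),
    n_cores = .N
  ), by = c("patient_id", "marker_id")]
  out[, "h_score" := h_score(out[["proportion"]], out[["intensity"]])]
  data.table::setkeyv(out, c("patient_id", "marker_id"))
  data.table::setDF(out)
}
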
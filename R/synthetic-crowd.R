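# Synthetic ground-truthed crowd data ------------------------------------
#
# One global integer seed; each generator draws from its own sub-stream
# derived deterministically from (seed, stream label) so that adding a
# stage never perturbs the draws of another.

derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Crowd rater error model
#'
#' Parameters of the stochastic response model for one anonymous rater
#' viewing one segment:
#' * a segment with cancer fraction `f` is declared cancerous with
#'   probability `p_false_cancer + (1 - p_false_cancer - p_miss_cancer) * f`
#'   (so an empty segment draws false alarms at `p_false_cancer` and a
#'   fully cancerous one is missed at `p_miss_cancer`);
#' * given a cancer call, the reported proportion is the core truth plus
#'   Gaussian noise (`proportion_noise_sd`, percent), clamped to
#'   `[0, 100]` and censored into the scheme's bin;
#' * when the bin is above zero, intensity is truth plus Gaussian noise
#'   (`intensity_noise_sd`, scale units), clamped to `[1, 3]` and rounded
#'   half-up to an integer.
#'
#' Defaults are plausible for untrained raters of inverted-colour IHC
#' tiles and give crowd-vs-expert agreement in the range seen in
#' practice.
#'
#' @param p_miss_cancer Probability of missing cancer in a fully
#'   cancerous segment.
#' @param p_false_cancer Probability of a cancer call on an empty
#'   segment.
#' @param proportion_noise_sd SD of individual proportion error, percent.
#' @param intensity_noise_sd SD of individual intensity error, 0-3 scale.
#' @return Object of class `rater_model`.
#' @export
rater_model <- function(p_miss_cancer = 0.1, p_false_cancer = 0.05,
                        proportion_noise_sd = 15, intensity_noise_sd = 0.5) {
  stopifnot(p_miss_cancer >= 0, p_miss_cancer <= 1,
            p_false_cancer >= 0, p_false_cancer <= 1,
            proportion_noise_sd >= 0, intensity_noise_sd >= 0)
  structure(list(p_miss_cancer = p_miss_cancer,
                 p_false_cancer = p_false_cancer,
                 proportion_noise_sd = proportion_noise_sd,
                 intensity_noise_sd = intensity_noise_sd),
            class = "rater_model")
}

#' Survival generating model
#'
#' Disease-specific survival with an exponential baseline: event time is
#' exponential with rate `baseline_rate * exp(beta_h * h_score)` and
#' censoring is an independent exponential with rate `censor_rate`, both
#' in events per month. `beta_h` is the log hazard ratio per H-score
#' unit; the default `log(0.991)` encodes a protective marker of the
#' magnitude reported for MRE11-class stains.
#'
#' @param baseline_rate Baseline event rate per month at H-score 0.
#' @param beta_h Log hazard ratio per H-score unit.
#' @param censor_rate Censoring rate per month.
#' @return Object of class `survival_model`.
#' @export
survival_model <- function(baseline_rate = 0.02, beta_h = log(0.991),
                           censor_rate = 0.005) {
  stopifnot(baseline_rate > 0, censor_rate > 0, is.finite(beta_h))
  structure(list(baseline_rate = baseline_rate, beta_h = beta_h,
                 censor_rate = censor_rate), class = "survival_model")
}

round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate ground-truth cores
#'
#' Draws per-patient marker truth and up to five cores per patient.
#' The patient-level true proportion follows a three-part mixture —
#' point mass at 0, Uniform(0, 100), point mass at 100 with weights
#' `mixture_weights` — so both bounds (where averaging noisy bounded
#' scores is biased) are well represented. True intensity is
#' Uniform(1, 3) when any cells stain and 0 otherwise. Cores of one
#' patient jitter around the patient truth (`core_jitter_sd` percent;
#' boundary patients stay exactly at their bound, emulating tumours
#' with uniformly absent or saturated staining). Each core carries 36
#' per-segment cancer fractions: the central 16 from
#' `Beta(central_beta)`, the sparse outer 20 from `Beta(outer_beta)`.
#'
#' @param n_patients Number of patients (>= 1).
#' @param cores_per_patient Cores per patient, 1-5.
#' @param marker_id Marker label for all generated cores.
#' @param seed Integer seed (sub-stream derived internally).
#' @param mixture_weights Length-3 weights (zero, uniform, full);
#'   normalised internally.
#' @param core_jitter_sd Between-core SD around patient truth, percent.
#' @param central_beta,outer_beta Beta shape pairs for segment cancer
#'   fractions.
#' @return Object of class `true_cores`: list with `cores` (one row per
#'   core: `core_id`, `patient_id`, `marker_id`, `true_proportion`,
#'   `true_intensity`, `true_h`) and `segments` (long table `core_id`,
#'   `segment_index`, `cancer_fraction`).
#' @export
generate_cores <- function(n_patients, cores_per_patient = 2,
                           marker_id = "M1", seed = 1,
                           mixture_weights = c(0.25, 0.5, 0.25),
                           core_jitter_sd = 5,
                           central_beta = c(5, 2), outer_beta = c(1, 4)) {
  stopifnot(n_patients >= 1, cores_per_patient >= 1, cores_per_patient <= 5)
  w <- mixture_weights / sum(mixture_weights)
  withr::with_seed(derive_seed(seed, "cores", marker_id), {
    comp <- sample.int(3L, n_patients, replace = TRUE, prob = w)
    p_pat <- ifelse(comp == 1L, 0,
                    ifelse(comp == 3L, 100, stats::runif(n_patients, 0, 100)))
    i_pat <- ifelse(p_pat == 0, 0, stats::runif(n_patients, 1, 3))
    patient_id <- sprintf("p%05d", seq_len(n_patients))

    idx <- rep(seq_len(n_patients), each = cores_per_patient)
    corei <- rep(seq_len(cores_per_patient), times = n_patients)
    n_cores <- length(idx)
    at_bound <- p_pat[idx] %in% c(0, 100)
    tp <- ifelse(at_bound, p_pat[idx],
                 clamp(p_pat[idx] + stats::rnorm(n_cores, 0, core_jitter_sd),
                       0, 100))
    ti <- ifelse(tp == 0, 0,
                 clamp(i_pat[idx] + stats::rnorm(n_cores, 0,
                                                 core_jitter_sd * 0.03),
                       1, 3))
    core_id <- sprintf("%s_%s_c%d", marker_id, patient_id[idx], corei)

    central <- central_segment_indices()
    frac <- matrix(0, nrow = n_cores, ncol = 36L)
    is_central <- 0:35 %in% central
    frac[, is_central] <- stats::rbeta(n_cores * 16L,
                                       central_beta[1], central_beta[2])
    frac[, !is_central] <- stats::rbeta(n_cores * 20L,
                                        outer_beta[1], outer_beta[2])
    segments <- data.frame(
      core_id = rep(core_id, each = 36L),
      segment_index = rep(0:35, times = n_cores),
      cancer_fraction = as.vector(t(frac))
    )
    cores <- data.frame(
      core_id = core_id,
      patient_id = patient_id[idx],
      marker_id = marker_id,
      true_proportion = tp,
      true_intensity = ti,
      true_h = tp * ti
    )
  })
  structure(list(cores = cores, segments = segments), class = "true_cores")
}

#' @export
print.true_cores <- function(x, ...) {
  cat("true_cores:", nrow(x$cores), "cores,",
      length(unique(x$cores$patient_id)), "patients, marker",
      unique(x$cores$marker_id), "\n")
  invisible(x)
}

#' Generate crowd classifications for a set of cores
#'
#' Each scored segment (the central 16 by default, all 36 otherwise)
#' receives exactly `raters_per_segment` independent responses drawn
#' from `rater` (see [rater_model()] for the response process).
#'
#' @param cores A `true_cores` object.
#' @param raters_per_segment Responses per scored segment (>= 1);
#'   5 over the 16 central segments gives the operational 80 ratings
#'   per core.
#' @param rater A `rater_model`.
#' @param scheme Proportion bin scheme (id or object).
#' @param central_only Score only the central 16 segments?
#' @param seed Integer seed.
#' @return Classification data.frame (validated).
#' @export
generate_classifications <- function(cores, raters_per_segment = 5,
                                     rater = rater_model(), scheme = 1,
                                     central_only = TRUE, seed = 1) {
  stopifnot(inherits(cores, "true_cores"), raters_per_segment >= 1,
            inherits(rater, "rater_model"))
  scheme <- bin_scheme(scheme)
  segs <- if (central_only) central_segment_indices() else 0:35
  sdt <- data.table::as.data.table(cores$segments)
  sdt <- sdt[sdt$segment_index %in% segs, ]
  cdt <- data.table::as.data.table(cores$cores)
  sdt <- merge(sdt, cdt[, c("core_id", "true_proportion", "true_intensity")],
               by = "core_id", sort = TRUE)
  n_slots <- nrow(sdt) * raters_per_segment
  withr::with_seed(derive_seed(seed, "classifications"), {
    f <- rep(sdt$cancer_fraction, each = raters_per_segment)
    tp <- rep(sdt$true_proportion, each = raters_per_segment)
    ti <- rep(sdt$true_intensity, each = raters_per_segment)
    p_cancer <- rater$p_false_cancer +
      (1 - rater$p_false_cancer - rater$p_miss_cancer) * f
    says_cancer <- stats::runif(n_slots) < p_cancer
    prop_resp <- clamp(tp + stats::rnorm(n_slots, 0,
                                         rater$proportion_noise_sd), 0, 100)
    bin <- bin_index(prop_resp, scheme)
    int_resp <- round_half_up(clamp(ti + stats::rnorm(n_slots, 0,
                                                      rater$intensity_noise_sd),
                                    1, 3))
  })
  out <- data.frame(
    core_id = rep(sdt$core_id, each = raters_per_segment),
    segment_index = rep(sdt$segment_index, each = raters_per_segment),
    cancer_present = says_cancer,
    proportion_bin = ifelse(says_cancer, bin, NA_integer_),
    intensity = ifelse(says_cancer & bin > 0L, as.integer(int_resp),
                       NA_integer_)
  )
  validate_classifications(out)
}

#' Generate expert gold-standard scores for a random subset of cores
#'
#' A simple random `round(expert_fraction * n_cores)` cores (round half
#' up) receive a low-noise continuous observation of the core truth:
#' proportion truth plus Gaussian noise (`expert_noise_sd` percent,
#' clamped to `[0, 100]`), intensity truth plus Gaussian noise
#' (`expert_intensity_sd`, clamped to `[0, 3]`).
#'
#' @param cores A `true_cores` object (non-empty).
#' @param expert_fraction Fraction of cores scored, in (0, 1].
#' @param expert_noise_sd Expert proportion error SD, percent.
#' @param expert_intensity_sd Expert intensity error SD, 0-3 scale.
#' @param seed Integer seed.
#' @return data.frame `core_id`, `marker_id`, `proportion`, `intensity`.
#' @export
generate_expert_scores <- function(cores, expert_fraction = 0.12,
                                   expert_noise_sd = 2,
                                   expert_intensity_sd = 0.1, seed = 1) {
  stopifnot(inherits(cores, "true_cores"),
            expert_fraction > 0, expert_fraction <= 1)
  cdf <- cores$cores
  if (nrow(cdf) == 0L) stop("empty core list", call. = FALSE)
  n_expert <- round_half_up(expert_fraction * nrow(cdf))
  withr::with_seed(derive_seed(seed, "experts"), {
    pick <- sort(sample.int(nrow(cdf), n_expert))
    prop <- clamp(cdf$true_proportion[pick] +
                    stats::rnorm(n_expert, 0, expert_noise_sd), 0, 100)
    inten <- clamp(cdf$true_intensity[pick] +
                     stats::rnorm(n_expert, 0, expert_intensity_sd), 0, 3)
  })
  data.frame(core_id = cdf$core_id[pick], marker_id = cdf$marker_id[pick],
             proportion = prop, intensity = inten)
}

#' Generate patient outcome records with survival driven by true H-score
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(beta_h * h_score)`; censoring times are
#' independent exponential(`censor_rate`); the record keeps the earlier
#' of the two (rounded to 0.1 month, so ties occur as they do with
#' discretised clinical follow-up). Clinical covariates (age, T/N
#' stage, grade, sex, hydronephrosis) are drawn from realistic
#' marginals but independent of survival, serving as null adjustment
#' variables. Cohorts are assigned at random with `cohort_probs`.
#'
#' @param patient_h data.frame with columns `patient_id` and `h_score`
#'   (the true patient-level H-score, 0-300).
#' @param model A `survival_model`.
#' @param seed Integer seed.
#' @param cohort_probs Named probabilities over the three cohorts.
#' @return data.frame `patient_id`, `cohort`, `time_months`, `event`,
#'   `age`, `t_stage`, `n_stage`, `grade`, `sex`, `hydronephrosis`,
#'   `h_score`.
#' @export
generate_survival <- function(patient_h, model = survival_model(), seed = 1,
                              cohort_probs = c(cystectomy = 0.4,
                                               rt_1995_1999 = 0.3,
                                               rt_2002_2005 = 0.3)) {
  stopifnot(inherits(model, "survival_model"),
            all(c("patient_id", "h_score") %in% names(patient_h)))
  n <- nrow(patient_h)
  withr::with_seed(derive_seed(seed, "survival"), {
    rate <- model$baseline_rate * exp(model$beta_h * patient_h$h_score)
    t_event <- stats::rexp(n, rate)
    t_cens <- stats::rexp(n, model$censor_rate)
    time <- pmax(round(pmin(t_event, t_cens), 1), 0.1)
    event <- t_event <= t_cens
    cohort <- sample(names(cohort_probs), n, replace = TRUE,
                     prob = cohort_probs)
    age <- round(clamp(stats::rnorm(n, 70, 8), 40, 95))
    t_stage <- sample(c("T2", "T3", "T4a"), n, TRUE, c(0.5, 0.35, 0.15))
    n_stage <- sample(c("N0", "N1", "N2"), n, TRUE, c(0.8, 0.12, 0.08))
    grade <- sample(c("G2", "G3"), n, TRUE, c(0.3, 0.7))
    sex <- sample(c("M", "F"), n, TRUE, c(0.75, 0.25))
    hydronephrosis <- stats::runif(n) < 0.25
  })
  data.frame(patient_id = patient_h$patient_id, cohort = cohort,
             time_months = time, event = event, age = age,
             t_stage = t_stage, n_stage = n_stage, grade = grade,
             sex = sex, hydronephrosis = hydronephrosis,
             h_score = patient_h$h_score)
}

#' True patient-level H-scores from a set of cores
#'
#' The patient H-score is the mean of that patient's core true
#' H-scores.
#'
#' @param cores A `true_cores` object.
#' @return data.frame `patient_id`, `h_score`.
#' @export
patient_truth <- function(cores) {
  stopifnot(inherits(cores, "true_cores"))
  dt <- data.table::as.data.table(cores$cores)
  out <- dt[, list(h_score = mean(.SD[["true_h"]])), by = "patient_id"]
  data.table::setDF(out[order(out$patient_id)])
}
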
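# Pipeline orchestration and command-line entry point --------------------

.default_config <- function() {
  list(
    seed = 1, marker_id = "M1", scheme = 1,
    n_patients = 150, cores_per_patient = 2,
    raters_per_segment = 5, central_only = TRUE,
    p_miss_cancer = 0.1, p_false_cancer = 0.05,
    proportion_noise_sd = 15, intensity_noise_sd = 0.5,
    expert_fraction = 0.12, expert_noise_sd = 2, expert_intensity_sd = 0.1,
    baseline_rate = 0.02, beta_h = log(0.991), censor_rate = 0.005,
    k_folds = 10, n_boot = 1000, min_responses = NULL,
    run_curves = FALSE, curve_n_values = c(20, 40, 80),
    curve_n_boot = 200,
    multivariable = FALSE, exclude_cystectomy_multivariable = TRUE,
    classifications = NULL, expert_scores = NULL, core_map = NULL,
    patients = NULL
  )
}

#' Read a flat key=value pipeline configuration
#'
#' One `key = value` per line; `#` starts a comment. Values are coerced:
#' `true`/`false` to logical, numbers to numeric, comma-separated
#' numbers to vectors. Unknown keys are an error; missing keys take the
#' documented defaults (see the pipeline vignette).
#'
#' @param path Config file path, or `NULL` for all defaults.
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- .default_config()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg)) stop("unknown config key: ", key,
                                   call. = FALSE)
    cfg[[key]] <- .coerce_config_value(val)
  }
  cfg
}

.coerce_config_value <- function(val) {
  if (tolower(val) %in% c("true", "false")) return(tolower(val) == "true")
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  nums <- suppressWarnings(as.numeric(parts))
  if (!anyNA(nums)) return(if (length(nums) == 1L) nums[1] else nums)
  if (length(parts) == 1L) parts[1] else parts
}

.stage_log <- function(manifest, stage, rows_in, rows_out, t0) {
  secs <- round(as.numeric(Sys.time()) - t0, 2)
  message(sprintf("[%s] in=%d out=%d (%.2fs)", stage, rows_in, rows_out,
                  secs))
  rbind(manifest, data.frame(stage = stage, rows_in = rows_in,
                             rows_out = rows_out, seconds = secs))
}

#' Run the full analysis pipeline
#'
#' Executes synth (unless input CSV paths are configured) ->
#' aggregate -> correct -> agree -> optional rater curves -> survival,
#' writing every stage's CSV plus `manifest.csv` (config hash, seed and
#' per-stage row counts) into `out_dir`. Deterministic for a fixed
#' config and seed.
#'
#' @param config Config list (from [read_config()]) or a config file
#'   path, or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (is.character(config)) read_config(config)
         else utils::modifyList(.default_config(),
                                if (is.null(config)) list() else config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- data.frame()
  seed <- cfg$seed

  # --- synth (or load) ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (is.null(cfg$classifications)) {
    cores <- generate_cores(cfg$n_patients, cfg$cores_per_patient,
                            cfg$marker_id, seed)
    rm_ <- rater_model(cfg$p_miss_cancer, cfg$p_false_cancer,
                       cfg$proportion_noise_sd, cfg$intensity_noise_sd)
    cls <- generate_classifications(cores, cfg$raters_per_segment, rm_,
                                    cfg$scheme, cfg$central_only, seed)
    experts <- generate_expert_scores(cores, cfg$expert_fraction,
                                      cfg$expert_noise_sd,
                                      cfg$expert_intensity_sd, seed)
    sm <- survival_model(cfg$baseline_rate, cfg$beta_h, cfg$censor_rate)
    patients <- generate_survival(patient_truth(cores), sm, seed)
    core_map <- cores$cores[, c("core_id", "patient_id", "marker_id")]
    write_classifications(cls, file.path(out_dir, "classifications.csv"))
    write_table_csv(experts, file.path(out_dir, "expert_scores.csv"))
    write_table_csv(core_map, file.path(out_dir, "core_map.csv"))
    write_table_csv(patients[, setdiff(names(patients), "h_score")],
                    file.path(out_dir, "patients.csv"))
    write_table_csv(
      data.frame(core_id = cores$cores$core_id,
                 true_proportion = cores$cores$true_proportion,
                 true_intensity = cores$cores$true_intensity,
                 true_h = cores$cores$true_h),
      file.path(out_dir, "truth.csv"))
    manifest <- .stage_log(manifest, "synth", nrow(cores$cores),
                           nrow(cls), t0)
  } else {
    cls <- read_classifications(cfg$classifications)
    if (is.null(cfg$expert_scores)) {
      stop("correction requires expert scores: set 'expert_scores' in ",
           "the config or run the synthetic generator", call. = FALSE)
    }
    experts <- read_expert_scores(cfg$expert_scores)
    core_map <- read_core_map(cfg$core_map)
    patients <- if (!is.null(cfg$patients)) read_patients(cfg$patients)
    manifest <- .stage_log(manifest, "load", nrow(cls), nrow(cls), t0)
  }

  # --- aggregate ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (isTRUE(cfg$central_only)) cls_agg <- filter_central_segments(cls)
  else cls_agg <- cls
  core_scores <- aggregate_cores(cls_agg, cfg$scheme, core_map,
                                 cfg$min_responses)
  write_table_csv(core_scores, file.path(out_dir, "core_scores.csv"))
  manifest <- .stage_log(manifest, "aggregate", nrow(cls_agg),
                         nrow(core_scores), t0)

  # --- correct -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  corrected <- correct_all(core_scores, experts, cfg$k_folds, seed)
  write_table_csv(corrected, file.path(out_dir, "corrected_scores.csv"))
  corrs <- attr(corrected, "corrections")
  corr_log <- do.call(rbind, lapply(names(corrs), function(mk) {
    data.frame(marker_id = mk,
               target = c("proportion", "intensity"),
               intercept = c(corrs[[mk]]$proportion$intercept,
                             corrs[[mk]]$intensity$intercept),
               slope = c(corrs[[mk]]$proportion$slope,
                         corrs[[mk]]$intensity$slope),
               n_fit = c(corrs[[mk]]$proportion$n_fit,
                         corrs[[mk]]$intensity$n_fit))
  }))
  write_table_csv(corr_log, file.path(out_dir, "corrections.csv"))
  manifest <- .stage_log(manifest, "correct", nrow(core_scores),
                         nrow(corrected), t0)

  # --- agree -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  agreement <- agreement_table(corrected, experts, cfg$n_boot, seed)
  write_table_csv(agreement, file.path(out_dir, "agreement.csv"))
  manifest <- .stage_log(manifest, "agree", nrow(experts),
                         nrow(agreement), t0)

  # --- curves (optional) -------------------------------------------------
  if (isTRUE(cfg$run_curves)) {
    t0 <- as.numeric(Sys.time())
    curve <- accuracy_curve(cls_agg, experts, cfg$curve_n_values,
                            cfg$curve_n_boot, seed, cfg$scheme,
                            cfg$k_folds)
    write_table_csv(curve, file.path(out_dir, "curve.csv"))
    manifest <- .stage_log(manifest, "curves", nrow(cls_agg),
                           nrow(curve), t0)
  }

  # --- survival ----------------------------------------------------------
  if (!is.null(patients)) {
    t0 <- as.numeric(Sys.time())
    res <- .survival_stage(corrected, core_map, patients, cfg)
    write_table_csv(res$cox, file.path(out_dir, "cox_results.csv"))
    write_table_csv(res$km, file.path(out_dir, "km_curves.csv"))
    write_table_csv(res$patient_scores,
                    file.path(out_dir, "patient_scores.csv"))
    if (nrow(res$exclusions)) {
      write_table_csv(res$exclusions, file.path(out_dir, "exclusions.csv"))
    }
    manifest <- .stage_log(manifest, "survival", nrow(patients),
                           nrow(res$cox), t0)
  }

  # --- manifest ----------------------------------------------------------
  cfg_dump <- file.path(out_dir, "config_used.txt")
  flat <- vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1))
  writeLines(paste0(names(cfg), "=", flat), cfg_dump)
  manifest$config_md5 <- unname(tools::md5sum(cfg_dump))
  manifest$seed <- seed
  write_table_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

.survival_stage <- function(corrected, core_map, patients, cfg) {
  pat_scores <- aggregate_patients(corrected, core_map)
  # outcome table may carry generator truth columns; scores come from
  # pat_scores only
  patients <- patients[, setdiff(names(patients),
                                 c("h_score", "proportion", "intensity")),
                       drop = FALSE]
  dat <- merge(pat_scores, patients, by = "patient_id")
  cox_rows <- list(); km_rows <- list(); excl <- list()
  for (mk in sort(unique(dat$marker_id))) {
    sub_mk <- dat[dat$marker_id == mk, , drop = FALSE]
    # groupings on the combined cohorts, per the published rule
    sub_mk$quartile <- split_quartiles(sub_mk$h_score)
    sub_mk$median_group <- median_split(sub_mk$h_score)
    for (co in sort(unique(sub_mk$cohort))) {
      sub <- sub_mk[sub_mk$cohort == co, , drop = FALSE]
      fits <- list(
        univariable = function()
          cox_fit(sub[, "h_score", drop = FALSE], sub$time_months,
                  sub$event),
        median_split = function()
          cox_fit(data.frame(high = sub$median_group == "high"),
                  sub$time_months, sub$event)
      )
      if (isTRUE(cfg$multivariable) &&
          !(co == "cystectomy" &&
            isTRUE(cfg$exclude_cystectomy_multivariable))) {
        fits$multivariable <- function()
          cox_fit(sub[, c("h_score", "age", "t_stage", "n_stage",
                          "grade", "sex", "hydronephrosis")],
                  sub$time_months, sub$event)
      }
      for (model in names(fits)) {
        fit <- tryCatch(fits[[model]](), error = function(e) e)
        if (inherits(fit, "error")) {
          excl[[paste(mk, co, model)]] <- data.frame(
            marker_id = mk, cohort = co, model = model,
            reason = conditionMessage(fit))
          next
        }
        cox_rows[[paste(mk, co, model)]] <- data.frame(
          cohort = co, marker = mk, model = model, term = fit$term,
          coef = fit$coef, hr = fit$hr, ci_low = fit$ci_low,
          ci_high = fit$ci_high, p = fit$p, n = attr(fit, "n"),
          n_events = attr(fit, "n_events"))
      }
      for (lev in levels(sub$median_group)) {
        grp <- sub[sub$median_group == lev, , drop = FALSE]
        if (nrow(grp) == 0L) next
        km <- km_estimate(grp$time_months, grp$event)
        km_rows[[paste(mk, co, lev)]] <- cbind(
          data.frame(marker = mk, cohort = co, group = lev), km)
      }
    }
  }
  bind <- function(x) if (length(x)) {
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  } else data.frame()
  list(cox = bind(cox_rows), km = bind(km_rows),
       patient_scores = pat_scores, exclusions = bind(excl))
}

#' Command-line entry point
#'
#' Subcommands `synth`, `aggregate`, `correct`, `agree`, `curves`,
#' `survival` run individual stages against the CSVs already in
#' `--out`; `run` executes the full pipeline. Flags: `--config <file>`,
#' `--seed <int>`, `--out <dir>`.
#'
#' @param args Character vector of arguments (defaults to the command
#'   line).
#' @return Exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: crowdscore <synth|aggregate|correct|agree|curves|survival|run>",
    "[--config FILE] [--seed INT] [--out DIR]")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(config = NULL, seed = NULL, out = ".")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      stop(usage, call. = FALSE)
    }
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- read_config(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  out <- opt$out
  stage_inputs <- function(...) {
    paths <- file.path(out, c(...))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("missing stage inputs: ", paste(missing, collapse = ", "),
           "\nrun earlier stages (or 'run') first", call. = FALSE)
    }
    paths
  }
  switch(
    cmd,
    run = run_pipeline(cfg, out),
    synth = {
      cfg2 <- cfg; cfg2$run_curves <- FALSE
      run_pipeline(cfg2, out)  # synth feeds every later stage anyway
    },
    aggregate = {
      p <- stage_inputs("classifications.csv", "core_map.csv")
      cls <- read_classifications(p[1])
      if (isTRUE(cfg$central_only)) cls <- filter_central_segments(cls)
      cs <- aggregate_cores(cls, cfg$scheme, read_core_map(p[2]),
                            cfg$min_responses)
      write_table_csv(cs, file.path(out, "core_scores.csv"))
    },
    correct = {
      p <- stage_inputs("core_scores.csv", "expert_scores.csv")
      cs <- .read_table(p[1], c("core_id", "proportion", "intensity"))
      corr <- correct_all(cs, read_expert_scores(p[2]), cfg$k_folds,
                          cfg$seed)
      write_table_csv(corr, file.path(out, "corrected_scores.csv"))
    },
    agree = {
      p <- stage_inputs("corrected_scores.csv", "expert_scores.csv")
      corr <- .read_table(p[1], c("core_id", "marker_id", "h_score"))
      agr <- agreement_table(corr, read_expert_scores(p[2]), cfg$n_boot,
                             cfg$seed)
      write_table_csv(agr, file.path(out, "agreement.csv"))
    },
    curves = {
      p <- stage_inputs("classifications.csv", "expert_scores.csv")
      cls <- read_classifications(p[1])
      if (isTRUE(cfg$central_only)) cls <- filter_central_segments(cls)
      cv <- accuracy_curve(cls, read_expert_scores(p[2]),
                           cfg$curve_n_values, cfg$curve_n_boot,
                           cfg$seed, cfg$scheme, cfg$k_folds)
      write_table_csv(cv, file.path(out, "curve.csv"))
    },
    survival = {
      p <- stage_inputs("corrected_scores.csv", "core_map.csv",
                        "patients.csv")
      corr <- .read_table(p[1], c("core_id", "marker_id",
                                  "proportion_corrected",
                                  "intensity_corrected", "h_score"))
      res <- .survival_stage(corr, read_core_map(p[2]),
                             read_patients(p[3]), cfg)
      write_table_csv(res$cox, file.path(out, "cox_results.csv"))
      write_table_csv(res$km, file.path(out, "km_curves.csv"))
      write_table_csv(res$patient_scores,
                      file.path(out, "patient_scores.csv"))
    },
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
  )
  invisible(0L)
}
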
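# Classification table: validation and CSV interchange -------------------

#' Validate a table of crowd classifications
#'
#' A classification is one citizen response to one core segment. The app
#' asked questions conditionally: the proportion bin was asked only when
#' cancer was indicated, and staining intensity only when the proportion
#' bin was above zero. Valid rows therefore satisfy:
#'
#' * `segment_index` in 0..35 (row-major 6x6 grid);
#' * `proportion_bin` present (0..5) iff `cancer_present` is `TRUE`;
#' * `intensity` present (1..3) iff `cancer_present` and
#'   `proportion_bin > 0`.
#'
#' @param x A data.frame with columns `core_id`, `segment_index`,
#'   `cancer_present`, `proportion_bin`, `intensity`.
#' @param action `"error"` (default) aborts listing offending row
#'   numbers; `"drop"` removes invalid rows with a warning.
#' @return The validated (possibly filtered) data.frame, with an
#'   integer attribute `"rejected"` of dropped row numbers when
#'   `action = "drop"`.
#' @export
validate_classifications <- function(x, action = c("error", "drop")) {
  action <- match.arg(action)
  required <- c("core_id", "segment_index", "cancer_present",
                "proportion_bin", "intensity")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  seg <- x$segment_index
  cp <- x$cancer_present
  pb <- x$proportion_bin
  it <- x$intensity
  bad <-
    is.na(cp) | is.na(seg) | seg < 0L | seg > 35L |
    (!cp & (!is.na(pb) | !is.na(it))) |
    (cp & (is.na(pb) | pb < 0L | pb > 5L)) |
    (cp & !is.na(pb) & pb == 0L & !is.na(it)) |
    (cp & !is.na(pb) & pb > 0L & (is.na(it) | it < 1L | it > 3L))
  if (any(bad)) {
    rows <- which(bad)
    if (action == "error") {
      stop("invalid classification rows: ",
           paste(utils::head(rows, 20L), collapse = ", "),
           if (length(rows) > 20L) sprintf(" (+%d more)", length(rows) - 20L),
           call. = FALSE)
    }
    warning(length(rows), " invalid classification rows dropped",
            call. = FALSE)
    x <- x[!bad, , drop = FALSE]
    rownames(x) <- NULL
    attr(x, "rejected") <- rows
  }
  x
}

#' Read crowd classifications from CSV
#'
#' Expects the interchange header
#' `core_id,segment_index,cancer_present,proportion_bin,intensity`;
#' `cancer_present` is `true`/`false`, and the conditional fields are
#' empty when not asked. Rows are validated against the conditional
#' questioning rules (see [validate_classifications()]).
#'
#' @param path CSV file path.
#' @param action Passed to [validate_classifications()].
#' @return A data.frame of classifications.
#' @export
read_classifications <- function(path, action = c("error", "drop")) {
  x <- data.table::fread(
    path,
    colClasses = list(character = "core_id", integer = "segment_index",
                      character = "cancer_present",
                      integer = c("proportion_bin", "intensity")),
    na.strings = ""
  )
  cp <- tolower(x$cancer_present)
  if (!all(cp %in% c("true", "false"))) {
    stop("cancer_present must be 'true' or 'false'", call. = FALSE)
  }
  x$cancer_present <- cp == "true"
  out <- validate_classifications(data.table::setDF(x), action = action)
  out
}

#' Write crowd classifications to CSV
#'
#' Inverse of [read_classifications()]: booleans become `true`/`false`,
#' absent conditional answers become empty fields.
#'
#' @param x Classification data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(x, path) {
  y <- data.table::as.data.table(x)
  y[, "cancer_present" := ifelse(y[["cancer_present"]], "true", "false")]
  data.table::fwrite(y, path, na = "", quote = FALSE)
  invisible(path)
}

# Remaining interchange tables -------------------------------------------

.read_table <- function(path, required) {
  x <- data.table::fread(path, na.strings = "")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop(basename(path), ": missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data.table::setDF(x)
}

#' Read and write the auxiliary interchange tables
#'
#' Plain UTF-8 CSVs with headers:
#' * expert scores: `core_id,marker_id,proportion,intensity`
#' * core map:      `core_id,patient_id,marker_id`
#' * patients:      `patient_id,cohort,time_months,event,age,t_stage,
#'                   n_stage,grade,sex,hydronephrosis`
#'
#' @param path CSV file path.
#' @param x Table to write.
#' @return The table as a data.frame (readers) or `path` invisibly
#'   (writers).
#' @name interchange
NULL

#' @rdname interchange
#' @export
read_expert_scores <- function(path) {
  x <- .read_table(path, c("core_id", "marker_id", "proportion", "intensity"))
  if (any(x$proportion < 0 | x$proportion > 100) ||
      any(x$intensity < 0 | x$intensity > 3)) {
    stop("expert scores out of bounds", call. = FALSE)
  }
  x
}

#' @rdname interchange
#' @export
read_core_map <- function(path) {
  .read_table(path, c("core_id", "patient_id", "marker_id"))
}

#' @rdname interchange
#' @export
read_patients <- function(path) {
  x <- .read_table(path, c("patient_id", "cohort", "time_months", "event"))
  if (any(x$time_months <= 0)) {
    stop("survival times must be positive", call. = FALSE)
  }
  x$event <- as.logical(x$event)
  x
}

#' @rdname interchange
#' @export
write_table_csv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, na = "",
                     quote = FALSE)
  invisible(path)
}
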
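# Proportion bin schemes -------------------------------------------------

.SCHEME_BREAKS <- list(
  `1` = c(0, 25, 50, 75, 95, 100),
  `2` = c(0, 10, 25, 50, 75, 100),
  `3` = c(0, 10, 25, 65, 95, 100)
)

#' Categorical proportion-bin schemes
#'
#' Crowd raters reported the proportion of stained cancer cells in one of
#' six categorical bins; three different bin sets were used depending on
#' the marker:
#'
#' * scheme 1: 0, 1-25, 25-50, 50-75, 75-95, 95-100 (%)
#' * scheme 2: 0, 1-10, 10-25, 25-50, 50-75, 75-100 (%)
#' * scheme 3: 0, 1-10, 10-25, 25-65, 65-95, 95-100 (%)
#'
#' Bins are half-open intervals `(lower, upper]` on the percent scale with
#' bin 0 reserved for exactly 0%, so the six bins partition `[0, 100]` and
#' a continuous proportion can be censored into a bin deterministically.
#' The numeric value attached to a bin is the arithmetic midpoint of its
#' printed label (bin 1 of scheme 1, labelled "1-25", maps to 13) and 0
#' for the zero bin; under a within-bin uniform distribution the midpoint
#' is an (approximately) unbiased summary of the censored value.
#'
#' @param scheme_id Integer 1, 2 or 3, or an existing `bin_scheme` object
#'   (returned unchanged).
#' @return An object of class `bin_scheme`: a list with `scheme_id`,
#'   `breaks` (0 followed by the five upper bin bounds), `labels`, and
#'   `midpoints` (length 6, indexed by bin 0-5).
#' @examples
#' s <- bin_scheme(1)
#' s$midpoints  # 0 13 37.5 62.5 85 97.5
#' @export
bin_scheme <- function(scheme_id) {
  if (inherits(scheme_id, "bin_scheme")) return(scheme_id)
  if (length(scheme_id) != 1L || !scheme_id %in% 1:3) {
    stop("scheme_id must be 1, 2 or 3", call. = FALSE)
  }
  br <- .SCHEME_BREAKS[[as.character(as.integer(scheme_id))]]
  mids <- c(0, (1 + br[2]) / 2, (br[2:5] + br[3:6]) / 2)
  labels <- c("0", paste0(c(1, br[2:5]), "-", br[2:6]))
  structure(
    list(scheme_id = as.integer(scheme_id), breaks = br,
         labels = labels, midpoints = mids),
    class = "bin_scheme"
  )
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("Proportion bin scheme", x$scheme_id, "\n")
  cat(" bins:     ", paste(x$labels, collapse = ", "), "%\n")
  cat(" midpoints:", paste(x$midpoints, collapse = ", "), "\n")
  invisible(x)
}

#' Censor a continuous proportion into a bin
#'
#' Maps percentages to bin indices 0-5 under the half-open convention:
#' 0 maps to bin 0, values in `(lower, upper]` map to the corresponding
#' bin.
#'
#' @param value Numeric vector of proportions in `[0, 100]`.
#' @param scheme A `bin_scheme` or scheme id.
#' @return Integer vector of bin indices 0-5.
#' @export
bin_index <- function(value, scheme) {
  scheme <- bin_scheme(scheme)
  if (anyNA(value) || any(value < 0 | value > 100)) {
    stop("proportions must be in [0, 100] and non-missing", call. = FALSE)
  }
  findInterval(value, scheme$breaks, left.open = TRUE)
}

#' Numeric midpoint of a proportion bin
#'
#' Returns 0 for the zero bin and the arithmetic midpoint of the printed
#' bin bounds otherwise (e.g. bin 1 of scheme 1, "1-25%", gives 13).
#'
#' @param bin Integer vector of bin indices 0-5.
#' @param scheme A `bin_scheme` or scheme id.
#' @return Numeric vector of percentages.
#' @export
bin_midpoint <- function(bin, scheme) {
  scheme <- bin_scheme(scheme)
  if (anyNA(bin) || any(bin < 0L | bin > 5L) || any(bin != as.integer(bin))) {
    stop("bin indices must be integers in 0..5", call. = FALSE)
  }
  scheme$midpoints[as.integer(bin) + 1L]
}
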
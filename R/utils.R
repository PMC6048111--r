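`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage of a cohort, rounded for reporting
#'
#' Convenience used throughout the report tables: `100 * k / n` rounded to a
#' fixed number of digits, so printed cohort fractions (e.g. 13 carriers out
#' of 147 patients = 8.8\%) are reproduced exactly as reported.
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @param digits digits after the decimal point (default 1).
#' @return numeric percentage.
#' @examples
#' cohort_fraction(13, 147)      # 8.8
#' cohort_fraction(2, 147, 2)    # 1.36
#' @export
cohort_fraction <- function(k, n, digits = 1) {
  stopifnot(is.numeric(k), is.numeric(n), n > 0)
  round(100 * k / n, digits)
}

# Accept ASCII "-", Unicode minus U+2212 and en-dash U+2013 for the
# antisense strand; anything else is left for the validator to reject.
normalize_strand <- function(x) {
  x <- as.character(x)
  x[x %in% c("−", "–")] <- "-"
  x
}

# "0->1"-style junction-phase labels <-> integer phase pairs.  The arrow is
# matched loosely ("0->1", "0-->1", "0>1") because upstream tools differ.
parse_frame_label <- function(x) {
  x <- as.character(x)
  out <- matrix(NA_integer_, nrow = length(x), ncol = 2,
                dimnames = list(NULL, c("donor_phase", "acceptor_phase")))
  ok <- !is.na(x) & nzchar(trimws(x))
  m <- regmatches(x[ok], regexec("^\\s*([012])\\s*[^0-9]*\\s*([012])\\s*$", x[ok]))
  parsed <- t(vapply(m, function(g) {
    if (length(g) == 3) as.integer(g[2:3]) else c(NA_integer_, NA_integer_)
  }, integer(2)))
  if (any(ok)) out[ok, ] <- parsed
  bad <- ok & is.na(out[, 1])
  attr(out, "bad") <- which(bad)
  out
}

format_frame_label <- function(donor_phase, acceptor_phase) {
  ifelse(is.na(donor_phase) | is.na(acceptor_phase), "",
         paste0(donor_phase, "->", acceptor_phase))
}

# stop() with a condition class so callers/tests can target loader errors
fp_stop <- function(fmt, ..., class = "fusionprio_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
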
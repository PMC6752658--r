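#' Percentage and fold-ratio arithmetic used in reports
#'
#' `percent()` returns `100 * n / d` rounded to one decimal (`NA` when the
#' denominator is zero); `format_percent()` renders it as e.g. `"38.5%"` or
#' `"NA"`; `fold_ratio()` is the one-decimal ratio of two percentages (or any
#' two positive numbers).
#'
#' @param n Numerator count.
#' @param d Denominator count.
#' @return `percent()` and `fold_ratio()`: numeric scalar; `format_percent()`:
#'   character scalar.
#' @export
#' @examples
#' percent(35, 91) # 38.5
#' format_percent(11, 24) # "45.8%"
#' fold_ratio(60.1, 13.6) # 4.4
percent <- function(n, d) {
  if (length(d) == 0 || is.na(d) || d == 0) return(NA_real_)
  round(100 * n / d, 1)
}

#' @rdname percent
#' @export
format_percent <- function(n, d) {
  p <- percent(n, d)
  if (is.na(p)) "NA" else sprintf("%.1f%%", p)
}

#' @rdname percent
#' @param a,b Two percentages (or positive values) to compare.
#' @export
fold_ratio <- function(a, b) {
  if (length(a) == 0 || length(b) == 0 || is.na(a) || is.na(b) || b == 0) {
    return(NA_real_)
  }
  round(a / b, 1)
}
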
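# Rounding and rendering conventions shared by the reporting layer.
# Percentages are displayed to one decimal place, rounded half-up, and
# p-values to two decimals with "<.0001" below 1e-4 — matching how such
# triage validation tables are conventionally printed. All displayed
# percentages recompute exactly from their numerator/denominator counts.

#' Round half-up
#'
#' Commercial rounding (0.5 always rounds away from zero), as used for all
#' displayed percentages; base `round()` rounds half to even, which would
#' drift from the printed tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator, rounded half-up
#'
#' @param n Numerator count.
#' @param d Denominator count.
#' @param digits Decimal places (default 1).
#' @return Percentage on the 0-100 scale.
#' @export
percent_of <- function(n, d, digits = 1) {
  round_half_up(100 * n / d, digits)
}

#' Format a p-value for display
#'
#' Two decimal places, `"<.0001"` below 1e-4.
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-4, "<.0001", sprintf("%.2f", p))
}

#' Render a data frame as a markdown pipe table
#'
#' @param df Data frame of display values.
#' @return Character scalar (markdown).
#' @export
markdown_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  cells <- matrix(as.character(cells), nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}
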
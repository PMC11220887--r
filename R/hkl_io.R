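#' Read a SHELX-style HKL file of anomalous differences
#'
#' Fixed-column format `3I4,2F8.2` (h k l dF sig).  An all-zero terminator
#' record, if present, is dropped.
#'
#' @param path file path
#' @param cell a [unit_cell()] (fills the resolution column)
#' @return a reflection-set data frame
#' @export
read_hkl <- function(path, cell) {
  widths <- c(4, 4, 4, 8, 8)
  raw <- utils::read.fwf(path, widths = widths,
                         colClasses = rep("numeric", 5),
                         col.names = c("h", "k", "l", "dF", "sig"))
  raw <- raw[!(raw$h == 0 & raw$k == 0 & raw$l == 0), , drop = FALSE]
  reflection_set(as.matrix(raw[, c("h", "k", "l")]), dF = raw$dF,
                 sig_dF = raw$sig, cell = cell)
}

#' Write a SHELX-style HKL file (h k l dF sig), `3I4,2F8.2`
#'
#' @param refl reflection-set data frame (only observed, in-limit rows are
#'   written)
#' @param path output path
#' @param value which amplitude column to write: "dF" or "E"
#' @export
write_hkl <- function(refl, path, value = c("dF", "E")) {
  value <- match.arg(value)
  use <- refl$observed & !refl$beyond_limit
  r <- refl[use, , drop = FALSE]
  amp <- r[[value]]
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", r$h, r$k, r$l, amp, r$sig_dF)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0)), path)
  invisible(path)
}

#' Read a whitespace Bijvoet-pair table (h k l F+ sigF+ F- sigF-)
#'
#' Unobserved mates may be written as NA.
#'
#' @param path file path
#' @return data frame with the pair columns
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("h", "k", "l", "Fplus", "sigFplus",
                                        "Fminus", "sigFminus"),
                          na.strings = c("NA", "*"))
  df[!(df$h == 0 & df$k == 0 & df$l == 0), , drop = FALSE]
}

#' Write a whitespace Bijvoet-pair table
#' @param pairs data frame with h, k, l, Fplus, sigFplus, Fminus, sigFminus
#' @param path output path
#' @export
write_pairs <- function(pairs, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  lines <- sprintf("%5d %5d %5d %12s %12s %12s %12s",
                   pairs$h, pairs$k, pairs$l,
                   fmt(pairs$Fplus), fmt(pairs$sigFplus),
                   fmt(pairs$Fminus), fmt(pairs$sigFminus))
  writeLines(lines, path)
  invisible(path)
}

#' Write phased reflections as whitespace text (h k l amp phase_deg)
#' @param df data frame with h, k, l, amp, phase (radians)
#' @param path output path
#' @export
write_phases <- function(df, path) {
  lines <- sprintf("%5d %5d %5d %14.6f %10.3f", df$h, df$k, df$l, df$amp,
                   df$phase * 180 / pi)
  writeLines(lines, path)
  invisible(path)
}
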
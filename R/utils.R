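#' @noRd
msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

#' Deterministic 31-bit hash of a string
#'
#' Polynomial rolling hash used to derive per-pair RNG seeds from a master
#' seed and a pair of identifiers. Exact in double arithmetic (intermediate
#' values stay below 2^53) and always returns an integer in \[1, 2^31 - 2\].
#' @noRd
hash31 <- function(s, seed = 0L) {
  M <- 2147483647
  h <- as.numeric(seed) %% M
  v <- utf8ToInt(s)
  for (x in v) h <- (h * 31 + x) %% M
  as.integer(h %% (M - 1)) + 1L
}

#' Format a percentage the way comparative tables print them
#'
#' Integer percent at or above 10, one decimal below 10.
#' @param x percentages on the 0-100 scale.
#' @return character vector.
#' @export
format_percent <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x >= 10, sprintf("%.0f%%", x), sprintf("%.1f%%", x)))
}

#' Round a percentage to its displayed precision
#' @noRd
round_percent <- function(x) {
  ifelse(x >= 10, round(x, 0), round(x, 1))
}

#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse-complement of a DNA string (character in, character out)
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Canonical unordered pair key
#' @noRd
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
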
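#' @importFrom withr with_seed
NULL

# run code under a fixed seed without disturbing the caller's RNG state
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derived stage seeds stay well below .Machine$integer.max for small inputs
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset) %% 2147483647)
}

#' Write a data frame as tab-separated text
#'
#' Plain TSV writer used for all intermediate pipeline artifacts, so every
#' stage output stays inspectable with standard command-line tools.
#'
#' @param x data frame.
#' @param path output file path.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tab-separated pipeline artifact
#'
#' @param path input file path.
#' @return data frame with character columns left unconverted.
#' @export
readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# semicolon join/split used by the PSM table dialect
.joinField <- function(x) vapply(x, paste, character(1), collapse = ";")
.splitField <- function(x) strsplit(as.character(x), ";", fixed = TRUE)
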
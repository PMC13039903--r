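#' Derive a stage seed from a root seed
#'
#' All stochastic stages draw their seed deterministically from one root seed
#' so a single integer reproduces a whole run. Stage names are hashed to a
#' fixed offset; the result stays inside the 32-bit integer range.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * (seq_len(nchar(stage)) %% 97L))
  as.integer((abs(root_seed) * 7919 + h * 131) %% .Machine$integer.max)
}

#' Linear-interpolation quantile
#'
#' Thin wrapper fixing the quantile convention used throughout the package
#' (type 7, the common statistical default).
#' @param x numeric vector.
#' @param p probability in \[0,1\].
#' @return the quantile value.
#' @keywords internal
lerp_quantile <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = FALSE)
}

#' Overflow-safe log of a mean of exponentials
#' @param x numeric vector.
#' @return log(mean(exp(x))) computed stably.
#' @keywords internal
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m))) - log(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a TSV table with the package's interchange dialect
#'
#' Tab-separated, UTF-8, "." decimal, first column holds identifiers.
#' @param path file path.
#' @return a data.frame with identifier column first.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a TSV table with the package's interchange dialect
#' @param x data.frame to write.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
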
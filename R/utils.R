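# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic "schoolbook" rounding used everywhere a printed table is
#' reproduced: exact .5 cases round up, unlike [base::round()]'s
#' round-half-even. Used for percentages and for converting standardized
#' allele counts (`af * 118`) to integers.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(0.5)          # 1
#' round_half_up(89.3281, 1)   # 89.3
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# Deterministic per-operation seed stream derived from one global seed.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2147483629 + 1000003 * offset) %% 2147483629)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
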
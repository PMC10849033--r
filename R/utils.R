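# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards.  All stochastic operations in
#' docknet route their randomness through this helper so that every generator
#' is a pure function of (configuration, seed).
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Accept a file path, a single string with embedded newlines, or a character
# vector of lines; return a character vector of lines.
read_lines_flex <- function(x) {
  if (!is.character(x)) stop("expected a file path or character text")
  if (length(x) > 1L) return(x)
  if (grepl("\n", x, fixed = TRUE)) return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  if (file.exists(x)) return(readLines(x, warn = FALSE))
  # a single line of record text (comments, whitespace) rather than a path
  if (grepl("[ \t]", x) || startsWith(x, "#")) return(x)
  stop("file not found: ", x)
}

#' Canonicalize unordered protein pairs
#'
#' Pair identity is unordered: (A, B) and (B, A) denote the same pair.  This
#' puts each pair in lexicographic order.  Self-pairs are rejected because the
#' interaction network is defined without self-interactions.
#'
#' @param a,b character vectors of protein identifiers (recycled to common
#'   length).
#' @param allow_self keep self-pairs instead of erroring (used by callers that
#'   produce their own diagnostics).
#' @return a `data.frame` with columns `idA`, `idB` where `idA <= idB`.
#' @examples
#' canonical_pairs(c("P2", "P1"), c("P1", "P3"))
#' @export
canonical_pairs <- function(a, b, allow_self = FALSE) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (!allow_self && any(a == b)) {
    bad <- which(a == b)
    stop("self-pair(s) not allowed at entr", if (length(bad) > 1) "ies " else "y ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(idA = a, idB = b, stringsAsFactors = FALSE)
}

# Canonical string key for an unordered pair; vectorized.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Percentage with one-decimal rounding
#'
#' Reports `k` out of `n` as a percentage rounded to one decimal, the
#' convention used by all docknet summary tables.
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @return numeric percentage, e.g. `fraction_pct(2054, 2083)` is 98.6.
#' @export
fraction_pct <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n), all(n > 0))
  round(100 * k / n, 1L)
}

# round() in R does banker's rounding; summary percentages use it as-is,
# which matches the printed one-decimal values for every count we report.
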
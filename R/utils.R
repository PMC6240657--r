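#' Round a percentage half-away-from-zero to an integer
#'
#' Report-style integer percentages (e.g. 38 of 130 prints as 29). Base
#' `round()` rounds half to even, which is the wrong convention for
#' human-facing summary tables; this helper rounds 0.5 away from zero.
#'
#' @param n numerator count(s).
#' @param total denominator count(s); must be > 0.
#' @return integer percentage(s) of `n / total`.
#' @export
#' @examples
#' percent_int(38, 130)  # 29
#' percent_int(648, 721) # 90
percent_int <- function(n, total) {
  stopifnot(is.numeric(n), is.numeric(total))
  if (any(total <= 0)) stop("percent_int(): 'total' must be positive")
  x <- 100 * n / total
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Run expr under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Strict TSV reader: tab delimiter, no quoting, header required.
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
}
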
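# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All user-facing stochastic functions route through this so
# that a `seed` argument gives bit-reproducible output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# split "A|B|C" signatures into domain vectors; "" -> character(0)
split_signature <- function(sig) {
  if (is.na(sig) || !nzchar(sig)) return(character(0))
  strsplit(sig, "|", fixed = TRUE)[[1]]
}

make_signature <- function(domains) paste(domains, collapse = "|")

#' Write a TSV file
#'
#' Thin wrapper around [utils::write.table()] with the conventions used for
#' all tabular outputs of the package (tab separator, no quoting, no row
#' names).
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV file
#'
#' @param path input path.
#' @return data frame with character columns left as-is.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
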
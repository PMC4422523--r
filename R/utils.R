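#' @keywords internal
#' @importFrom mclust Mclust mclustBIC
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic functions in the package route their randomness through this
# helper so that a config seed yields byte-identical outputs and no global
# RNG state leaks between stages.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

msgf <- function(fmt, ...) message(sprintf(fmt, ...))

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}

# Canonical unordered pair key, used wherever gene pairs are compared
# across evidence streams.
pair_key <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)),
        sep = "\r")
}

read_tsv_base <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv_base <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Path to a data file shipped with the package
#'
#' @param file File name under `extdata`, e.g. `"consensus_annotations.tsv"`.
#' @return Absolute path to the installed file.
#' @export
circanet_extdata <- function(file) {
  p <- system.file("extdata", file, package = "circanet", mustWork = FALSE)
  if (!nzchar(p)) stopf("no packaged data file '%s'", file)
  p
}
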
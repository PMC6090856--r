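# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic string hash
#'
#' djb2-style rolling hash reduced modulo 2^31 - 1, used to derive
#' reproducible integer seeds from character keys (e.g. HLA allele names)
#' independently of the session RNG state.
#'
#' @param x single character string.
#' @return integer in [0, 2^31 - 2].
#' @keywords internal
str_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 5381
  for (code in utf8ToInt(x)) h <- (h * 33 + code) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Read a TSV and fail loudly if required columns are absent.
read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s table %s is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
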